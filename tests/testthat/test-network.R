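# Data model and I/O for IPD/AgD studies and the treatment network

test_that("IPD tables parse into per-study objects", {
  ipd <- read_ipd(tiny_ipd_df(),
                  schema = list(study = "study", treatment = "treatment",
                                outcome = "y",
                                covariates = c("age", "sex")))
  expect_length(ipd, 1L)
  expect_equal(nrow(ipd[[1]]$rows), 3L)
  expect_setequal(unique(ipd[[1]]$rows$treatment), c("A", "B"))
})

test_that("IPD validation names the offending column or row", {
  df <- tiny_ipd_df()
  expect_error(read_ipd(df, schema = list(study = "study",
                                          treatment = "trt",
                                          outcome = "y")), "trt")
  df2 <- df; df2$y[2] <- 2
  expect_error(read_ipd(df2, schema = list(study = "study",
                                           treatment = "treatment",
                                           outcome = "y")), "\\{0, 1\\}")
  df3 <- df; df3$age[3] <- NA
  expect_error(read_ipd(df3, schema = list(study = "study",
                                           treatment = "treatment",
                                           outcome = "y",
                                           covariates = c("age", "sex"))),
               "age.*row 3")
  expect_error(read_ipd(df[0, ], schema = list(study = "study",
                                               treatment = "treatment",
                                               outcome = "y")), "empty")
})

test_that("IPD write/read round-trips the table", {
  ipd <- read_ipd(tiny_ipd_df(),
                  schema = list(study = "study", treatment = "treatment",
                                outcome = "y",
                                covariates = c("age", "sex")))
  path <- file.path(tempdir(), "ipd_rt.csv")
  write_ipd(ipd, path)
  back <- read_ipd(path, schema = list(study = "study",
                                       treatment = "treatment",
                                       outcome = "y",
                                       covariates = c("age", "sex")))
  expect_equal(back[[1]]$rows, ipd[[1]]$rows)
})

test_that("AgD tables parse with covariate summary blocks", {
  agd <- read_agd(tiny_agd_df())
  expect_length(agd, 1L)
  s <- agd[[1]]
  expect_equal(nrow(s$arms), 4L)
  expect_equal(sum(s$arms$n), 1306L)
  expect_length(s$covariate_summaries, 5L)
  expect_equal(s$covariate_summaries$weight$mean, 83.3)
  expect_equal(s$covariate_summaries$prevsys$prop, 0.64)
})

test_that("AgD validation catches impossible counts and proportions", {
  df <- tiny_agd_df(); df$events[1] <- 400
  expect_error(read_agd(df), "\\[0, n\\]")
  df2 <- tiny_agd_df(); df2$cov_prevsys_prop <- 1.2
  expect_error(read_agd(df2), "outside \\[0, 1\\]")
  df3 <- tiny_agd_df(); df3$cov_age_sd <- NA
  expect_error(read_agd(df3), "no sd")
  expect_warning(read_agd(tiny_agd_df()[1, ]), "single arm")
})

test_that("AgD write/read round-trips", {
  agd <- read_agd(tiny_agd_df())
  path <- file.path(tempdir(), "agd_rt.csv")
  write_agd(agd, path)
  back <- read_agd(path)
  expect_equal(back[[1]]$arms, agd[[1]]$arms)
  expect_equal(back[[1]]$covariate_summaries,
               agd[[1]]$covariate_summaries)
})

test_that("networks assemble with the reference first and are connected", {
  sim <- small_sim()
  net <- sim$network
  expect_s3_class(net, "mlnmr_network")
  expect_equal(net$treatments$id[1], "A")
  expect_equal(net$treatments$index, 1:6)
  # one two-arm study is trivially connected
  one <- read_ipd(tiny_ipd_df(),
                  schema = list(study = "study", treatment = "treatment",
                                outcome = "y",
                                covariates = c("age", "sex")))
  n1 <- build_network(ipd = one, covariates = c("age", "sex"))
  expect_equal(nrow(n1$treatments), 2L)
})

test_that("disconnected networks fail listing the components", {
  i1 <- read_ipd(data.frame(study = "S1", treatment = c("A", "A", "B"),
                            y = c(0, 1, 1)),
                 schema = list(study = "study", treatment = "treatment",
                               outcome = "y", covariates = character()))
  i2 <- read_ipd(data.frame(study = "S2", treatment = c("C", "C", "D"),
                            y = c(0, 1, 0)),
                 schema = list(study = "study", treatment = "treatment",
                               outcome = "y", covariates = character()))
  expect_error(build_network(ipd = c(i1, i2), covariates = character()),
               "disconnected.*A.*C")
})

test_that("duplicate arms of one treatment are merged with a warning", {
  df <- tiny_agd_df()
  df <- rbind(df, df[2, ])
  agd <- read_agd(df)
  expect_warning(net <- build_network(agd = agd,
                                      covariates = character()),
                 "merging")
  arms <- net$studies[[1]]$arms
  expect_equal(nrow(arms), 4L)
  expect_equal(arms$n[arms$treatment == "E"], 2L * 327L)
})

test_that("connectivity agrees with a brute-force BFS on random graphs", {
  bfs_connected <- function(sets, nodes) {
    adj <- stats::setNames(vector("list", length(nodes)), nodes)
    for (ts in sets) for (a in ts) adj[[a]] <- union(adj[[a]],
                                                     setdiff(ts, a))
    seen <- nodes[1]; frontier <- nodes[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(nodes)
  }
  withr::with_seed(99, {
    for (rep in 1:25) {
      nodes <- LETTERS[1:sample(3:8, 1)]
      sets <- replicate(sample(2:4, 1),
                        sample(nodes, sample(2:3, 1)), simplify = FALSE)
      comp <- mlnmr:::.connected_components(sets, nodes)
      expect_equal(length(comp) == 1L, bfs_connected(sets, nodes))
    }
  })
})

test_that("missing covariates in any study are rejected", {
  ipd <- read_ipd(tiny_ipd_df(),
                  schema = list(study = "study", treatment = "treatment",
                                outcome = "y",
                                covariates = c("age", "sex")))
  expect_error(build_network(ipd = ipd, covariates = c("age", "bmi")),
               "bmi")
  agd <- read_agd(tiny_agd_df())
  expect_error(build_network(ipd = ipd, agd = agd,
                             covariates = c("age", "sex")),
               "sex")
})
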