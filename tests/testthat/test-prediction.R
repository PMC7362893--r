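# Population-average contrasts and absolute predictions

test_that("self-contrast is exactly zero with a zero-width interval", {
  fit <- fake_fit()
  est <- population_contrast(fit, "S1", "B", "B")
  expect_true(all(est$draws == 0))
  expect_equal(est$summary$lower, 0)
  expect_equal(est$summary$upper, 0)
})

test_that("contrasts within a shared class are identical across
          populations, per draw", {
  fit <- fake_fit()
  pops <- c("S1", "S2", "S3", "S4")
  # B and C share an interaction vector in the default scenario
  draws <- lapply(pops, function(p)
    population_contrast(fit, p, "B", "C")$draws)
  for (i in 2:4) expect_identical(draws[[1]], draws[[i]])
  # across classes the contrast does depend on the population
  d2 <- lapply(pops, function(p)
    population_contrast(fit, p, "D", "B")$draws)
  expect_false(identical(d2[[1]], d2[[4]]))
})

test_that("grid-based evaluation equals plug-in at the grid means", {
  fit <- fake_fit()
  g <- fit$grids$S4
  est_grid <- population_contrast(fit, "S4", "A", "D")
  pop_means <- target_population("means", means = colMeans(g$points))
  est_plug <- population_contrast(fit, pop_means, "A", "D")
  expect_equal(est_grid$draws, est_plug$draws, tolerance = 1e-10)
})

test_that("consistency of population contrasts holds within a
          population", {
  fit <- fake_fit()
  d_ab <- population_contrast(fit, "S4", "B", "D")$draws
  d_b <- population_contrast(fit, "S4", "A", "B")$draws
  d_a <- population_contrast(fit, "S4", "A", "D")$draws
  expect_equal(d_ab, d_a - d_b, tolerance = 1e-12)
})

test_that("absolute predictions use the inverse link correctly", {
  fit <- fake_fit()
  dr <- fit$draws
  # all coefficients zero and baseline 0 gives probability one half
  dr$beta1[] <- 0; dr$beta2[] <- 0; dr$gamma[] <- 0; dr$mu[] <- 0
  fit0 <- fit; fit0$draws <- dr
  est <- population_absolute(fit0, "S1", "B")
  expect_equal(unique(est$draws), 0.5)
  # degenerate population at a single covariate point: exactly Phi(eta)
  x0 <- fit$grids$S4$points[7, , drop = FALSE]
  pop <- target_population("pt", ipd = as.data.frame(x0), baseline = 0.3)
  est2 <- population_absolute(fit, pop, "D")
  d <- length(fit$prep$covariates)
  b <- fit$draws$beta1 +
    matrix(fit$draws$beta2[, fit$draws$beta2_row[["D"]], ],
           nrow = fit$draws$n_draws)
  eta <- 0.3 + drop(b %*% drop(x0)) + fit$draws$gamma[, "D"]
  expect_equal(est2$draws, pnorm(eta), tolerance = 1e-12)
  expect_true(all(est2$draws >= 0 & est2$draws <= 1))
})

test_that("a normal covariate population matches the closed-form
          probit-normal average", {
  fit <- fake_fit()
  dr <- fit$draws
  dr$beta1[] <- 0; dr$beta2[] <- 0
  dr$beta1[, "age"] <- 0.8
  dr$gamma[] <- 0.4
  dr$gamma[, 1] <- 0
  fit2 <- fit; fit2$draws <- dr
  m <- list(marginal_spec("age", "normal", mean = 0, sd = 1),
            marginal_spec("weight", "normal", mean = 90, sd = 10),
            marginal_spec("duration", "normal", mean = 18, sd = 5),
            marginal_spec("prevsys", "bernoulli", prop = 0.6),
            marginal_spec("comorb", "bernoulli", prop = 0.2))
  g <- build_grid(m, n_points = 10000, seed = 17)
  pop <- target_population("ext", grid = g, baseline = 0.2)
  est <- population_absolute(fit2, pop, "B")
  closed <- pnorm((0.2 + 0.4) / sqrt(1 + 0.8^2))
  expect_lt(abs(mean(est$draws) - closed), 1e-3)
})

test_that("external baselines can be fixed or sampled", {
  fit <- fake_fit()
  pop_fix <- target_population("ext", means = colMeans(fit$grids$S4$points),
                               baseline = -1)
  expect_error(population_absolute(fit, pop_fix, "B"), "full covariate")
  g <- fit$grids$S4
  pop_n <- target_population("ext", grid = g, baseline = c(-1, 0.15))
  withr::with_seed(4, {
    e1 <- population_absolute(fit, pop_n, "B")
  })
  expect_true(sd(e1$draws) > 0)
})

test_that("the pairwise table covers all pairs and matches single calls", {
  fit <- fake_fit()
  tab <- all_pairwise(fit, "S2", absolute = TRUE)
  expect_equal(nrow(tab$contrasts), choose(6, 2))
  expect_equal(nrow(tab$absolute), 6L)
  one <- population_contrast(fit, "S2", "A", "D")$summary
  row <- tab$contrasts[tab$contrasts$contrast == "D vs A", ]
  expect_equal(row$mean, one$mean)
  expect_equal(row$lower, one$lower)
  # absolute predictions are monotone in gamma, per draw, when the
  # treatments share an interaction vector
  pb <- population_absolute(fit, "S2", "B")$draws
  pc <- population_absolute(fit, "S2", "C")$draws
  gb <- fit$draws$gamma[, "B"]; gc <- fit$draws$gamma[, "C"]
  expect_identical(pb > pc, gb > gc)
})

test_that("unknown treatments and populations are rejected", {
  fit <- fake_fit()
  expect_error(population_contrast(fit, "S1", "A", "Z"), "not in network")
  expect_error(population_contrast(fit, "S9", "A", "B"), "unknown")
})
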