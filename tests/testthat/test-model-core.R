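# Linear predictor, aggregate moments, two-parameter binomial,
# likelihood contributions, random-effects structure, consistency

mk_params <- function(mu = c(S1 = -1), beta1 = c(x = 0.5),
                      beta2 = NULL, gamma = c(A = 0, B = 2)) {
  d <- length(beta1)
  if (is.null(beta2)) {
    beta2 <- matrix(0, 2, d,
                    dimnames = list(c("A", "B"), names(beta1)))
    beta2["B", ] <- 0.2
  }
  list(mu = mu, beta1 = beta1, beta2 = beta2,
       beta2_row = c(A = 1L, B = 2L), gamma = gamma)
}

test_that("linear predictor assembles mu + x'(beta1+beta2) + gamma", {
  p <- mk_params()
  # reference treatment at x = 0 reduces to the study intercept
  expect_equal(linear_predictor(c(x = 0), "S1", "A", p), -1)
  # mu=-1, beta1=0.5, beta2=0.2, gamma=2, x=1 -> -1+0.7+2 = 1.7
  expect_equal(linear_predictor(c(x = 1), "S1", "B", p), 1.7)
  # prognostic-only terms cancel in within-study arm differences
  x <- matrix(c(2.5), 1, dimnames = list(NULL, "x"))
  diff_eta <- linear_predictor(x, "S1", "B", p) -
    linear_predictor(x, "S1", "A", p)
  p2 <- p; p2$beta1 <- c(x = 99)
  diff_eta2 <- linear_predictor(x, "S1", "B", p2) -
    linear_predictor(x, "S1", "A", p2)
  expect_equal(diff_eta, diff_eta2)
  expect_error(linear_predictor(c(x = 0), "S9", "A", p), "unknown study")
  expect_error(linear_predictor(c(x = 0), "S1", "Z", p),
               "unknown treatment")
})

test_that("aggregate moments reduce to the plain inverse link when the
          integrand is constant", {
  p <- mk_params(beta1 = c(x = 0))
  p$beta2[] <- 0
  g <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "x"))
  mo <- aggregate_moments(g, "S1", "B", p, link = "probit")
  expect_equal(mo$pbar, pnorm(-1 + 2), tolerance = 1e-12)
  expect_equal(mo$p2bar, pnorm(1)^2, tolerance = 1e-12)
  expect_error(aggregate_moments(g[0, , drop = FALSE], "S1", "B", p),
               "empty")
})

test_that("probit-normal aggregate moments match closed form and
          quadrature", {
  # eta = 1 + x, x ~ N(0,1): closed form pbar = Phi(1/sqrt(2))
  m <- list(marginal_spec("x", "normal", mean = 0, sd = 1))
  g <- build_grid(m, n_points = 10000, seed = 31)
  p <- mk_params(mu = c(S1 = 1), beta1 = c(x = 1),
                 gamma = c(A = 0, B = 0))
  p$beta2[] <- 0
  mo <- aggregate_moments(g, "S1", "A", p, link = "probit")
  expect_lt(abs(mo$pbar - pnorm(1 / sqrt(2))), 1e-3)
  # p2bar against adaptive 1-D quadrature of Phi(1+x)^2 phi(x)
  oracle <- integrate(function(x) pnorm(1 + x)^2 * dnorm(x),
                      -Inf, Inf, rel.tol = 1e-10)$value
  expect_lt(abs(mo$p2bar - oracle), 1e-3)
})

test_that("two-parameter binomial matches Poisson-binomial moments", {
  # worked case p = (0.2, 0.5, 0.8)
  p <- c(0.2, 0.5, 0.8)
  mo <- list(pbar = mean(p), p2bar = mean(p^2))
  ab <- two_param_binomial(3, mo)
  expect_equal(ab$N, 3 * 0.25 / 0.31, tolerance = 1e-12)
  expect_equal(ab$p, 0.62, tolerance = 1e-12)
  expect_equal(ab$N * ab$p, sum(p), tolerance = 1e-12)            # mean
  expect_equal(ab$N * ab$p * (1 - ab$p), sum(p * (1 - p)),
               tolerance = 1e-12)                                 # variance
  # homogeneous probabilities give back the plain binomial
  ab0 <- two_param_binomial(7, list(pbar = 0.4, p2bar = 0.16))
  expect_equal(ab0$N, 7)
  expect_equal(ab0$p, 0.4)
  expect_error(two_param_binomial(3, list(pbar = 0.5, p2bar = 0.1)),
               "invalid moments")
})

test_that("adjusted variance never exceeds the naive binomial variance", {
  withr::with_seed(8, {
    for (i in 1:200) {
      N <- sample(2:40, 1)
      p <- runif(N)
      mo <- list(pbar = mean(p), p2bar = mean(p^2))
      ab <- two_param_binomial(N, mo)
      expect_lte(ab$N * ab$p * (1 - ab$p),
                 N * mo$pbar * (1 - mo$pbar) + 1e-12)
      expect_lte(ab$N, N + 1e-12)
    }
  })
})

test_that("individual likelihood contributions are exact", {
  expect_equal(individual_loglik(1, 0.5, "bernoulli"), log(0.5))
  expect_equal(individual_loglik(0, 0.5, "bernoulli"), log(0.5))
  expect_gt(individual_loglik(1, 1 - 1e-12, "bernoulli"), -1e-9)
  expect_error(individual_loglik(1, 1.2, "bernoulli"), "\\(0, 1\\)")
  expect_equal(individual_loglik(1.3, 1, "normal", sigma = 2),
               dnorm(1.3, 1, 2, log = TRUE))
  expect_equal(individual_loglik(4, 2.5, "poisson"),
               dpois(4, 2.5, log = TRUE))
})

test_that("aggregate likelihood generalises the binomial and differs from
          it under heterogeneity", {
  # homogeneous moments: equals the standard binomial pmf
  ll <- aggregate_loglik(5, 10, list(pbar = 0.5, p2bar = 0.25),
                         "bernoulli")
  expect_equal(ll, dbinom(5, 10, 0.5, log = TRUE), tolerance = 1e-12)
  expect_equal(ll, log(0.24609375), tolerance = 1e-9)
  # heterogeneous moments: strictly different (two-parameter correction)
  ll2 <- aggregate_loglik(5, 10, list(pbar = 0.5, p2bar = 0.30),
                          "bernoulli")
  expect_false(isTRUE(all.equal(ll, ll2)))
  # continuous and count variants
  expect_equal(aggregate_loglik(1.2, 50, list(pbar = 1.0), "normal",
                                se = 0.2),
               dnorm(1.2, 1.0, 0.2, log = TRUE))
  expect_equal(aggregate_loglik(30, 100, list(pbar = 0.25), "poisson"),
               dpois(30, 25, log = TRUE))
  # events beyond the adjusted size use the continuous extension, flagged
  expect_warning(aggregate_loglik(10, 10, list(pbar = 0.5, p2bar = 0.45),
                                  "bernoulli"), "exceed")
})

test_that("random-effects covariance has tau^2 diagonal and 0.5
          correlation", {
  S <- random_effects_cov(1, 2)
  expect_equal(S, matrix(c(1, 0.5, 0.5, 1), 2))
  expect_equal(random_effects_cov(0, 3), matrix(0, 3, 3))
  for (m in 1:6) {
    S <- random_effects_cov(0.7, m)
    expect_true(all(eigen(S, symmetric = TRUE)$values > 0))
    if (m > 1) {
      D <- diag(1 / sqrt(diag(S)))
      expect_equal(unique(round((D %*% S %*% D)[upper.tri(S)], 12)), 0.5)
    }
  }
  expect_error(random_effects_cov(-1, 2), "tau")
  expect_error(random_effects_cov(1, 0), "non-reference")
})

test_that("effect-modifier structures tie parameters as declared", {
  trts <- data.frame(id = c("P", "I1", "I2", "S1", "S2"),
                     class = c("P", "il", "il", "il", "il"),
                     index = 1:5)
  shared <- effect_modifier_structure(trts, "shared")
  expect_equal(shared$n_rows, 2L)           # one interaction vector
  expect_equal(shared$row, c(1L, 2L, 2L, 2L, 2L))
  indep <- effect_modifier_structure(trts, "independent")
  expect_equal(indep$n_rows, 5L)
  exch <- effect_modifier_structure(trts, "exchangeable")
  expect_equal(lengths(exch$groups), c(il = 4L))
  trts2 <- data.frame(id = c("P", "X"), class = c("P", "X"), index = 1:2)
  expect_error(effect_modifier_structure(trts2, "exchangeable"),
               "< 2 treatments")
  # all singleton classes, independent: one vector per non-reference trt
  trts3 <- data.frame(id = c("P", "Q", "R"), class = c("P", "Q", "R"),
                      index = 1:3)
  expect_equal(effect_modifier_structure(trts3, "independent")$n_rows, 3L)
})

test_that("consistency expansion is antisymmetric and transitive", {
  g <- c(A = 0, B = 1, C = 3)
  tab <- consistency_expand(g)
  expect_equal(tab$gamma_ab[tab$a == "B" & tab$b == "C"], 2)
  for (i in seq_len(nrow(tab))) {
    rev <- tab[tab$a == tab$b[i] & tab$b == tab$a[i], ]
    expect_equal(tab$gamma_ab[i], -rev$gamma_ab)
  }
  withr::with_seed(2, {
    g6 <- setNames(c(0, rnorm(5)), LETTERS[1:6])
    b2 <- matrix(rnorm(12), 6, 2,
                 dimnames = list(LETTERS[1:6], c("x1", "x2")))
    tab6 <- consistency_expand(g6, b2)
    expect_equal(nrow(tab6), 30L)  # ordered pairs
    for (i in sample(nrow(tab6), 10)) {
      a <- tab6$a[i]; b <- tab6$b[i]
      expect_equal(tab6$gamma_ab[i], g6[[b]] - g6[[a]])
      expect_equal(tab6$beta2_ab_x1[i], b2[b, "x1"] - b2[a, "x1"])
    }
    # triangle identity
    gab <- function(a, b) tab6$gamma_ab[tab6$a == a & tab6$b == b]
    expect_identical(gab("A", "B") + gab("B", "C"), gab("A", "C"))
  })
})
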