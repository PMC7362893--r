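# Shared fixtures, built in code. Expensive MCMC fits are memoised so
# several test files can share one small fit.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# tiny IPD table: 1 study, 2 arms, 3 individuals
tiny_ipd_df <- function() {
  data.frame(study = "S1", treatment = c("A", "A", "B"), y = c(0, 1, 1),
             age = c(40, 50, 45), sex = c(0, 1, 1))
}

# tiny AgD table: 4 arms, 5 covariate summaries (psoriasis-like shape)
tiny_agd_df <- function() {
  data.frame(study = "F1", treatment = c("A", "E", "F", "D"),
             events = c(16, 249, 220, 142),
             n = c(324, 327, 323, 332),
             cov_age_mean = 44.5, cov_age_sd = 12.9,
             cov_weight_mean = 83.3, cov_weight_sd = 20.8,
             cov_duration_mean = 16.5, cov_duration_sd = 12.0,
             cov_prevsys_prop = 0.64, cov_comorb_prop = 0.147)
}

# small simulated mixed network shared across test files
small_sim <- function() memo("small_sim", {
  simulate_network(default_scenario(n_per_arm = 80), seed = 424)
})

small_grids <- function() memo("small_grids", {
  build_network_grids(small_sim()$network,
                      families = c(weight = "gamma", duration = "gamma"),
                      n_points = 64, seed = 9)
})

small_model <- function(...) {
  covs <- c("age", "weight", "duration", "prevsys", "comorb")
  mlnmr_model("bernoulli", "probit", prognostic = covs,
              effect_modifiers = covs, em_structure = "shared", ...)
}

small_fit <- function() memo("small_fit", {
  suppressWarnings(
    mlnmr_fit(small_sim()$network, small_model(), small_grids(),
              config = fit_config(chains = 2, warmup = 400, iter = 400,
                                  seed = 77, n_points = 64)))
})

# a fabricated fit object with hand-set draws, for prediction arithmetic
# tests that need no MCMC
fake_fit <- function(n_draws = 50, seed = 3) {
  fit <- small_fit()
  withr::with_seed(seed, {
    dr <- fit$draws
    nd <- n_draws
    dr$n_draws <- nd
    dr$mu <- matrix(rnorm(nd * ncol(dr$mu), -1, 0.2), nd,
                    ncol(dr$mu), dimnames = list(NULL, colnames(dr$mu)))
    dr$beta1 <- matrix(rnorm(nd * ncol(dr$beta1), 0, 0.05), nd,
                       ncol(dr$beta1),
                       dimnames = list(NULL, colnames(dr$beta1)))
    b2 <- array(rnorm(nd * dim(dr$beta2)[2] * dim(dr$beta2)[3], 0, 0.05),
                dim = c(nd, dim(dr$beta2)[2], dim(dr$beta2)[3]),
                dimnames = dimnames(dr$beta2))
    b2[, 1, ] <- 0
    dr$beta2 <- b2
    g <- matrix(rnorm(nd * ncol(dr$gamma), 2, 0.5), nd, ncol(dr$gamma),
                dimnames = list(NULL, colnames(dr$gamma)))
    g[, 1] <- 0
    dr$gamma <- g
    fit$draws <- dr
  })
  fit
}
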