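# Synthetic networks of IPD and AgD trials with known parameters: the
# test bed for every stage of the method and the parameter-recovery
# surface. The generative model is exactly the individual-level model the
# package fits (probit-linear by default), with covariates drawn from the
# same marginal-plus-Gaussian-copula law the integration module assumes,
# so that the fitted model can be well specified.

#' Default synthetic scenario
#'
#' A network shaped like a typical phase-3 psoriasis evidence base:
#' 6 treatments (reference `A`), two treatment classes sharing effect
#' modifiers (`B`, `C`, `E`, `F` in one class, `D` alone), three IPD
#' studies and one aggregate study, five covariates (three continuous, of
#' which one right-skewed; two binary), and a probit outcome model with
#' prognostic and effect-modifying coefficients. Sample sizes default to
#' 200 per arm.
#'
#' @param n_per_arm individuals per arm.
#' @param tau between-study heterogeneity sd of the true effects
#'   (0 = fixed effect).
#' @return a `scenario` list: study design, true parameters, covariate
#'   generative law and treatment classes.
#' @export
default_scenario <- function(n_per_arm = 200, tau = 0) {
  covs <- c("age", "weight", "duration", "prevsys", "comorb")
  marginals <- list(
    age      = list(family = "normal", mean = 45, sd = 13),
    weight   = list(family = "gamma", mean = 90, sd = 23),
    duration = list(family = "gamma", mean = 18, sd = 12),
    prevsys  = list(family = "bernoulli", prop = 0.65),
    comorb   = list(family = "bernoulli", prop = 0.22)
  )
  # rank correlations on the latent scale: age/duration/weight weakly
  # positively related; previous systemic use rises with duration
  spearman <- diag(5)
  dimnames(spearman) <- list(covs, covs)
  spearman["age", "duration"] <- spearman["duration", "age"] <- 0.3
  spearman["age", "weight"] <- spearman["weight", "age"] <- 0.15
  spearman["weight", "duration"] <- spearman["duration", "weight"] <- 0.1
  spearman["duration", "prevsys"] <- spearman["prevsys", "duration"] <- 0.25
  spearman["age", "comorb"] <- spearman["comorb", "age"] <- 0.15
  # per-study shifts of the continuous covariate means (trial populations
  # differ modestly, as across real phase-3 programmes)
  shifts <- list(S1 = c(age = 0, weight = 0, duration = 0),
                 S2 = c(age = -1, weight = 2, duration = 1),
                 S3 = c(age = 1.5, weight = -2, duration = -1.5),
                 S4 = c(age = -2, weight = -6, duration = -2))
  props <- list(S1 = c(prevsys = 0.65, comorb = 0.22),
                S2 = c(prevsys = 0.60, comorb = 0.25),
                S3 = c(prevsys = 0.70, comorb = 0.20),
                S4 = c(prevsys = 0.62, comorb = 0.15))
  # true coefficients, expressed per unit of covariate (continuous
  # coefficients chosen as moderate effects per ~1 sd)
  beta1 <- c(age = -0.01, weight = -0.004, duration = 0.008,
             prevsys = 0.2, comorb = -0.15)
  beta2 <- rbind(
    bcef = c(age = 0, weight = -0.006, duration = 0.012, prevsys = 0.15,
             comorb = 0),
    d    = c(age = 0, weight = -0.004, duration = 0.008, prevsys = 0.1,
             comorb = 0))
  list(
    treatments = c("A", "B", "C", "D", "E", "F"),
    classes = c(B = "bcef", C = "bcef", E = "bcef", F = "bcef", D = "d"),
    studies = list(S1 = c("A", "B", "C"), S2 = c("A", "B", "C"),
                   S3 = c("A", "D"), S4 = c("A", "E", "F", "D")),
    agd_studies = "S4",
    n_per_arm = n_per_arm,
    covariates = covs,
    marginals = marginals,
    spearman = spearman,
    shifts = shifts,
    props = props,
    mu = c(S1 = -1.1, S2 = -1.0, S3 = -1.2, S4 = -0.9),
    beta1 = beta1,
    beta2 = beta2,
    gamma = c(A = 0, B = 2.8, C = 2.5, D = 1.7, E = 2.2, F = 2.5),
    tau = tau
  )
}

# covariate coefficient vector beta1 + beta2_k for a scenario treatment
.scenario_bvec <- function(scenario, trt) {
  b <- scenario$beta1
  if (trt != scenario$treatments[1]) {
    cl <- scenario$classes[[trt]]
    b <- b + scenario$beta2[cl, names(b)]
  }
  b
}

#' Simulate IPD trials from a scenario
#'
#' Draws covariates from the scenario's marginal-plus-copula law, assigns
#' individuals to arms with equal randomisation, and generates binary
#' outcomes from the probit individual-level model. Under a heterogeneity
#' sd `tau > 0`, study-specific effects are drawn with pairwise
#' correlation 0.5 around the true population effects.
#'
#' @param scenario from [default_scenario()] (or a modified copy).
#' @param seed integer seed; the same seed yields the identical dataset.
#' @return list with `ipd` (every study as an `ipd_study`, including those
#'   designated aggregate-only), `truth` (true parameter record including
#'   any realised study-specific effects) and `scenario`.
#' @export
simulate_ipd <- function(scenario = default_scenario(), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    covs <- scenario$covariates
    ipd <- list()
    delta_truth <- list()
    for (sid in names(scenario$studies)) {
      arms <- scenario$studies[[sid]]
      marg <- lapply(covs, function(cv) {
        mspec <- scenario$marginals[[cv]]
        if (mspec$family == "bernoulli")
          marginal_spec(cv, "bernoulli", prop = scenario$props[[sid]][cv])
        else
          marginal_spec(cv, mspec$family,
                        mean = mspec$mean + scenario$shifts[[sid]][cv],
                        sd = mspec$sd)
      })
      n <- scenario$n_per_arm * length(arms)
      X <- .copula_sample(n, marg, spearman_to_copula(scenario$spearman))
      trt <- rep(arms, each = scenario$n_per_arm)
      # realised study effects: gamma (FE) or correlated random effects
      eff <- scenario$gamma[arms]
      if (scenario$tau > 0) {
        nonref <- arms != scenario$treatments[1]
        m <- sum(nonref)
        S <- random_effects_cov(scenario$tau, m)
        z <- drop(crossprod(chol(S), stats::rnorm(m)))
        eff[nonref] <- eff[nonref] + z
        delta_truth[[sid]] <- stats::setNames(eff[nonref], arms[nonref])
      }
      effv <- eff[match(trt, arms)]
      eta <- scenario$mu[sid] + effv +
        vapply(seq_len(n), function(i)
          sum(X[i, ] * .scenario_bvec(scenario, trt[i])), 0)
      y <- stats::rbinom(n, 1, stats::pnorm(eta))
      rows <- data.frame(treatment = trt, y = y)
      rows[covs] <- as.data.frame(X)
      ipd[[sid]] <- structure(list(study_id = sid, rows = rows,
                                   covariates = covs, outcome = "binary"),
                              class = "ipd_study")
    }
    list(ipd = ipd,
         truth = list(mu = scenario$mu, beta1 = scenario$beta1,
                      beta2 = scenario$beta2, gamma = scenario$gamma,
                      tau = scenario$tau, delta = delta_truth,
                      classes = scenario$classes),
         scenario = scenario)
  })
}

#' Reduce an IPD study to its published aggregate view
#'
#' Computes per-arm event counts and sample sizes and study-level
#' covariate summaries (mean and sd for continuous covariates, proportion
#' for binary ones), discarding the individual rows.
#'
#' @param ipd_study an `ipd_study` with binary outcome.
#' @return an `agd_study`.
#' @export
aggregate_from_ipd <- function(ipd_study) {
  stopifnot(inherits(ipd_study, "ipd_study"))
  if (ipd_study$outcome != "binary")
    stop("aggregation is implemented for binary outcomes")
  r <- ipd_study$rows
  arms <- do.call(rbind, lapply(split(r, r$treatment), function(sub)
    data.frame(treatment = sub$treatment[1], events = sum(sub$y),
               n = nrow(sub))))
  arms <- arms[match(unique(r$treatment), arms$treatment), ]
  rownames(arms) <- NULL
  cs <- lapply(ipd_study$covariates, function(cv) {
    v <- r[[cv]]
    if (all(v %in% c(0, 1))) list(prop = mean(v))
    else list(mean = mean(v), sd = stats::sd(v))
  })
  names(cs) <- ipd_study$covariates
  structure(list(study_id = ipd_study$study_id, arms = arms,
                 covariate_summaries = cs,
                 covariates = ipd_study$covariates, outcome = "binary",
                 single_arm = nrow(arms) == 1L),
            class = "agd_study")
}

#' Build the mixed IPD/AgD network for a simulated scenario
#'
#' Simulates all studies as IPD, reduces the designated aggregate studies
#' to their published summaries, and assembles the network.
#'
#' @param scenario from [default_scenario()].
#' @param seed simulation seed.
#' @return list with `network`, `truth` and the full-IPD version of the
#'   aggregated studies (`hidden_ipd`) for paired-comparison tests.
#' @export
simulate_network <- function(scenario = default_scenario(), seed = 1L) {
  sim <- simulate_ipd(scenario, seed)
  agd_ids <- scenario$agd_studies
  ipd <- sim$ipd[setdiff(names(sim$ipd), agd_ids)]
  agd <- lapply(sim$ipd[agd_ids], aggregate_from_ipd)
  network <- build_network(ipd = unname(ipd), agd = unname(agd),
                           reference = scenario$treatments[1],
                           classes = scenario$classes,
                           covariates = scenario$covariates)
  list(network = network, truth = sim$truth,
       hidden_ipd = sim$ipd[agd_ids], scenario = scenario)
}

#' Parameter-recovery report
#'
#' Compares posterior summaries against the generating truth: z-scores
#' `(posterior mean - truth) / posterior sd` and whether the 95% credible
#' interval covers the truth, for the treatment effects, prognostic and
#' effect-modifier coefficients (and `tau` under random effects).
#'
#' @param fit an `mlnmr_fit` of a simulated network.
#' @param truth truth record from [simulate_network()].
#' @return data frame with one row per parameter.
#' @export
recovery_report <- function(fit, truth) {
  stopifnot(inherits(fit, "mlnmr_fit"))
  rows <- list()
  push <- function(name, true, draws) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, truth = true, mean = mean(draws),
      sd = stats::sd(draws),
      z = (mean(draws) - true) / stats::sd(draws),
      covered = stats::quantile(draws, 0.025) <= true &
        true <= stats::quantile(draws, 0.975), row.names = NULL)
  }
  dr <- fit$draws
  for (k in colnames(dr$gamma)[-1]) {
    if (!k %in% names(truth$gamma))
      stop("treatment '", k, "' not present in the truth record")
    push(paste0("gamma.", k), truth$gamma[[k]], dr$gamma[, k])
  }
  for (cv in colnames(dr$beta1)) {
    if (truth$beta1[cv] != 0 || cv %in% fit$model$prognostic)
      push(paste0("beta1.", cv), truth$beta1[[cv]], dr$beta1[, cv])
  }
  em_labels <- dimnames(dr$beta2)[[2]]
  for (r in seq_along(em_labels)[-1]) {
    lab <- em_labels[r]
    if (!lab %in% rownames(truth$beta2)) next
    for (cv in dimnames(dr$beta2)[[3]]) {
      if (cv %in% fit$model$effect_modifiers)
        push(paste0("beta2.", lab, ".", cv), truth$beta2[lab, cv],
             dr$beta2[, r, cv])
    }
  }
  if (!is.null(dr$tau)) push("tau", truth$tau, dr$tau)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
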