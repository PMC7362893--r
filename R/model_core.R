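# Core model components: the individual-level linear predictor, aggregate
# moments obtained by integrating the inverse-link over a covariate grid,
# the two-parameter binomial approximation to the Poisson-binomial, and
# the individual / aggregate likelihood contributions.

.links <- list(
  probit  = list(ginv = stats::pnorm, g = stats::qnorm),
  logit   = list(ginv = stats::plogis, g = stats::qlogis),
  identity = list(ginv = identity, g = identity),
  log     = list(ginv = exp, g = log)
)

#' Specify a multilevel network meta-regression model
#'
#' Describes the likelihood, link, covariate roles, effect-modifier
#' structure and priors of the individual-level regression model. The
#' linear predictor for an individual with covariates `x` on treatment `k`
#' in study `j` is
#' `eta = mu_j + x' (beta1 + beta2_k) + gamma_k`,
#' where `beta1` are prognostic coefficients (zero for covariates declared
#' effect-modifier only), `beta2_k` are effect-modifier interactions (zero
#' for the reference treatment and for covariates declared prognostic
#' only), and `gamma_k` is the individual-level treatment effect versus the
#' reference. Aggregate outcomes are modelled by integrating the
#' inverse-link of `eta` over the study's covariate distribution.
#'
#' @param likelihood `"bernoulli"`, `"normal"` or `"poisson"`.
#' @param link `"probit"` or `"logit"` (bernoulli), `"identity"` (normal),
#'   `"log"` (poisson).
#' @param prognostic character vector of prognostic covariates.
#' @param effect_modifiers character vector of effect-modifying covariates
#'   (covariates may appear in both).
#' @param em_structure `"shared"` (one interaction vector per treatment
#'   class), `"independent"` (one per non-reference treatment) or
#'   `"exchangeable"` (per-treatment interactions drawn from a class-level
#'   normal with estimated mean and sd).
#' @param effects `"fixed"` or `"random"` study-level relative effects; the
#'   random-effects model uses a common heterogeneity sd `tau` with
#'   correlation 0.5 between the effects of multi-arm studies.
#' @param priors named list overriding defaults: `mu`, `beta1`, `beta2`,
#'   `gamma` are normal sds (default 100), `tau` and `sigma_beta2`
#'   half-normal scales (default 2.5), `sigma` half-normal scale for the
#'   normal-likelihood outcome sd (default 10).
#' @return an object of class `mlnmr_model`.
#' @export
mlnmr_model <- function(likelihood = c("bernoulli", "normal", "poisson"),
                        link = NULL,
                        prognostic = character(),
                        effect_modifiers = character(),
                        em_structure = c("shared", "independent",
                                         "exchangeable"),
                        effects = c("fixed", "random"),
                        priors = list()) {
  likelihood <- match.arg(likelihood)
  em_structure <- match.arg(em_structure)
  effects <- match.arg(effects)
  link <- link %||% switch(likelihood, bernoulli = "probit",
                           normal = "identity", poisson = "log")
  ok <- switch(likelihood, bernoulli = c("probit", "logit"),
               normal = "identity", poisson = "log")
  if (!(link %in% ok))
    stop("link '", link, "' is not valid for a ", likelihood, " likelihood")
  pr <- utils::modifyList(list(mu = 100, beta1 = 100, beta2 = 100,
                               gamma = 100, tau = 2.5, sigma_beta2 = 2.5,
                               sigma = 10), priors)
  structure(list(likelihood = likelihood, link = link,
                 prognostic = prognostic,
                 effect_modifiers = effect_modifiers,
                 covariates = union(prognostic, effect_modifiers),
                 em_structure = em_structure, effects = effects,
                 priors = pr),
            class = "mlnmr_model")
}

#' @export
print.mlnmr_model <- function(x, ...) {
  cat("<mlnmr model> ", x$likelihood, " likelihood, ", x$link, " link, ",
      x$effects, " effects\n", sep = "")
  cat("  prognostic:      ", paste(x$prognostic, collapse = ", "), "\n")
  cat("  effect modifiers:", paste(x$effect_modifiers, collapse = ", "),
      "(", x$em_structure, ")\n")
  invisible(x)
}

#' Map treatments to effect-modifier interaction vectors
#'
#' Returns the parameter-tying map implied by the effect-modifier structure:
#' which interaction vector each treatment uses. Row 1 is the zero vector
#' (reference treatment); `"shared"` gives one row per treatment class,
#' `"independent"` one per non-reference treatment, and `"exchangeable"`
#' one per non-reference treatment with class-level hierarchical pooling.
#'
#' @param treatments data frame with `id` and `class` columns, reference
#'   first (as in `network$treatments`).
#' @param structure `"shared"`, `"independent"` or `"exchangeable"`.
#' @return list with `row` (integer vector per treatment; 1 = zero vector),
#'   `labels` (row labels, `"<reference>"` first), `n_rows`, and for the
#'   exchangeable structure `groups` (rows per class, each with >= 2
#'   treatments) plus `group_of_row`.
#' @export
effect_modifier_structure <- function(treatments,
                                      structure = c("shared", "independent",
                                                    "exchangeable")) {
  structure <- match.arg(structure)
  K <- nrow(treatments)
  ref <- treatments$id[1]
  row <- integer(K); row[1] <- 1L
  if (structure == "shared") {
    cls <- unique(treatments$class[-1])
    row[-1] <- 1L + match(treatments$class[-1], cls)
    labels <- c(ref, cls)
    out <- list(row = row, labels = labels, n_rows = 1L + length(cls))
  } else {
    row[-1] <- 1L + seq_len(K - 1L)
    labels <- c(ref, treatments$id[-1])
    out <- list(row = row, labels = labels, n_rows = K)
    if (structure == "exchangeable") {
      cls <- treatments$class[-1]
      groups <- split(1L + seq_len(K - 1L), cls)
      small <- names(groups)[lengths(groups) < 2L]
      if (length(small) > 0L)
        stop("exchangeable effect-modifier class(es) with < 2 treatments ",
             "(variance not identifiable): ", paste(small, collapse = ", "))
      out$groups <- groups
      out$group_of_row <- integer(out$n_rows)
      for (gidx in seq_along(groups))
        out$group_of_row[groups[[gidx]]] <- gidx
    }
  }
  out$structure <- structure
  out
}

#' Individual-level linear predictor
#'
#' `eta = mu_j + x' (beta1 + beta2_k) + gamma_k` (fixed effects), or with
#' the study-specific effect `delta_jk` in place of `gamma_k` under random
#' effects.
#'
#' @param x covariate vector or matrix (rows = individuals or grid points),
#'   columns named as in `params$beta1`.
#' @param study study label.
#' @param treatment treatment label.
#' @param params list with `mu` (named by study), `beta1` (named by
#'   covariate), `beta2` (matrix: tying rows x covariates; row 1 zero),
#'   `beta2_row` (integer vector named by treatment), `gamma` (named by
#'   treatment, reference 0) and optionally `delta` (matrix studies x
#'   treatments) when `effects = "random"`.
#' @param effects `"fixed"` or `"random"`.
#' @return numeric vector of linear predictor values.
#' @export
linear_predictor <- function(x, study, treatment, params,
                             effects = c("fixed", "random")) {
  effects <- match.arg(effects)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(params$beta1)))
  if (!study %in% names(params$mu)) stop("unknown study '", study, "'")
  if (!treatment %in% names(params$gamma))
    stop("unknown treatment '", treatment, "'")
  b2 <- params$beta2[params$beta2_row[[treatment]], colnames(x),
                     drop = TRUE]
  b <- params$beta1[colnames(x)] + b2
  eff <- if (effects == "random") params$delta[study, treatment]
         else params$gamma[[treatment]]
  drop(params$mu[[study]] + x %*% b + eff)
}

#' Aggregate outcome moments over an integration grid
#'
#' Approximates the mean outcome probability and mean squared probability
#' for an aggregate-study arm by averaging the inverse-link of the linear
#' predictor over the study's fixed integration grid:
#' `pbar = mean(ginv(eta))`, `p2bar = mean(ginv(eta)^2)`. Both are clamped
#' into `(1e-12, 1 - 1e-12)` for numerical stability.
#'
#' @param grid an `mlnmr_grid` (or a plain matrix of covariate points).
#' @param study,treatment labels passed to [linear_predictor()].
#' @param params parameter list, see [linear_predictor()].
#' @param link link function name.
#' @param effects `"fixed"` or `"random"`.
#' @return list with `pbar` and `p2bar` (for non-binary likelihoods,
#'   `pbar` is the average mean outcome and `p2bar` the average squared
#'   mean, unclamped).
#' @export
aggregate_moments <- function(grid, study, treatment, params,
                              link = "probit",
                              effects = c("fixed", "random")) {
  X <- if (inherits(grid, "mlnmr_grid")) grid$points else grid
  if (is.null(X) || nrow(X) == 0L) stop("empty integration grid")
  eta <- linear_predictor(X, study, treatment, params, effects)
  ginv <- .links[[link]]$ginv
  p <- ginv(eta)
  if (link %in% c("probit", "logit")) {
    eps <- 1e-12
    pbar <- min(max(mean(p), eps), 1 - eps)
    p2bar <- min(max(mean(p^2), pbar^2), pbar)
    list(pbar = pbar, p2bar = p2bar)
  } else {
    list(pbar = mean(p), p2bar = mean(p^2))
  }
}

#' Two-parameter binomial approximation to the Poisson-binomial
#'
#' The sum of independent Bernoulli outcomes with unequal probabilities is
#' Poisson-binomial. Matching both its mean and variance with a binomial
#' requires adjusting both parameters:
#' `N' = N pbar^2 / p2bar`, `p' = p2bar / pbar`, so that
#' `N' p' = N pbar` and `N' p' (1 - p') = sum p_i (1 - p_i)`. When all
#' individual probabilities are equal (`p2bar = pbar^2`) this reduces to
#' the plain binomial.
#'
#' @param N arm sample size.
#' @param moments list with `pbar`, `p2bar` (see [aggregate_moments()]).
#' @return list with `N` (adjusted, real-valued, `<= N`) and `p`.
#' @export
two_param_binomial <- function(N, moments) {
  pbar <- moments$pbar; p2bar <- moments$p2bar
  if (p2bar < pbar^2 - 1e-12 || p2bar > pbar + 1e-12)
    stop("invalid moments: p2bar must lie in [pbar^2, pbar]")
  p2bar <- min(max(p2bar, pbar^2), pbar)
  list(N = N * pbar^2 / p2bar, p = p2bar / pbar)
}

#' Individual-level log-likelihood contribution
#'
#' @param y observed outcome (0/1, real, or count).
#' @param theta conditional mean outcome (probability for bernoulli, mean
#'   for normal, rate for poisson). Vectorised over `y` and `theta`.
#' @param likelihood `"bernoulli"`, `"normal"` or `"poisson"`.
#' @param sigma outcome sd (normal likelihood only).
#' @return log-likelihood value(s).
#' @export
individual_loglik <- function(y, theta,
                              likelihood = c("bernoulli", "normal",
                                             "poisson"),
                              sigma = NULL) {
  likelihood <- match.arg(likelihood)
  switch(likelihood,
    bernoulli = {
      if (any(theta <= 0 | theta >= 1))
        stop("bernoulli probability outside (0, 1)")
      y * log(theta) + (1 - y) * log(1 - theta)
    },
    normal = stats::dnorm(y, mean = theta, sd = sigma, log = TRUE),
    poisson = stats::dpois(y, lambda = theta, log = TRUE))
}

#' Aggregate-level log-likelihood contribution
#'
#' Binary outcomes use the two-parameter binomial approximation with a
#' real-valued size, evaluated through the log-gamma generalisation of the
#' binomial coefficient. Continuous outcomes use
#' `ybar ~ N(pbar, se^2)`; counts use `y ~ Pois(N * pbar)`.
#'
#' @param y summary outcome (event count, mean, or total count).
#' @param N arm sample size (or exposure for counts).
#' @param moments list with `pbar`, `p2bar`.
#' @param likelihood `"bernoulli"`, `"normal"` or `"poisson"`.
#' @param se standard error of the summary mean (normal likelihood).
#' @return log-likelihood value.
#' @export
aggregate_loglik <- function(y, N, moments,
                             likelihood = c("bernoulli", "normal",
                                            "poisson"),
                             se = NULL) {
  likelihood <- match.arg(likelihood)
  switch(likelihood,
    bernoulli = {
      ab <- two_param_binomial(N, moments)
      if (y > ab$N)
        warning("observed events (", y, ") exceed the adjusted binomial ",
                "size N' = ", signif(ab$N, 6),
                "; using the continuous density extension")
      lgamma(ab$N + 1) - lgamma(y + 1) - lgamma(ab$N - y + 1) +
        y * log(ab$p) + (ab$N - y) * log1p(-ab$p)
    },
    normal = stats::dnorm(y, mean = moments$pbar, sd = se, log = TRUE),
    poisson = stats::dpois(y, lambda = N * moments$pbar, log = TRUE))
}

#' Random-effects covariance of a multi-arm study
#'
#' Under a common heterogeneity variance, the study-specific effects of the
#' non-reference arms of a multi-arm study are jointly normal with variance
#' `tau^2` and pairwise correlation exactly 0.5.
#'
#' @param tau heterogeneity standard deviation (>= 0).
#' @param n_nonref_arms number of non-reference arms (>= 1).
#' @return covariance matrix, `tau^2` on the diagonal and `tau^2 / 2` off
#'   it.
#' @export
random_effects_cov <- function(tau, n_nonref_arms) {
  if (tau < 0) stop("tau must be >= 0")
  if (n_nonref_arms < 1) stop("need at least one non-reference arm")
  m <- n_nonref_arms
  tau^2 * (0.5 * diag(m) + 0.5 * matrix(1, m, m))
}

#' Expand reference-based effects to all pairwise contrasts
#'
#' Applies the consistency equations `gamma_ab = gamma_b - gamma_a` (and
#' `beta2_ab = beta2_b - beta2_a` when interactions are supplied) to every
#' treatment pair. The resulting table is antisymmetric and satisfies the
#' triangle identity exactly.
#'
#' @param gamma named vector of treatment effects versus the reference
#'   (reference entry 0).
#' @param beta2 optional matrix of interaction vectors, one row per
#'   treatment (in the same order as `gamma`).
#' @return data frame with columns `a`, `b`, `gamma_ab` and, if requested,
#'   one `beta2_ab_<covariate>` column per interaction covariate.
#' @export
consistency_expand <- function(gamma, beta2 = NULL) {
  k <- length(gamma)
  nm <- names(gamma) %||% as.character(seq_len(k))
  pairs <- expand.grid(ai = seq_len(k), bi = seq_len(k))
  pairs <- pairs[pairs$ai != pairs$bi, ]
  out <- data.frame(a = nm[pairs$ai], b = nm[pairs$bi],
                    gamma_ab = gamma[pairs$bi] - gamma[pairs$ai],
                    row.names = NULL)
  if (!is.null(beta2)) {
    d <- beta2[pairs$bi, , drop = FALSE] - beta2[pairs$ai, , drop = FALSE]
    colnames(d) <- paste0("beta2_ab_", colnames(beta2))
    out <- cbind(out, as.data.frame(d, row.names = NULL))
  }
  out
}
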