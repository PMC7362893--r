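# Population-average estimates in a named target population: relative
# effects (contrasts on the linear-predictor scale) and absolute outcome
# predictions, both evaluated per posterior draw by averaging over the
# population's covariate distribution.

#' Define a target population for prediction
#'
#' A target population is represented either by individual covariate rows
#' (an IPD study or registry sample), by an integration grid built from
#' marginal summaries plus a copula (exactly as for an aggregate study),
#' or — for contrasts only — by effect-modifier means.
#'
#' @param name population label.
#' @param study take the covariate representation (and baseline) from this
#'   study of a fitted network: IPD rows for an IPD study, the fitted
#'   integration grid for an AgD study.
#' @param ipd a data frame of individual covariate rows.
#' @param grid an `mlnmr_grid`.
#' @param means named vector of covariate means (contrasts only).
#' @param baseline baseline (reference-treatment intercept on the linear
#'   predictor scale) for absolute predictions: `"study"` uses the
#'   study-specific intercept draws (requires `study`), a single number is
#'   a fixed external value, a length-2 vector `c(mean, sd)` samples a
#'   normal external distribution per draw.
#' @return an object of class `target_population`.
#' @export
target_population <- function(name, study = NULL, ipd = NULL, grid = NULL,
                              means = NULL, baseline = "study") {
  n_spec <- sum(!is.null(study), !is.null(ipd), !is.null(grid),
                !is.null(means))
  if (n_spec != 1L)
    stop("give exactly one of `study`, `ipd`, `grid`, `means`")
  structure(list(name = name, study = study,
                 X = if (!is.null(ipd)) as.matrix(ipd) else
                     if (!is.null(grid)) grid$points else NULL,
                 means = means, baseline = baseline),
            class = "target_population")
}

# resolve a population against a fit: returns list(X or means, mu draws)
.resolve_population <- function(fit, population) {
  if (is.character(population) && length(population) == 1L)
    population <- target_population(population, study = population)
  stopifnot(inherits(population, "target_population"))
  out <- list(name = population$name, X = population$X,
              means = population$means)
  if (!is.null(population$study)) {
    sid <- population$study
    studies <- fit$network$studies
    ix <- match(sid, vapply(studies, `[[`, "", "study_id"))
    if (is.na(ix)) stop("unknown population/study '", sid, "'")
    s <- studies[[ix]]
    if (inherits(s, "ipd_study")) {
      out$X <- as.matrix(s$rows[fit$network$covariates])
    } else {
      g <- fit$grids[[sid]]
      if (is.null(g)) stop("no integration grid stored for study '", sid,
                           "'")
      out$X <- g$points
    }
  }
  bl <- population$baseline
  if (identical(bl, "study")) {
    if (is.null(population$study))
      out$mu <- NULL
    else out$mu <- fit$draws$mu[, population$study]
  } else if (is.numeric(bl) && length(bl) == 1L) {
    out$mu <- rep(bl, fit$draws$n_draws)
  } else if (is.numeric(bl) && length(bl) == 2L) {
    out$mu <- stats::rnorm(fit$draws$n_draws, bl[1], bl[2])
  } else stop("invalid `baseline` specification")
  out
}

# per-draw matrix of beta1 + beta2_k coefficient vectors for treatment k
.bvec_draws <- function(fit, k) {
  dr <- fit$draws
  d <- length(fit$prep$covariates)
  if (d == 0L) return(NULL)
  r <- dr$beta2_row[[k]]
  dr$beta1 + matrix(dr$beta2[, r, seq_len(d)], nrow = dr$n_draws)
}

.summarise_draws <- function(h) {
  c(mean = mean(h), sd = stats::sd(h),
    lower = unname(stats::quantile(h, 0.025)),
    upper = unname(stats::quantile(h, 0.975)))
}

#' Population-average relative effect between two treatments
#'
#' The population-average contrast of `b` versus `a` on the linear
#' predictor scale is, per posterior draw,
#' `d_ab(P) = xbar_P' (beta2_b - beta2_a) + gamma_b - gamma_a`,
#' with `xbar_P` the effect-modifier means of the target population (for a
#' linear function of the covariates, averaging over the population equals
#' plugging in the means). Contrasts satisfy consistency within each
#' population by construction.
#'
#' @param fit an `mlnmr_fit` (consistency model).
#' @param population a [target_population()] or a study id.
#' @param a,b treatment labels (`b` versus `a`).
#' @return an object of class `mlnmr_estimate`: list with `draws` and a
#'   one-row summary data frame (posterior mean, sd, 95% equal-tailed
#'   credible interval).
#' @export
population_contrast <- function(fit, population, a, b) {
  stopifnot(inherits(fit, "mlnmr_fit"))
  if (fit$ume) stop("population contrasts require the consistency model")
  trts <- fit$prep$treatments
  if (!a %in% trts || !b %in% trts)
    stop("treatment not in network: ", paste(setdiff(c(a, b), trts),
                                             collapse = ", "))
  pop <- .resolve_population(fit, population)
  dr <- fit$draws
  h <- dr$gamma[, b] - dr$gamma[, a]
  d <- length(fit$prep$covariates)
  if (d > 0L && dr$beta2_row[[a]] != dr$beta2_row[[b]]) {
    xbar <- if (!is.null(pop$means)) pop$means[fit$prep$covariates]
            else colMeans(pop$X[, fit$prep$covariates, drop = FALSE])
    db <- .bvec_draws(fit, b) - .bvec_draws(fit, a)
    h <- h + drop(db %*% xbar)
  }
  structure(list(kind = "contrast", population = pop$name,
                 treatments = c(a = a, b = b), draws = h,
                 summary = data.frame(population = pop$name,
                                      contrast = paste(b, "vs", a),
                                      t(.summarise_draws(h)))),
            class = "mlnmr_estimate")
}

#' Population-average absolute outcome on a treatment
#'
#' Averages the inverse-link of the individual linear predictor over the
#' population's covariate representation per posterior draw:
#' `mean over x of ginv(mu_P + x'(beta1 + beta2_k) + gamma_k)`.
#'
#' @param fit an `mlnmr_fit`.
#' @param population a [target_population()] or study id; must carry a full
#'   covariate representation (rows or grid) and a resolvable baseline.
#' @param k treatment label.
#' @return an `mlnmr_estimate` (probability scale for binary outcomes).
#' @export
population_absolute <- function(fit, population, k) {
  stopifnot(inherits(fit, "mlnmr_fit"))
  if (fit$ume) stop("absolute predictions require the consistency model")
  trts <- fit$prep$treatments
  if (!k %in% trts) stop("treatment not in network: ", k)
  pop <- .resolve_population(fit, population)
  if (is.null(pop$mu))
    stop("population '", pop$name, "' has no baseline: give `baseline` or ",
         "a study-based population")
  dr <- fit$draws
  ginv <- .links[[fit$model$link]]$ginv
  d <- length(fit$prep$covariates)
  if (d == 0L) {
    h <- ginv(pop$mu + dr$gamma[, k])
  } else {
    if (is.null(pop$X))
      stop("absolute predictions need a full covariate representation ",
           "(IPD rows or a grid), not just means")
    X <- pop$X[, fit$prep$covariates, drop = FALSE]
    B <- .bvec_draws(fit, k)            # ndraws x d
    ETA <- tcrossprod(B, X)             # ndraws x npoints
    h <- rowMeans(ginv(ETA + pop$mu + dr$gamma[, k]))
  }
  structure(list(kind = "absolute", population = pop$name,
                 treatments = k, draws = h,
                 summary = data.frame(population = pop$name, treatment = k,
                                      t(.summarise_draws(h)))),
            class = "mlnmr_estimate")
}

#' All pairwise contrasts and absolute outcomes in a population
#'
#' @param fit an `mlnmr_fit`.
#' @param population a [target_population()] or study id.
#' @param absolute also compute the absolute outcome on every treatment
#'   (needs a baseline and full covariate representation).
#' @return list with data frames `contrasts` (K(K-1)/2 rows) and
#'   `absolute` (K rows or `NULL`).
#' @export
all_pairwise <- function(fit, population, absolute = TRUE) {
  trts <- fit$prep$treatments
  prs <- utils::combn(trts, 2L)
  cl <- lapply(seq_len(ncol(prs)), function(i)
    population_contrast(fit, population, prs[1, i], prs[2, i])$summary)
  contrasts <- do.call(rbind, cl)
  abs_tab <- NULL
  if (absolute) {
    al <- lapply(trts, function(k)
      population_absolute(fit, population, k)$summary)
    abs_tab <- do.call(rbind, al)
  }
  list(contrasts = contrasts, absolute = abs_tab)
}

#' @export
print.mlnmr_estimate <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
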