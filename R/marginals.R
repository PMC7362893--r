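# Marginal covariate distributions for aggregate-data studies, parameterised
# from published summary statistics (mean/SD or a proportion) by moment
# matching. Each spec carries a quantile function used in the inverse-CDF
# step of the copula transform.

#' Specify a marginal covariate distribution from summary statistics
#'
#' Builds a moment-matched marginal distribution for one covariate in an
#' aggregate-data study. Continuous covariates are matched to the reported
#' mean and standard deviation; binary covariates to the reported proportion.
#'
#' Supported families:
#' \describe{
#'   \item{`normal`}{mean/SD as given.}
#'   \item{`gamma`}{moment matched, `shape = (mean/sd)^2`,
#'     `rate = mean/sd^2`; suitable for right-skewed covariates such as
#'     weight or disease duration.}
#'   \item{`logitnormal`}{a logit-normal rescaled to `bounds` (default
#'     `[0, 100]`), for percentage covariates such as body surface area;
#'     location/scale found by numerical moment matching.}
#'   \item{`bernoulli`}{binary covariate with the given proportion.}
#' }
#'
#' @param name covariate name.
#' @param family one of `"normal"`, `"gamma"`, `"logitnormal"`, `"bernoulli"`.
#' @param mean,sd summary mean and standard deviation (continuous families).
#' @param prop proportion in `[0, 1]` (`bernoulli` only).
#' @param bounds support for `logitnormal`, default `c(0, 100)`.
#' @return an object of class `mlnmr_marginal` with the matched parameters
#'   and a quantile function `qfun(u)`.
#' @examples
#' m <- marginal_spec("weight", "gamma", mean = 83.3, sd = 20.8)
#' m$params
#' @export
marginal_spec <- function(name, family = c("normal", "gamma", "logitnormal",
                                           "bernoulli"),
                          mean = NULL, sd = NULL, prop = NULL,
                          bounds = c(0, 100)) {
  family <- match.arg(family)
  if (!is.null(mean)) mean <- unname(mean)
  if (!is.null(sd)) sd <- unname(sd)
  if (!is.null(prop)) prop <- unname(prop)
  out <- list(name = name, family = family, bounds = bounds)
  if (family == "bernoulli") {
    if (is.null(prop) || is.na(prop) || prop < 0 || prop > 1)
      stop("bernoulli marginal '", name, "' requires `prop` in [0, 1]")
    out$prop <- prop
    out$params <- c(prop = prop)
    # latent standard normal thresholded at the (1 - prop) quantile
    out$qfun <- function(u) as.numeric(u > 1 - prop)
  } else {
    if (is.null(mean) || is.null(sd) || is.na(mean) || is.na(sd))
      stop("marginal '", name, "' requires `mean` and `sd`")
    if (sd <= 0) stop("marginal '", name, "' requires sd > 0")
    out$mean <- mean; out$sd <- sd
    if (family == "normal") {
      out$params <- c(mean = mean, sd = sd)
      out$qfun <- function(u) stats::qnorm(u, mean = mean, sd = sd)
    } else if (family == "gamma") {
      if (mean <= 0) stop("gamma marginal '", name, "' requires mean > 0")
      shape <- (mean / sd)^2
      rate <- mean / sd^2
      out$params <- c(shape = shape, rate = rate)
      out$qfun <- function(u) stats::qgamma(u, shape = shape, rate = rate)
    } else { # logitnormal on [lo, hi]
      lo <- bounds[1]; hi <- bounds[2]
      if (mean <= lo || mean >= hi)
        stop("logitnormal marginal '", name, "' requires mean inside bounds")
      pars <- .logitnormal_match(mean, sd, lo, hi)
      mu <- pars[1]; sigma <- pars[2]
      out$params <- c(mu = mu, sigma = sigma, lo = lo, hi = hi)
      out$qfun <- function(u)
        lo + (hi - lo) * stats::plogis(mu + sigma * stats::qnorm(u))
    }
  }
  # moment check: matched parameters must reproduce the declared summaries
  chk <- .marginal_moments(out)
  if (family %in% c("normal", "gamma")) {
    stopifnot(abs(chk[1] - mean) < 1e-6 * max(1, abs(mean)),
              abs(chk[2] - sd) < 1e-6 * max(1, sd))
  } else if (family == "logitnormal") {
    if (abs(chk[1] - mean) > 1e-2 * max(1, abs(mean)) ||
        abs(chk[2] - sd) > 1e-2 * max(1, sd))
      stop("logitnormal moment matching failed for '", name,
           "': achieved mean ", signif(chk[1], 6), ", sd ", signif(chk[2], 6))
  }
  structure(out, class = "mlnmr_marginal")
}

# mean and sd implied by a marginal spec (numeric for logitnormal)
.marginal_moments <- function(m) {
  switch(m$family,
    normal = c(m$mean, m$sd),
    gamma = {
      s <- m$params[["shape"]]; r <- m$params[["rate"]]
      c(s / r, sqrt(s) / r)
    },
    bernoulli = c(m$prop, sqrt(m$prop * (1 - m$prop))),
    logitnormal = {
      mu <- m$params[["mu"]]; sigma <- m$params[["sigma"]]
      lo <- m$params[["lo"]]; hi <- m$params[["hi"]]
      mo <- .logitnormal_moments(mu, sigma)
      c(lo + (hi - lo) * mo[1], (hi - lo) * mo[2])
    })
}

# mean/sd of plogis(mu + sigma Z), Z ~ N(0,1), by Gauss-Legendre on (0,1)
.logitnormal_moments <- function(mu, sigma) {
  u <- (seq_len(201) - 0.5) / 201
  z <- stats::qnorm(u)
  p <- stats::plogis(mu + sigma * z)
  m1 <- mean(p)
  m2 <- mean(p^2)
  c(m1, sqrt(max(m2 - m1^2, 0)))
}

# solve for (mu, sigma) of the scaled logit-normal matching mean/sd
.logitnormal_match <- function(mean, sd, lo, hi) {
  tm <- (mean - lo) / (hi - lo)
  ts <- sd / (hi - lo)
  obj <- function(par) {
    mo <- .logitnormal_moments(par[1], exp(par[2]))
    (mo[1] - tm)^2 + (mo[2] - ts)^2
  }
  start <- c(stats::qlogis(tm), log(max(ts / (tm * (1 - tm)), 0.1)))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  if (opt$value > 1e-6)
    stop("could not match logit-normal moments: mean ", mean, ", sd ", sd,
         " on [", lo, ", ", hi, "] (residual ", signif(opt$value, 3), ")")
  c(opt$par[1], exp(opt$par[2]))
}

#' @export
print.mlnmr_marginal <- function(x, ...) {
  cat("<marginal>", x$name, "~", x$family, "(",
      paste(names(x$params), signif(unname(x$params), 4), sep = " = ",
            collapse = ", "), ")\n")
  invisible(x)
}
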