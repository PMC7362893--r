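# Gaussian copula correlation structure for aggregate-study covariates,
# borrowed from the rank correlations observed in the IPD studies.

#' Convert a Spearman rank correlation to a Gaussian copula correlation
#'
#' For a bivariate Gaussian copula with latent correlation `r`, the Spearman
#' rank correlation of the transformed margins is `(6 / pi) * asin(r / 2)`.
#' This function inverts that relationship, `r = 2 sin(pi * rho_s / 6)`, so
#' that a copula built from IPD rank correlations reproduces them on the
#' generated integration points.
#'
#' @param rho_s Spearman rank correlation(s) in `[-1, 1]` (vector or matrix).
#' @return latent normal correlation(s), same shape as the input.
#' @examples
#' spearman_to_copula(0.5)  # 0.5176381
#' @export
spearman_to_copula <- function(rho_s) {
  if (any(is.na(rho_s)) || any(abs(rho_s) > 1))
    stop("Spearman correlations must lie in [-1, 1]")
  2 * sin(pi * rho_s / 6)
}

#' Estimate the covariate correlation structure from IPD studies
#'
#' Computes Spearman rank correlations between covariates within each IPD
#' study and pools them across studies, weighting each study's estimate by
#' its sample size. The pooled rank correlations are mapped to a latent
#' Gaussian copula correlation matrix (see [spearman_to_copula()]), which is
#' repaired to the nearest positive semi-definite matrix if the elementwise
#' transform leaves the PSD cone.
#'
#' @param ipd list of IPD studies (from [read_ipd()] or [simulate_ipd()]).
#' @param covariates character vector of covariate names (>= 2).
#' @return an object of class `mlnmr_correlation` with elements
#'   `covariates`, `spearman` (pooled rank correlation matrix) and `copula`
#'   (latent normal correlation matrix, PSD-repaired).
#' @export
estimate_ipd_correlation <- function(ipd, covariates) {
  if (inherits(ipd, "ipd_study")) ipd <- list(ipd)
  if (length(covariates) < 2L)
    stop("need at least 2 covariates to estimate a correlation structure")
  n_tot <- sum(vapply(ipd, function(s) nrow(s$rows), 0L))
  if (n_tot < 3L) stop("need at least 3 pooled individuals")
  d <- length(covariates)
  acc <- matrix(0, d, d, dimnames = list(covariates, covariates))
  wsum <- 0
  for (s in ipd) {
    miss <- setdiff(covariates, names(s$rows))
    if (length(miss) > 0L)
      stop("study '", s$study_id, "' is missing covariates: ",
           paste(miss, collapse = ", "))
    X <- as.matrix(s$rows[covariates])
    cst <- covariates[apply(X, 2, function(v) stats::sd(v) == 0)]
    if (length(cst) > 0L)
      stop("correlation undefined: covariate(s) constant in study '",
           s$study_id, "': ", paste(cst, collapse = ", "))
    w <- nrow(X)
    acc <- acc + w * stats::cor(X, method = "spearman")
    wsum <- wsum + w
  }
  rho <- acc / wsum
  off <- rho[upper.tri(rho)]
  if (any(abs(off) > 1 - 1e-12))
    warning("degenerate rank correlation of +/-1 between covariates; ",
            "check for duplicated columns")
  cop <- spearman_to_copula(pmin(pmax(rho, -1), 1))
  diag(cop) <- 1
  cop <- repair_psd(cop)
  structure(list(covariates = covariates, spearman = rho, copula = cop),
            class = "mlnmr_correlation")
}

#' Project a symmetric matrix onto the positive semi-definite cone
#'
#' Eigenvalues below `tol` are clipped to `tol` and the matrix is rescaled
#' back to unit diagonal. Elementwise transforms of valid correlation
#' matrices (such as the Spearman-to-copula map) can lose positive
#' semi-definiteness; this restores a usable correlation matrix.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param tol eigenvalue floor, default `1e-8`.
#' @return a positive definite correlation matrix.
#' @export
repair_psd <- function(R, tol = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-10)) stop("matrix must be symmetric")
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values >= tol)) return(R)
  v <- pmax(e$values, tol)
  out <- e$vectors %*% (v * t(e$vectors))
  s <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(s)
  dimnames(out) <- dimnames(R)
  out
}

#' @export
print.mlnmr_correlation <- function(x, ...) {
  cat("<correlation model>", length(x$covariates), "covariates\n")
  cat("Pooled Spearman rank correlations:\n")
  print(round(x$spearman, 3))
  invisible(x)
}

# Draw pseudo-random correlated covariates from marginals + copula
# (used by the synthetic-data generator; the integration grids use Sobol'
# points instead).
.copula_sample <- function(n, marginals, copula = NULL) {
  d <- length(marginals)
  Z <- matrix(stats::rnorm(n * d), n, d)
  if (!is.null(copula) && d > 1L) {
    R <- copula[vapply(marginals, `[[`, "", "name"),
                vapply(marginals, `[[`, "", "name")]
    Z <- Z %*% chol(repair_psd(R))
  }
  U <- stats::pnorm(Z)
  X <- vapply(seq_len(d), function(l) marginals[[l]]$qfun(U[, l]),
              numeric(n))
  colnames(X) <- vapply(marginals, `[[`, "", "name")
  X
}
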