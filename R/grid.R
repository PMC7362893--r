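# Fixed quasi-Monte-Carlo integration grids representing each aggregate
# study's joint covariate distribution. A grid is built once from the
# published marginal summaries plus the IPD-borrowed copula correlation,
# and then held fixed through every posterior evaluation.

#' Build a QMC integration grid for an aggregate-data study
#'
#' Generates `n_points` Sobol' points in the unit hypercube (one dimension
#' per covariate), maps them to correlated latent normals through the
#' Cholesky factor of the Gaussian copula correlation matrix, and applies
#' each covariate's marginal quantile function to the normal CDF values.
#' The result preserves each declared marginal distribution exactly while
#' imposing the IPD rank correlation structure.
#'
#' @param marginals list of [marginal_spec()] objects, one per covariate,
#'   covering every adjustment covariate.
#' @param corr optional `mlnmr_correlation` (from
#'   [estimate_ipd_correlation()]) or a copula correlation matrix with
#'   dimnames; `NULL` means independent covariates.
#' @param n_points number of integration points (default 10000).
#' @param seed seed for the Sobol' scrambling.
#' @param study_id label for the study the grid represents.
#' @return an object of class `mlnmr_grid`: list with `study_id`, `points`
#'   (an `n_points` by `d` matrix with covariate names), `n_points`, `seed`,
#'   `marginals` and `copula`.
#' @examples
#' m <- list(marginal_spec("age", "normal", mean = 45, sd = 13),
#'           marginal_spec("psa", "bernoulli", prop = 0.2))
#' g <- build_grid(m, n_points = 256, seed = 42)
#' colMeans(g$points)
#' @export
build_grid <- function(marginals, corr = NULL, n_points = 10000, seed = 1L,
                       study_id = NULL) {
  if (inherits(marginals, "mlnmr_marginal")) marginals <- list(marginals)
  stopifnot(length(marginals) >= 1L,
            all(vapply(marginals, inherits, TRUE, "mlnmr_marginal")))
  nm <- vapply(marginals, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate covariate names in marginals")
  d <- length(nm)
  R <- diag(d)
  dimnames(R) <- list(nm, nm)
  if (!is.null(corr)) {
    M <- if (inherits(corr, "mlnmr_correlation")) corr$copula else corr
    if (is.null(dimnames(M)) && !identical(dim(M), c(d, d)))
      stop("copula correlation matrix must carry covariate dimnames")
    if (!is.null(dimnames(M))) {
      miss <- setdiff(nm, rownames(M))
      if (length(miss) > 0L)
        stop("copula correlation missing covariates: ",
             paste(miss, collapse = ", "))
      M <- M[nm, nm]
    }
    R <- repair_psd(M)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("copula correlation matrix is not positive definite after repair")
  }
  U <- sobol_unit_points(n_points, d, seed = seed)
  Z <- stats::qnorm(pmin(pmax(U, 1e-12), 1 - 1e-12))
  if (d > 1L) Z <- Z %*% chol(R)
  U2 <- stats::pnorm(Z)
  X <- vapply(seq_len(d), function(l) marginals[[l]]$qfun(U2[, l]),
              numeric(n_points))
  colnames(X) <- nm
  structure(list(study_id = study_id, points = X,
                 n_points = as.integer(n_points), seed = as.integer(seed),
                 marginals = marginals, copula = R),
            class = "mlnmr_grid")
}

#' Build integration grids for every aggregate study in a network
#'
#' Convenience wrapper: chooses marginal specifications from each AgD
#' study's covariate summaries, estimates the covariate correlation from the
#' network's IPD studies (when two or more covariates are present and IPD
#' are available), and builds one fixed grid per aggregate study.
#'
#' @param network an `mlnmr_network`.
#' @param families named character vector giving the marginal family per
#'   covariate (`"normal"`, `"gamma"`, `"logitnormal"`, `"bernoulli"`);
#'   covariates with only a proportion summary default to `"bernoulli"`,
#'   others to `"normal"`.
#' @param covariates covariates to include; default all network covariates.
#' @param n_points,seed passed to [build_grid()]; grid seeds are offset by
#'   the study position so each study gets a distinct scrambling.
#' @param corr optional correlation model; default estimated from IPD.
#' @param bounds named list of support bounds for `logitnormal` covariates.
#' @return named list of `mlnmr_grid`, one per AgD study.
#' @export
build_network_grids <- function(network, families = NULL, covariates = NULL,
                                n_points = 10000, seed = 1L, corr = NULL,
                                bounds = NULL) {
  stopifnot(inherits(network, "mlnmr_network"))
  covariates <- covariates %||% network$covariates
  agd <- Filter(function(s) inherits(s, "agd_study"), network$studies)
  ipd <- Filter(function(s) inherits(s, "ipd_study"), network$studies)
  if (length(agd) == 0L) return(list())
  if (is.null(corr) && length(ipd) > 0L && length(covariates) >= 2L)
    corr <- estimate_ipd_correlation(ipd, covariates)
  grids <- list()
  for (i in seq_along(agd)) {
    s <- agd[[i]]
    marg <- lapply(covariates, function(cv) {
      cs <- s$covariate_summaries[[cv]]
      if (is.null(cs))
        stop("AgD study '", s$study_id, "' has no summary for covariate '",
             cv, "'")
      fam <- if (!is.null(families) && cv %in% names(families))
        families[[cv]]
      else if (!is.null(cs$prop)) "bernoulli" else "normal"
      if (fam == "bernoulli")
        marginal_spec(cv, "bernoulli", prop = cs$prop)
      else
        marginal_spec(cv, fam, mean = cs$mean, sd = cs$sd,
                      bounds = bounds[[cv]] %||% c(0, 100))
    })
    grids[[s$study_id]] <- build_grid(marg, corr = corr, n_points = n_points,
                                      seed = as.integer(seed) + i - 1L,
                                      study_id = s$study_id)
  }
  grids
}

#' Write / read an integration grid with a provenance sidecar
#'
#' The points are written as CSV and a JSON sidecar records the seed, the
#' number of points, the marginal specifications and the copula matrix, so
#' a grid can be reloaded bit-identically or rebuilt from its provenance.
#'
#' @param grid an `mlnmr_grid`.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `write_grid` returns `path` invisibly; `read_grid` the grid.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "mlnmr_grid"))
  utils::write.csv(as.data.frame(grid$points), path, row.names = FALSE)
  meta <- list(
    study_id = grid$study_id,
    n_points = grid$n_points,
    seed = grid$seed,
    marginals = lapply(grid$marginals, function(m)
      list(name = m$name, family = m$family, params = as.list(m$params),
           bounds = m$bounds)),
    copula = grid$copula
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  X <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  marginals <- lapply(meta$marginals, function(row) {
    fam <- row$family
    p <- row$params
    if (fam == "bernoulli")
      marginal_spec(row$name, fam, prop = p$prop)
    else if (fam == "logitnormal") {
      mo <- .logitnormal_moments(p$mu, p$sigma)
      marginal_spec(row$name, fam,
                    mean = p$lo + (p$hi - p$lo) * mo[1],
                    sd = (p$hi - p$lo) * mo[2],
                    bounds = unlist(row$bounds))
    } else if (fam == "gamma")
      marginal_spec(row$name, fam, mean = p$shape / p$rate,
                    sd = sqrt(p$shape) / p$rate)
    else
      marginal_spec(row$name, fam, mean = p$mean, sd = p$sd)
  })
  cop <- do.call(rbind, lapply(meta$copula, unlist))
  dimnames(cop) <- list(colnames(X), colnames(X))
  structure(list(study_id = meta$study_id, points = X,
                 n_points = as.integer(meta$n_points),
                 seed = as.integer(meta$seed),
                 marginals = marginals, copula = cop),
            class = "mlnmr_grid")
}

#' @export
print.mlnmr_grid <- function(x, ...) {
  cat("<integration grid>", if (!is.null(x$study_id)) x$study_id else "",
      "\n  ", x$n_points, "points x", ncol(x$points), "covariates (",
      paste(colnames(x$points), collapse = ", "), ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
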