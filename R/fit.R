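# Bayesian posterior sampling of the multilevel model via Gibbs/slice
# sampling (JAGS), with covariate centring for sampling efficiency and
# un-centring of the reported draws.

#' Sampler configuration
#'
#' @param chains number of parallel chains (>= 2 for convergence
#'   diagnostics; defaults to 4).
#' @param warmup iterations discarded per chain (adaptation + burn-in).
#' @param iter posterior iterations kept per chain.
#' @param seed integer seed; chain `c` uses RNG seed `seed + c`.
#' @param n_points default number of integration points when grids are
#'   built internally.
#' @return a `fit_config` list.
#' @export
fit_config <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1L,
                       n_points = 10000) {
  stopifnot(chains >= 1, warmup > 0, iter > 0)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 n_points = as.integer(n_points)),
            class = "fit_config")
}

# warn when an effect-modifier tying group has no identifying data
.check_identifiability <- function(network, model, prep) {
  if (length(model$effect_modifiers) == 0L) return(invisible())
  em <- prep$em
  at <- prep$arm_tab
  for (r in seq.int(2L, length.out = em$n_rows - 1L)) {
    trts <- which(em$row == r)
    arms <- at[at$t_ix %in% trts, ]
    n_ipd <- sum(arms$kind == "I")
    n_agd_studies <- length(unique(arms$s_ix[arms$kind == "A"]))
    if (n_ipd == 0L && n_agd_studies < 2L)
      warning("effect-modifier group '", em$labels[r],
              "' is supported by no IPD study and fewer than 2 AgD ",
              "studies; interactions may not be identifiable", call. = FALSE)
  }
  invisible()
}

#' Fit a multilevel network meta-regression model
#'
#' Samples the joint posterior of the study intercepts, prognostic and
#' effect-modifier coefficients, treatment effects (and heterogeneity sd
#' under random effects) by MCMC. IPD studies contribute individual-level
#' likelihood terms; each aggregate study contributes arm-level terms whose
#' mean outcome integrates the individual model over the study's fixed
#' integration grid (the two-parameter binomial approximation for binary
#' outcomes). Grids are held fixed across iterations.
#'
#' @param network an `mlnmr_network`.
#' @param model an `mlnmr_model`.
#' @param grids named list of `mlnmr_grid` objects keyed by AgD study id;
#'   built automatically via [build_network_grids()] when `NULL` and the
#'   model has covariates.
#' @param config a [fit_config()].
#' @param ume fit the unrelated-mean-effects (inconsistency) model instead
#'   of the consistency model; see [ume_fit()].
#' @param quiet suppress JAGS progress output.
#' @return an object of class `mlnmr_fit` carrying uncentred posterior
#'   draws, the raw `coda::mcmc.list`, the model/data preparation and
#'   sampler diagnostics.
#' @export
mlnmr_fit <- function(network, model, grids = NULL, config = fit_config(),
                      ume = FALSE, quiet = TRUE) {
  stopifnot(inherits(network, "mlnmr_network"),
            inherits(model, "mlnmr_model"))
  if (network$outcome != switch(model$likelihood, bernoulli = "binary",
                                normal = "continuous", poisson = "count"))
    stop("model likelihood '", model$likelihood,
         "' does not match the network outcome kind '", network$outcome, "'")
  miss <- setdiff(model$covariates, network$covariates)
  if (length(miss) > 0L)
    stop("model covariates not in network: ", paste(miss, collapse = ", "))
  has_agd <- any(!vapply(network$studies, inherits, TRUE, "ipd_study"))
  if (is.null(grids) && has_agd && length(model$covariates) > 0L)
    grids <- build_network_grids(network, n_points = config$n_points,
                                 seed = config$seed,
                                 covariates = model$covariates)
  prep <- .prepare_jags(network, model, grids, ume = ume)
  .check_identifiability(network, model, prep)
  code <- .jags_code(prep, model)
  dat <- prep$data

  monitors <- "mu"
  if (length(prep$covariates) > 0L) monitors <- c(monitors, "beta1")
  if (length(prep$covariates) > 0L && prep$em$n_rows > 1L) monitors <- c(monitors, "beta2")
  if (ume) { if (dat$nPair > 0L) monitors <- c(monitors, "dume") }
  else if (dat$nT > 1L) monitors <- c(monitors, "gamma")
  if (model$effects == "random")
    monitors <- c(monitors, "tau", if (nrow(prep$delta_index) > 0L) "dd")
  if (prep$em$structure == "exchangeable")
    monitors <- c(monitors, "mB", "sigB")
  if (model$likelihood == "normal" && dat$nI > 0L)
    monitors <- c(monitors, "sigma")
  if (dat$nArmA > 0L) monitors <- c(monitors, "llA")

  inits <- lapply(seq_len(config$chains), function(ch) {
    ii <- list(.RNG.name = "base::Mersenne-Twister",
               .RNG.seed = config$seed + ch)
    if (model$effects == "random") ii$tau <- 0.5
    ii
  })
  n_adapt <- min(500L, max(100L, config$warmup %/% 2L))
  n_burn <- max(0L, config$warmup - n_adapt)
  t0 <- Sys.time()
  jd <- dat
  if (length(prep$covariates) == 0L)
    jd[c("d", "tI", "tA", "qA", "emrow")] <- NULL
  if (model$likelihood == "normal") jd$nA <- NULL
  if (dat$nI == 0L) jd$nI <- NULL
  if (dat$nArmA == 0L) jd$nArmA <- NULL
  jm <- rjags::jags.model(textConnection(code), data = jd,
                          inits = inits, n.chains = config$chains,
                          n.adapt = n_adapt, quiet = quiet)
  if (n_burn > 0L)
    stats::update(jm, n_burn,
                  progress.bar = if (quiet) "none" else "text")
  mcmc <- rjags::coda.samples(jm, monitors, n.iter = config$iter,
                              progress.bar = if (quiet) "none" else "text")
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  fit <- structure(list(network = network, model = model, grids = grids,
                        config = config, prep = prep, code = code,
                        mcmc = mcmc, ume = ume, runtime = runtime),
                   class = "mlnmr_fit")
  fit$draws <- .extract_draws(fit)
  fit$diagnostics <- diagnostics(fit)
  ndiv <- sum(fit$diagnostics$rhat > 1.01, na.rm = TRUE)
  if (ndiv > 0L)
    warning(ndiv, " parameter(s) with split-Rhat > 1.01; consider more ",
            "iterations", call. = FALSE)
  fit
}

# columns of the stacked mcmc matrix for a parameter group
.mcmc_cols <- function(M, name) {
  cols <- grep(paste0("^", name, "(\\[|$)"), colnames(M))
  M[, cols, drop = FALSE]
}

# first index of "name[i]" column labels ("name" alone, as coda writes
# length-1 nodes, is index 1)
.idx1 <- function(cols, name) {
  ix <- suppressWarnings(
    as.integer(sub(paste0(name, "\\[(\\d+)\\]"), "\\1", cols)))
  ix[cols == name] <- 1L
  ix
}

# (row, col) indices of "name[i,j]" labels; a bare "name" is (1, 1)
.idx2 <- function(cols, name) {
  m <- regmatches(cols, regexec(paste0(name, "\\[(\\d+),(\\d+)\\]"), cols))
  t(vapply(seq_along(cols), function(i) {
    if (length(m[[i]]) == 3L) as.integer(m[[i]][2:3]) else c(1L, 1L)
  }, integer(2)))
}

# Uncentre and relabel the raw draws. Centred-scale relations:
#   mu* = mu + xbar' beta1,  gamma* = gamma + xbar' beta2_k,
#   delta* = delta + xbar' beta2_k,  dume* = dume + xbar'(beta2_b - beta2_a)
.extract_draws <- function(fit) {
  prep <- fit$prep; model <- fit$model
  M <- as.matrix(do.call(rbind, lapply(fit$mcmc, unclass)))
  ndraw <- nrow(M)
  d <- length(prep$covariates)
  xv <- prep$covariates
  xbar <- prep$xbar
  em <- prep$em
  K <- length(prep$treatments)

  out <- list(n_draws = ndraw)
  beta1 <- matrix(0, ndraw, max(d, 1L),
                  dimnames = list(NULL, if (d > 0L) xv else "none"))
  beta2 <- array(0, dim = c(ndraw, em$n_rows, max(d, 1L)),
                 dimnames = list(NULL, em$labels,
                                 if (d > 0L) xv else "none"))
  if (d > 0L) {
    xsd <- prep$xsd
    B1 <- .mcmc_cols(M, "beta1")
    ll1 <- .idx1(colnames(B1), "beta1")
    # sampled coefficients are per standardised unit; rescale to raw units
    beta1[, ll1] <- sweep(B1, 2, xsd[ll1], `/`)
    colnames(beta1) <- xv
    if (em$n_rows > 1L) {
      B2 <- .mcmc_cols(M, "beta2")
      ij <- .idx2(colnames(B2), "beta2")
      for (c1 in seq_len(nrow(ij))) {
        r <- ij[c1, 1]; l <- ij[c1, 2]
        beta2[, r, l] <- B2[, c1] / xsd[l]
      }
    }
  }
  out$beta1 <- beta1[, seq_len(d), drop = FALSE]
  out$beta2 <- beta2[, , seq_len(max(d, 1L)), drop = FALSE]
  out$beta2_row <- stats::setNames(em$row, prep$treatments)

  # beta2 contribution xbar' beta2_k per tying row (for uncentring)
  off_row <- matrix(0, ndraw, em$n_rows)
  if (d > 0L)
    for (r in seq_len(em$n_rows))
      off_row[, r] <- drop(matrix(beta2[, r, seq_len(d)],
                                  nrow = ndraw) %*% xbar)

  MU <- .mcmc_cols(M, "mu")
  off_mu <- if (d > 0L) drop(beta1[, seq_len(d), drop = FALSE] %*% xbar)
            else 0
  out$mu <- MU - off_mu
  colnames(out$mu) <- prep$studies
  if (fit$ume && d > 0L) {
    # under unrelated mean effects mu_j is the study baseline-arm
    # intercept; remove that arm's interaction offset too
    at <- prep$arm_tab
    for (j in seq_along(prep$studies)) {
      bj <- at$base[match(j, at$s_ix)]
      out$mu[, j] <- out$mu[, j] - off_row[, em$row[bj]]
    }
  }

  if (!fit$ume) {
    gamma <- matrix(0, ndraw, K, dimnames = list(NULL, prep$treatments))
    if (K > 1L) {
      G <- .mcmc_cols(M, "gamma")
      kk <- .idx1(colnames(G), "gamma")
      gamma[, kk] <- G
    }
    for (k in seq_len(K)) gamma[, k] <- gamma[, k] - off_row[, em$row[k]]
    out$gamma <- gamma
  } else {
    pairs <- prep$ume_pairs
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      DU <- .mcmc_cols(M, "dume")
      ee <- .idx1(colnames(DU), "dume")
      DU <- DU[, order(ee), drop = FALSE]
      for (e in seq_len(nrow(pairs))) {
        ra <- em$row[match(pairs$a[e], prep$treatments)]
        rb <- em$row[match(pairs$b[e], prep$treatments)]
        DU[, e] <- DU[, e] - (off_row[, rb] - off_row[, ra])
      }
      colnames(DU) <- paste(pairs$b, "vs", pairs$a)
      out$dume <- DU
      out$ume_pairs <- pairs
    }
  }

  if (model$effects == "random") {
    out$tau <- drop(.mcmc_cols(M, "tau"))
    di <- prep$delta_index
    if (nrow(di) > 0L) {
      DD <- matrix(0, ndraw, nrow(di),
                   dimnames = list(NULL, paste(di$study, di$treatment,
                                               sep = ":")))
      Draw <- .mcmc_cols(M, "dd")
      jm <- .idx2(colnames(Draw), "dd")
      for (c1 in seq_len(nrow(jm))) {
        j <- jm[c1, 1]; m <- jm[c1, 2]
        r <- which(di$s_ix == j & di$m == m)
        off <- off_row[, em$row[di$t_ix[r]]]
        if (fit$ume) {
          at <- prep$arm_tab
          bj <- at$base[match(j, at$s_ix)]
          off <- off - off_row[, em$row[bj]]
        }
        DD[, r] <- Draw[, c1] - off
      }
      out$delta <- DD
      out$delta_index <- di
    }
  }
  if (prep$em$structure == "exchangeable") {
    out$m_beta2 <- .mcmc_cols(M, "mB")
    out$sigma_beta2 <- .mcmc_cols(M, "sigB")
  }
  if (model$likelihood == "normal" && prep$data$nI > 0L) {
    out$sigma <- .mcmc_cols(M, "sigma")
    colnames(out$sigma) <- prep$studies[seq_len(ncol(out$sigma))]
  }
  if (prep$data$nArmA > 0L) {
    LL <- .mcmc_cols(M, "llA")
    aa <- .idx1(colnames(LL), "llA")
    LL <- LL[, order(aa), drop = FALSE]
    colnames(LL) <- paste(prep$agd_index$study, prep$agd_index$treatment,
                          sep = ":")
    out$agd_loglik <- LL
  }
  out
}

#' Convergence and sampling diagnostics
#'
#' Split-chain potential scale reduction factors, effective sample sizes
#' and Monte Carlo standard errors for every monitored parameter.
#' Parameters with `rhat > 1.01` are flagged.
#'
#' @param fit an `mlnmr_fit` (or a `coda::mcmc.list`).
#' @return a data frame with columns `parameter`, `mean`, `sd`, `rhat`,
#'   `ess`, `mcse`, `flag`.
#' @export
diagnostics <- function(fit) {
  mcmc <- if (inherits(fit, "mlnmr_fit")) fit$mcmc else fit
  stopifnot(inherits(mcmc, "mcmc.list"))
  keep <- !grepl("^llA\\[", coda::varnames(mcmc))
  mcmc <- mcmc[, keep, drop = FALSE]
  # drop constant columns (structural zeros) which break gelman.diag
  M <- as.matrix(do.call(rbind, lapply(mcmc, unclass)))
  variable <- apply(M, 2, function(v) stats::sd(v) > 0)
  stats_mean <- colMeans(M)
  stats_sd <- apply(M, 2, stats::sd)
  rhat <- rep(NA_real_, ncol(M))
  if (coda::nchain(mcmc) >= 2L && any(variable)) {
    # split each chain in half for a split-chain Rhat
    split_list <- coda::mcmc.list(unlist(lapply(mcmc, function(ch) {
      n <- nrow(ch); h <- n %/% 2L
      list(coda::mcmc(ch[seq_len(h), variable, drop = FALSE]),
           coda::mcmc(ch[(h + 1L):(2L * h), variable, drop = FALSE]))
    }), recursive = FALSE))
    rhat[variable] <- tryCatch(
      coda::gelman.diag(split_list, autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1],
      error = function(e) NA_real_)
  }
  ess <- rep(NA_real_, ncol(M))
  ess[variable] <- coda::effectiveSize(mcmc[, variable, drop = FALSE])
  mcse <- ifelse(ess > 0, stats_sd / sqrt(ess), NA_real_)
  out <- data.frame(parameter = colnames(M), mean = stats_mean,
                    sd = stats_sd, rhat = rhat, ess = ess, mcse = mcse,
                    flag = !is.na(rhat) & rhat > 1.01, row.names = NULL)
  if (coda::nchain(mcmc) < 2L)
    attr(out, "note") <- "single chain: rhat unavailable"
  out
}

#' @export
print.mlnmr_fit <- function(x, ...) {
  cat("<mlnmr fit> ", x$model$likelihood, "/", x$model$link, ", ",
      x$model$effects, " effects", if (x$ume) ", unrelated mean effects",
      "\n", sep = "")
  cat("  ", x$config$chains, " chains x ", x$config$iter,
      " iterations (", round(x$runtime, 1), " s)\n", sep = "")
  dg <- x$diagnostics
  cat("  max split-Rhat: ", round(max(dg$rhat, na.rm = TRUE), 4),
      ", min ESS: ", round(min(dg$ess, na.rm = TRUE)), "\n", sep = "")
  if (!x$ume && !is.null(x$draws$gamma)) {
    cat("Individual-level treatment effects vs ",
        x$network$reference, ":\n", sep = "")
    g <- x$draws$gamma[, -1, drop = FALSE]
    qs <- t(apply(g, 2, function(v)
      c(mean = mean(v), stats::quantile(v, c(0.025, 0.975)))))
    print(round(qs, 3))
  }
  invisible(x)
}

#' Extract a tidy summary of the posterior draws
#'
#' @param object an `mlnmr_fit`.
#' @param ... unused.
#' @return data frame with posterior mean, sd and 95% credible interval
#'   per reported (uncentred) parameter.
#' @export
summary.mlnmr_fit <- function(object, ...) {
  dr <- object$draws
  blocks <- list()
  push <- function(M, prefix) {
    if (is.null(M)) return()
    M <- as.matrix(M)
    blocks[[length(blocks) + 1L]] <<- data.frame(
      parameter = paste0(prefix, colnames(M) %||%
                           as.character(seq_len(ncol(M)))),
      mean = colMeans(M), sd = apply(M, 2, stats::sd),
      lower = apply(M, 2, stats::quantile, 0.025),
      upper = apply(M, 2, stats::quantile, 0.975), row.names = NULL)
  }
  push(dr$mu, "mu.")
  push(dr$beta1, "beta1.")
  if (!is.null(dr$beta2) && dim(dr$beta2)[2] > 1L) {
    for (r in 2:dim(dr$beta2)[2])
      push(matrix(dr$beta2[, r, ], nrow = dim(dr$beta2)[1],
                  dimnames = list(NULL, dimnames(dr$beta2)[[3]])),
           paste0("beta2.", dimnames(dr$beta2)[[2]][r], "."))
  }
  if (!is.null(dr$gamma)) push(dr$gamma[, -1, drop = FALSE], "gamma.")
  if (!is.null(dr$dume)) push(dr$dume, "d.")
  if (!is.null(dr$tau)) push(matrix(dr$tau, ncol = 1,
                                    dimnames = list(NULL, "tau")), "")
  if (!is.null(dr$delta)) push(dr$delta, "delta.")
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
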