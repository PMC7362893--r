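# Goodness of fit: residual deviance per data point (IPD rows and AgD
# arms), DIC, residual-heterogeneity assessment (fixed vs random effects)
# and the unrelated-mean-effects inconsistency check.

# Per-draw parameter set for internal likelihood evaluation (uncentred).
.param_draws <- function(fit) {
  dr <- fit$draws
  list(n = dr$n_draws, mu = dr$mu, beta1 = dr$beta1, beta2 = dr$beta2,
       beta2_row = dr$beta2_row, gamma = dr$gamma, delta = dr$delta,
       delta_index = dr$delta_index, dume = dr$dume,
       ume_pairs = dr$ume_pairs, sigma = dr$sigma)
}

# posterior means of the same parameter set (for Dhat)
.param_means <- function(pd) {
  out <- pd
  for (nm in c("mu", "beta1", "gamma", "delta", "dume", "sigma"))
    if (!is.null(pd[[nm]]))
      out[[nm]] <- matrix(colMeans(as.matrix(pd[[nm]])), nrow = 1,
                          dimnames = list(NULL,
                                          colnames(as.matrix(pd[[nm]]))))
  if (!is.null(pd$beta2)) {
    m <- apply(pd$beta2, c(2, 3), mean)
    out$beta2 <- array(m, dim = c(1, dim(pd$beta2)[2], dim(pd$beta2)[3]),
                       dimnames = c(list(NULL), dimnames(pd$beta2)[2:3]))
  }
  out$n <- 1L
  out
}

# treatment-effect term draws for one arm (vector over draws)
.arm_effect <- function(fit, pd, s_ix, t_ix) {
  prep <- fit$prep
  if (fit$model$effects == "random") {
    key <- paste(prep$studies[s_ix], prep$treatments[t_ix], sep = ":")
    if (!is.null(pd$delta) && key %in% colnames(pd$delta))
      return(pd$delta[, key])
  }
  if (fit$ume) {
    at <- prep$arm_tab
    base <- at$base[match(s_ix, at$s_ix)]
    if (t_ix == base) return(rep(0, pd$n))
    lab <- paste(prep$treatments[t_ix], "vs", prep$treatments[base])
    if (fit$model$effects == "random") return(rep(0, pd$n))  # handled above
    return(pd$dume[, lab])
  }
  if (t_ix == 1L) rep(0, pd$n) else pd$gamma[, t_ix]
}

# ndraws x d coefficient matrix beta1 + beta2_k
.bvec_pd <- function(pd, t_ix, prep) {
  d <- length(prep$covariates)
  if (d == 0L) return(NULL)
  r <- pd$beta2_row[[prep$treatments[t_ix]]]
  pd$beta1 + matrix(pd$beta2[, r, seq_len(d)], nrow = pd$n)
}

# Per-data-point deviance averaged over the given parameter draws.
# Returns a data frame: one row per IPD individual and per AgD arm.
.pointwise_deviance <- function(fit, pd) {
  prep <- fit$prep
  dat <- prep$data
  lik <- fit$model$likelihood
  ginv <- .links[[fit$model$link]]$ginv
  d <- length(prep$covariates)
  xbar <- prep$xbar
  out <- list()

  if (dat$nI > 0L) {
    dev <- numeric(dat$nI)
    for (a in seq_len(dat$nArmI)) {
      ii <- dat$startI[a]:dat$endI[a]
      y <- dat$yI[ii]
      eta <- matrix(rep(pd$mu[, dat$sI[a]], length(ii)), nrow = pd$n) +
        .arm_effect(fit, pd, dat$sI[a], dat$tI[a])
      if (d > 0L) {
        Xraw <- sweep(sweep(dat$XI[ii, , drop = FALSE], 2, prep$xsd, `*`),
                      2, -xbar)
        eta <- eta + tcrossprod(.bvec_pd(pd, dat$tI[a], prep), Xraw)
      }
      if (lik == "bernoulli") {
        p <- pmin(pmax(ginv(eta), 1e-12), 1 - 1e-12)
        ll <- t(y * t(log(p)) + (1 - y) * t(log1p(-p)))
        dev[ii] <- colMeans(-2 * ll)
      } else if (lik == "normal") {
        sg <- pd$sigma[, dat$sI[a]]
        dev[ii] <- colMeans(sweep(eta, 2, y)^2 / sg^2)
      } else {
        lam <- exp(eta)
        sat <- ifelse(y > 0, y * log(y) - y, 0)
        ll <- t(y * t(log(lam))) - lam
        dev[ii] <- colMeans(2 * (sat - ll))
      }
    }
    out$ipd <- data.frame(level = "individual",
                          study = prep$ipd_index$study,
                          treatment = prep$ipd_index$treatment,
                          deviance = dev)
  }

  if (dat$nArmA > 0L) {
    devA <- numeric(dat$nArmA)
    for (a in seq_len(dat$nArmA)) {
      y <- dat$yA[a]; N <- dat$nA[a]
      eta0 <- pd$mu[, dat$sA[a]] + .arm_effect(fit, pd, dat$sA[a],
                                               dat$tA[a])
      if (d > 0L) {
        q <- dat$qA[a]
        Graw <- sweep(sweep(matrix(dat$XG[q, seq_len(dat$ngrid[q]), ],
                                   ncol = d), 2, prep$xsd, `*`),
                      2, -xbar)
        ETA <- tcrossprod(.bvec_pd(pd, dat$tA[a], prep), Graw) + eta0
        P <- ginv(ETA)
        pbar <- rowMeans(P)
        p2bar <- rowMeans(P^2)
      } else {
        pbar <- ginv(eta0)
        p2bar <- pbar^2
      }
      if (lik == "bernoulli")
        pbar <- pmin(pmax(pbar, 1e-12), 1 - 1e-12)
      if (lik == "bernoulli") {
        p2bar <- pmin(pmax(p2bar, pbar^2), pbar)
        Nadj <- N * pbar^2 / p2bar
        padj <- p2bar / pbar
        fitted <- Nadj * padj
        t1 <- if (y > 0) y * log(y / fitted) else 0
        t2 <- ifelse(Nadj - y > 0,
                     (Nadj - y) * log((Nadj - y) / (Nadj * (1 - padj))),
                     0)
        devA[a] <- mean(2 * (t1 + t2))
      } else if (lik == "normal") {
        devA[a] <- mean((y - pbar)^2 / dat$seA[a]^2)
      } else {
        lam <- N * pbar
        sat <- if (y > 0) y * log(y) - y else 0
        devA[a] <- mean(2 * (sat - (y * log(lam) - lam)))
      }
    }
    out$agd <- data.frame(level = "aggregate",
                          study = prep$agd_index$study,
                          treatment = prep$agd_index$treatment,
                          deviance = devA)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Residual deviance report
#'
#' Posterior mean residual deviance per data point (each IPD individual
#' and each AgD arm counts as one data point), with IPD and aggregate
#' subtotals. Binary IPD rows use the Bernoulli deviance; AgD arms the
#' two-parameter-adjusted binomial deviance (the observed count is
#' compared against the adjusted size `N'`). A well-fitting model
#' contributes about 1 per data point.
#'
#' @param fit an `mlnmr_fit`.
#' @return an object of class `mlnmr_fit_report`: list with `total`,
#'   `ipd_total`, `agd_total`, `n_points`, `per_point` (data frame), and
#'   the DIC components `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
residual_deviance <- function(fit) {
  stopifnot(inherits(fit, "mlnmr_fit"))
  pd <- .param_draws(fit)
  pp <- .pointwise_deviance(fit, pd)
  dic_parts <- dic(fit, per_point = pp)
  structure(list(total = sum(pp$deviance),
                 ipd_total = sum(pp$deviance[pp$level == "individual"]),
                 agd_total = sum(pp$deviance[pp$level == "aggregate"]),
                 n_points = nrow(pp),
                 per_point = pp,
                 Dbar = dic_parts$Dbar, Dhat = dic_parts$Dhat,
                 pD = dic_parts$pD, DIC = dic_parts$DIC),
            class = "mlnmr_fit_report")
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean total residual deviance, `Dhat` the total
#' residual deviance at the posterior means of the parameters,
#' `pD = Dbar - Dhat` the effective number of parameters and
#' `DIC = Dbar + pD`.
#'
#' @param fit an `mlnmr_fit`.
#' @param per_point optionally reuse a per-point deviance table.
#' @return list with `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
dic <- function(fit, per_point = NULL) {
  pd <- .param_draws(fit)
  if (is.null(per_point)) per_point <- .pointwise_deviance(fit, pd)
  Dbar <- sum(per_point$deviance)
  Dhat <- sum(.pointwise_deviance(fit, .param_means(pd))$deviance)
  if (!is.finite(Dbar) || !is.finite(Dhat))
    stop("non-finite deviance")
  list(Dbar = Dbar, Dhat = Dhat, pD = Dbar - Dhat, DIC = Dbar + (Dbar - Dhat))
}

#' @export
print.mlnmr_fit_report <- function(x, ...) {
  cat("Residual deviance:", round(x$total, 2), "on", x$n_points,
      "data points\n")
  cat("  individual-level contribution:", round(x$ipd_total, 2), "\n")
  cat("  aggregate-level contribution: ", round(x$agd_total, 2), "\n")
  cat("pD =", round(x$pD, 1), "  DIC =", round(x$DIC, 1), "\n")
  invisible(x)
}

#' Residual heterogeneity assessment
#'
#' Compares a fixed-effect and a random-effects fit of the same data by
#' DIC and summarises the posterior of the heterogeneity sd `tau`.
#'
#' @param fe_fit,re_fit `mlnmr_fit` objects for the fixed-effect and
#'   random-effects models on identical data.
#' @return list with `dic` (comparison table) and `tau` (posterior
#'   median and 95% credible interval).
#' @export
heterogeneity_check <- function(fe_fit, re_fit) {
  stopifnot(inherits(fe_fit, "mlnmr_fit"), inherits(re_fit, "mlnmr_fit"))
  if (re_fit$model$effects != "random")
    stop("`re_fit` must be a random-effects fit")
  same <- identical(fe_fit$prep$data$yI, re_fit$prep$data$yI) &&
    identical(fe_fit$prep$data$yA, re_fit$prep$data$yA)
  if (!same) stop("fits are not on identical data")
  fe_dic <- dic(fe_fit); re_dic <- dic(re_fit)
  tau <- re_fit$draws$tau
  list(dic = data.frame(model = c("fixed effect", "random effects"),
                        Dbar = c(fe_dic$Dbar, re_dic$Dbar),
                        pD = c(fe_dic$pD, re_dic$pD),
                        DIC = c(fe_dic$DIC, re_dic$DIC)),
       tau = c(median = stats::median(tau),
               lower = unname(stats::quantile(tau, 0.025)),
               upper = unname(stats::quantile(tau, 0.975))))
}

#' Unrelated-mean-effects inconsistency check
#'
#' Fits the unrelated-mean-effects (UME) model — replacing the
#' consistency-constrained treatment effects by an independent effect for
#' every observed (study-baseline, treatment) design pair — and compares
#' it against a consistency fit by DIC and per-data-point deviance. A
#' clearly better UME fit indicates inconsistency between direct and
#' indirect evidence.
#'
#' @param network,model,grids,config as in [mlnmr_fit()].
#' @param consistency_fit optional already-computed consistency fit of the
#'   same data (refitted when `NULL`).
#' @return list with `ume_fit`, `consistency_fit`, `dic` comparison table
#'   and `per_point` deviance differences (UME minus consistency).
#' @export
ume_fit <- function(network, model, grids = NULL, config = fit_config(),
                    consistency_fit = NULL) {
  ume <- mlnmr_fit(network, model, grids = grids, config = config,
                   ume = TRUE)
  if (is.null(consistency_fit))
    consistency_fit <- mlnmr_fit(network, model, grids = grids,
                                 config = config)
  du <- residual_deviance(ume)
  dc <- residual_deviance(consistency_fit)
  pp <- dc$per_point[c("level", "study", "treatment")]
  pp$dev_consistency <- dc$per_point$deviance
  pp$dev_ume <- du$per_point$deviance
  pp$difference <- pp$dev_ume - pp$dev_consistency
  list(ume_fit = ume, consistency_fit = consistency_fit,
       dic = data.frame(model = c("consistency", "unrelated mean effects"),
                        Dbar = c(dc$Dbar, du$Dbar),
                        pD = c(dc$pD, du$pD),
                        DIC = c(dc$DIC, du$DIC)),
       per_point = pp)
}
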