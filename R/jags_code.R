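# Generation of the BUGS/JAGS model code and data list for the multilevel
# model. The individual-level likelihood is evaluated directly on the IPD
# rows; each aggregate arm's likelihood integrates the inverse-link of the
# linear predictor over the study's fixed QMC grid and uses the
# two-parameter binomial approximation (via the zeros trick, since the
# adjusted size is real-valued). Covariates are centred before fitting.

# Internal container with everything the sampler needs, plus the index
# maps required to un-centre and relabel the draws afterwards.
.prepare_jags <- function(network, model, grids, ume = FALSE) {
  xv <- model$covariates
  d <- length(xv)
  studies <- Filter(function(s) !isTRUE(s$single_arm), network$studies)
  sid <- vapply(studies, `[[`, "", "study_id")
  trt <- network$treatments
  K <- nrow(trt)
  tix <- stats::setNames(trt$index, trt$id)
  em <- effect_modifier_structure(trt, model$em_structure)

  is_ipd <- vapply(studies, inherits, TRUE, "ipd_study")
  ipd <- studies[is_ipd]
  agd <- studies[!is_ipd]

  # standardisation: pooled IPD covariate means and sds (falling back to
  # sample-size-weighted AgD summaries when no IPD are present); sampling
  # runs on centred, unit-sd covariates and draws are transformed back
  xbar <- stats::setNames(numeric(d), xv)
  xsd <- stats::setNames(rep(1, d), xv)
  if (d > 0L) {
    if (length(ipd) > 0L) {
      allx <- as.matrix(do.call(rbind, lapply(ipd, function(s) s$rows[xv])))
      xbar[] <- colMeans(allx)
      xsd[] <- apply(allx, 2, stats::sd)
    } else if (length(agd) > 0L) {
      w <- vapply(agd, function(s) sum(s$arms$n), 0)
      for (cv in xv) {
        ms <- vapply(agd, function(s) {
          cs <- s$covariate_summaries[[cv]]
          if (!is.null(cs$prop)) cs$prop else cs$mean
        }, 0)
        ss <- vapply(agd, function(s) {
          cs <- s$covariate_summaries[[cv]]
          if (!is.null(cs$prop)) sqrt(cs$prop * (1 - cs$prop)) else cs$sd
        }, 0)
        xbar[cv] <- sum(w * ms) / sum(w)
        xsd[cv] <- sum(w * ss) / sum(w)
      }
    }
    xsd[xsd == 0 | !is.finite(xsd)] <- 1
  }

  dat <- list(nS = length(studies), nT = K, d = d)
  if (d > 0L) dat$emrow <- em$row
  out <- list(studies = sid, treatments = trt$id, covariates = xv,
              xbar = xbar, xsd = xsd, em = em, ume = ume, is_ipd = is_ipd)

  # ---- IPD rows, sorted into contiguous study-arm blocks ----
  if (length(ipd) > 0L) {
    XI <- NULL
    rows <- do.call(rbind, lapply(ipd, function(s) {
      data.frame(s_ix = match(s$study_id, sid),
                 t_ix = unname(tix[s$rows$treatment]),
                 y = s$rows$y)
    }))
    if (d > 0L)
      XI <- as.matrix(do.call(rbind, lapply(ipd, function(s) s$rows[xv])))
    ord <- order(rows$s_ix, rows$t_ix)
    rows <- rows[ord, ]
    if (d > 0L)
      XI <- sweep(sweep(XI[ord, , drop = FALSE], 2, xbar), 2, xsd, `/`)
    arm_id <- cumsum(!duplicated(rows[c("s_ix", "t_ix")]))
    nArmI <- max(arm_id)
    dat$nI <- nrow(rows)
    dat$yI <- rows$y
    dat$nArmI <- nArmI
    dat$startI <- vapply(seq_len(nArmI),
                         function(a) min(which(arm_id == a)), 0L)
    dat$endI <- vapply(seq_len(nArmI),
                       function(a) max(which(arm_id == a)), 0L)
    dat$sI <- rows$s_ix[dat$startI]
    dat$tI <- rows$t_ix[dat$startI]
    if (model$likelihood == "normal") dat$sI_of_i <- rows$s_ix
    if (d > 0L) dat$XI <- XI
    out$ipd_index <- data.frame(study = sid[rows$s_ix],
                                treatment = trt$id[rows$t_ix])
  } else dat$nI <- 0L

  # ---- AgD arms and integration grids ----
  if (length(agd) > 0L) {
    gsid <- vapply(agd, `[[`, "", "study_id")
    if (d > 0L) {
      miss <- setdiff(gsid, names(grids))
      if (length(miss) > 0L)
        stop("no integration grid supplied for AgD stud",
             if (length(miss) > 1) "ies: " else "y: ",
             paste(miss, collapse = ", "))
      ng <- vapply(gsid, function(g) grids[[g]]$n_points, 0L)
      XG <- array(0, dim = c(length(gsid), max(ng), d))
      for (q in seq_along(gsid)) {
        P <- grids[[gsid[q]]]$points
        miss <- setdiff(xv, colnames(P))
        if (length(miss) > 0L)
          stop("grid for study '", gsid[q], "' lacks covariate(s): ",
               paste(miss, collapse = ", "))
        XG[q, seq_len(ng[q]), ] <- sweep(sweep(P[, xv, drop = FALSE],
                                               2, xbar), 2, xsd, `/`)
      }
      dat$XG <- XG
      dat$ngrid <- unname(ng)
    }
    arms <- do.call(rbind, lapply(agd, function(s) {
      af <- data.frame(s_ix = match(s$study_id, sid),
                       q_ix = match(s$study_id, gsid),
                       t_ix = unname(tix[s$arms$treatment]),
                       n = s$arms$n)
      if (network$outcome == "binary") af$y <- s$arms$events
      else if (network$outcome == "continuous") {
        af$y <- s$arms$mean; af$se <- s$arms$se
      } else {
        af$y <- s$arms$events; af$n <- s$arms$exposure
      }
      af
    }))
    dat$nArmA <- nrow(arms)
    dat$sA <- arms$s_ix; dat$qA <- arms$q_ix; dat$tA <- arms$t_ix
    dat$nA <- arms$n; dat$yA <- arms$y
    if (network$outcome == "continuous") dat$seA <- arms$se
    if (network$outcome == "binary") dat$zeros <- rep(0, nrow(arms))
    out$agd_index <- data.frame(study = sid[arms$s_ix],
                                treatment = trt$id[arms$t_ix])
  } else dat$nArmA <- 0L

  # ---- treatment-effect term per arm ----
  # Under consistency, non-reference arms take gamma (FE) or a study
  # random effect with mean gamma (RE). Under unrelated mean effects each
  # arm's effect is measured against the study's own baseline arm with a
  # free parameter per observed (baseline, treatment) design pair.
  arm_tab <- rbind(
    if (dat$nI > 0L) data.frame(kind = "I", a = seq_len(dat$nArmI),
                                s_ix = dat$sI, t_ix = dat$tI),
    if (dat$nArmA > 0L) data.frame(kind = "A", a = seq_len(dat$nArmA),
                                   s_ix = dat$sA, t_ix = dat$tA))
  if (ume) {
    base_of_study <- tapply(arm_tab$t_ix, arm_tab$s_ix, min)
    arm_tab$base <- base_of_study[as.character(arm_tab$s_ix)]
    pr <- unique(arm_tab[arm_tab$t_ix != arm_tab$base, c("base", "t_ix")])
    pr <- pr[order(pr$base, pr$t_ix), ]
    out$ume_pairs <- data.frame(a = trt$id[pr$base], b = trt$id[pr$t_ix])
    arm_tab$pair <- ifelse(
      arm_tab$t_ix == arm_tab$base, 0L,
      match(paste(arm_tab$base, arm_tab$t_ix),
            paste(pr$base, pr$t_ix)))
    dat$nPair <- nrow(pr)
  }
  ref_arm <- if (ume) arm_tab$t_ix == arm_tab$base else arm_tab$t_ix == 1L

  if (model$effects == "random") {
    # enumerate study random effects (one per non-reference arm)
    darm <- arm_tab[!ref_arm, ]
    darm <- darm[!duplicated(darm[c("s_ix", "t_ix")]), ]
    darm <- darm[order(darm$s_ix, darm$t_ix), ]
    darm$m <- stats::ave(darm$s_ix, darm$s_ix, FUN = seq_along)
    out$delta_index <- data.frame(study = sid[darm$s_ix],
                                  treatment = trt$id[darm$t_ix],
                                  s_ix = darm$s_ix, m = darm$m,
                                  t_ix = darm$t_ix,
                                  pair = if (ume) darm$pair else NA)
    key <- paste(arm_tab$s_ix, arm_tab$t_ix)
    dkey <- paste(darm$s_ix, darm$t_ix)
    arm_tab$dm <- match(key, dkey)
  }
  out$arm_tab <- arm_tab
  out$data <- dat
  out
}

# effect term expression for one arm, as JAGS code
.eff_expr <- function(prep, model, kind, a) {
  at <- prep$arm_tab
  row <- at[at$kind == kind & at$a == a, ]
  if (model$effects == "random") {
    if (is.na(row$dm)) "0" else {
      di <- prep$delta_index[row$dm, ]
      sprintf("dd[%d,%d]", di$s_ix, di$m)
    }
  } else if (prep$ume) {
    if (row$pair == 0L) "0" else sprintf("dume[%d]", row$pair)
  } else {
    sprintf("gamma[%d]", row$t_ix)
  }
}

# mean of a study random effect: gamma (consistency) or dume (UME)
.re_mean_expr <- function(prep, di) {
  if (prep$ume) {
    if (di$pair == 0L) "0" else sprintf("dume[%d]", di$pair)
  } else sprintf("gamma[%d]", di$t_ix)
}

.jags_code <- function(prep, model) {
  dat <- prep$data
  d <- length(prep$covariates)
  pr <- model$priors
  em <- prep$em
  lik <- model$likelihood
  ginv <- switch(model$link, probit = "phi", logit = "ilogit",
                 log = "exp", identity = "")
  L <- character()
  add <- function(...) L <<- c(L, sprintf(...))
  add("model {")

  xprod <- function(Xexpr, k)
    if (d == 0L) NULL
    else if (d == 1L) sprintf("%s * bvec[%s,1]", Xexpr, k)
    else sprintf("%s %%*%% bvec[%s,]", Xexpr, k)

  # ---- individual level ----
  if (dat$nI > 0L) {
    add("  for (a in 1:nArmI) {")
    if (d > 0L) {
      terms <- c(
        xprod(if (d == 1L) "XI[startI[a]:endI[a],1]"
              else "XI[startI[a]:endI[a],]", "tI[a]"),
        "mu[sI[a]]", "effI[a]")
      add("    etaI[startI[a]:endI[a]] <- %s",
          paste(terms, collapse = " + "))
    } else {
      add("    for (i in startI[a]:endI[a]) { etaI[i] <- mu[sI[a]] + effI[a] }")
    }
    add("  }")
    for (a in seq_len(dat$nArmI))
      add("  effI[%d] <- %s", a, .eff_expr(prep, model, "I", a))
    if (lik == "bernoulli") {
      add("  for (i in 1:nI) {")
      add("    pI[i] <- max(1e-12, min(1 - 1e-12, %s(etaI[i])))", ginv)
      add("    yI[i] ~ dbern(pI[i])")
      add("  }")
    } else if (lik == "normal") {
      add("  for (i in 1:nI) {")
      add("    yI[i] ~ dnorm(etaI[i], precSigma[sI_of_i[i]])")
      add("  }")
    } else {
      add("  for (i in 1:nI) {")
      add("    lamI[i] <- exp(etaI[i])")
      add("    yI[i] ~ dpois(lamI[i])")
      add("  }")
    }
  }

  # ---- aggregate level ----
  if (dat$nArmA > 0L) {
    add("  for (a in 1:nArmA) {")
    if (d > 0L) {
      terms <- c(xprod(if (d == 1L) "XG[qA[a],1:ngrid[qA[a]],1]"
                       else "XG[qA[a],1:ngrid[qA[a]],]", "tA[a]"),
                 "mu[sA[a]]", "effA[a]")
      add("    etaG[a,1:ngrid[qA[a]]] <- %s", paste(terms, collapse = " + "))
      if (lik == "bernoulli") {
        add("    for (g in 1:ngrid[qA[a]]) { pg[a,g] <- %s(etaG[a,g]) }",
            ginv)
        add("    pbar[a] <- max(1e-12, min(1 - 1e-12, mean(pg[a,1:ngrid[qA[a]]])))")
        add("    p2bar[a] <- max(pbar[a]^2, min(pbar[a], mean(pg[a,1:ngrid[qA[a]]]^2)))")
      } else if (lik == "normal") {
        add("    pbar[a] <- mean(etaG[a,1:ngrid[qA[a]]])")
      } else {
        add("    for (g in 1:ngrid[qA[a]]) { pg[a,g] <- exp(etaG[a,g]) }")
        add("    pbar[a] <- mean(pg[a,1:ngrid[qA[a]]])")
      }
    } else {
      add("    etaA[a] <- mu[sA[a]] + effA[a]")
      if (lik == "bernoulli") {
        add("    pbar[a] <- max(1e-12, min(1 - 1e-12, %s(etaA[a])))", ginv)
        add("    p2bar[a] <- pbar[a]^2")
      } else if (lik == "normal") {
        add("    pbar[a] <- etaA[a]")
      } else {
        add("    pbar[a] <- exp(etaA[a])")
      }
    }
    if (lik == "bernoulli") {
      # two-parameter binomial via the zeros trick (real-valued size)
      add("    Nadj[a] <- nA[a] * pbar[a]^2 / p2bar[a]")
      add("    padj[a] <- p2bar[a] / pbar[a]")
      add("    llA[a] <- loggam(Nadj[a] + 1) - loggam(yA[a] + 1) - loggam(Nadj[a] - yA[a] + 1) + yA[a] * log(padj[a]) + (Nadj[a] - yA[a]) * log(1 - padj[a])")
      add("    zeros[a] ~ dpois(1e6 - llA[a])")
    } else if (lik == "normal") {
      add("    precA[a] <- 1 / seA[a]^2")
      add("    yA[a] ~ dnorm(pbar[a], precA[a])")
      add("    llA[a] <- logdensity.norm(yA[a], pbar[a], precA[a])")
    } else {
      add("    rateA[a] <- nA[a] * pbar[a]")
      add("    yA[a] ~ dpois(rateA[a])")
      add("    llA[a] <- logdensity.pois(yA[a], rateA[a])")
    }
    add("  }")
    for (a in seq_len(dat$nArmA))
      add("  effA[%d] <- %s", a, .eff_expr(prep, model, "A", a))
  }

  # ---- coefficients ----
  add("  for (j in 1:nS) { mu[j] ~ dnorm(0, %.8g) }", 1 / pr$mu^2)
  if (d > 0L) {
    # Hierarchically-centred coefficient parameterisation: sample the
    # reference-arm coefficient vector b[1,] = beta1 and the per-group
    # arm coefficient vectors b[r,] ~ N(b[1,] (+ class mean), sd_beta2^2),
    # so beta2[r,] = b[r,] - b[1,] is derived. This is the same joint
    # prior as independent normals on beta1 and beta2 (unit-Jacobian
    # change of variables) but removes the beta1/beta2 posterior ridge
    # that cripples one-coordinate-at-a-time sampling.
    prog <- prep$covariates %in% model$prognostic
    emod <- prep$covariates %in% model$effect_modifiers
    for (l in seq_len(d)) {
      if (prog[l]) add("  b[1,%d] ~ dnorm(0, %.8g)", l, 1 / pr$beta1^2)
      else add("  b[1,%d] <- 0", l)
      add("  beta1[%d] <- b[1,%d]", l, l)
      add("  beta2[1,%d] <- 0", l)
    }
    if (em$n_rows > 1L) {
      for (r in 2:em$n_rows) for (l in seq_len(d)) {
        if (!emod[l]) add("  b[%d,%d] <- b[1,%d]", r, l, l)
        else if (em$structure == "exchangeable")
          add("  b[%d,%d] ~ dnorm(b[1,%d] + mB[%d,%d], precB[%d,%d])",
              r, l, l, em$group_of_row[r], l, em$group_of_row[r], l)
        else add("  b[%d,%d] ~ dnorm(b[1,%d], %.8g)", r, l, l,
                 1 / pr$beta2^2)
        add("  beta2[%d,%d] <- b[%d,%d] - b[1,%d]", r, l, r, l, l)
      }
      if (em$structure == "exchangeable") {
        ng <- length(em$groups)
        for (gidx in seq_len(ng)) for (l in seq_len(d)) {
          if (emod[l]) {
            add("  mB[%d,%d] ~ dnorm(0, %.8g)", gidx, l, 1 / pr$beta2^2)
            add("  sigB[%d,%d] ~ dnorm(0, %.8g) T(0,)", gidx, l,
                1 / pr$sigma_beta2^2)
            add("  precB[%d,%d] <- 1 / sigB[%d,%d]^2", gidx, l, gidx, l)
          }
        }
      }
    }
    add("  for (k in 1:nT) { for (l in 1:d) { bvec[k,l] <- b[emrow[k],l] } }")
  }

  # ---- treatment effects ----
  if (prep$ume) {
    if (dat$nPair > 0L)
      add("  for (e in 1:nPair) { dume[e] ~ dnorm(0, %.8g) }", 1 / pr$gamma^2)
  } else {
    add("  gamma[1] <- 0")
    if (dat$nT > 1L)
      add("  for (k in 2:nT) { gamma[k] ~ dnorm(0, %.8g) }", 1 / pr$gamma^2)
  }

  # ---- random effects: sequential conditional form of the multivariate
  # normal with common tau^2 and correlation 0.5 ----
  if (model$effects == "random") {
    di <- prep$delta_index
    for (r in seq_len(nrow(di))) {
      j <- di$s_ix[r]; m <- di$m[r]
      mexpr <- .re_mean_expr(prep, di[r, ])
      add("  md[%d,%d] <- %s", j, m, mexpr)
      if (m == 1L) {
        add("  dd[%d,1] ~ dnorm(md[%d,1], precTau)", j, j)
      } else {
        prev <- paste(sprintf("(dd[%d,%d] - md[%d,%d])", j, seq_len(m - 1),
                              j, seq_len(m - 1)), collapse = " + ")
        add("  dd[%d,%d] ~ dnorm(md[%d,%d] + (%s) / %d, precTau * %.8g)",
            j, m, j, m, prev, m, 2 * m / (m + 1))
      }
    }
    add("  tau ~ dnorm(0, %.8g) T(0,)", 1 / pr$tau^2)
    add("  precTau <- 1 / tau^2")
  }

  if (lik == "normal" && dat$nI > 0L) {
    add("  for (j in 1:nS) { sigma[j] ~ dnorm(0, %.8g) T(0,) ", 1 / pr$sigma^2)
    add("    precSigma[j] <- 1 / sigma[j]^2 }")
  }

  add("}")
  paste(L, collapse = "\n")
}
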