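# Data model and I/O for IPD studies, aggregate-data studies and the
# treatment network. IPD tables are long format (one row per randomised
# individual); AgD tables have one row per arm plus study-level covariate
# summary columns `cov_<name>_mean`, `cov_<name>_sd`, `cov_<name>_prop`.

.read_table <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    df <- utils::read.csv(x, check.names = FALSE, stringsAsFactors = FALSE)
  } else df <- as.data.frame(x)
  if (nrow(df) == 0L) stop("input table is empty")
  df
}

#' Read individual patient data studies from a long-format table
#'
#' One row per randomised individual. Each distinct study label becomes one
#' IPD study object carrying a treatment label, outcome value and covariate
#' vector per individual.
#'
#' @param table CSV path or data frame.
#' @param schema named list mapping roles to column names:
#'   `study`, `treatment`, `outcome` and `covariates` (character vector).
#' @param outcome one of `"binary"`, `"continuous"`, `"count"`.
#' @return list of `ipd_study` objects, one per study.
#' @export
read_ipd <- function(table,
                     schema = list(study = "study", treatment = "treatment",
                                   outcome = "y", covariates = NULL),
                     outcome = c("binary", "continuous", "count")) {
  outcome <- match.arg(outcome)
  df <- .read_table(table)
  covs <- schema$covariates %||%
    setdiff(names(df), c(schema$study, schema$treatment, schema$outcome))
  need <- c(schema$study, schema$treatment, schema$outcome, covs)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s) in IPD table: ", paste(miss, collapse = ", "))
  y <- df[[schema$outcome]]
  if (outcome == "binary" && !all(y %in% c(0, 1)))
    stop("binary outcome column '", schema$outcome,
         "' has values outside {0, 1}")
  if (outcome == "count" && (any(y < 0) || any(y != round(y))))
    stop("count outcome column '", schema$outcome,
         "' must contain non-negative integers")
  for (cv in covs) {
    bad <- which(is.na(df[[cv]]))
    if (length(bad) > 0L)
      stop("missing covariate value: '", cv, "' at row ", bad[1],
           " (missing-data handling is out of scope)")
  }
  out <- lapply(split(df, factor(df[[schema$study]],
                                 levels = unique(df[[schema$study]]))),
                function(sub) {
    rows <- data.frame(treatment = as.character(sub[[schema$treatment]]),
                       y = sub[[schema$outcome]],
                       check.names = FALSE)
    rows[covs] <- sub[covs]
    structure(list(study_id = as.character(sub[[schema$study]][1]),
                   rows = rows, covariates = covs, outcome = outcome),
              class = "ipd_study")
  })
  unname(out)
}

#' Write IPD studies back to a long-format table
#'
#' Inverse of [read_ipd()] (up to column order): one row per individual with
#' `study`, `treatment`, `y` and covariate columns.
#'
#' @param ipd list of `ipd_study` objects (or a single one).
#' @param path optional CSV path; if `NULL` the data frame is returned.
#' @export
write_ipd <- function(ipd, path = NULL) {
  if (inherits(ipd, "ipd_study")) ipd <- list(ipd)
  df <- do.call(rbind, lapply(ipd, function(s)
    cbind(study = s$study_id, s$rows)))
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  df
}

#' Read aggregate-data studies from an arm-level table
#'
#' One row per study arm. Binary outcomes need `events` and `n` columns;
#' continuous outcomes `mean`, `se` (or `sd`) and `n`; count outcomes
#' `events` and `exposure`. Study-level covariate summaries are carried in
#' wide columns `cov_<name>_mean` / `cov_<name>_sd` (continuous) or
#' `cov_<name>_prop` (binary), repeated on each arm row of the study.
#'
#' @param table CSV path or data frame.
#' @param schema named list with `study`, `treatment` and, as applicable,
#'   `events`, `n`, `mean`, `se`, `sd`, `exposure` column names.
#' @param covariates covariate names whose summaries must be present; by
#'   default every `cov_*` column found.
#' @param outcome one of `"binary"`, `"continuous"`, `"count"`.
#' @return list of `agd_study` objects.
#' @export
read_agd <- function(table,
                     schema = list(study = "study", treatment = "treatment",
                                   events = "events", n = "n",
                                   mean = "mean", se = "se", sd = "sd",
                                   exposure = "exposure"),
                     covariates = NULL,
                     outcome = c("binary", "continuous", "count")) {
  outcome <- match.arg(outcome)
  df <- .read_table(table)
  need <- c(schema$study, schema$treatment)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s) in AgD table: ", paste(miss, collapse = ", "))
  if (is.null(covariates)) {
    covariates <- unique(sub("^cov_(.*)_(mean|sd|prop)$", "\\1",
                             grep("^cov_.*_(mean|sd|prop)$", names(df),
                                  value = TRUE)))
  }
  out <- lapply(split(df, factor(df[[schema$study]],
                                 levels = unique(df[[schema$study]]))),
                function(sub) {
    sid <- as.character(sub[[schema$study]][1])
    arms <- data.frame(treatment = as.character(sub[[schema$treatment]]))
    if (outcome == "binary") {
      if (!all(c(schema$events, schema$n) %in% names(sub)))
        stop("binary AgD study '", sid, "' needs columns '", schema$events,
             "' and '", schema$n, "'")
      arms$events <- sub[[schema$events]]
      arms$n <- sub[[schema$n]]
      if (any(arms$n <= 0)) stop("non-positive sample size in '", sid, "'")
      if (any(arms$events != round(arms$events)) ||
          any(arms$n != round(arms$n)))
        stop("events and n must be integers in '", sid, "'")
      if (any(arms$events < 0) || any(arms$events > arms$n))
        stop("events outside [0, n] in study '", sid, "'")
    } else if (outcome == "continuous") {
      if (!(schema$mean %in% names(sub)) || !(schema$n %in% names(sub)))
        stop("continuous AgD study '", sid, "' needs mean and n columns")
      arms$mean <- sub[[schema$mean]]
      arms$n <- sub[[schema$n]]
      if (schema$se %in% names(sub)) arms$se <- sub[[schema$se]]
      else if (schema$sd %in% names(sub))
        arms$se <- sub[[schema$sd]] / sqrt(arms$n)
      else stop("continuous AgD study '", sid, "' needs an se or sd column")
      if (any(arms$n <= 0)) stop("non-positive sample size in '", sid, "'")
    } else {
      if (!all(c(schema$events, schema$exposure) %in% names(sub)))
        stop("count AgD study '", sid, "' needs events and exposure columns")
      arms$events <- sub[[schema$events]]
      arms$exposure <- sub[[schema$exposure]]
      arms$n <- if (schema$n %in% names(sub)) sub[[schema$n]]
                else sub[[schema$exposure]]
    }
    cs <- list()
    for (cv in covariates) {
      mcol <- paste0("cov_", cv, "_mean"); scol <- paste0("cov_", cv, "_sd")
      pcol <- paste0("cov_", cv, "_prop")
      if (pcol %in% names(sub) && !is.na(sub[[pcol]][1])) {
        p <- sub[[pcol]][1]
        if (p < 0 || p > 1)
          stop("proportion summary for covariate '", cv, "' in study '",
               sid, "' is outside [0, 1]: ", p)
        cs[[cv]] <- list(prop = p)
      } else if (mcol %in% names(sub) && !is.na(sub[[mcol]][1])) {
        if (!(scol %in% names(sub)) || is.na(sub[[scol]][1]))
          stop("covariate '", cv, "' in study '", sid,
               "' has a mean but no sd summary")
        cs[[cv]] <- list(mean = sub[[mcol]][1], sd = sub[[scol]][1])
      } else {
        stop("covariate summary missing for '", cv, "' in study '", sid, "'")
      }
    }
    if (nrow(arms) == 1L)
      warning("study '", sid, "' has a single arm; it is accepted but ",
              "excluded from relative-effect estimation by default")
    structure(list(study_id = sid, arms = arms, covariate_summaries = cs,
                   covariates = covariates, outcome = outcome,
                   single_arm = nrow(arms) == 1L),
              class = "agd_study")
  })
  unname(out)
}

#' Write aggregate-data studies to an arm-level table
#' @param agd list of `agd_study` objects (or a single one).
#' @param path optional CSV path; if `NULL` the data frame is returned.
#' @export
write_agd <- function(agd, path = NULL) {
  if (inherits(agd, "agd_study")) agd <- list(agd)
  df <- do.call(rbind, lapply(agd, function(s) {
    out <- cbind(study = s$study_id, s$arms)
    for (cv in names(s$covariate_summaries)) {
      cs <- s$covariate_summaries[[cv]]
      if (!is.null(cs$prop)) out[[paste0("cov_", cv, "_prop")]] <- cs$prop
      else {
        out[[paste0("cov_", cv, "_mean")]] <- cs$mean
        out[[paste0("cov_", cv, "_sd")]] <- cs$sd
      }
    }
    out
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  df
}

.study_treatments <- function(s) {
  if (inherits(s, "ipd_study")) unique(s$rows$treatment)
  else unique(s$arms$treatment)
}

#' Assemble a treatment network from IPD and AgD studies
#'
#' Assigns treatment indices (reference treatment first), records treatment
#' classes, checks that every named covariate is available in every study,
#' and verifies that the study-treatment graph is connected.
#'
#' Single-arm AgD studies are kept in the object but flagged and excluded
#' from the connectivity check and from fitting.
#'
#' @param ipd list of `ipd_study` objects (possibly empty).
#' @param agd list of `agd_study` objects (possibly empty).
#' @param reference reference treatment label; defaults to the first
#'   treatment encountered.
#' @param classes optional named character vector mapping treatment label to
#'   class label, for shared or exchangeable effect-modifier structures.
#'   Unlisted treatments form singleton classes.
#' @param covariates covariate names the model will adjust for; default is
#'   the covariates of the first study.
#' @return an object of class `mlnmr_network`.
#' @export
build_network <- function(ipd = list(), agd = list(), reference = NULL,
                          classes = NULL, covariates = NULL) {
  if (inherits(ipd, "ipd_study")) ipd <- list(ipd)
  if (inherits(agd, "agd_study")) agd <- list(agd)
  studies <- c(ipd, agd)
  if (length(studies) == 0L) stop("need at least one study")
  sids <- vapply(studies, `[[`, "", "study_id")
  if (anyDuplicated(sids))
    stop("duplicated study ids: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))

  # merge duplicate arms of the same treatment within an AgD study
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    if (inherits(s, "agd_study") && anyDuplicated(s$arms$treatment)) {
      warning("study '", s$study_id,
              "' has multiple arms of the same treatment; merging")
      agg <- stats::aggregate(s$arms[setdiff(names(s$arms), "treatment")],
                              by = list(treatment = s$arms$treatment),
                              FUN = sum)
      studies[[i]]$arms <- agg[match(unique(s$arms$treatment),
                                     agg$treatment), ]
    }
  }

  trts <- unique(unlist(lapply(studies, .study_treatments)))
  reference <- reference %||% trts[1]
  if (!(reference %in% trts))
    stop("reference treatment '", reference, "' not found in any study")
  trts <- c(reference, setdiff(trts, reference))
  cls <- vapply(trts, function(tr)
    if (!is.null(classes) && tr %in% names(classes)) classes[[tr]] else tr,
    "")
  treatments <- data.frame(id = trts, class = unname(cls),
                           index = seq_along(trts))

  covariates <- covariates %||% studies[[1]]$covariates
  for (s in studies) {
    if (inherits(s, "ipd_study")) {
      miss <- setdiff(covariates, names(s$rows))
      if (length(miss) > 0L)
        stop("IPD study '", s$study_id, "' is missing covariate(s): ",
             paste(miss, collapse = ", "))
      if (length(unique(s$rows$treatment)) < 2L)
        stop("IPD study '", s$study_id, "' has fewer than 2 treatments")
    } else {
      miss <- setdiff(covariates, names(s$covariate_summaries))
      if (length(miss) > 0L)
        stop("AgD study '", s$study_id, "' is missing covariate summaries: ",
             paste(miss, collapse = ", "))
    }
  }

  active <- Filter(function(s) !isTRUE(s$single_arm), studies)
  comp <- .connected_components(lapply(active, .study_treatments), trts)
  if (length(comp) > 1L)
    stop("treatment network is disconnected; components: ",
         paste(vapply(comp, paste, "", collapse = ","), collapse = " | "))

  outk <- unique(vapply(studies, `[[`, "", "outcome"))
  if (length(outk) > 1L)
    stop("studies mix outcome kinds: ", paste(outk, collapse = ", "))

  structure(list(treatments = treatments, studies = studies,
                 covariates = covariates, outcome = outk,
                 reference = reference),
            class = "mlnmr_network")
}

# connected components of the treatment graph via igraph
.connected_components <- function(study_trt_sets, all_trts) {
  edges <- do.call(rbind, lapply(study_trt_sets, function(ts) {
    if (length(ts) < 2L) return(NULL)
    t(utils::combn(ts, 2L))
  }))
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(edges %||% matrix(character(), 0, 2)),
    directed = FALSE,
    vertices = data.frame(name = all_trts))
  cm <- igraph::components(g)
  split(names(cm$membership), cm$membership)
}

#' @export
print.mlnmr_network <- function(x, ...) {
  n_ipd <- sum(vapply(x$studies, inherits, TRUE, "ipd_study"))
  n_agd <- length(x$studies) - n_ipd
  cat("<mlnmr network> ", nrow(x$treatments), " treatments (reference: ",
      x$reference, "), ", n_ipd, " IPD + ", n_agd, " AgD studies, outcome: ",
      x$outcome, "\n", sep = "")
  cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  for (s in x$studies) {
    kind <- if (inherits(s, "ipd_study")) "IPD" else "AgD"
    n <- if (kind == "IPD") nrow(s$rows) else sum(s$arms$n)
    cat(sprintf("  %-12s %s  N=%-6d arms: %s\n", s$study_id, kind, n,
                paste(.study_treatments(s), collapse = ", ")))
  }
  invisible(x)
}
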