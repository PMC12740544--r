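#' Reference TIAs from an all-time-points population fit
#'
#' Fits the population model to the full cohort with all sessions, then
#' derives each subject's empirical-Bayes parameters, reference TIA
#' ([soef_tia()]), its delta-method SD ([tia_sd_delta()]) and CV. Subjects
#' missing sessions are kept (the mixed-effects machinery handles
#' unbalanced data) but reported with a warning.
#'
#' @param dataset An `ftp_cohort` data frame.
#' @param init Starting centers, a [population_model()].
#' @param control A [fit_control()].
#' @param consts [physical_constants()].
#' @return Object of class `reference_tias`: `fit` (the [fit_population()]
#'   result), `individuals` (list of [estimate_individual()] results) and
#'   `tias` (data frame: `subject_id`, `method = "ATP"`,
#'   `role = "reference"`, `tia_h`, `sd_h`, `cv`).
#' @export
reference_tias <- function(dataset, init = default_init(),
                           control = fit_control(),
                           consts = physical_constants()) {
  dataset <- if (inherits(dataset, "ftp_cohort")) dataset else
    cohort_dataset(dataset)
  n_sessions <- length(attr(dataset, "session_labels"))
  counts <- table(dataset$subject_id)
  short <- names(counts)[counts < n_sessions]
  if (length(short))
    warning("subject(s) with fewer than ", n_sessions, " sessions kept in ",
            "the fit: ", paste(short, collapse = ", "), call. = FALSE)
  fit <- fit_population(dataset, init = init, control = control,
                        consts = consts)
  subs <- split_subjects(dataset)
  individuals <- lapply(subs, function(s)
    estimate_individual(fit, s, subset = NULL, consts = consts,
                        control = control))
  tias <- do.call(rbind, lapply(individuals, function(ind) {
    v <- soef_tia(ind$params, consts)
    s <- tia_sd_delta(ind$params, ind$param_cov, consts)
    data.frame(subject_id = ind$subject_id, method = "ATP",
               role = "reference", tia_h = v, sd_h = s, cv = s / v,
               stringsAsFactors = FALSE)
  }))
  structure(list(fit = fit, individuals = individuals, tias = tias,
                 consts = consts),
            class = "reference_tias")
}

#' Leave-one-out training fits
#'
#' For each subject, fits the population model to the remaining subjects'
#' full (all-session) data. Every training fit starts from the same
#' data-independent centers (`init`): initializing from the full-cohort fit
#' would let the left-out subject's own observations shape the prior used
#' to estimate it (a leakage path), so that is deliberately avoided. The N
#' fits are computed once and reused across every session subset (the
#' caching contract: at most N training fits no matter how many subsets
#' are evaluated).
#'
#' @param dataset An `ftp_cohort`.
#' @param init Starting centers, a [population_model()]; must not be
#'   derived from the full cohort if leave-one-out independence matters.
#' @param control A [fit_control()]; training fits use `loo_n_starts`
#'   starts and skip the estimate covariance.
#' @param consts [physical_constants()].
#' @return Named list (by left-out subject id) of `population_fit` objects.
#' @export
loo_fits <- function(dataset, init = default_init(),
                     control = fit_control(),
                     consts = physical_constants()) {
  stopifnot(inherits(init, "population_model"))
  ids <- unique(dataset$subject_id)
  ctl <- control
  ctl$n_starts <- control$loo_n_starts
  ctl$compute_cov <- FALSE
  out <- vector("list", length(ids))
  names(out) <- ids
  for (sid in ids) {
    train <- dataset[dataset$subject_id != sid, , drop = FALSE]
    out[[sid]] <- tryCatch(
      fit_population(cohort_dataset(as.data.frame(train),
                                    nominal_times = stats::setNames(
                                      attr(dataset, "nominal_times"),
                                      attr(dataset, "session_labels"))),
                     init = init, control = ctl, consts = consts),
      error = function(e) {
        warning("leave-one-out training fit failed for subject '", sid,
                "': ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  out
}

#' Jackknife few-time-point TIAs for one session subset
#'
#' For each subject: the population model trained without that subject
#' (from [loo_fits()]) is held fixed, and the subject's parameters are
#' estimated by empirical Bayes from only the subset's observations; the
#' estimated TIA, its delta-method SD and CV follow. Subjects lacking all
#' subset sessions, or whose training fit failed, are skipped with a
#' warning.
#'
#' @param dataset An `ftp_cohort`.
#' @param subset A [subset_label()] (or character session labels).
#' @param loo Named list from [loo_fits()].
#' @param control A [fit_control()].
#' @param consts [physical_constants()].
#' @return Data frame: `subject_id`, `method` (the subset name), `role =
#'   "estimated"`, `tia_h`, `sd_h`, `cv`.
#' @export
ftp_tias_jackknife <- function(dataset, subset, loo,
                               control = fit_control(),
                               consts = physical_constants()) {
  if (!inherits(subset, "subset_label")) {
    labels <- as.character(subset)
    idx <- as.integer(sub("^TP", "", labels))
    subset <- subset_label(idx, length(attr(dataset, "session_labels")))
  }
  n_sessions <- length(attr(dataset, "session_labels"))
  if (length(subset$sessions) >= n_sessions)
    stop("subset must be a proper subset of the session set", call. = FALSE)
  subs <- split_subjects(dataset)
  rows <- list()
  for (s in subs) {
    sid <- s$subject_id
    if (is.null(loo[[sid]])) next
    if (!all(subset$labels %in% s$tp_label)) {
      warning("subject '", sid, "' lacks session(s) of ", subset$name,
              "; skipped", call. = FALSE)
      next
    }
    ind <- estimate_individual(loo[[sid]], s, subset = subset,
                               consts = consts, control = control)
    v <- soef_tia(ind$params, consts)
    sd_v <- tia_sd_delta(ind$params, ind$param_cov, consts)
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = sid, method = subset$name, role = "estimated",
                 tia_h = v, sd_h = sd_v, cv = sd_v / v,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' No-time-point surrogate TIAs
#'
#' The fixed-activity surrogate: every subject is assigned the same
#' representative parameter vector — the componentwise mean (`NTPme`) or
#' median (`NTPmd`) of the cohort's empirical-Bayes individual parameters
#' from the all-time-points fit — and hence the same estimated TIA. The SD
#' attached to that TIA propagates the sampling covariance of the
#' representative vector (sample covariance of the individual parameters
#' divided by N) through the TIA gradient.
#'
#' @param reference A [reference_tias()] result.
#' @param mode `"mean"` or `"median"`.
#' @return Data frame in the layout of [ftp_tias_jackknife()], method
#'   `"NTPme"` or `"NTPmd"`.
#' @export
ntp_tias <- function(reference, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "reference_tias"))
  P <- do.call(rbind, lapply(reference$individuals,
                             function(i) unclass(i$params)))
  rep_par <- apply(P, 2L, if (mode == "mean") mean else stats::median)
  n <- nrow(P)
  cov_rep <- stats::cov(P) / n
  consts <- reference$consts
  v <- soef_tia(rep_par, consts)
  s <- tia_sd_delta(rep_par, cov_rep, consts)
  method <- if (mode == "mean") "NTPme" else "NTPmd"
  data.frame(subject_id = vapply(reference$individuals, `[[`, "",
                                 "subject_id"),
             method = method, role = "estimated",
             tia_h = v, sd_h = s, cv = s / v, stringsAsFactors = FALSE)
}

#' Best session subset per subset size
#'
#' Within each subset size, the schedule minimizing RMSE wins; ties resolve
#' to the lexicographically smallest name. When the MAPE minimizer
#' disagrees with the RMSE minimizer the row is flagged.
#'
#' @param accuracy Data frame with at least `method`, `size`, `rmse`,
#'   `mape` (e.g. the `accuracy` table of [run_ftp_study()]); NTP rows
#'   (size NA or 0) are ignored.
#' @return Data frame: `size`, `method`, `rmse`, `mape`,
#'   `mape_disagrees`.
#' @export
best_subset <- function(accuracy) {
  stopifnot(is.data.frame(accuracy), nrow(accuracy) > 0L)
  acc <- accuracy[!is.na(accuracy$size) & accuracy$size > 0, , drop = FALSE]
  if (nrow(acc) == 0L) stop("no subset rows to rank", call. = FALSE)
  out <- lapply(sort(unique(acc$size)), function(sz) {
    a <- acc[acc$size == sz, , drop = FALSE]
    a <- a[order(a$rmse, a$method), , drop = FALSE]
    best_mape <- a$method[order(a$mape, a$method)][1L]
    data.frame(size = sz, method = a$method[1L], rmse = a$rmse[1L],
               mape = a$mape[1L],
               mape_disagrees = best_mape != a$method[1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the complete few-time-point evaluation protocol
#'
#' The full pipeline on one cohort: (1) all-time-points population fit and
#' reference TIAs; (2) leave-one-out training fits, one per subject, reused
#' across subsets; (3) jackknife estimated TIAs for every requested session
#' subset; (4) optional no-time-point surrogates; (5) accuracy
#' (RD/RMSE/MAPE, threshold counts, eTIA-vs-rTIA regression) and precision
#' (CV) summaries per method.
#'
#' @param dataset An `ftp_cohort` data frame.
#' @param init Starting centers ([population_model()]).
#' @param control A [fit_control()].
#' @param subsets `"all"` for every proper subset, or a list of
#'   [subset_label()] objects / character vectors of session labels.
#' @param ntp Include the NTPme/NTPmd surrogates.
#' @param consts [physical_constants()].
#' @return Object of class `ftp_study`: `reference`, `loo`, `tias` (long
#'   table of every TIA estimate), `accuracy` (per-method summary table),
#'   `cv` (per-method CV summary, ATP included), `best` (per-size winners),
#'   `reports` (named list of [accuracy_report()] objects).
#' @export
run_ftp_study <- function(dataset, init = default_init(),
                          control = fit_control(), subsets = "all",
                          ntp = TRUE, consts = physical_constants()) {
  dataset <- if (inherits(dataset, "ftp_cohort")) dataset else
    cohort_dataset(dataset)
  n_sessions <- length(attr(dataset, "session_labels"))
  if (identical(subsets, "all")) {
    subsets <- enumerate_subsets(n_sessions)
  } else {
    subsets <- lapply(subsets, function(s) {
      if (inherits(s, "subset_label")) s
      else subset_label(as.integer(sub("^TP", "", as.character(s))),
                        n_sessions)
    })
  }

  reference <- reference_tias(dataset, init = init, control = control,
                              consts = consts)
  loo <- loo_fits(dataset, init = init, control = control, consts = consts)

  ref <- reference$tias
  tia_tables <- list(ref)
  reports <- list()
  cv_rows <- list(cbind(method = "ATP", size = n_sessions,
                        cv_summary(ref$cv)))
  for (sl in subsets) {
    est <- ftp_tias_jackknife(dataset, sl, loo, control = control,
                              consts = consts)
    if (is.null(est) || nrow(est) == 0L) next
    tia_tables[[length(tia_tables) + 1L]] <- est
    m <- merge(est, ref[c("subject_id", "tia_h", "sd_h")],
               by = "subject_id", suffixes = c("", "_ref"))
    reports[[sl$name]] <- accuracy_report(m$tia_h, m$sd_h, m$tia_h_ref,
                                          m$sd_h_ref, method = sl$name)
    cv_rows[[length(cv_rows) + 1L]] <-
      cbind(method = sl$name, size = length(sl$sessions), cv_summary(est$cv))
  }
  if (isTRUE(ntp)) {
    for (mode in c("mean", "median")) {
      est <- ntp_tias(reference, mode)
      tia_tables[[length(tia_tables) + 1L]] <- est
      m <- merge(est, ref[c("subject_id", "tia_h", "sd_h")],
                 by = "subject_id", suffixes = c("", "_ref"))
      reports[[est$method[1L]]] <-
        accuracy_report(m$tia_h, m$sd_h, m$tia_h_ref, m$sd_h_ref,
                        method = est$method[1L])
    }
  }

  accuracy <- do.call(rbind, lapply(reports, function(r) {
    sz <- if (grepl("^TP[0-9]+$", r$method)) nchar(r$method) - 2L else NA_integer_
    data.frame(method = r$method, size = sz, n = r$n,
               rd_median = r$rd_median, rd_min = r$rd_min, rd_max = r$rd_max,
               rmse = r$rmse, rmse_sd = r$rmse_sd,
               mape = r$mape, mape_sd = r$mape_sd,
               rd10 = r$rd10, rd10_pct = r$rd10_pct,
               rd20 = r$rd20, rd20_pct = r$rd20_pct,
               slope = if (is.null(r$regression)) NA_real_ else r$regression$slope,
               intercept = if (is.null(r$regression)) NA_real_ else r$regression$intercept,
               p_slope = if (is.null(r$regression)) NA_real_ else r$regression$p_slope,
               stringsAsFactors = FALSE)
  }))
  rownames(accuracy) <- NULL
  cv_table <- do.call(rbind, cv_rows)
  rownames(cv_table) <- NULL
  best <- if (any(!is.na(accuracy$size))) best_subset(accuracy) else NULL

  structure(list(reference = reference, loo = loo,
                 tias = do.call(rbind, tia_tables), accuracy = accuracy,
                 cv = cv_table, best = best, reports = reports),
            class = "ftp_study")
}

#' @export
print.ftp_study <- function(x, ...) {
  cat("Few-time-point TIA study:", x$reference$fit$n_subjects, "subjects,",
      length(x$reports), "methods evaluated\n")
  if (!is.null(x$best)) {
    cat("Best schedule per size (by RMSE):\n")
    b <- x$best
    for (i in seq_len(nrow(b)))
      cat(sprintf("  %dTP: %-7s RMSE %.1f%%  MAPE %.1f%%\n", b$size[i],
                  b$method[i], 100 * b$rmse[i], b$mape[i]))
  }
  invisible(x)
}
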