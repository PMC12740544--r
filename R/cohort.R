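#' Nominal imaging schedule of the study design
#'
#' Mean post-injection times (hours) of the five SPECT/CT sessions the
#' analysis is organized around, and their between-patient SDs.
#'
#' @return Named list with `means` and `sds`, both length 5.
#' @export
nominal_schedule <- function() {
  list(means = c(TP1 = 1.8, TP2 = 18.7, TP3 = 42.6, TP4 = 66.3, TP5 = 160.3),
       sds   = c(TP1 = 0.8, TP2 = 0.9, TP3 = 1.0, TP4 = 0.9, TP5 = 24.2))
}

#' Assemble and validate a time-activity cohort
#'
#' A cohort is a data frame with one row per observation and columns
#' `subject_id`, `time_h`, `activity_fraction`, optionally `sd` and
#' `tp_label`. Times must be positive and strictly increasing within each
#' subject; activities must be non-negative. Missing `tp_label` values are
#' filled by nearest-nominal-session assignment
#' (see [assign_timepoint_labels()]).
#'
#' @param df Data frame of observations.
#' @param nominal_times Session means in hours used for label assignment.
#' @return The validated data frame with class `ftp_cohort` and attributes
#'   `session_labels` and `nominal_times`.
#' @export
cohort_dataset <- function(df, nominal_times = nominal_schedule()$means) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("cohort must be a non-empty data frame", call. = FALSE)
  need <- c("subject_id", "time_h", "activity_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  for (col in intersect(c("time_h", "activity_fraction", "sd"), names(df))) {
    if (!is.numeric(df[[col]]))
      stop("column '", col, "' must be numeric", call. = FALSE)
  }
  bad <- which(!is.finite(df$time_h) | df$time_h <= 0)
  if (length(bad))
    stop("non-positive or non-finite time_h at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$activity_fraction) | df$activity_fraction < 0)
  if (length(bad))
    stop("negative or non-finite activity_fraction at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  for (sid in unique(df$subject_id)) {
    tt <- df$time_h[df$subject_id == sid]
    if (any(diff(tt) <= 0))
      stop("times not strictly increasing for subject '", sid, "'",
           call. = FALSE)
  }
  labels <- names(nominal_times)
  if (is.null(labels)) labels <- paste0("TP", seq_along(nominal_times))
  if (is.null(df$tp_label) || anyNA(df$tp_label)) {
    df <- assign_timepoint_labels(df, nominal_times)
  } else {
    unknown <- setdiff(unique(df$tp_label), labels)
    if (length(unknown))
      stop("unknown tp_label value(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    dup <- stats::aggregate(seq_len(nrow(df)),
                            by = df[c("subject_id", "tp_label")], FUN = length)
    if (any(dup$x > 1L))
      stop("duplicate (subject, session) pair(s), e.g. subject '",
           dup$subject_id[dup$x > 1L][1L], "' session ",
           dup$tp_label[dup$x > 1L][1L], call. = FALSE)
  }
  structure(df, class = c("ftp_cohort", "data.frame"),
            session_labels = labels, nominal_times = unname(nominal_times))
}

#' Label each observation with its nearest nominal session
#'
#' Each sample gets the session label (`TP1` ... `TPk`) of the nominal mean
#' time it lies closest to. Two samples of one subject mapping to the same
#' session is treated as a data error.
#'
#' @param df Observation data frame (`subject_id`, `time_h`, ...).
#' @param nominal_times Session mean times in hours.
#' @return `df` with a `tp_label` column.
#' @export
assign_timepoint_labels <- function(df,
                                    nominal_times = nominal_schedule()$means) {
  labels <- names(nominal_times)
  if (is.null(labels)) labels <- paste0("TP", seq_along(nominal_times))
  idx <- vapply(df$time_h,
                function(t) which.min(abs(t - nominal_times)), integer(1))
  df$tp_label <- labels[idx]
  for (sid in unique(df$subject_id)) {
    lab <- df$tp_label[df$subject_id == sid]
    if (anyDuplicated(lab)) {
      d <- lab[duplicated(lab)][1L]
      stop("subject '", sid, "': two samples assigned to session ", d,
           " (times ",
           paste(signif(df$time_h[df$subject_id == sid][lab == d], 4),
                 collapse = ", "), " h)", call. = FALSE)
    }
  }
  df
}

# list of per-subject records (id, t, y, tp), preserving first-appearance order
#' @keywords internal
split_subjects <- function(cohort) {
  ids <- unique(cohort$subject_id)
  lapply(ids, function(sid) {
    rows <- cohort[cohort$subject_id == sid, , drop = FALSE]
    list(subject_id = sid, time_h = rows$time_h,
         activity_fraction = rows$activity_fraction, tp_label = rows$tp_label)
  })
}

#' Read a time-activity cohort from delimited text
#'
#' Expects a header with columns `subject_id`, `time_h`, `activity_fraction`
#' and optionally `sd` and `tp_label`; one row per observation. The result is
#' validated and labelled via [cohort_dataset()].
#'
#' @param path File path; comma- or tab-delimited inferred from extension.
#' @param nominal_times Session means for label assignment.
#' @return An `ftp_cohort` data frame.
#' @export
read_cohort <- function(path, nominal_times = nominal_schedule()$means) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  cohort_dataset(df, nominal_times = nominal_times)
}

#' Write a cohort as CSV
#'
#' @param cohort An `ftp_cohort` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
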