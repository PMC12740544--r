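#' Write accuracy and precision tables to disk
#'
#' Renders the per-method accuracy table (and, when supplied, the CV table)
#' of an [run_ftp_study()] result as CSV or markdown, with percentages
#' formatted to one decimal. Output is deterministic: fixed column order,
#' methods in the input row order.
#'
#' @param study An `ftp_study` object, or its `accuracy` data frame.
#' @param path Output file path (basename is reused with a `_cv` suffix for
#'   the precision table when a full study is given).
#' @param format `"csv"` or `"markdown"`.
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_report <- function(study, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  acc <- if (inherits(study, "ftp_study")) study$accuracy else study
  if (!is.data.frame(acc) || nrow(acc) == 0L)
    stop("no accuracy rows to write", call. = FALSE)
  fmt1 <- function(x) sprintf("%.1f", x)
  out <- data.frame(
    method = acc$method,
    rd_median_pct = fmt1(100 * acc$rd_median),
    rd_min_pct = fmt1(100 * acc$rd_min),
    rd_max_pct = fmt1(100 * acc$rd_max),
    rmse_pct = fmt1(100 * acc$rmse), rmse_sd_pct = fmt1(100 * acc$rmse_sd),
    mape_pct = fmt1(acc$mape), mape_sd_pct = fmt1(acc$mape_sd),
    rd10 = acc$rd10, rd10_pct = acc$rd10_pct,
    rd20 = acc$rd20, rd20_pct = acc$rd20_pct,
    stringsAsFactors = FALSE)
  files <- character()
  emit <- function(df, p) {
    if (format == "csv") {
      utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    } else {
      con <- file(p, "w")
      on.exit(close(con), add = TRUE)
      writeLines(paste0("| ", paste(names(df), collapse = " | "), " |"), con)
      writeLines(paste0("|", paste(rep("---", ncol(df)), collapse = "|"),
                        "|"), con)
      for (i in seq_len(nrow(df)))
        writeLines(paste0("| ", paste(unlist(df[i, ]), collapse = " | "),
                          " |"), con)
    }
    p
  }
  files <- c(files, emit(out, path))
  if (inherits(study, "ftp_study") && !is.null(study$cv)) {
    cvt <- study$cv
    cv_out <- data.frame(
      method = cvt$method, size = cvt$size,
      cv_mean_pct = fmt1(100 * cvt$mean), cv_sd_pct = fmt1(100 * cvt$sd),
      cv_median_pct = fmt1(100 * cvt$median),
      cv_min_pct = fmt1(100 * cvt$min), cv_max_pct = fmt1(100 * cvt$max),
      stringsAsFactors = FALSE)
    ext <- tools::file_ext(path)
    cv_path <- if (nzchar(ext))
      sub(paste0("\\.", ext, "$"), paste0("_cv.", ext), path)
    else paste0(path, "_cv")
    files <- c(files, emit(cv_out, cv_path))
  }
  invisible(files)
}

#' Serialize a population fit to JSON
#'
#' Writes estimates, objective value, covariance, convergence diagnostics
#' and per-start records in a stable structured layout.
#'
#' @param fit A [fit_population()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "population_fit"))
  obj <- list(
    theta = as.list(fit$model$theta),
    omega = as.list(fit$model$omega),
    sigma = fit$model$sigma,
    error_model = fit$model$error_model,
    ofv = fit$ofv,
    converged = fit$converged,
    n_obs = fit$n_obs,
    n_subjects = fit$n_subjects,
    best_start = fit$best_start,
    starts = fit$starts,
    est_cov = if (is.null(fit$est_cov)) NULL else unclass(fit$est_cov),
    cov_ok = fit$cov_ok
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' A flat configuration document for scripted runs: optional keys
#' `n_subjects`, `nominal_times`, `time_jitter_sd`, `noise_late_inflation`,
#' `seed`, `n_starts`, `error_model`, `subsets`. Unknown keys are rejected
#' so that typos fail loudly.
#'
#' @param path JSON file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("n_subjects", "nominal_times", "time_jitter_sd",
               "noise_late_inflation", "seed", "n_starts", "error_model",
               "subsets")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg
}
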