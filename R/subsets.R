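#' Canonical label for a set of imaging sessions
#'
#' @param sessions Integer session indices (1-based), unique; stored sorted.
#' @param n_sessions Total number of sessions in the design (default 5).
#' @return Object of class `subset_label` with `sessions` (sorted indices),
#'   `labels` (session label strings) and `name` — `"TP"` plus the
#'   concatenated digits, or `"ATP"` for the full set.
#' @examples
#' subset_label(c(5, 2))$name   # "TP25"
#' subset_label(1:5)$name       # "ATP"
#' @export
subset_label <- function(sessions, n_sessions = 5L) {
  sessions <- sort(unique(as.integer(sessions)))
  if (length(sessions) == 0L || any(sessions < 1L) ||
      any(sessions > n_sessions))
    stop("'sessions' must be non-empty indices in 1..", n_sessions,
         call. = FALSE)
  name <- if (length(sessions) == n_sessions) "ATP"
          else paste0("TP", paste(sessions, collapse = ""))
  structure(list(sessions = sessions,
                 labels = paste0("TP", sessions),
                 name = name, n_sessions = as.integer(n_sessions)),
            class = "subset_label")
}

#' All proper session subsets of a sampling design
#'
#' Every non-empty subset of `{1..n_sessions}` of size strictly less than
#' `n_sessions`, ordered by size then lexicographically — the candidate
#' few-time-point schedules. For the five-session design this yields 30
#' subsets (5 single + 10 pairs + 10 triples + 5 quadruples).
#'
#' @param n_sessions Number of sessions, at least 2.
#' @return List of [subset_label()] objects.
#' @export
enumerate_subsets <- function(n_sessions = 5L) {
  n_sessions <- as.integer(n_sessions)
  if (length(n_sessions) != 1L || is.na(n_sessions) || n_sessions < 2L)
    stop("'n_sessions' must be a single integer >= 2", call. = FALSE)
  out <- list()
  for (k in seq_len(n_sessions - 1L)) {
    cols <- utils::combn(n_sessions, k)
    for (j in seq_len(ncol(cols)))
      out[[length(out) + 1L]] <- subset_label(cols[, j], n_sessions)
  }
  out
}

#' @export
print.subset_label <- function(x, ...) {
  cat(x$name, " (sessions ", paste(x$sessions, collapse = ", "), " of ",
      x$n_sessions, ")\n", sep = "")
  invisible(x)
}
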