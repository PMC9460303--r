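#' RR-interval series
#'
#' An `rr_series` holds one experimental run's sequence of RR intervals
#' (the times between consecutive heartbeats, in milliseconds) together with
#' the cumulative beat times derived from them. Beat times start at 0 s at
#' the first beat, so interval `i` is attributed to the time span
#' `(t[i], t[i+1]]` seconds.
#'
#' @param rr_ms Numeric vector of RR intervals in milliseconds; all values
#'   must be strictly positive.
#' @param subject_id,run_id Character labels identifying the run.
#' @return An object of class `rr_series`: a list with fields `subject_id`,
#'   `run_id`, `rr_ms` and `t_beats_s` (length `length(rr_ms) + 1`, strictly
#'   increasing, starting at 0).
#' @examples
#' s <- rr_series(c(800, 820, 810), "S01", "R1")
#' duration_s(s)
#' @export
rr_series <- function(rr_ms, subject_id = "S1", run_id = "R1") {
  rr_ms <- as.numeric(rr_ms)
  if (length(rr_ms) == 0L) {
    stop("rr_series: at least one RR interval is required", call. = FALSE)
  }
  if (anyNA(rr_ms)) {
    stop("rr_series: RR intervals must not contain NA", call. = FALSE)
  }
  if (any(rr_ms <= 0)) {
    stop("rr_series: all RR intervals must be > 0 ms", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      run_id = as.character(run_id),
      rr_ms = rr_ms,
      t_beats_s = c(0, cumsum(rr_ms) / 1000)
    ),
    class = "rr_series"
  )
}

#' Run duration in seconds
#'
#' Total duration of an RR series: the time of the last beat, equal to
#' `sum(rr_ms) / 1000`.
#'
#' @param series An [rr_series()].
#' @return Duration in seconds.
#' @export
duration_s <- function(series) {
  stopifnot(inherits(series, "rr_series"))
  series$t_beats_s[length(series$t_beats_s)]
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "<rr_series> subject %s, run %s: %d intervals, %.1f s, mean RR %.1f ms\n",
    x$subject_id, x$run_id, length(x$rr_ms), duration_s(x), mean(x$rr_ms)
  ))
  invisible(x)
}

#' Study collection of RR series
#'
#' A `study_set` bundles the runs of one study. The `(subject_id, run_id)`
#' pair of every run must be unique.
#'
#' @param runs List of [rr_series()] objects.
#' @param provenance Free-text description of where the runs came from
#'   (a file manifest, or the synthetic generator configuration).
#' @return An object of class `study_set`.
#' @export
study_set <- function(runs, provenance = "") {
  if (!is.list(runs) || !all(vapply(runs, inherits, logical(1), "rr_series"))) {
    stop("study_set: `runs` must be a list of rr_series objects", call. = FALSE)
  }
  ids <- vapply(runs, function(r) paste(r$subject_id, r$run_id, sep = "\r"),
                character(1))
  if (anyDuplicated(ids)) {
    stop("study_set: (subject_id, run_id) pairs must be unique", call. = FALSE)
  }
  structure(list(runs = runs, provenance = provenance), class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  d <- vapply(x$runs, duration_s, numeric(1))
  cat(sprintf("<study_set> %d runs, durations %.0f-%.0f s\n",
              length(x$runs),
              if (length(d)) min(d) else NA, if (length(d)) max(d) else NA))
  invisible(x)
}

#' @export
length.study_set <- function(x) length(x$runs)

#' Keep only runs longer than a duration threshold
#'
#' Retains exactly the runs whose duration strictly exceeds
#' `min_duration_s`. The strict inequality mirrors the usual screening of
#' runs with "more than" the reference window length, so a run of exactly
#' 180 s cannot serve a 180-second reference window with at least one
#' placement margin.
#'
#' @param study A [study_set()].
#' @param min_duration_s Positive threshold in seconds (default 180, the
#'   reference window).
#' @return A `study_set` with the surviving runs, provenance annotated with
#'   the filter.
#' @export
filter_runs_by_duration <- function(study, min_duration_s = 180) {
  stopifnot(inherits(study, "study_set"))
  if (!is.numeric(min_duration_s) || min_duration_s < 0) {
    stop("filter_runs_by_duration: min_duration_s must be >= 0", call. = FALSE)
  }
  keep <- vapply(study$runs, duration_s, numeric(1)) > min_duration_s
  study_set(
    study$runs[keep],
    provenance = sprintf("%s | duration > %g s (%d/%d runs kept)",
                         study$provenance, min_duration_s,
                         sum(keep), length(keep))
  )
}
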