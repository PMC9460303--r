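#' Sliding-window grid
#'
#' The default grid holds the 18 window durations used throughout the
#' multi-resolution analysis: 180 s down to 10 s in steps of 10 s, slid with
#' a 1-second hop. The largest window acts as the reference ("gold
#' standard") resolution.
#'
#' @param sizes_s Ordered window durations in seconds (all > 0).
#' @param step_s Hop between consecutive window placements in seconds.
#' @return A `window_grid` list with fields `sizes_s` and `step_s`.
#' @examples
#' window_sizes(window_grid())   # 180, 170, ..., 10
#' @export
window_grid <- function(sizes_s = seq(180, 10, by = -10), step_s = 1) {
  sizes_s <- as.numeric(sizes_s)
  if (!length(sizes_s) || any(sizes_s <= 0)) {
    stop("window_grid: all window sizes must be > 0", call. = FALSE)
  }
  if (step_s <= 0) stop("window_grid: step_s must be > 0", call. = FALSE)
  structure(list(sizes_s = sizes_s, step_s = step_s), class = "window_grid")
}

#' @rdname window_grid
#' @param grid A `window_grid`.
#' @export
window_sizes <- function(grid = window_grid()) {
  stopifnot(inherits(grid, "window_grid"))
  grid$sizes_s
}

#' Segment an RR series with a sliding window
#'
#' Window placements start at run time 0 and advance by `step_s`; placement
#' `k` covers the half-open interval `[k * step_s, k * step_s + window_s)`
#' and is associated with its centre time `k * step_s + window_s / 2`. An RR
#' interval belongs to a placement iff its whole attributed span
#' `(t[i-1], t[i]]` lies inside the placement, which prevents double
#' counting of boundary beats. The number of placements is
#' `floor((duration - window_s) / step_s) + 1`.
#'
#' @param series An [rr_series()].
#' @param window_s Window duration in seconds.
#' @param step_s Hop in seconds (default 1).
#' @return A list with `centers_s` (numeric) and `first`/`last` (integer
#'   vectors indexing `series$rr_ms`: the intervals of each placement are
#'   `rr_ms[first[k]:last[k]]`, empty when `last < first`). Returns zero
#'   placements, with a warning, when the run is shorter than the window.
#' @export
segment_series <- function(series, window_s, step_s = 1) {
  stopifnot(inherits(series, "rr_series"))
  dur <- duration_s(series)
  if (dur < window_s) {
    warning(sprintf(
      "segment_series: run %s/%s (%.1f s) shorter than %g-s window; no placements",
      series$subject_id, series$run_id, dur, window_s))
    return(list(centers_s = numeric(0), first = integer(0), last = integer(0)))
  }
  n_place <- floor((dur - window_s) / step_s) + 1
  starts <- (seq_len(n_place) - 1) * step_s
  t <- series$t_beats_s
  n <- length(series$rr_ms)
  # interval i spans (t[i], t[i+1]] (1-based beat times); it is inside
  # [s, s + w) iff t[i] >= s and t[i+1] < s + w
  t_lo <- t[seq_len(n)]        # left endpoint of interval i
  t_hi <- t[seq_len(n) + 1L]   # right endpoint of interval i
  eps <- 1e-9
  first <- findInterval(starts - eps, t_lo) + 1L
  last <- findInterval(starts + window_s - eps, t_hi)
  list(centers_s = starts + window_s / 2,
       first = as.integer(first), last = as.integer(last))
}

#' Align a short-window feature vector to the reference vector
#'
#' A feature vector extracted with a short window has more measurements
#' than the 180-second reference vector from the same run. For pairwise
#' analyses (Spearman correlation, Bland-Altman) the short vector is
#' restricted to the measurement instants of the reference vector: for each
#' reference centre time the short-vector value at the same centre is
#' taken. On the default grid all window sizes share the 1-second centre
#' lattice, so centres match exactly; for custom grids whose centres are
#' offset by exactly half a step, the nearest short-vector centre is
#' snapped, ties broken toward earlier time.
#'
#' @param short,ref Feature vectors as data frames with columns `center_s`
#'   and `value` (as produced by [extract_all()] after filtering one
#'   feature/window/run), `short` from a window no longer than `ref`'s.
#' @param step_s Centre spacing of the shared grid (default 1).
#' @return A [tibble::tibble] with columns `center_s`, `short`, `ref`, one
#'   row per reference measurement (same length as `ref`).
#' @export
align_to_reference <- function(short, ref, step_s = 1) {
  sc <- short$center_s
  rc <- ref$center_s
  if (!length(sc) || !length(rc)) {
    stop("align_to_reference: empty feature vector", call. = FALSE)
  }
  if (max(sc) < min(rc) - step_s / 2 || min(sc) > max(rc) + step_s / 2) {
    stop("align_to_reference: no overlapping centres between vectors",
         call. = FALSE)
  }
  eps <- 1e-6
  # fast path: shared 1-second lattice -> exact centre matches
  idx <- match(round(rc * 1e6), round(sc * 1e6))
  for (i in which(is.na(idx))) {
    d <- abs(sc - rc[i])
    jn <- which(d <= step_s / 2 + eps)
    if (length(jn)) idx[i] <- jn[which.min(sc[jn])]  # snap, tie toward earlier
  }
  if (anyNA(idx)) {
    stop("align_to_reference: reference centres without a matching short-window centre",
         call. = FALSE)
  }
  tibble::tibble(center_s = rc, short = short$value[idx], ref = ref$value)
}
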