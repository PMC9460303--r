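# compute the requested feature domains on one RR segment; returns a named
# numeric vector over `registry$feature_id`
.segment_features <- function(rr, t_end_s, window_s, t_start, registry,
                              opts) {
  out <- rep(NA_real_, nrow(registry))
  names(out) <- registry$feature_id
  if (length(rr) < opts$min_beats) return(out)
  doms <- unique(registry$domain)
  if ("time" %in% doms) {
    v <- time_domain_features(rr)
    out[intersect(names(v), names(out))] <-
      v[intersect(names(v), names(out))]
  }
  if ("geometric" %in% doms) {
    v <- geometric_features(rr, opts)
    out[intersect(names(v), names(out))] <-
      v[intersect(names(v), names(out))]
  }
  if ("nonlinear" %in% doms) {
    sdn <- sd(rr)
    v <- c(
      ApEn = approximate_entropy(rr, m = opts$apen_m,
                                 r = opts$apen_r_factor * sdn),
      poincare_sd(rr),
      PTM = point_transition_measure(rr),
      KFD = katz_fd(rr, cap = opts$kfd_cap),
      HFD = higuchi_fd(rr)
    )
    out[intersect(names(v), names(out))] <-
      v[intersect(names(v), names(out))]
  }
  if ("frequency" %in% doms && window_s >= 10 && length(rr) >= 4L) {
    spec <- estimate_psd(rr, t_s = t_end_s, window_s = window_s,
                         t_start = t_start, resample_hz = opts$resample_hz)
    v <- frequency_features(spec)
    out[intersect(names(v), names(out))] <-
      v[intersect(names(v), names(out))]
  }
  out
}

#' Extract every feature at every window size from one run
#'
#' Slides each window of the grid across the run (1-second hop by default)
#' and computes every registry feature on every placement. With the default
#' registry and grid this yields 558 feature vectors per run (31 features x
#' 18 window sizes), each value stamped with the centre time of the window
#' that produced it. Placements with fewer than `opts$min_beats` RR
#' intervals propagate `NA` markers for all features.
#'
#' @param series An [rr_series()].
#' @param grid A [window_grid()].
#' @param registry A [feature_registry()] (possibly restricted, which
#'   skips the unneeded domain computations entirely).
#' @param opts A [feature_options()] list.
#' @return A long-format [tibble::tibble] with columns `subject_id`,
#'   `run_id`, `feature_id`, `window_s`, `center_s`, `value`.
#' @examples
#' run <- generate_rr(gen_config(gen_segment(200), seed = 7))
#' feats <- extract_all(run, window_grid(c(180, 60)),
#'                      feature_registry("time"))
#' dplyr::count(feats, feature_id, window_s)
#' @export
extract_all <- function(series, grid = window_grid(),
                        registry = feature_registry(),
                        opts = feature_options()) {
  stopifnot(inherits(series, "rr_series"), inherits(grid, "window_grid"))
  if (nrow(registry) == 0L) {
    stop("extract_all: empty feature registry", call. = FALSE)
  }
  rr <- series$rr_ms
  t_end <- series$t_beats_s[-1]
  pieces <- vector("list", length(grid$sizes_s))
  for (wi in seq_along(grid$sizes_s)) {
    w <- grid$sizes_s[wi]
    seg <- segment_series(series, w, grid$step_s)
    np <- length(seg$centers_s)
    if (np == 0L) next
    vals <- matrix(NA_real_, nrow = np, ncol = nrow(registry))
    for (k in seq_len(np)) {
      i1 <- seg$first[k]; i2 <- seg$last[k]
      if (i2 < i1) next
      idx <- i1:i2
      vals[k, ] <- .segment_features(
        rr[idx], t_end[idx], w, seg$centers_s[k] - w / 2, registry, opts
      )
    }
    pieces[[wi]] <- tibble::tibble(
      window_s = w,
      center_s = rep(seg$centers_s, times = nrow(registry)),
      feature_id = rep(registry$feature_id, each = np),
      value = as.vector(vals)
    )
  }
  out <- dplyr::bind_rows(pieces)
  tibble::tibble(
    subject_id = series$subject_id,
    run_id = series$run_id,
    feature_id = out$feature_id,
    window_s = out$window_s,
    center_s = out$center_s,
    value = out$value
  )
}

#' Extract features for every run of a study
#'
#' @param study A [study_set()].
#' @inheritParams extract_all
#' @return Row-bound long tibble over all runs (see [extract_all()]).
#' @export
extract_study <- function(study, grid = window_grid(),
                          registry = feature_registry(),
                          opts = feature_options()) {
  stopifnot(inherits(study, "study_set"))
  dplyr::bind_rows(lapply(study$runs, extract_all,
                          grid = grid, registry = registry, opts = opts))
}
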