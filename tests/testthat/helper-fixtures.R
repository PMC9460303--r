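# programmatic fixtures; no stored data files

# constant-RR series of a given duration
const_series <- function(rr_ms = 800, duration_s = 200,
                         subject_id = "S1", run_id = "R1") {
  n <- ceiling(duration_s * 1000 / rr_ms)
  rr_series(rep(rr_ms, n), subject_id = subject_id, run_id = run_id)
}

# beat-recursion sinusoidal RR segment (deterministic tachogram fixture);
# returns list(rr, t_end) with t_end the beat time ending each interval
sine_segment <- function(mean_ms = 800, amp_ms = 40, f_hz = 0.25,
                         duration_s = 180) {
  rr <- numeric(0); t <- 0
  while (t < duration_s) {
    v <- mean_ms + amp_ms * sin(2 * pi * f_hz * t)
    rr <- c(rr, v)
    t <- t + v / 1000
  }
  list(rr = rr, t_end = cumsum(rr) / 1000)
}

# long feature tibble built directly (bypasses extraction) for the
# reliability-stage unit tests
feature_tbl <- function(subject_id, run_id, feature_id, window_s, values,
                        centers = seq_along(values) - 1 + window_s / 2) {
  tibble::tibble(subject_id = subject_id, run_id = run_id,
                 feature_id = feature_id, window_s = window_s,
                 center_s = centers, value = values)
}
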