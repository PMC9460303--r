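#' The 31-feature HRV registry
#'
#' Ordered registry of the HRV features computed per window placement: six
#' time-domain, three geometric, six non-linear and sixteen frequency-domain
#' features (31 in total). Rows are in the conventional reporting order;
#' all downstream matrices use this row order.
#'
#' @param domains Optional character vector to restrict the registry to a
#'   subset of `c("time", "geometric", "nonlinear", "frequency")`.
#' @param features Optional character vector of feature ids to keep (applied
#'   after `domains`), e.g. `"mNN"` for a mean-RR-only analysis.
#' @return A [tibble::tibble] with columns `feature_id` and `domain`.
#' @export
feature_registry <- function(domains = NULL, features = NULL) {
  reg <- tibble::tibble(
    feature_id = c(
      "mNN", "SDNN", "SDSD", "RMSSD", "NN50", "pNN50",
      "TI", "TINN", "SI",
      "ApEn", "SD1", "SD2", "PTM", "KFD", "HFD",
      "VLF", "LF", "HF", "VLFnu", "LFnu", "HFnu",
      "VLFpeak", "LFpeak", "HFpeak",
      "VLFpeak_nu", "LFpeak_nu", "HFpeak_nu",
      "totPow", "Peak", "LF_HF", "LFpeak_HFpeak"
    ),
    domain = rep(c("time", "geometric", "nonlinear", "frequency"),
                 times = c(6L, 3L, 6L, 16L))
  )
  if (!is.null(domains)) reg <- reg[reg$domain %in% domains, ]
  if (!is.null(features)) reg <- reg[reg$feature_id %in% features, ]
  if (nrow(reg) == 0L) {
    stop("feature_registry: empty registry", call. = FALSE)
  }
  reg
}

#' Feature tunables
#'
#' All feature-bank tunables in one list. Defaults follow common HRV
#' practice: sample (N-1) standard deviations, approximate entropy with
#' embedding `m = 2` and tolerance `0.2 * SDNN` of the segment, 1/128-s
#' histogram bins for TI/TINN, 50-ms bins for the Baevsky stress index,
#' 4-Hz tachogram resampling for spectra, and a minimum of 4 RR intervals
#' per window (shorter segments yield undefined-value markers).
#'
#' @param apen_m Approximate-entropy embedding dimension.
#' @param apen_r_factor Tolerance as a multiple of the segment SDNN.
#' @param kmax_max Upper cap of the Higuchi `kmax` (the effective value is
#'   `min(kmax_max, floor((N - 1) / 2))`, following the window size).
#' @param ti_bin_ms TI/TINN histogram bin width (ms); 1000/128 by convention.
#' @param si_bin_ms Stress-index histogram bin width (ms).
#' @param resample_hz Tachogram resampling rate for spectral estimation.
#' @param min_beats Minimum RR intervals per window; below it every feature
#'   of the placement is the undefined marker `NA`.
#' @param kfd_cap Cap reported for Katz fractal dimension when its
#'   denominator degenerates toward zero (alternating-extreme segments).
#' @return A named list of class `feature_options`.
#' @export
feature_options <- function(apen_m = 2L, apen_r_factor = 0.2,
                            kmax_max = 8L,
                            ti_bin_ms = 1000 / 128, si_bin_ms = 50,
                            resample_hz = 4, min_beats = 4L,
                            kfd_cap = 10) {
  structure(list(apen_m = as.integer(apen_m), apen_r_factor = apen_r_factor,
                 kmax_max = as.integer(kmax_max),
                 ti_bin_ms = ti_bin_ms, si_bin_ms = si_bin_ms,
                 resample_hz = resample_hz, min_beats = as.integer(min_beats),
                 kfd_cap = kfd_cap),
            class = "feature_options")
}

#' Time-domain HRV features
#'
#' `mNN` is the mean RR interval; `SDNN` the sample standard deviation of
#' the intervals; successive differences `d[i] = rr[i+1] - rr[i]` give
#' `SDSD` (their sample standard deviation), `RMSSD = sqrt(mean(d^2))`,
#' `NN50` (count of `|d| > 50` ms) and `pNN50 = 100 * NN50 / (N - 1)`.
#'
#' @param rr RR segment in milliseconds.
#' @return Named numeric vector `mNN`, `SDNN`, `SDSD`, `RMSSD`, `NN50`,
#'   `pNN50`; all `NA` when fewer than 4 intervals.
#' @export
time_domain_features <- function(rr) {
  if (length(rr) < 4L) {
    return(c(mNN = NA_real_, SDNN = NA_real_, SDSD = NA_real_,
             RMSSD = NA_real_, NN50 = NA_real_, pNN50 = NA_real_))
  }
  d <- diff(rr)
  nn50 <- sum(abs(d) > 50)
  c(mNN = mean(rr), SDNN = sd(rr), SDSD = sd(d),
    RMSSD = sqrt(mean(d^2)), NN50 = as.numeric(nn50),
    pNN50 = 100 * nn50 / (length(rr) - 1L))
}

# histogram on bins [k*bw, (k+1)*bw) anchored at 0; returns counts over the
# contiguous occupied range plus the bin index offset
.anchored_hist <- function(rr, bw) {
  idx <- floor(rr / bw)
  lo <- min(idx)
  counts <- tabulate(idx - lo + 1L, nbins = max(idx) - lo + 1L)
  list(counts = counts, lo = lo, bw = bw)
}

# exhaustive best-triangle baseline width (ms) for the NN histogram:
# the apex is pinned at the modal bin centre/height and all (M, N) bin-edge
# pairs bracketing the modal bin are scored by summed squared error
.tinn <- function(h) {
  counts <- h$counts
  if (sum(counts > 0) <= 1L) return(0)
  bw <- h$bw
  nb <- length(counts)
  mstar <- which.max(counts)
  centers <- (h$lo + seq_len(nb) - 0.5) * bw
  X <- centers[mstar]
  Y <- counts[mstar]
  # pad one empty bin each side so the triangle is scored where D = 0 too
  cent_ext <- c(centers[1] - bw, centers, centers[nb] + bw)
  d_ext <- c(0, counts, 0)
  m_edges <- (h$lo + 0:(mstar - 1L)) * bw          # left edges <= modal bin's
  n_edges <- (h$lo + (mstar):nb) * bw              # right edges >= modal bin's
  best <- Inf; best_w <- 0
  for (M in m_edges) {
    for (N in n_edges) {
      q <- numeric(length(cent_ext))
      rise <- cent_ext > M & cent_ext <= X
      fall <- cent_ext > X & cent_ext < N
      if (N > X) q[fall] <- Y * (N - cent_ext[fall]) / (N - X)
      if (X > M) q[rise] <- Y * (cent_ext[rise] - M) / (X - M)
      q[abs(cent_ext - X) < 1e-12] <- Y
      err <- sum((d_ext - q)^2)
      if (err < best - 1e-12) { best <- err; best_w <- N - M }
    }
  }
  best_w
}

#' Geometric HRV features
#'
#' `TI` (HRV triangular index) is the number of intervals divided by the
#' height of the NN histogram (bin width `ti_bin_ms`, bins anchored at 0).
#' `TINN` is the baseline width (ms) of the best triangular interpolation of
#' that histogram, found by exhaustive search over bin-edge pairs bracketing
#' the modal bin with the apex at the modal height. `SI` is Baevsky's stress
#' index `AMo / (2 * Mo * MxDMn)` computed on a 50-ms histogram whose bins
#' are centred on multiples of 50 ms: `Mo` is the modal bin centre in
#' seconds, `AMo` the percentage of intervals in the modal bin and `MxDMn`
#' the RR range in seconds. A constant segment has no spread, so `SI` is
#' undefined (`NA`) and `TINN` is 0.
#'
#' @param rr RR segment in milliseconds.
#' @param opts A [feature_options()] list.
#' @return Named numeric vector `TI`, `TINN`, `SI`.
#' @export
geometric_features <- function(rr, opts = feature_options()) {
  if (length(rr) < 4L) return(c(TI = NA_real_, TINN = NA_real_, SI = NA_real_))
  n <- length(rr)
  h <- .anchored_hist(rr, opts$ti_bin_ms)
  ti <- n / max(h$counts)
  tinn <- .tinn(h)
  # SI: bins centred on multiples of si_bin_ms (nearest-bin assignment)
  b <- round(rr / opts$si_bin_ms)
  blo <- min(b)
  cnt <- tabulate(b - blo + 1L, nbins = max(b) - blo + 1L)
  mo_bin <- blo + which.max(cnt) - 1L              # tie -> lower RR
  mo_s <- mo_bin * opts$si_bin_ms / 1000
  amo <- 100 * max(cnt) / n
  mxdmn_s <- (max(rr) - min(rr)) / 1000
  si <- if (mxdmn_s <= 0 || mo_s <= 0) NA_real_ else amo / (2 * mo_s * mxdmn_s)
  c(TI = ti, TINN = tinn, SI = si)
}

#' Poincare-plot dispersions SD1 and SD2
#'
#' Points `(rr[i], rr[i+1])` are rotated by 45 degrees:
#' `u = (rr[i+1] - rr[i]) / sqrt(2)`, `v = (rr[i] + rr[i+1]) / sqrt(2)`.
#' `SD1` is the sample standard deviation of `u` (dispersion perpendicular
#' to the identity line) and `SD2` of `v` (along it). Computed directly from
#' the rotation, so `SD1 == SDSD / sqrt(2)` holds exactly under the shared
#' sample-deviation convention.
#'
#' @param rr RR segment in milliseconds.
#' @return Named numeric vector `SD1`, `SD2` (ms).
#' @export
poincare_sd <- function(rr) {
  if (length(rr) < 4L) return(c(SD1 = NA_real_, SD2 = NA_real_))
  n <- length(rr)
  u <- (rr[-1] - rr[-n]) / sqrt(2)
  v <- (rr[-1] + rr[-n]) / sqrt(2)
  c(SD1 = sd(u), SD2 = sd(v))
}

#' Approximate entropy of an RR segment
#'
#' Standard ApEn with self-matches: `C_i^m(r)` is the fraction of templates
#' within Chebyshev distance `r` of template `i`, `Phi^m` the mean of
#' `log(C_i^m)`, and `ApEn = Phi^m - Phi^(m+1)`. The default tolerance is
#' `0.2 * SDNN` of the segment.
#'
#' @param rr RR segment in milliseconds.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance in ms; default `0.2 * sd(rr)`.
#' @return ApEn (dimensionless), `NA` when fewer than `m + 2` intervals.
#' @export
approximate_entropy <- function(rr, m = 2L, r = 0.2 * sd(rr)) {
  if (!is.finite(r) || r < 0) {
    stop("approximate_entropy: tolerance r must be >= 0", call. = FALSE)
  }
  if (length(rr) < m + 2L) return(NA_real_)
  apen_cpp(as.numeric(rr), as.integer(m), r)
}

#' Point transition measure
#'
#' Temporal variation at the point-to-point level of the Poincare plot:
#' the mean Euclidean distance between consecutive Poincare points,
#' `mean(sqrt(d[i]^2 + d[i+1]^2))` with `d = diff(rr)`. Translation of the
#' whole segment leaves it unchanged.
#'
#' @param rr RR segment in milliseconds.
#' @return PTM in ms; `NA` when fewer than 4 intervals.
#' @export
point_transition_measure <- function(rr) {
  if (length(rr) < 4L) return(NA_real_)
  d <- diff(rr)
  k <- length(d)
  mean(sqrt(d[-k]^2 + d[-1]^2))
}

#' Katz fractal dimension
#'
#' The segment is treated as a waveform with unit abscissa spacing:
#' `L` is the total ordinate path length `sum(|diff(rr)|)`, `d` the maximal
#' deviation from the first sample, and with `n = N - 1`,
#' `KFD = log10(n) / (log10(n) + log10(d / L))`. A monotone ramp has
#' `d == L` and hence KFD 1. When the denominator degenerates to zero
#' (possible on short alternating segments where `log10(d/L) == -log10(n)`)
#' the value is capped at `cap`; values above the cap are truncated to it.
#'
#' @param rr RR segment in milliseconds.
#' @param cap Reported ceiling for degenerate denominators.
#' @return KFD (dimensionless, >= 1); `NA` for constant segments.
#' @export
katz_fd <- function(rr, cap = 10) {
  if (length(rr) < 4L) return(NA_real_)
  L <- sum(abs(diff(rr)))
  if (L == 0) return(NA_real_)
  d <- max(abs(rr - rr[1]))
  n <- length(rr) - 1L
  denom <- log10(n) + log10(d / L)
  if (denom < 1e-12) return(cap)
  min(log10(n) / denom, cap)
}

#' Higuchi fractal dimension
#'
#' Standard Higuchi construction: for each scale `k = 1..kmax` and offset
#' `m = 1..k`, the curve length of the decimated series is normalised by
#' `(N - 1) / (floor((N - m) / k) * k)` and by `k`; `L(k)` is the offset
#' mean and HFD the least-squares slope of `log(L(k))` against
#' `log(1 / k)`. The default `kmax` follows the window size as
#' `min(8, floor((N - 1) / 2))`.
#'
#' @param rr RR segment in milliseconds.
#' @param kmax Maximal scale; must be >= 2 when supplied.
#' @return HFD (dimensionless, ~1 for a line, ~2 for white noise); `NA`
#'   when the segment is constant or too short for `kmax >= 2`.
#' @export
higuchi_fd <- function(rr, kmax = NULL) {
  N <- length(rr)
  default_kmax <- is.null(kmax)
  if (default_kmax) kmax <- min(8L, floor((N - 1) / 2))
  if (kmax < 2L) {
    if (default_kmax) return(NA_real_)
    stop("higuchi_fd: kmax must be >= 2", call. = FALSE)
  }
  if (N < 2L * kmax) return(NA_real_)
  x <- as.numeric(rr)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm_sum <- 0
    for (m in seq_len(k)) {
      idx <- seq(m, N, by = k)
      ni <- length(idx) - 1L
      lm_sum <- lm_sum +
        sum(abs(diff(x[idx]))) * (N - 1) / (ni * k) / k
    }
    Lk[k] <- lm_sum / k
  }
  if (any(Lk <= 0)) return(NA_real_)
  lx <- log(1 / seq_len(kmax))
  ly <- log(Lk)
  unname(coef(lm(ly ~ lx))[2])
}
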