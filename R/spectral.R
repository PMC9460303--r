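# trapezoidal integral
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# trapezoidal band power over [lo, hi] with linear interpolation of the
# spectrum at the band edges, so adjacent bands add exactly to their union
.band_power <- function(freqs, psd, lo, hi) {
  flo <- max(lo, freqs[1])
  fhi <- min(hi, freqs[length(freqs)])
  if (fhi <= flo) return(NA_real_)
  inside <- freqs > flo & freqs < fhi
  fx <- c(flo, freqs[inside], fhi)
  fy <- stats::approx(freqs, psd, xout = fx, rule = 2)$y
  .trapz(fx, fy)
}

#' Canonical HRV frequency bands
#'
#' The spectral features integrate over the very-low-frequency,
#' low-frequency and high-frequency bands, half-open on the left so that
#' the three bands partition the axis up to 0.4 Hz. The band edges imply
#' the slowest oscillation each band contains: a full VLF cycle takes at
#' least `1 / 0.04 = 25` s and a full LF cycle between `1 / 0.15` (about
#' 6.7 s) and 25 s, which is why windows shorter than those periods cannot
#' resolve the band.
#'
#' @return A [tibble::tibble] with columns `band`, `lo_hz`, `hi_hz`.
#' @export
frequency_bands <- function() {
  tibble::tibble(band = c("VLF", "LF", "HF"),
                 lo_hz = c(0, 0.04, 0.15),
                 hi_hz = c(0.04, 0.15, 0.4))
}

#' Power spectral density of an RR segment
#'
#' The tachogram (RR value against its beat time) is interpolated with a
#' cubic spline onto a uniform grid at `resample_hz` spanning the window,
#' with constant extrapolation outside the beat support; the mean is
#' removed, a Hann taper applied, and a single-segment periodogram computed
#' with density normalisation, so that the integral of the PSD over
#' frequency matches the tapered signal's variance (in ms^2) up to taper
#' leakage. Frequencies run from `1 / window_s` to `resample_hz / 2` Hz
#' (2 Hz at the default 4-Hz resampling). A single segment is used rather
#' than Welch averaging because the shortest windows (10 s) leave nothing
#' to average.
#'
#' @param rr RR segment in milliseconds.
#' @param t_s Beat time (s) at the *end* of each interval; defaults to the
#'   cumulative sum of `rr`.
#' @param window_s Nominal window duration (s); defaults to the beat span.
#' @param t_start Window start time (s); defaults to the left endpoint of
#'   the first interval.
#' @param resample_hz Resampling rate (Hz).
#' @return List of class `spectral_estimate` with `freqs_hz`, `psd`
#'   (ms^2/Hz), `resample_hz`, `window_s`.
#' @export
estimate_psd <- function(rr, t_s = cumsum(rr) / 1000,
                         window_s = NULL, t_start = NULL,
                         resample_hz = 4) {
  if (length(rr) < 4L) {
    stop("estimate_psd: at least 4 RR intervals required", call. = FALSE)
  }
  if (is.null(t_start)) t_start <- t_s[1] - rr[1] / 1000
  if (is.null(window_s)) window_s <- t_s[length(t_s)] - t_start
  if (window_s < 10) {
    stop("estimate_psd: window shorter than 10 s", call. = FALSE)
  }
  fs <- resample_hz
  n <- round(window_s * fs)
  grid <- t_start + (seq_len(n) - 1L) / fs
  gi <- pmin(pmax(grid, t_s[1]), t_s[length(t_s)])  # constant extrapolation
  x <- spline(t_s, rr, xout = gi)$y
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  U <- mean(w^2)
  X <- fft(x * w)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)
  p <- Mod(X[k + 1L])^2 / (fs * n * U)
  mult <- rep(2, kmax)
  if (n %% 2 == 0) mult[kmax] <- 1   # Nyquist bin is not mirrored
  structure(
    list(freqs_hz = k * fs / n, psd = mult * p,
         resample_hz = fs, window_s = window_s),
    class = "spectral_estimate"
  )
}

#' Frequency-domain HRV features from a spectral estimate
#'
#' Band powers are trapezoidal integrals of the PSD over the canonical
#' bands VLF (0, 0.04], LF (0.04, 0.15] and HF (0.15, 0.4] Hz (half-open on
#' the left so the bands partition the axis); `totPow` integrates over
#' (0, 0.4], making `VLFnu + LFnu + HFnu = 100` an exact identity whenever
#' all three bands are resolvable. `Xpeak` is the frequency of the PSD
#' maximum inside band X, `Peak` the overall maximum below 0.4 Hz, and the
#' `Xpeak_nu` variants report the PSD value at the band peak divided by the
#' summed PSD below 0.4 Hz. Bands not resolvable at the window's frequency
#' resolution (e.g. VLF for windows under 25 s) yield `NA` markers, as does
#' `LF_HF` when the HF power is zero.
#'
#' @param spec A `spectral_estimate` from [estimate_psd()].
#' @return Named numeric vector of the 16 frequency-domain features, in
#'   registry order.
#' @export
frequency_features <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  f <- spec$freqs_hz
  p <- spec$psd
  bands <- frequency_bands()
  edges <- stats::setNames(
    lapply(seq_len(nrow(bands)), function(i) c(bands$lo_hz[i], bands$hi_hz[i])),
    bands$band)
  pow <- vapply(edges, function(e) .band_power(f, p, e[1], e[2]), numeric(1))
  tot <- .band_power(f, p, 0, 0.4)
  nu <- 100 * pow / tot
  in_tot <- f <= 0.4 + 1e-12
  sum_tot <- sum(p[in_tot])
  pk <- vapply(edges, function(e) {
    inb <- f > e[1] + 1e-12 & f <= e[2] + 1e-12
    if (!any(inb)) return(c(NA_real_, NA_real_))
    fb <- f[inb]; pb <- p[inb]
    i <- which.max(pb)
    c(fb[i], pb[i] / sum_tot)
  }, numeric(2))
  peak_all <- if (any(in_tot)) f[in_tot][which.max(p[in_tot])] else NA_real_
  lf_hf <- if (!is.na(pow[["HF"]]) && pow[["HF"]] > 0)
    pow[["LF"]] / pow[["HF"]] else NA_real_
  pkf <- unname(pk[1, ])  # band peak frequencies (VLF, LF, HF)
  pkn <- unname(pk[2, ])  # band peak normalised values
  pk_ratio <- if (!is.na(pkf[3]) && pkf[3] > 0) pkf[2] / pkf[3] else NA_real_
  c(VLF = pow[["VLF"]], LF = pow[["LF"]], HF = pow[["HF"]],
    VLFnu = nu[["VLF"]], LFnu = nu[["LF"]], HFnu = nu[["HF"]],
    VLFpeak = pkf[1], LFpeak = pkf[2], HFpeak = pkf[3],
    VLFpeak_nu = pkn[1], LFpeak_nu = pkn[2], HFpeak_nu = pkn[3],
    totPow = tot, Peak = peak_all, LF_HF = lf_hf,
    LFpeak_HFpeak = pk_ratio)
}
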