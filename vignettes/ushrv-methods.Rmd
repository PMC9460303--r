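---
title: "Multi-resolution HRV reliability: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution HRV reliability: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ushrv` quantifies how reliably heart-rate-variability features survive a
shortening of the extraction window. This vignette is the package's own
account of the procedure, its assumptions, the tunables that matter, and
the places where a genuine design choice had to be made.

## The data model

An RR series is a strictly positive sequence of inter-beat intervals in
milliseconds. Beat times are derived with the first beat at `t = 0`, so
interval `i` occupies the span `(t[i-1], t[i]]` seconds and the run
duration equals `sum(rr)/1000`. Runs enter the reliability analysis only
when strictly longer than the reference window (180 s by default): a run
of exactly 180 s admits no sliding of the reference window and carries no
comparative information. No ectopic-beat or outlier-RR correction is
applied — the package consumes RR series as given, and users with raw ECG
should clean their series upstream.

## Sliding windows and alignment

Windows of duration `w` are placed at starts `0, 1, 2, … s` (1-s hop) and
cover the half-open span `[start, start + w)`. An RR interval belongs to a
placement iff its whole span lies inside; the half-open convention
prevents an interval from being counted by two adjacent placements of the
same size. Each measurement is stamped with the window centre
`start + w/2`, giving `floor((duration − w)/step) + 1` measurements per
feature, so shorter windows always produce at least as many measurements.

The rank-sum comparison deliberately uses the *full* vectors of unequal
length — it compares distributions, not paired instants. Correlation and
Bland–Altman need pairs, so the short vector is restricted to the
reference's measurement instants. On the default grid all window sizes are
multiples of 10 s and all centres share the 1-second lattice, so this
restriction is an exact centre match; for custom grids whose centres are
offset by exactly half a step, the nearest short-window centre is taken,
with ties resolved toward earlier time. Windows with fewer than 4
intervals yield undefined markers for every feature (the approximate
entropy with embedding 2 is the binding constraint); undefined values are
never imputed — they are dropped pairwise downstream and counted in drop
logs.

## The feature bank

Thirty-one features in four domains, all on the RR segment of one window
placement:

* **Time (6)** — mNN, SDNN, SDSD, RMSSD, NN50, pNN50. All standard
  deviations in the package use the sample (`N−1`) denominator; on
  ultra-short windows the population/sample choice is material, and the
  sample convention matches common HRV software. `pNN50` divides by the
  number of successive differences (`N−1`).
* **Geometric (3)** — TI and TINN use the conventional NN histogram with
  1/128-s bins anchored at 0. TINN is found by exhaustive search over all
  bin-edge pairs that bracket the modal bin, scoring each candidate
  triangle (apex pinned at the modal bin) by summed squared error against
  the histogram. The Baevsky stress index uses a separate 50-ms histogram
  whose bins are *centred* on multiples of 50 ms (nearest-50 assignment),
  so a modal value of 800 ms reports a mode of 0.80 s;
  `SI = AMo / (2 · Mo · MxDMn)` with AMo in percent and Mo, MxDMn in
  seconds. A constant segment has no spread: SI is undefined, TINN is 0.
* **Non-linear (6)** — SD1/SD2 are computed by the explicit 45° rotation
  of the Poincaré cloud rather than the SDNN/SDSD approximation, which can
  misbehave on ultra-short alternating segments; with the shared
  denominator convention `SD1 = SDSD/√2` holds exactly. ApEn uses `m = 2`,
  tolerance `0.2·SDNN` of the segment, self-matches included (conventional
  defaults). The point transition measure is defined here as the mean
  Euclidean distance between consecutive Poincaré points — a concrete,
  translation-invariant reading of "point-to-point temporal variation";
  the adopted definition is stated in the documentation because published
  variants differ. Katz FD follows the waveform convention (path length =
  sum of ordinate steps, unit abscissa); its denominator can reach zero on
  short alternating extremes, in which case the value is capped (default
  10) rather than reported as infinite. Higuchi FD uses
  `kmax = min(8, floor((N−1)/2))`, deliberately tied to the window size.
* **Frequency (16)** — the tachogram is cubic-spline resampled at 4 Hz
  over the window (constant extrapolation outside the beat support), mean
  removed, Hann-tapered, and a single-segment periodogram is computed with
  density normalisation (integral ≈ variance). A single segment is used
  instead of Welch averaging because a 10-s window leaves nothing to
  split; the method is deterministic, which matters for reproducible
  matrices. Bands are half-open on the left — VLF (0, 0.04], LF
  (0.04, 0.15], HF (0.15, 0.4] Hz — so they partition the axis; powers are
  trapezoidal integrals with the spectrum linearly interpolated at band
  edges, making `VLF + LF + HF = totPow` and hence
  `VLFnu + LFnu + HFnu = 100` exact identities whenever all bands are
  resolvable. Band peaks are reported in hertz (the natural unit of a
  frequency location, whatever unit label tables elsewhere may carry);
  the "normalised peak" variants report the PSD value at the band peak
  divided by the summed PSD below 0.4 Hz — one concrete reading of an
  otherwise under-specified quantity, stated here and in the docs. The
  normalisation base for the `nu` powers is total power including VLF, so
  `VLFnu` is well defined. A window shorter than a band's slowest period
  (25 s for VLF, ~6.7 s for LF) cannot resolve that band: its features are
  undefined markers, not zeros.

## Reliability statistics

The Kolmogorov–Smirnov screen standardises each run's measurements before
testing against the standard normal CDF — without standardisation a test
against N(0, 1) would be vacuous for raw feature scales. Because the
parameters are estimated from the data, the p-values carry the Lilliefors
bias; the screen is a motivation step for non-parametric testing, not an
inference, so the bias is recorded rather than corrected.

The Wilcoxon rank-sum stage uses the exact null distribution when both
vectors have at most 10 values and the tie-corrected normal approximation
otherwise (`exact = "exact"/"approx"` overrides). A pooled sample with
zero variance is reported as `p = 1`: two identical constants are not
evidence of difference. Spearman's ρ uses mid-ranks; per-run coefficients
are aggregated with Fisher's z, weights `n − 3`, after clipping |ρ| at
`1 − 1e-12` to keep `atanh` finite. Cells lose a run (and log it) when the
run's vector is entirely undefined or a correlation is undefined
(constant vector); nothing is imputed. α = 0.05 throughout, with no
multiple-testing correction — the matrices are descriptive summaries of
per-run tests, and users can post-process the logged p-values with
`p.adjust` if they need family-wise control.

Trend regressions place the reference window at the origin and measure
`x` in units of 10-s reduction, so slopes read as "change per 10 s of
window shrinkage" and intercepts as the value at 180 s. A constant
response has slope 0 and an undefined R². The Bland–Altman summary is
fully non-parametric: median bias and 2.5th/97.5th interpolated
percentiles (R's type-7 quantiles) as limits of agreement; by
construction the limits contain ≈95 % of differences for large n, and at
least 10 defined pairs are required for the summary to be meaningful.

## The synthetic generator

`generate_rr()` produces each interval as
`mean_rr + amp_lf·sin(2πf_lf t) + amp_hf·sin(2πf_hf t) + ε`, evaluated at
the current beat time, with `ε ~ N(0, noise_sd²)` and the beat clock
advanced by the generated interval. This beat-domain modulation is an
auditable approximation to full integral-pulse-frequency modulation; it
places spectral peaks at the configured frequencies (which the tests
verify) without modelling the cardiac pacemaker. Candidate intervals at or
below 250 ms are resampled — a physiological floor that leaves typical
configurations unbiased. Defaults describe a plausible resting-to-load
adult: mean RR 850 ms, LF drive 40 ms at 0.10 Hz, HF drive 30 ms at
0.25 Hz, noise 20 ms; run durations drawn uniformly from 200–900 s over
21 subjects with up to 4 runs, with per-subject jitter of ±5 % on the mean
and ±10 % on amplitudes. Per-run seeds and all draws derive
deterministically from one master seed via a seeded RNG stream, so studies
are byte-reproducible while runs stay independent. Piecewise segments can
shift any parameter mid-run to emulate cognitive-state changes.

What the generator does *not* emulate: respiratory coupling that moves
the HF frequency, ectopic beats and artefacts, circadian drift, and the
inter-subject heterogeneity of real populations. Passing tests therefore
demonstrate that the pipeline measures what it claims on signals with
known structure — not that any particular feature is reliable in a given
real-world population.

## Problem sizes and numerical tolerances

The test-suite and acceptance-script studies are sized for a single CPU:
one full-registry extraction of a 600-s run (558 vectors), small
three-to-four-run studies for end-to-end structure, a 21-run single-window
study for the correlation-degradation property, and 500 replicates for the
type-I calibration of the rank-sum stage. Algebraic identities
(`SD1 = SDSD/√2`, the `nu` sum, the RMSSD–SDSD relation) are asserted to
1e-9 relative or better; spectral peak locations to one frequency bin
(`1/window` Hz); the Parseval-style integral check to 10 % (Hann leakage);
brute-force oracle comparisons to 1e-12.

## Known limitations

* The spectral stage assumes local stationarity within a window; strongly
  non-stationary segments blur band powers (this is intrinsic to the
  windowed analysis, not to the implementation).
* TINN's exhaustive triangle fit is resolution-limited by the 1/128-s bin
  width; very sparse histograms (tiny windows) make it coarse.
* KFD on quasi-alternating segments saturates at the documented cap; treat
  capped values as "degenerate", not as measurements.
* The KS screen's Lilliefors bias is documented, not corrected.
* Wilcoxon exact p-values are unavailable under ties (R's standard
  behaviour); the tie-corrected approximation is used there even for
  small samples.
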