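test_that("band definitions partition the axis and imply the period limits", {
  b <- frequency_bands()
  expect_equal(b$band, c("VLF", "LF", "HF"))
  expect_equal(b$lo_hz[-1], b$hi_hz[-3])          # contiguous partition
  expect_equal(1 / b$hi_hz[b$band == "VLF"], 25)  # slowest VLF cycle: 25 s
  expect_equal(1 / b$hi_hz[b$band == "LF"], 6.7, tolerance = 0.01)
})

test_that("a constant tachogram has (numerically) zero power everywhere", {
  sp <- estimate_psd(rep(800, 225), window_s = 180, t_start = 0)
  expect_true(all(sp$psd <= 1e-6))
  expect_equal(range(sp$freqs_hz), c(1 / 180, 2), tolerance = 1e-9)
})

test_that("sinusoidal tachograms put the spectral peak at the driving frequency", {
  fix_hf <- sine_segment(mean_ms = 800, amp_ms = 40, f_hz = 0.25,
                         duration_s = 180)
  sp <- estimate_psd(fix_hf$rr, t_s = fix_hf$t_end, window_s = 180,
                     t_start = 0)
  bin <- 1 / 180
  expect_lt(abs(sp$freqs_hz[which.max(sp$psd)] - 0.25), bin + 1e-9)
  ff <- frequency_features(sp)
  expect_lt(abs(ff[["HFpeak"]] - 0.25), bin + 1e-9)
  expect_gt(ff[["HFnu"]], 80)
  expect_lt(ff[["LF_HF"]], 0.25)

  fix_lf <- sine_segment(mean_ms = 800, amp_ms = 40, f_hz = 0.10,
                         duration_s = 180)
  ff2 <- frequency_features(estimate_psd(fix_lf$rr, t_s = fix_lf$t_end,
                                         window_s = 180, t_start = 0))
  expect_lt(abs(ff2[["LFpeak"]] - 0.10), bin + 1e-9)
  expect_equal(ff2[["Peak"]], ff2[["LFpeak"]])
  expect_equal(ff2[["LFpeak_HFpeak"]], ff2[["LFpeak"]] / ff2[["HFpeak"]])
})

test_that("PSD integral approximates the resampled signal variance", {
  set.seed(23)
  fix <- sine_segment(mean_ms = 850, amp_ms = 30, f_hz = 0.1,
                      duration_s = 180)
  rr <- fix$rr + rnorm(length(fix$rr), 0, 15)
  sp <- estimate_psd(rr, t_s = fix$t_end, window_s = 180, t_start = 0)
  # reconstruct the detrended resampled series exactly as the estimator does
  n <- 180 * 4
  grid <- (seq_len(n) - 1) / 4
  gi <- pmin(pmax(grid, fix$t_end[1]), max(fix$t_end))
  x <- spline(fix$t_end, rr, xout = gi)$y
  x <- x - mean(x)
  integ <- sum(diff(sp$freqs_hz)[1] * sp$psd)
  expect_lt(abs(integ - var(x)) / var(x), 0.10)
})

test_that("normalised band powers sum to 100 when all bands are resolvable", {
  set.seed(29)
  for (i in 1:3) {
    fix <- sine_segment(mean_ms = 800, amp_ms = runif(1, 10, 50),
                        f_hz = runif(1, 0.05, 0.35), duration_s = 180)
    rr <- fix$rr + rnorm(length(fix$rr), 0, 10)
    ff <- frequency_features(estimate_psd(rr, t_s = fix$t_end,
                                          window_s = 180, t_start = 0))
    expect_equal(ff[["VLFnu"]] + ff[["LFnu"]] + ff[["HFnu"]], 100,
                 tolerance = 1e-6)
    expect_gte(ff[["totPow"]],
               ff[["VLF"]] + ff[["LF"]] + ff[["HF"]] - 1e-9)
    # every band peak lies inside its band
    expect_true(ff[["LFpeak"]] > 0.04 && ff[["LFpeak"]] <= 0.15)
    expect_true(ff[["HFpeak"]] > 0.15 && ff[["HFpeak"]] <= 0.4)
  }
})

test_that("bands unresolvable at short windows yield undefined markers", {
  fix <- sine_segment(mean_ms = 800, amp_ms = 30, f_hz = 0.25,
                      duration_s = 20)
  ff <- frequency_features(estimate_psd(fix$rr, t_s = fix$t_end,
                                        window_s = 20, t_start = 0))
  # 1/20 Hz resolution cannot cover (0, 0.04]
  expect_true(is.na(ff[["VLF"]]))
  expect_true(is.na(ff[["VLFpeak"]]))
  expect_false(is.na(ff[["HF"]]))
  expect_error(estimate_psd(rep(800, 8), window_s = 6, t_start = 0),
               "shorter than 10")
})

test_that("LF dominance holds on the 0.10-Hz fixture for windows >= 60 s", {
  fix <- sine_segment(mean_ms = 800, amp_ms = 50, f_hz = 0.10,
                      duration_s = 200)
  run <- rr_series(fix$rr)
  f <- extract_all(run, window_grid(c(180, 120, 60)),
                   feature_registry("frequency"))
  wide <- tidyr::pivot_wider(f, names_from = "feature_id",
                             values_from = "value")
  expect_true(all(wide$LF > wide$HF))
  expect_true(all(abs(wide$LFpeak - 0.10) <= 1 / wide$window_s + 1e-9))
})
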