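test_that("KS screen accepts normal draws and rejects exponential ones", {
  set.seed(41)
  expect_gt(ks_normality(rnorm(1000)), 0.05)
  expect_lt(ks_normality(rexp(1000)), 0.01)
  expect_true(is.na(ks_normality(rep(5, 20))))
  expect_error(ks_normality(c(1, 2, 3)), "at least 8")
})

test_that("rank-sum p-values match the exhaustive allocation oracle (n <= 7)", {
  expect_equal(ushrv:::.wilcox_p(1:5, 10:14), 2 / 252, tolerance = 1e-12)
  set.seed(43)
  for (i in 1:20) {
    nx <- sample(3:7, 1); ny <- sample(3:7, 1)
    x <- sample(seq(1, 400), nx)   # distinct pooled values: exact null applies
    y <- sample(seq(401, 800), ny) * runif(1)
    expect_equal(ushrv:::.wilcox_p(x, y), wilcox_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman rho matches rank-formula and brute mid-rank oracles", {
  v <- feature_tbl("S1", "R1", "f", 60, values = c(3, 1, 2), centers = 1:3)
  r <- feature_tbl("S1", "R1", "f", 60, values = c(1, 2, 3), centers = 1:3)
  expect_equal(spearman_per_run(v, r)$rho, -0.5)   # 1 - 6*6/(3*8)

  ident <- spearman_per_run(r, r)
  expect_equal(ident$rho, 1)
  rev <- feature_tbl("S1", "R1", "f", 60, values = c(3, 2, 1), centers = 1:3)
  expect_equal(spearman_per_run(rev, r)$rho, -1)

  set.seed(47)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    x <- round(runif(n, 0, 10), 1)   # occasional ties: mid-ranks exercised
    y <- round(runif(n, 0, 10), 1)
    got <- ushrv:::.spearman(x, y)
    if (is.na(got$rho)) next
    expect_equal(got$rho, spearman_brute_rho(x, y), tolerance = 1e-12)
  }
  # constant vectors are undefined markers
  cst <- feature_tbl("S1", "R1", "f", 60, values = rep(2, 5), centers = 1:5)
  var5 <- feature_tbl("S1", "R1", "f", 60, values = c(1, 3, 2, 5, 4),
                      centers = 1:5)
  expect_true(is.na(spearman_per_run(cst, var5)$rho))
})

test_that("Fisher-z aggregation weights runs by their length", {
  expect_equal(fisher_mean_correlation(c(0.5, 0.5), c(20, 200)), 0.5)
  expect_equal(fisher_mean_correlation(c(0, 0.8), c(103, 203)),
               tanh(200 * atanh(0.8) / 300), tolerance = 1e-12)
  expect_equal(fisher_mean_correlation(0.37, 50), 0.37, tolerance = 1e-12)
  expect_equal(fisher_mean_correlation(c(NA, 0.6), c(10, 40)), 0.6)
  expect_true(is.na(fisher_mean_correlation(NA_real_, 10)))
  # clipping keeps perfect correlations finite
  expect_lte(fisher_mean_correlation(c(1, 1), c(50, 60)), 1)
})

test_that("window-trend regression agrees with the normal equations", {
  wins <- seq(180, 10, by = -10)
  x <- (180 - wins) / 10
  fit <- window_trend_regression(100 - 5 * x, wins)
  expect_equal(fit$slope, -5)
  expect_equal(fit$intercept, 100)
  expect_equal(fit$r2, 1)

  cst <- window_trend_regression(rep(100, 18), wins)
  expect_equal(cst$slope, 0)
  expect_true(is.na(cst$r2))

  set.seed(53)
  y <- 90 - 3 * x + rnorm(18, 0, 4)
  got <- window_trend_regression(y, wins)
  want <- ols_brute(x, y)
  expect_equal(got$slope, want$slope, tolerance = 1e-9)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-9)
  expect_equal(got$r2, want$r2, tolerance = 1e-9)
  expect_error(window_trend_regression(c(1, 2, rep(NA, 16)), wins),
               "3 defined")
})

test_that("Bland-Altman uses median bias and interpolated percentile limits", {
  ref <- feature_tbl("S1", "R1", "f", 180, values = rnorm(30), centers = 1:30)
  ident <- bland_altman(ref, ref)
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))
  expect_equal(ident$frac_within, 1)

  d <- 1:100
  short <- feature_tbl("S1", "R1", "f", 60, values = rnorm(100) , centers = 1:100)
  refd <- feature_tbl("S1", "R1", "f", 180, values = short$value - d,
                      centers = 1:100)
  ba <- bland_altman(short, refd)
  expect_equal(ba$bias, 50.5)
  expect_equal(ba$loa_low, 3.475)
  expect_equal(ba$loa_high, 97.525)

  # symmetric differences: zero bias, symmetric limits
  dsym <- c(-(1:50), 1:50)
  refs <- feature_tbl("S1", "R1", "f", 180, values = short$value - dsym,
                      centers = 1:100)
  bas <- bland_altman(short, refs)
  expect_equal(bas$bias, 0)
  expect_equal(bas$loa_low, -bas$loa_high)
  expect_error(bland_altman(feature_tbl("S1", "R1", "f", 60, values = 1:5,
                                        centers = 1:5),
                            feature_tbl("S1", "R1", "f", 180, values = 1:5,
                                        centers = 1:5)),
               "fewer than 10")
})

test_that("percentile limits contain 94-96 % of large i.i.d. samples", {
  set.seed(59)
  for (i in 1:3) {
    n <- 200 + 100 * i
    vals <- rnorm(n)
    short <- feature_tbl("S1", "R1", "f", 60, values = vals, centers = 1:n)
    ref <- feature_tbl("S1", "R1", "f", 180, values = rep(0, n), centers = 1:n)
    ba <- bland_altman(short, ref)
    expect_gte(ba$frac_within, 0.94)
    expect_lte(ba$frac_within, 0.96)
  }
})

test_that("acceptance matrix counts accepting runs and forces the reference column", {
  # 4 runs of one feature at windows 180 / 90; three runs agree with the
  # reference, one is shifted far away
  mk <- function(subj, shift) {
    set.seed(match(subj, paste0("P", 1:4)))
    base <- rnorm(40, 100, 5)
    dplyr::bind_rows(
      feature_tbl(subj, "R1", "mNN", 180, values = base),
      feature_tbl(subj, "R1", "mNN", 90, values = rnorm(60, 100 + shift, 5))
    )
  }
  feats <- dplyr::bind_rows(mk("P1", 0), mk("P2", 0), mk("P3", 0),
                            mk("P4", 50))
  am <- wilcoxon_acceptance_matrix(feats, alpha = 0.05)
  expect_equal(dim(am$pct), c(1, 2))
  expect_equal(am$pct["mNN", "180s"], 100)
  expect_equal(am$pct["mNN", "90s"], 75)
  expect_equal(sum(am$n_dropped), 0)

  # a run whose short vector is entirely undefined is dropped and logged
  feats2 <- dplyr::bind_rows(
    feats,
    feature_tbl("P5", "R1", "mNN", 180, values = rnorm(40, 100, 5)),
    feature_tbl("P5", "R1", "mNN", 90, values = rep(NA_real_, 60))
  )
  am2 <- wilcoxon_acceptance_matrix(feats2)
  expect_equal(am2$n_dropped["mNN", "90s"], 1)
  expect_equal(am2$pct["mNN", "90s"], 75)   # still 3 of 4 tested runs
})

test_that("correlation summary reproduces single-run results and noise behaviour", {
  # one run whose 60-s vector is a monotone transform of the reference
  ref <- feature_tbl("S1", "R1", "f", 180, values = sin(seq(0, 3, length.out = 40)),
                     centers = 90 + 0:39)
  short <- feature_tbl("S1", "R1", "f", 60,
                       values = (sin(seq(0, 3, length.out = 40)))^3,
                       centers = 90 + 0:39)
  cs <- correlation_summary(dplyr::bind_rows(ref, short))
  one <- spearman_per_run(short, ref)
  expect_equal(cs$fisher_mean["f", "60s"], one$rho, tolerance = 1e-12)
  expect_equal(cs$fisher_mean["f", "180s"], 1)
  expect_equal(cs$sig_pct["f", "180s"], 100)

  # pure-noise feature: significant-correlation rate near the alpha level
  set.seed(61)
  runs <- lapply(1:120, function(i) {
    dplyr::bind_rows(
      feature_tbl(sprintf("N%03d", i), "R1", "noise", 180,
                  values = rnorm(40), centers = 90 + 0:39),
      feature_tbl(sprintf("N%03d", i), "R1", "noise", 60,
                  values = rnorm(40), centers = 90 + 0:39))
  })
  csn <- correlation_summary(dplyr::bind_rows(runs))
  expect_lt(abs(csn$sig_pct["noise", "60s"] - 5), 4 + 1e-9)
  expect_lt(abs(csn$fisher_mean["noise", "60s"]), 0.2)
})
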