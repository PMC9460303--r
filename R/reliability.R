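#' Kolmogorov-Smirnov normality screen
#'
#' Standardises the measurements of one run (subtract the mean, divide by
#' the sample standard deviation) and tests them against the standard
#' normal distribution with a one-sample Kolmogorov-Smirnov test
#' (asymptotic p-value). Rejection across runs motivates the use of
#' non-parametric tests downstream. Because the null parameters are
#' estimated from the same data, the p-value carries the well-known
#' Lilliefors bias; this screen reports the plain KS value.
#'
#' @param values Numeric vector of feature measurements from one run; at
#'   least 8 defined values are required.
#' @return The KS p-value, or `NA` when the values have zero variance.
#' @export
ks_normality <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 8L) {
    stop("ks_normality: at least 8 defined values required", call. = FALSE)
  }
  s <- sd(v)
  if (s == 0) return(NA_real_)
  z <- (v - mean(v)) / s
  suppressWarnings(ks.test(z, "pnorm"))$p.value
}

# two-sided rank-sum p-value; exact null when both samples are small
.wilcox_p <- function(x, y, exact = "auto") {
  if (sd(c(x, y)) == 0) return(1)  # fully tied pooled sample: no evidence
  ex <- switch(exact,
               auto = length(x) <= 10L && length(y) <= 10L,
               exact = TRUE, approx = FALSE,
               stop("exact must be 'auto', 'exact' or 'approx'"))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = ex)
  )$p.value
}

# Spearman rho and p on aligned pairs; NA when either side is constant
.spearman <- function(x, y, exact = "auto") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ex <- switch(exact, auto = n <= 9L, exact = TRUE, approx = FALSE,
               stop("exact must be 'auto', 'exact' or 'approx'"))
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = ex)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Spearman correlation of a short-window vector with its reference
#'
#' Aligns the short-window feature vector to the measurement instants of
#' the 180-second reference vector ([align_to_reference()]), drops pairs
#' with undefined values, and computes Spearman's rank correlation with
#' mid-ranks for ties (exact permutation p for 9 or fewer pairs, t
#' approximation otherwise).
#'
#' @param short,ref Data frames with columns `center_s`, `value` for one
#'   feature/run, `short` from the shorter window.
#' @param step_s Shared centre lattice spacing (default 1 s).
#' @param exact `"auto"` (default), `"exact"` or `"approx"`.
#' @return List with `rho`, `p` and `n` (number of defined pairs); `rho`
#'   is `NA` when either aligned vector is constant.
#' @export
spearman_per_run <- function(short, ref, step_s = 1, exact = "auto") {
  al <- align_to_reference(short, ref, step_s = step_s)
  .spearman(al$short, al$ref, exact = exact)
}

#' Fisher-z weighted mean of per-run correlations
#'
#' Correlations are variance-stabilised with `atanh`, averaged with
#' weights `n - 3` (so runs with longer feature vectors weigh more), and
#' back-transformed with `tanh`. Coefficients are clipped to
#' `1 - 1e-12` in magnitude beforehand to keep the transform finite;
#' undefined coefficients are dropped.
#'
#' @param rhos Per-run Spearman coefficients.
#' @param ns Per-run pair counts (each >= 4).
#' @return The back-transformed weighted mean, or `NA` if no run is
#'   defined.
#' @export
fisher_mean_correlation <- function(rhos, ns) {
  stopifnot(length(rhos) == length(ns))
  keep <- is.finite(rhos) & is.finite(ns)
  rhos <- rhos[keep]; ns <- ns[keep]
  if (!length(rhos)) return(NA_real_)
  r <- pmin(pmax(rhos, -(1 - 1e-12)), 1 - 1e-12)
  w <- ns - 3
  tanh(sum(w * atanh(r)) / sum(w))
}

# split a long feature tibble into per-run tibbles (stable order)
.split_runs <- function(features) {
  key <- paste(features$subject_id, features$run_id, sep = "\r")
  split(features, factor(key, levels = unique(key)))
}

# feature ids of a long tibble in registry order (extras appended)
.feature_order <- function(features) {
  ids <- unique(features$feature_id)
  c(intersect(feature_registry()$feature_id, ids),
    setdiff(ids, feature_registry()$feature_id))
}

#' Wilcoxon acceptance matrix
#'
#' For every run, feature and window size, the full short-window feature
#' vector is compared against the full 180-second reference vector of the
#' same run with a two-sided Wilcoxon rank-sum test (no alignment; the two
#' vectors legitimately differ in length). Each matrix cell is the
#' percentage of runs in which no significant difference was found
#' (`p > alpha`). The reference column is 100 % by construction. Runs whose
#' vector is entirely undefined at some cell are excluded there and counted
#' in the drop log.
#'
#' @param features Long feature tibble from [extract_study()].
#' @param alpha Significance level (default 0.05).
#' @param ref_window_s Reference window (default: the largest present).
#' @param exact `"auto"` (exact null when both vectors have at most 10
#'   values), `"exact"`, or `"approx"` (tie-corrected normal).
#' @return An `acceptance_matrix` object: list with `pct`
#'   (features x windows percentage matrix), `n_tested`, `n_dropped`,
#'   `alpha`, `ref_window_s`.
#' @export
wilcoxon_acceptance_matrix <- function(features, alpha = 0.05,
                                       ref_window_s = NULL,
                                       exact = "auto") {
  wins <- sort(unique(features$window_s), decreasing = TRUE)
  if (is.null(ref_window_s)) ref_window_s <- wins[1]
  feats <- .feature_order(features)
  acc <- n_tested <- n_drop <-
    matrix(0, length(feats), length(wins),
           dimnames = list(feats, paste0(wins, "s")))
  for (run in .split_runs(features)) {
    by_feat <- split(run, factor(run$feature_id, levels = feats))
    for (fi in seq_along(feats)) {
      df <- by_feat[[fi]]
      refv <- df$value[df$window_s == ref_window_s]
      refv <- refv[is.finite(refv)]
      for (wi in seq_along(wins)) {
        xv <- df$value[df$window_s == wins[wi]]
        xv <- xv[is.finite(xv)]
        if (!length(xv) || !length(refv)) {
          n_drop[fi, wi] <- n_drop[fi, wi] + 1
          next
        }
        p <- .wilcox_p(xv, refv, exact = exact)
        n_tested[fi, wi] <- n_tested[fi, wi] + 1
        acc[fi, wi] <- acc[fi, wi] + (p > alpha)
      }
    }
  }
  pct <- 100 * acc / n_tested
  pct[, wins == ref_window_s][n_tested[, wins == ref_window_s] > 0] <- 100
  structure(list(pct = pct, n_tested = n_tested, n_dropped = n_drop,
                 alpha = alpha, ref_window_s = ref_window_s),
            class = "acceptance_matrix")
}

#' @export
print.acceptance_matrix <- function(x, ...) {
  cat(sprintf("<acceptance_matrix> %d features x %d windows, alpha %g, ref %gs\n",
              nrow(x$pct), ncol(x$pct), x$alpha, x$ref_window_s))
  print(round(x$pct, 1))
  invisible(x)
}

#' Correlation summary across a study
#'
#' For every run, feature and window size the short-window vector is
#' aligned to the reference instants and Spearman-correlated with the
#' reference vector. Per cell, the per-run coefficients are averaged with
#' [fisher_mean_correlation()] (weights follow run length) and the
#' percentage of runs with a significant correlation (`p < alpha`) is
#' recorded. The reference column is 1 / 100 % by construction. Undefined
#' correlations (constant vectors, too few pairs) are dropped and counted.
#'
#' @inheritParams wilcoxon_acceptance_matrix
#' @param step_s Centre lattice spacing used for alignment.
#' @return A `correlation_summary` object: list with `fisher_mean`,
#'   `sig_pct`, `n_tested`, `n_dropped`, `alpha`, `ref_window_s`.
#' @export
correlation_summary <- function(features, alpha = 0.05,
                                ref_window_s = NULL, step_s = 1,
                                exact = "auto") {
  wins <- sort(unique(features$window_s), decreasing = TRUE)
  if (is.null(ref_window_s)) ref_window_s <- wins[1]
  feats <- .feature_order(features)
  runs <- .split_runs(features)
  nr <- length(runs)
  rho_arr <- p_arr <- n_arr <-
    array(NA_real_, dim = c(length(feats), length(wins), nr))
  for (ri in seq_along(runs)) {
    run <- runs[[ri]]
    by_feat <- split(run, factor(run$feature_id, levels = feats))
    for (fi in seq_along(feats)) {
      df <- by_feat[[fi]]
      ref <- df[df$window_s == ref_window_s, c("center_s", "value")]
      if (!nrow(ref)) next
      for (wi in seq_along(wins)) {
        sh <- df[df$window_s == wins[wi], c("center_s", "value")]
        if (!nrow(sh)) next
        res <- tryCatch(
          spearman_per_run(sh, ref, step_s = step_s, exact = exact),
          error = function(e) list(rho = NA_real_, p = NA_real_, n = 0)
        )
        rho_arr[fi, wi, ri] <- res$rho
        p_arr[fi, wi, ri] <- res$p
        n_arr[fi, wi, ri] <- res$n
      }
    }
  }
  dn <- list(feats, paste0(wins, "s"))
  fisher <- sig <- n_tested <- n_drop <-
    matrix(NA_real_, length(feats), length(wins), dimnames = dn)
  for (fi in seq_along(feats)) {
    for (wi in seq_along(wins)) {
      rhos <- rho_arr[fi, wi, ]
      ok <- is.finite(rhos)
      n_tested[fi, wi] <- sum(ok)
      n_drop[fi, wi] <- nr - sum(ok)
      fisher[fi, wi] <- fisher_mean_correlation(rhos[ok], n_arr[fi, wi, ][ok])
      sig[fi, wi] <- if (any(ok))
        100 * mean(p_arr[fi, wi, ][ok] < alpha) else NA_real_
    }
  }
  ref_col <- wins == ref_window_s
  fisher[, ref_col][n_tested[, ref_col] > 0] <- 1
  sig[, ref_col][n_tested[, ref_col] > 0] <- 100
  structure(list(fisher_mean = fisher, sig_pct = sig,
                 n_tested = n_tested, n_dropped = n_drop,
                 alpha = alpha, ref_window_s = ref_window_s),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("<correlation_summary> %d features x %d windows, alpha %g, ref %gs\n",
              nrow(x$fisher_mean), ncol(x$fisher_mean), x$alpha,
              x$ref_window_s))
  print(round(x$fisher_mean, 2))
  invisible(x)
}

#' Window-trend linear regression
#'
#' Regresses a per-window summary (acceptance percentage or Fisher-mean
#' correlation of one feature) on the window-reduction axis, where the
#' reference window sits at the origin and each unit corresponds to a
#' 10-second reduction: `x = (ref - window) / 10`. Ordinary least squares;
#' the intercept is the fitted value at the reference window.
#'
#' @param y Per-window values, in the order of `sizes_s`.
#' @param grid A [window_grid()] (or numeric vector of window sizes)
#'   matching `y`.
#' @param ref_window_s Window mapped to `x = 0` (default: largest size).
#' @return A `regression_summary` list: `slope` (per 10-s reduction),
#'   `intercept`, `r2` (`NA` when the response is constant).
#' @export
window_trend_regression <- function(y, grid = window_grid(),
                                    ref_window_s = NULL) {
  sizes <- if (inherits(grid, "window_grid")) grid$sizes_s else as.numeric(grid)
  stopifnot(length(y) == length(sizes))
  if (is.null(ref_window_s)) ref_window_s <- max(sizes)
  keep <- is.finite(y)
  if (sum(keep) < 3L) {
    stop("window_trend_regression: at least 3 defined values required",
         call. = FALSE)
  }
  x <- (ref_window_s - sizes[keep]) / 10
  yy <- y[keep]
  if (sd(yy) == 0) {
    out <- list(slope = 0, intercept = yy[1], r2 = NA_real_)
  } else {
    fit <- lm(yy ~ x)
    ssres <- sum(fit$residuals^2)
    sstot <- sum((yy - mean(yy))^2)
    out <- list(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r2 = 1 - ssres / sstot)
  }
  structure(out, class = "regression_summary")
}

#' Non-parametric Bland-Altman agreement
#'
#' Aligns the short-window vector to the reference instants, forms the
#' paired differences `short - ref`, and summarises them without normality
#' assumptions: the bias is the median difference and the limits of
#' agreement are the 2.5th and 97.5th percentiles
#' (linear-interpolation percentile definition), expected to contain about
#' 95 % of the differences.
#'
#' @inheritParams spearman_per_run
#' @return A `bland_altman_summary` list: `bias`, `loa_low`, `loa_high`,
#'   `frac_within`, `n` and the differences `d`.
#' @export
bland_altman <- function(short, ref, step_s = 1) {
  al <- align_to_reference(short, ref, step_s = step_s)
  d <- al$short - al$ref
  d <- d[is.finite(d)]
  if (length(d) < 10L) {
    stop("bland_altman: fewer than 10 defined pairs", call. = FALSE)
  }
  loa <- unname(quantile(d, c(0.025, 0.975), type = 7))
  structure(
    list(bias = median(d), loa_low = loa[1], loa_high = loa[2],
         frac_within = mean(d >= loa[1] & d <= loa[2]),
         n = length(d), d = d),
    class = "bland_altman_summary"
  )
}

#' @export
print.bland_altman_summary <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n %d: bias %.4g, LoA [%.4g, %.4g], %.1f%% within\n",
    x$n, x$bias, x$loa_low, x$loa_high, 100 * x$frac_within))
  invisible(x)
}
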