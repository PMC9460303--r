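# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# exhaustive two-sided rank-sum p: enumerate every allocation of the pooled
# ranks to the first sample and compare tail masses of the W statistic
wilcox_enum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  alloc <- utils::combn(length(pooled), m)
  w_all <- apply(alloc, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Spearman rho from first principles: mid-ranks by pairwise counting, then
# the explicit Pearson sum formula on the ranks
spearman_brute_rho <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# loop-based time-domain oracle
time_domain_brute <- function(rr) {
  n <- length(rr)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- rr[i + 1] - rr[i]
  nn50 <- 0
  for (di in d) if (abs(di) > 50) nn50 <- nn50 + 1
  mnn <- sum(rr) / n
  sdnn <- sqrt(sum((rr - mnn)^2) / (n - 1))
  sdsd <- sqrt(sum((d - sum(d) / (n - 1))^2) / (n - 2))
  rmssd <- sqrt(sum(d^2) / (n - 1))
  c(mNN = mnn, SDNN = sdnn, SDSD = sdsd, RMSSD = rmssd,
    NN50 = nn50, pNN50 = 100 * nn50 / (n - 1))
}

# closed-form normal-equations OLS oracle
ols_brute <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}
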