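# Independent brute-force oracles.

# per-voxel 6-SD comparison written as an explicit loop
brute_force_lge <- function(img, band, roi_values, k = 6) {
  mu <- mean(roi_values)
  s <- sqrt(sum((roi_values - mu)^2) / (length(roi_values) - 1))
  out <- array(FALSE, dim(img))
  for (i in seq_along(img)) {
    if (band[i] && img[i] > mu + k * s) out[i] <- TRUE
  }
  out
}

# exact two-sided signed-rank p by full enumeration of all 2^n sign patterns
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Pearson r from the definitional formula
pearson_r_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# ECV from the definitional relaxation-rate formula, written independently
ecv_oracle <- function(t1mn, t1mp, t1bn, t1bp, hct) {
  (1 - hct) * ((1 / t1mp - 1 / t1mn) / (1 / t1bp - 1 / t1bn))
}
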