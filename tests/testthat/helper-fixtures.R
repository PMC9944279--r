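# Shared fixtures, built in code at test time.

# Small clean shadowgraph scene: no noise, no gradient.
clean_scene <- function(shape = c(200, 200), pixel_scale = 0.05) {
  scene_params(image_shape = shape, pixel_scale = pixel_scale, unit = "mm",
               background = 0.85, blob_intensity = 0.25,
               background_gradient = 0, noise_sd = 0)
}

mm_config <- function(...) {
  imaging_config(pixel_scale = 0.05, unit = "mm", min_ecd = 0.4, ...)
}

# Independent rasterization oracle: count pixel centers inside a disc
# placed at (cx, cy) (pixel units) on an nr x nc grid.
raster_disc_count <- function(nr, nc, cx, cy, r) {
  centers_i <- rep(seq_len(nr) - 0.5, times = nc)
  centers_j <- rep(seq_len(nc) - 0.5, each = nr)
  sum((centers_i - cy)^2 + (centers_j - cx)^2 <= r^2)
}

# Independent OLS slope/intercept via the normal equations.
normal_equations_fit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of group
# assignments (feasible for n1 + n2 <= 10).
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  u_of <- function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, u_of)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}
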