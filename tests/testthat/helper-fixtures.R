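# Small shared fixtures, built once per test run. The coarse grid keeps the
# mask raster cheap; analyses that probe raster convergence build their own.

fix_grid <- visual_field_grid(extent_deg = 12, n_cells = 41L)
fix_apertures <- make_bar_masks(fix_grid, n_steps = 8L)
fix_hrf <- gam_hrf(tr_s = 2)

default_apertures <- make_bar_masks()   # 101 cells, 18 steps, 8 sweeps
default_hrf <- gam_hrf(tr_s = 2)

# brute-force bar mask, cell by cell: an independent re-derivation of the
# bar geometry used as the oracle for make_bar_masks
brute_bar_mask <- function(grid, u, centre_along_axis, bar_width) {
  m <- matrix(0L, grid$n_cells, grid$n_cells)
  for (i in seq_len(grid$n_cells)) {
    for (j in seq_len(grid$n_cells)) {
      p <- c(grid$x[i], grid$y[j])
      if (sqrt(sum(p^2)) <= grid$extent_deg / 2 &&
          abs(sum(p * u) - centre_along_axis) <= bar_width / 2)
        m[i, j] <- 1L
    }
  }
  m
}

# brute-force overlap of a Gaussian RF with one mask (independent of the
# separable fast path)
brute_overlap <- function(grid, mask, x0, y0, sigma) {
  G <- outer(grid$x, grid$y, function(x, y)
    exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2)))
  sum(mask * G) / sum(G)
}

# a two-voxel ground truth holding a perfect mirror pair: identical RF,
# opposite amplitude signs
mirror_pair_gt <- function(x = 1.5, y = -0.5, sigma = 1.2, amp = 1,
                           kappa = 1, noise_sd = 0) {
  gt <- sample_population(2, frac_negative = 0.5, kappa = kappa,
                          noise_sd = noise_sd, seed = 1)
  gt$truth$x_deg <- c(x, x); gt$truth$y_deg <- c(y, y)
  gt$truth$sigma_deg <- c(sigma, sigma)
  gt$truth$amplitude <- c(amp, -amp); gt$truth$sign <- c(1, -1)
  gt$prfs <- lapply(1:2, function(i)
    prf_model(x, y, sigma, amplitude = gt$truth$amplitude[i]))
  gt
}
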