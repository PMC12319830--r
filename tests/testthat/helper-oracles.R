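# Independent, deliberately naive re-implementations used as oracles for the
# vectorised production paths.

# exhaustive re-enumeration of all grid candidates through lm()
oracle_fit <- function(y, apertures, hrf, grid) {
  ext <- apertures$grid$extent_deg
  smax <- ext / 2
  xs <- seq(-ext / 2, ext / 2, length.out = grid$n_x)
  ys <- seq(-ext / 2, ext / 2, length.out = grid$n_y)
  sig <- seq_len(grid$n_sigma) / grid$n_sigma * smax
  best <- list(r2 = -Inf)
  idx <- 0L
  for (s in sig) for (yy in ys) for (xx in xs) {
    idx <- idx + 1L
    reg <- stats::convolve(rf_overlap_series(prf_model(xx, yy, s), apertures),
                           rev(hrf$values), type = "open")[seq_along(y)]
    if (stats::sd(reg) == 0) next
    fit <- stats::lm(y ~ reg)
    r2 <- summary(fit)$r.squared
    if (r2 > best$r2)
      best <- list(r2 = r2, x = xx, y = yy, sigma = s,
                   amplitude = unname(stats::coef(fit)[2]),
                   baseline = unname(stats::coef(fit)[1]), idx = idx)
  }
  best
}

# double-loop cross-RDM
naive_rdm <- function(pos, neg) {
  out <- matrix(NA_real_, ncol(pos), ncol(neg))
  for (i in seq_len(ncol(pos)))
    for (j in seq_len(ncol(neg)))
      out[i, j] <- 1 - cor(pos[, i], neg[, j])
  out
}

# double-loop best/worst pair selection
naive_pairs <- function(series, sign) {
  pos <- which(sign > 0); neg <- which(sign < 0)
  t(vapply(neg, function(j) {
    rs <- vapply(pos, function(i) cor(series[, j], series[, i]), numeric(1))
    c(matched = pos[which.min(rs)], unmatched = pos[which.max(rs)])
  }, c(matched = 0, unmatched = 0)))
}
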