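tiny_grid <- grid_spec(n_x = 5, n_y = 5, n_sigma = 3)

test_that("grid cardinality enumerates the advertised candidate space", {
  expect_equal(n_candidates(grid_spec("desk")), 40 * 40 * 20)
  expect_equal(n_candidates(tiny_grid), 75)
  expect_error(grid_spec(n_x = 0, n_y = 5, n_sigma = 3))
})

test_that("a noiseless grid-point voxel is recovered exactly", {
  smp <- opponentprf:::.grid_samples(tiny_grid, 12)
  truth <- prf_model(smp$x[4], smp$y[2], smp$sigma[2], amplitude = 1.2,
                     baseline = 0.5)
  y <- predict_timeseries(truth, fix_apertures, fix_hrf)
  co <- coef(fit_prf(y, fix_apertures, fix_hrf, tiny_grid))[1, ]
  expect_equal(unname(co["x_deg"]), smp$x[4])
  expect_equal(unname(co["y_deg"]), smp$y[2])
  expect_equal(unname(co["sigma_deg"]), smp$sigma[2])
  expect_equal(unname(co["r2"]), 1, tolerance = 1e-6)
  expect_gt(co["amplitude"], 0)

  # and the amplitude sign is identifiable
  neg <- prf_model(smp$x[4], smp$y[2], smp$sigma[2], amplitude = -0.8)
  co2 <- coef(fit_prf(predict_timeseries(neg, fix_apertures, fix_hrf),
                      fix_apertures, fix_hrf, tiny_grid))[1, ]
  expect_lt(co2["amplitude"], 0)
  expect_equal(unname(co2["r2"]), 1, tolerance = 1e-6)
})

test_that("vectorised fitter matches exhaustive lm enumeration on 20 voxels", {
  set.seed(21)
  gt <- sample_population(20, noise_sd = 0.4, seed = 77)
  Y <- simulate_mapping_run(gt, fix_apertures, fix_hrf, seed = 78)
  fit <- fit_prf(Y, fix_apertures, fix_hrf, tiny_grid)
  for (v in 1:20) {
    o <- oracle_fit(Y[, v], fix_apertures, fix_hrf, tiny_grid)
    expect_equal(fit$par$cand_index[v], o$idx)
    expect_equal(fit$par$x_deg[v], o$x)
    expect_equal(fit$par$y_deg[v], o$y)
    expect_equal(fit$par$sigma_deg[v], o$sigma)
    expect_equal(fit$par$r2[v], o$r2, tolerance = 1e-10)
    expect_equal(fit$par$amplitude[v], o$amplitude, tolerance = 1e-8)
    expect_equal(fit$par$baseline[v], o$baseline, tolerance = 1e-8)
  }
})

test_that("selected candidate beats randomly sampled rivals", {
  set.seed(5)
  gt <- sample_population(3, noise_sd = 0.3, seed = 9)
  Y <- simulate_mapping_run(gt, fix_apertures, fix_hrf, seed = 10)
  grid <- grid_spec(n_x = 9, n_y = 9, n_sigma = 4)
  fit <- fit_prf(Y, fix_apertures, fix_hrf, grid)
  smp <- opponentprf:::.grid_samples(grid, 12)
  for (v in 1:3) {
    y <- Y[, v]
    for (i in 1:100) {
      cx <- sample(smp$x, 1); cy <- sample(smp$y, 1); cs <- sample(smp$sigma, 1)
      reg <- predict_timeseries(prf_model(cx, cy, cs, amplitude = 1),
                                fix_apertures, fix_hrf)
      r2 <- stats::cor(y, reg)^2
      expect_lte(r2, fit$par$r2[v] + 1e-12)
    }
  }
})

test_that("constant voxels are flagged invalid rather than fitted", {
  Y <- cbind(rep(3, n_trs(fix_apertures)),
             predict_timeseries(prf_model(1, 1, 1), fix_apertures, fix_hrf))
  fit <- fit_prf(Y, fix_apertures, fix_hrf, tiny_grid)
  expect_false(fit$par$valid[1])
  expect_true(is.na(fit$par$r2[1]))
  expect_true(fit$par$valid[2])
})

test_that("noisy recovery keeps the median centre error within a grid step", {
  gt <- sample_population(50, noise_sd = 0.25, seed = 31)
  Y <- simulate_mapping_run(gt, default_apertures, default_hrf, seed = 32)
  fit <- fit_prf(Y, default_apertures, default_hrf, grid_spec("desk"))
  step <- 12 / (40 - 1)
  expect_lte(median(abs(fit$par$x_deg - gt$truth$x_deg)), step)
  expect_lte(median(abs(fit$par$y_deg - gt$truth$y_deg)), step)
  expect_gte(mean(sign(fit$par$amplitude) == gt$truth$sign), 0.95)
})

test_that("suprathreshold filtering applies both exclusions strictly", {
  pop <- data.frame(voxel = c("a", "b", "c"), sigma_deg = c(1, 1, 1),
                    amplitude = c(1, -1, 1), r2 = c(0.05, 0.08, 0.20))
  kept <- filter_suprathreshold(pop, sigma_max_deg = 6)
  expect_equal(kept$voxel, "c")                   # R^2 must exceed 0.08

  big <- data.frame(voxel = "d", sigma_deg = 0.96 * 6, amplitude = 1, r2 = 0.9)
  expect_warning(out <- filter_suprathreshold(big, sigma_max_deg = 6),
                 "no pRFs survive")
  expect_equal(nrow(out), 0)
  # boundary: sigma at exactly 0.95 of max survives
  edge <- data.frame(voxel = "e", sigma_deg = 0.95 * 6, amplitude = 1, r2 = 0.9)
  expect_equal(nrow(filter_suprathreshold(edge, sigma_max_deg = 6)), 1)

  empty <- pop[0, ]
  expect_warning(out <- filter_suprathreshold(empty, sigma_max_deg = 6))
  expect_equal(nrow(out), 0)
})

test_that("percent_negative is the negative share of the population", {
  pop <- data.frame(amplitude = c(rep(1, 175), rep(-1, 125)))
  expect_equal(percent_negative(pop), 100 * 125 / 300)
  expect_equal(round(percent_negative(pop), 2), 41.67)
  expect_equal(percent_negative(data.frame(amplitude = c(1, 2))), 0)
  expect_equal(percent_negative(data.frame(amplitude = c(-1, -2))), 100)
  expect_error(percent_negative(data.frame(amplitude = numeric(0))), "empty")
  # an exactly-zero amplitude belongs to neither class
  expect_equal(amplitude_class(data.frame(amplitude = c(1, 0, -1))),
               c("positive", NA, "negative"))
})

test_that("prf_fit methods are mutually consistent", {
  gt <- sample_population(4, noise_sd = 0.2, seed = 55)
  Y <- simulate_mapping_run(gt, fix_apertures, fix_hrf, seed = 56)
  fit <- fit_prf(Y, fix_apertures, fix_hrf, grid_spec(n_x = 9, n_y = 9,
                                                      n_sigma = 4))
  expect_equal(dim(coef(fit)), c(4, 6))
  expect_equal(fitted(fit) + residuals(fit), unname(Y),
               ignore_attr = TRUE)
  s <- summary(fit)
  expect_equal(s$n_voxels, 4)
  expect_output(print(fit), "pRF grid fit")
  # R^2 of the selected model matches 1 - SSres/SStot of its prediction
  v <- 1
  r2_direct <- 1 - sum(residuals(fit)[, v]^2) / sum((Y[, v] - mean(Y[, v]))^2)
  expect_equal(fit$par$r2[v], r2_direct, tolerance = 1e-10)
})
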