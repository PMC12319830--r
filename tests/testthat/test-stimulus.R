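test_that("default mapping design has the canonical geometry and timing", {
  ap <- default_apertures
  expect_equal(dim(ap$masks)[3], 8 * 18)
  expect_equal(ap$n_steps * ap$tr_s, 36)                  # one sweep
  expect_equal(dim(ap$masks)[3] * ap$tr_s, 8 * 18 * 2)    # run duration
  expect_true(all(ap$masks %in% c(0L, 1L)))

  # every cell beyond the aperture radius is dark at every TR
  ecc <- sqrt(outer(ap$grid$x^2, ap$grid$y^2, "+"))
  outside <- which(ecc > ap$grid$extent_deg / 2)
  flat <- matrix(ap$masks, nrow = ap$grid$n_cells^2)
  expect_true(all(flat[outside, ] == 0))
  # and the bar does light up cells inside
  expect_gt(sum(flat), 0)
})

test_that("opposite sweeps relate by step reversal and x-mirror (oracle)", {
  grid <- visual_field_grid(n_cells = 21)
  n_steps <- 6
  ap <- make_bar_masks(grid, n_steps = n_steps, bar_width_deg = 2,
                       sweep_order = c("left_to_right", "right_to_left"))
  steps <- seq(-6, 6, length.out = n_steps)

  for (k in seq_len(n_steps)) {
    # independent cell-by-cell oracle for both directions
    l2r <- brute_bar_mask(grid, c(1, 0), steps[k], 2)
    r2l <- brute_bar_mask(grid, c(-1, 0), steps[k], 2)
    expect_identical(ap$masks[, , k], l2r)
    expect_identical(ap$masks[, , n_steps + k], r2l)
    # the right-to-left sweep retraces the left-to-right positions in
    # reverse order...
    expect_identical(ap$masks[, , n_steps + (n_steps + 1 - k)], l2r)
    # ...and mirroring a right-to-left mask in x reproduces the
    # left-to-right mask at the same step
    expect_identical(ap$masks[rev(seq_len(21)), , n_steps + k], l2r)
  }
})

test_that("diagonal sweeps keep the bar perpendicular to its motion", {
  grid <- visual_field_grid(n_cells = 21)
  ap <- make_bar_masks(grid, n_steps = 5, bar_width_deg = 2,
                       sweep_order = "bottom_left_to_top_right")
  u <- c(1, 1) / sqrt(2)
  steps <- seq(-6, 6, length.out = 5)
  for (k in 1:5)
    expect_identical(ap$masks[, , k], brute_bar_mask(grid, u, steps[k], 2))
})

test_that("invalid mask parameters are rejected with guidance", {
  expect_error(make_bar_masks(fix_grid, sweep_order = "sideways"),
               "unknown sweep direction")
  expect_error(make_bar_masks(fix_grid, bar_width_deg = 15), "exceeds")
})

test_that("masks stay binary and aperture-clipped across random configs", {
  set.seed(11)
  for (i in 1:10) {
    grid <- visual_field_grid(extent_deg = runif(1, 6, 20),
                              n_cells = sample(15:41, 1))
    n_steps <- sample(4:12, 1)
    ord <- sample(default_sweep_order(), sample(2:8, 1))
    ap <- make_bar_masks(grid, n_steps = n_steps, tr_s = runif(1, 1, 3),
                         bar_width_deg = runif(1, 0.5, grid$extent_deg / 3),
                         sweep_order = ord)
    expect_equal(dim(ap$masks)[3], length(ord) * n_steps)
    expect_true(all(ap$masks %in% c(0L, 1L)))
    ecc <- sqrt(outer(grid$x^2, grid$y^2, "+"))
    flat <- matrix(ap$masks, nrow = grid$n_cells^2)
    expect_true(all(flat[ecc > grid$extent_deg / 2, ] == 0))
  }
})

test_that("recall design delivers the full factorial schedule", {
  des <- make_recall_design(seed = 42)
  expect_length(des, 6)
  labels <- unlist(lapply(des, `[[`, "label"))
  expect_length(labels, 144)                          # 24 x 6
  expect_equal(sort(unique(labels)), sprintf("item_%02d", 1:12))
  expect_true(all(table(labels) == 12))               # 2 per run x 6 runs
  for (run in des) {
    expect_equal(nrow(run), 24)
    expect_true(all(table(run$label) == 2))
    expect_true(all(run$duration_s == 10))            # 0.5 s cue + 9.5 s recall
    expect_true(all(diff(run$onset_s) > 0))
  }
  expect_identical(make_recall_design(seed = 42), des)
  expect_false(identical(make_recall_design(seed = 43)[[1]]$label,
                         des[[1]]$label))
  expect_error(make_recall_design(n_items = 0, seed = 1), "positive")
})

test_that("perception design presents each stimulus once per run", {
  des <- make_perception_design(seed = 7)
  expect_length(des, 2)
  for (run in des) {
    expect_equal(nrow(run), 96)
    expect_false(anyDuplicated(run$label) > 0)
    gaps <- diff(run$onset_s) - run$duration_s[-nrow(run)]
    expect_true(all(gaps >= 3 - 1e-9 & gaps <= 7 + 1e-9))
  }
  # reseeding permutes order but never the label multiset
  des2 <- make_perception_design(seed = 8)
  expect_setequal(des2[[1]]$label, des[[1]]$label)
  expect_false(identical(des2[[1]]$label, des[[1]]$label))
})

test_that("event designs are valid under timing constraints for many seeds", {
  ok <- vapply(1:1000, function(seed) {
    r <- make_recall_design(n_runs = 1, seed = seed)[[1]]
    gaps <- c(r$onset_s[1], diff(r$onset_s) - r$duration_s[-nrow(r)])
    all(diff(r$onset_s) > 0) &&
      all(gaps >= 2.5 - 1e-9 & gaps <= 7 + 1e-9) &&
      r$onset_s[nrow(r)] + 10 <= attr(r, "total_duration_s")
  }, logical(1))
  expect_true(all(ok), info = paste("first bad seed:", which(!ok)[1]))
})
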