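test_that("mirror populations are matched at r = -1 on the mapping series", {
  # each negative voxel has an exact sign-flipped twin, plus decoy positives
  set.seed(91)
  prfs <- list(c(2, 1, 1), c(-3, 0, 1.5), c(0, -2, 0.8))
  mk <- function(p, a) predict_timeseries(
    prf_model(p[1], p[2], p[3], amplitude = a), fix_apertures, fix_hrf)
  series <- cbind(sapply(prfs, mk, a = 1), sapply(prfs, mk, a = -1),
                  mk(c(4, 4, 2), 1))
  sign <- c(1, 1, 1, -1, -1, -1, 1)
  pr <- select_pairs(series, sign)
  expect_equal(pr$matched, 1:3)           # each twin found
  expect_equal(pr$r_matched, rep(-1, 3), tolerance = 1e-10)
  expect_true(all(pr$r_unmatched > pr$r_matched))
})

test_that("a single positive voxel forces matched = unmatched", {
  set.seed(92)
  series <- matrix(rnorm(30 * 4), 30)
  pr <- select_pairs(series, c(1, -1, -1, -1))
  expect_equal(pr$matched, pr$unmatched)
  expect_error(select_pairs(series, c(-1, -1, -1, -1)), "no positive")
})

test_that("pair selection matches the brute-force double loop", {
  set.seed(93)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    series <- matrix(rnorm(40 * n), 40)
    sign <- sample(c(-1, 1), n, replace = TRUE)
    if (sum(sign > 0) == 0 || sum(sign < 0) == 0) next
    pr <- select_pairs(series, sign)
    np <- naive_pairs(series, sign)
    expect_equal(pr$matched, unname(np[, "matched"]))
    expect_equal(pr$unmatched, unname(np[, "unmatched"]))
  }
})

test_that("matching analysis reproduces the idealised opponent ordering", {
  gt <- mirror_pair_gt(kappa = 1, noise_sd = 0)
  # extend to two mirror pairs and a decoy positive
  des <- make_recall_design(n_runs = 2, seed = 95)
  maps <- make_field_maps(unique(des[[1]]$label), fix_grid, seed = 96)
  ap <- fix_apertures
  mapping <- simulate_mapping_run(gt, ap, fix_hrf, seed = 97)
  ser <- simulate_task_session(gt, des, maps, fix_grid, fix_hrf, seed = 98)
  pr <- select_pairs(mapping, gt$truth$sign)
  ma <- matching_analysis(pr, do.call(rbind, ser), n_iter = 50, seed = 99)
  expect_equal(unname(ma$mean_r["matched"]), -1, tolerance = 1e-10)
  expect_gte(ma$mean_r["unmatched"], ma$mean_r["matched"])
})

test_that("the random scheme is seeded, convergent and never self-pairs", {
  set.seed(101)
  series <- matrix(rnorm(200 * 100), 200)
  sign <- rep(c(1, -1), 50)
  pr <- select_pairs(series, sign)
  a <- matching_analysis(pr, series, n_iter = 1000, seed = 7)
  b <- matching_analysis(pr, series, n_iter = 1000, seed = 7)
  expect_identical(a$mean_r, b$mean_r)

  rnd <- vapply(1:10, function(s)
    matching_analysis(pr, series, n_iter = 1000, seed = s)$mean_r["random"],
    numeric(1))
  expect_lt(sd(rnd), 0.01)

  # self-pairing audit: with one negative voxel and one partner candidate,
  # every random draw is forced to that partner; any self-pairing would
  # surface as a correlation of exactly 1
  two <- matrix(rnorm(60), 30)
  pr2 <- select_pairs(two, c(1, -1))
  m2 <- matching_analysis(pr2, two, n_iter = 500, seed = 11)
  expect_true(all(m2$random_iters == cor(two[, 1], two[, 2])))
})

test_that("bootstrap re-indexing equals naive RDM reconstruction", {
  set.seed(103)
  n <- 12
  mapping <- matrix(rnorm(50 * n), 50)
  task <- matrix(rnorm(40 * n), 40)
  sign <- rep(c(1, -1), each = 6)
  bn <- bootstrap_null(mapping, task, sign, n_iter = 25, seed = 5)

  # naive path: shuffle with the same RNG stream, rebuild RDMs explicitly
  obs <- correlate_rdms(build_cross_rdm(mapping[, sign > 0], mapping[, sign < 0]),
                        build_cross_rdm(task[, sign > 0], task[, sign < 0]))
  expect_equal(bn$observed_z, obs$z)
  set.seed(5)
  naive <- vapply(1:25, function(i) {
    s <- sample(sign)
    correlate_rdms(build_cross_rdm(mapping[, s > 0], mapping[, s < 0]),
                   build_cross_rdm(task[, s > 0], task[, s < 0]))$z
  }, numeric(1))
  expect_equal(bn$null_z, naive)
  expect_error(bootstrap_null(mapping, task, rep(c(1, -1, 1, 1), 3),
                              n_iter = 5, seed = 1), NA)
  expect_error(bootstrap_null(mapping, task, c(rep(1, 11), -1), n_iter = 5,
                              seed = 1), "at least 2")
})

test_that("the null is centred on zero for structureless data", {
  # per-dataset null means scatter around zero: test the grand mean over
  # independent structureless datasets against its own standard error
  set.seed(104)
  means <- vapply(1:12, function(i) {
    mapping <- matrix(rnorm(60 * 20), 60)
    task <- matrix(rnorm(80 * 20), 80)
    bn <- bootstrap_null(mapping, task, rep(c(1, -1), 10), n_iter = 100,
                         seed = i)
    stopifnot(all(is.finite(bn$null_z)))
    mean(bn$null_z)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 2 * se)
})
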