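test_that("alpha parameter matches direct evaluation and handles degeneracy", {
  expect_equal(alpha_parameter(c(1, exp(1))), 3.0, tolerance = 1e-12)
  expect_true(is.na(suppressMessages(alpha_parameter(c(5, 5, 5)))))
  expect_true(is.na(alpha_parameter(numeric())))
  expect_true(is.na(alpha_parameter(c(3))))
})

test_that("alpha MLE is consistent on power-law draws", {
  set.seed(21)
  x <- rpowerlaw(1e4, alpha = 1.8, xmin = 10)
  expect_lt(abs(alpha_parameter(x) - 1.8), 0.02)
})

test_that("S2 is the lognormal ML shape, scale-invariant, zero for equal lengths", {
  x <- c(2, 2, 2)
  expect_equal(bout_length_variability(x), 0)
  set.seed(22)
  y <- rlnorm(200, 3, 0.4)
  expect_equal(bout_length_variability(3.7 * y), bout_length_variability(y),
               tolerance = 1e-12)
  # brute-force oracle: population SD of the logs
  ly <- log(y)
  expect_equal(bout_length_variability(y),
               sqrt(sum((ly - mean(ly))^2) / length(ly)), tolerance = 1e-12)
  expect_true(is.na(bout_length_variability(c(4))))
})

test_that("S2 recovers the generating lognormal shape", {
  set.seed(23)
  x <- rlnorm(1e4, meanlog = 4, sdlog = 0.5)
  expect_lt(abs(bout_length_variability(x) - 0.5), 0.01)
})

test_that("vector magnitude is the per-sample Euclidean norm", {
  fs <- 100
  rec <- accel_recording((1:3) / fs, c(3, 0, 0.3), c(4, 0, -0.4),
                         c(0, -1, 1.2), fs)
  vm <- vector_magnitude(rec)
  expect_equal(vm[1], 5)
  expect_equal(vm[2], 1)
  expect_length(vm, 3)
  expect_equal(vector_magnitude(rec, units = "ms2"), vm * 9.80665)
})

test_that("vector magnitude is invariant to 3-D rotations", {
  set.seed(24)
  fs <- 100
  n <- 500
  acc <- matrix(rnorm(3 * n), n, 3)
  rec <- accel_recording((1:n) / fs, acc[, 1], acc[, 2], acc[, 3], fs)
  vm0 <- vector_magnitude(rec)
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rot <- acc %*% q
    reci <- accel_recording((1:n) / fs, rot[, 1], rot[, 2], rot[, 3], fs)
    expect_equal(vector_magnitude(reci), vm0, tolerance = 1e-9)
  }
})

test_that("volume and pattern scalars follow the stated thresholds", {
  bouts <- tibble::tibble(
    bout_id = c(1L, 2L, 3L, NA, NA),
    kind = c("walking", "walking", "walking", "non_walking", "non_walking"),
    start_s = c(0, 100, 800, 65, 1000),
    end_s = c(65, 701, 920, 100, 2300),
    length_s = c(65, 601, 120, 35, 1300))
  steps <- tibble::tibble(bout_id = rep(1:3, c(10, 20, 12)),
                          valid = TRUE)
  rec <- accel_recording((1:10) / 100, rep(-1, 10), rep(0, 10), rep(0, 10),
                         100)
  mac <- macro_features(bouts, steps, rec, 0, 2300)
  expect_equal(unname(mac$single["walking_volume__n_walking_bouts"]), 3)
  expect_equal(unname(mac$single["walking_volume__n_bouts_ge_10min"]), 1)
  expect_equal(unname(mac$single["nonwalking_volume__n_nonwalk_ge_20min"]), 1)
  expect_equal(unname(mac$single["nonwalking_volume__n_nonwalk_ge_30min"]), 0)
  expect_equal(unname(mac$single["pattern__mean_walking_time_s"]),
               mean(c(65, 601, 120)))
  # non-increasing long-gap counts
  cnt <- mac$single[c("nonwalking_volume__n_nonwalk_ge_20min",
                      "nonwalking_volume__n_nonwalk_ge_30min",
                      "nonwalking_volume__n_nonwalk_ge_50min")]
  expect_true(all(diff(unname(cnt)) <= 0))
  # bout-length series exclude the mean statistic when pooled
  st <- pool_statistics(mac$series$walking_volume__bout_length_s,
                        excl_mean = TRUE)
  expect_false("mean" %in% names(st))
})

test_that("no long gaps means zero long-gap counts", {
  bouts <- tibble::tibble(bout_id = 1L, kind = c("walking", "non_walking"),
                          start_s = c(0, 60), end_s = c(60, 200),
                          length_s = c(60, 140))
  rec <- accel_recording((1:10) / 100, rep(-1, 10), rep(0, 10), rep(0, 10),
                         100)
  mac <- macro_features(bouts, tibble::tibble(bout_id = integer(),
                                              valid = logical()),
                        rec, 0, 200)
  expect_equal(unname(mac$single[c("nonwalking_volume__n_nonwalk_ge_20min",
                                   "nonwalking_volume__n_nonwalk_ge_30min",
                                   "nonwalking_volume__n_nonwalk_ge_50min")]),
               c(0, 0, 0))
})

test_that("alpha and S2 recover generator parameters from simulated timelines", {
  # signal-free cohorts give plenty of true bout lengths quickly
  cfg <- sim_config(n_subjects = 40, days = 5, bout_length_max = 1e6,
                    nonwalk_lognorm_mu = log(120), seed = 31)
  co <- simulate_cohort(cfg, signal = FALSE)
  drawn <- co$truth$bouts$drawn_length_s
  # drop lengths clipped below xmin by the day end; the rest are power-law
  drawn <- drawn[drawn >= 10]
  expect_gt(length(drawn), 5e3)
  expect_lt(abs(alpha_parameter(drawn) - 1.8), 0.05)
})
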