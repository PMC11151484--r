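test_that("configuration invariants are enforced", {
  expect_error(sim_config(bout_length_alpha = 1), "alpha")
  expect_error(sim_config(flip_probability = 1.5))
  expect_error(sim_config(cadence_sd = -1))
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 1, days = 1, day_hours = 1, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$recordings[[1]]$vv, b$recordings[[1]]$vv)
  expect_identical(a$pro, b$pro)
  expect_identical(a$truth$bouts$start_s, b$truth$bouts$start_s)
})

test_that("zero jitter and fixed cadence give exactly regular contacts", {
  cfg <- sim_config(n_subjects = 1, days = 1, day_hours = 1,
                    cadence_hz = 2, cadence_sd = 0, step_jitter_sd = 0,
                    seed = 5)
  co <- simulate_cohort(cfg, signal = FALSE)
  ivl <- unlist(lapply(co$truth$bouts$ic_times, diff))
  expect_true(all(abs(ivl - 0.5) < 1e-9))
})

test_that("injected step count matches bout length times cadence", {
  cfg <- sim_config(n_subjects = 2, days = 1, seed = 6)
  co <- simulate_cohort(cfg, signal = FALSE)
  tb <- dplyr::left_join(co$truth$bouts,
                         co$truth$subjects[, c("subject_id", "cadence")],
                         by = "subject_id")
  n_steps <- vapply(tb$step_durs, length, integer(1))
  expected <- round(tb$drawn_length_s * tb$cadence)
  expect_true(all(abs(n_steps - pmax(expected, 4)) <= 1))
})

test_that("walking, rest and missing time partition each recording", {
  co <- messy_cohort()
  cfg_day_s <- 6 * 3600
  for (sid in names(co$recordings)) {
    rec <- co$recordings[[sid]]
    expect_equal(nrow(rec), 2 * cfg_day_s * 100) # 2 days on the full grid
    # missing fraction is near the configured 3%
    expect_lt(abs(mean(is.na(rec$vv)) - 0.03), 0.005)
  }
})

test_that("score scale and diary bins are respected", {
  co <- messy_cohort()
  sc <- c(co$pro$pf_score, co$pro$mf_score)
  sc <- sc[!is.na(sc)]
  expect_true(all(sc %in% 0:6))
  expect_true(all(co$pro$bin %in% c("morning", "early_afternoon",
                                    "late_afternoon", "evening")))
  # completion times sit inside their bins
  hr <- (co$pro$timestamp %% 86400) / 3600
  expect_true(all((co$pro$bin != "morning") | (hr >= 9 & hr < 12)))
  expect_true(all((co$pro$bin != "evening") | (hr >= 21)))
})

test_that("null coupling leaves scores independent of the gait feature", {
  # scores and features share subject-level structure (each subject has one
  # cadence and one latent intercept), so independence holds conditionally
  # on subject: a within-subject permutation test on subject-centred values
  # should find the observed correlation unexceptional
  cfg <- sim_config(n_subjects = 30, days = 4, coupling_beta = 0, seed = 77)
  co <- simulate_cohort(cfg, signal = FALSE)
  d <- dplyr::inner_join(co$pro, co$truth$pro_latent,
                         by = c("subject_id", "timestamp"))
  d <- d[!is.na(d$pf_score) & d$feature_z != 0, ]
  d <- d %>%
    dplyr::group_by(subject_id) %>%
    dplyr::mutate(sc = pf_score - mean(pf_score),
                  fz = feature_z - mean(feature_z)) %>%
    dplyr::ungroup()
  obs <- abs(cor(d$sc, d$fz))
  set.seed(1)
  null <- replicate(400, {
    perm <- d %>%
      dplyr::group_by(subject_id) %>%
      dplyr::mutate(sc = sample(sc)) %>%
      dplyr::ungroup()
    abs(cor(perm$sc, perm$fz))
  })
  expect_gt(mean(null >= obs), 0.05)
})

test_that("positive coupling induces the expected association direction", {
  cfg <- sim_config(n_subjects = 30, days = 4, coupling_beta = 1, seed = 78)
  co <- simulate_cohort(cfg, signal = FALSE)
  d <- dplyr::inner_join(co$pro, co$truth$pro_latent,
                         by = c("subject_id", "timestamp"))
  d <- d[!is.na(d$pf_score), ]
  expect_gt(cor(d$pf_score, d$feature_z), 0.1)
})

test_that("feature-window generator couples only the informative feature", {
  d <- simulate_feature_windows(40, 12, n_features = 3, coupling_beta = 1.5,
                                informative = 2, seed = 9)
  expect_equal(nrow(d), 480)
  c2 <- cor(d$pf_score, d$f2)
  c1 <- cor(d$pf_score, d$f1)
  expect_gt(c2, 0.3)
  expect_lt(abs(c1), 0.15)
  # mf is generated without coupling
  expect_lt(abs(cor(d$mf_score, d$f2)), 0.15)
})

test_that("cohorts round-trip through the CSV/JSON interchange", {
  skip_if_not_installed("jsonlite")
  cfg <- sim_config(n_subjects = 1, days = 1, day_hours = 1,
                    missing_frac = 0, seed = 12)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  rec <- load_recording(file.path(dir, "S01_acc.csv"), sampling_rate = 100,
                        subject_id = "S01")
  expect_equal(rec$vv, co$recordings[[1]]$vv, tolerance = 1e-6)
  pro <- load_pro_table(file.path(dir, "pro.csv"))
  expect_equal(pro$pf_score, co$pro$pf_score)
  truth <- jsonlite::read_json(file.path(dir, "S01_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$bouts), nrow(co$truth$bouts))
})
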