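mk_flags <- function(active, valid = rep(TRUE, length(active))) {
  tibble::tibble(window = seq_along(active) - 1L,
                 start_s = (seq_along(active) - 1) * 0.1,
                 sd_sum = NA_real_, vv_mean = NA_real_,
                 valid = valid, active = active & valid)
}

test_that("window activity thresholds implement the upright-and-moving rule", {
  fs <- 100
  set.seed(1)
  n <- 400
  # upright & moving / still / supine-but-moving
  vv <- c(-0.9 + 0.1 * sin(2 * pi * 2 * seq_len(n) / fs),
          rep(-1, n),
          0.02 + 0.2 * sin(2 * pi * 2 * seq_len(n) / fs))
  ml <- c(0.08 * sin(2 * pi * 2 * seq_len(n) / fs), rep(0, n),
          0.2 * cos(2 * pi * 2 * seq_len(n) / fs))
  ap <- rep(0, 3 * n)
  rec <- accel_recording(seq_len(3 * n) / fs, vv, ml, ap, fs)
  fl <- flag_active_windows(rec)
  third <- nrow(fl) / 3
  # compare away from segment boundaries: zero-phase filtering spreads a
  # short transient across each junction
  expect_true(mean(fl$active[seq_len(third - 4) + 2]) > 0.5) # walking-like
  expect_false(any(fl$active[third + 2 + seq_len(third - 4)]))     # still
  expect_false(any(fl$active[2 * third + 2 + seq_len(third - 4)])) # supine
})

test_that("thresholds are applied at the documented boundaries", {
  # constructed windows: SD sum just at/below 0.05, mean VV at/above -0.77
  fs <- 100
  fl <- mk_flags(rep(TRUE, 5))
  fl$sd_sum <- c(0.06, 0.05, 0.049, 0.06, 0.06)
  fl$vv_mean <- c(-0.9, -0.77, -0.9, -0.769, -0.78)
  act <- fl$valid & fl$sd_sum >= 0.05 & fl$vv_mean <= -0.77
  expect_equal(act, c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("run merging and short-bout exclusion follow the 20-window rules", {
  # runs [0,30) and [40,70): 10-window gap merges into one bout
  act <- rep(FALSE, 100)
  act[1:30] <- TRUE
  act[41:70] <- TRUE
  b <- assemble_bouts(mk_flags(act))
  wb <- b[b$kind == "walking", ]
  expect_equal(nrow(wb), 1)
  expect_equal(wb$start_window, 0L)
  expect_equal(wb$end_window, 70L)
  expect_equal(wb$length_s, 7, tolerance = 1e-9)

  # isolated 19-window run: excluded; 20-window run: retained
  act <- rep(FALSE, 100)
  act[11:29] <- TRUE
  expect_equal(nrow(assemble_bouts(mk_flags(act)) |>
                      dplyr::filter(kind == "walking")), 0)
  act[11:30] <- TRUE
  expect_equal(nrow(assemble_bouts(mk_flags(act)) |>
                      dplyr::filter(kind == "walking")), 1)

  # a gap of exactly 20 windows is NOT merged
  act <- rep(FALSE, 120)
  act[1:30] <- TRUE
  act[51:90] <- TRUE
  wb <- assemble_bouts(mk_flags(act)) |> dplyr::filter(kind == "walking")
  expect_equal(nrow(wb), 2)
})

test_that("chained short gaps merge to the fixpoint", {
  # seven 10-window runs separated by 15-window gaps: every gap merges and
  # the merged 185-window run is retained
  act <- rep(FALSE, 200)
  for (s in seq(1, 176, by = 25)) act[s:(s + 9)] <- TRUE
  wb <- assemble_bouts(mk_flags(act)) |> dplyr::filter(kind == "walking")
  expect_equal(nrow(wb), 1)
  expect_equal(wb$start_window, 0L)
  expect_equal(wb$end_window, 185L)
})

test_that("gaps over missing data are never merged and windows there are inactive", {
  act <- rep(FALSE, 100)
  act[1:30] <- TRUE
  act[41:70] <- TRUE
  valid <- rep(TRUE, 100)
  valid[35] <- FALSE # missing data inside the 10-window gap
  wb <- assemble_bouts(mk_flags(act, valid)) |> dplyr::filter(kind == "walking")
  expect_equal(nrow(wb), 2)
})

test_that("walking and non-walking bouts partition the valid windows", {
  co <- recovery_cohort()
  proc <- recovery_processed()[[1]]
  b <- proc$bouts
  fl <- flag_active_windows(proc$rec)
  covered <- sum(b$end_window - b$start_window)
  expect_equal(covered, sum(fl$valid))
  # no overlaps
  b <- dplyr::arrange(b, start_window)
  expect_true(all(diff(b$start_window) >= 0))
  expect_true(all(utils::head(b$end_window, -1) <= utils::tail(b$start_window, -1) |
                    diff(b$start_window) == 0))
})

test_that("detected bout count and boundaries match ground truth on clean data", {
  co <- recovery_cohort()
  procs <- recovery_processed()
  for (sid in names(procs)) {
    tb <- co$truth$bouts[co$truth$bouts$subject_id == sid, ]
    wb <- procs[[sid]]$bouts |> dplyr::filter(kind == "walking")
    expect_equal(nrow(wb), nrow(tb))
    err <- abs(wb$start_s - tb$start_s)
    err_end <- abs(wb$end_s - tb$end_s)
    expect_lt(max(c(err, err_end)), 0.3)
  }
})

test_that("bout selection before a diary entry is start-based over a 2-h window", {
  bouts <- tibble::tibble(
    kind = "walking",
    start_s = c(3660, 3540, 7260, 10700),
    end_s = c(3720, 3600, 7320, 11400),
    length_s = c(60, 60, 60, 700))
  ts <- 10800 # diary at 3 h
  sel <- bouts_before_pro(bouts, ts)
  # started 1h59 before: in; started 2h01 before: out (never began in window)
  expect_true(3660 %in% sel$start_s)
  expect_false(3540 %in% sel$start_s)
  # bout starting 100 s before the entry but ending after it: included whole
  expect_true(10700 %in% sel$start_s)
  expect_equal(sel$end_s[sel$start_s == 10700], 11400)
  # boundary: a bout starting exactly 2 h before is included
  expect_true(7260 %in% bouts_before_pro(bouts, 7260 + 7200)$start_s)
})

test_that("activity flags are invariant to a constant shift except via the mean test", {
  fx <- simple_walk_recording(n_steps = 20)
  rec <- fx$rec
  shifted <- accel_recording(rec$t, rec$vv - 0.1, rec$ml - 0.1, rec$ap - 0.1,
                             sampling_rate = 100)
  f1 <- flag_active_windows(rec)
  f2 <- flag_active_windows(shifted)
  # interior windows only: the filter's edge transient depends on absolute
  # signal values
  mid <- 6:(nrow(f1) - 5)
  expect_equal(f1$sd_sum[mid], f2$sd_sum[mid], tolerance = 1e-8)
  expect_equal(f2$vv_mean[mid], f1$vv_mean[mid] - 0.1, tolerance = 1e-6)
})

test_that("a recording shorter than one window yields no windows", {
  rec <- accel_recording(t = (1:5) / 100, vv = rep(-1, 5), ml = rep(0, 5),
                         ap = rep(0, 5), sampling_rate = 100)
  expect_equal(nrow(flag_active_windows(rec)), 0)
})
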