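# Shared fixtures, built in code and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noise-light cohort for detector-recovery checks: 5 subjects x 1 day,
# no missing data, no sensor flips
recovery_cohort <- function() {
  cached("recovery_cohort", {
    cfg <- sim_config(n_subjects = 5, days = 1, missing_frac = 0,
                      flip_probability = 0, seed = 101)
    simulate_cohort(cfg)
  })
}

# per-subject pipeline results for the recovery cohort
recovery_processed <- function() {
  cached("recovery_processed", {
    co <- recovery_cohort()
    hs <- setNames(co$truth$subjects$height, co$truth$subjects$subject_id)
    lapply(names(co$recordings), function(sid) {
      suppressMessages(process_recording(co$recordings[[sid]], hs[[sid]]))
    }) |> setNames(names(co$recordings))
  })
}

# small, messier cohort (flips + missing data) for io/windowing checks
messy_cohort <- function() {
  cached("messy_cohort", {
    cfg <- sim_config(n_subjects = 2, days = 2, day_hours = 6,
                      flip_probability = 0.5, missing_frac = 0.03,
                      seed = 202)
    simulate_cohort(cfg)
  })
}

# a hand-built recording: rest - synthetic walk - rest, with known step truth
simple_walk_recording <- function(n_steps = 30, cadence = 2, rest_s = 30,
                                  noise = 0.003, height = 1.70,
                                  step_len = 0.65, seed = 11) {
  set.seed(seed)
  fs <- 100
  step_durs <- rep(1 / cadence, n_steps)
  lens <- rep(step_len, n_steps)
  w <- gaitfatigue:::synth_bout_signal(step_durs, lens, height, fs, noise)
  nr <- round(rest_s * fs)
  rest <- function() list(vv = -1 + rnorm(nr, 0, noise),
                          ml = rnorm(nr, 0, noise), ap = rnorm(nr, 0, noise))
  r1 <- rest(); r2 <- rest()
  vv <- c(r1$vv, w$vv, r2$vv)
  ml <- c(r1$ml, w$ml, r2$ml)
  ap <- c(r1$ap, w$ap, r2$ap)
  rec <- accel_recording(t = seq_along(vv) / fs, vv = vv, ml = ml, ap = ap,
                         sampling_rate = fs, subject_id = "T1")
  list(rec = rec, ic_true = rest_s + w$ic_offsets, step_durs = step_durs,
       step_lens = lens, height = height,
       walk_start = rest_s, walk_end = rest_s + w$nsamp / fs)
}

# minimal fold-ready matrices with an informative first feature
toy_classes <- function(n = 60, p = 4, sep = 2, seed = 5) {
  set.seed(seed)
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1] <- x[, 1] + ifelse(y == "high", sep, 0)
  list(x = x, y = y)
}
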