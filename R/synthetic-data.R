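# Synthetic cohort generator.
#
# Emulates the study design end-to-end: subjects wear a lower-back sensor for
# several days; walking bouts (power-law lengths) alternate with rest
# (lognormal gaps); each walking bout carries a quasi-periodic step waveform
# whose vertical amplitude is set from the inverted-pendulum relation so that
# the injected step length is recoverable by the analysis chain; fatigue
# diary entries are generated from a latent logistic model with configurable
# coupling to a windowed true gait feature. Every quantity the pipeline is
# supposed to recover (bout intervals, initial-contact times, step times and
# lengths, latent fatigue) is returned as ground truth.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' describe a plausible free-living cohort: ~1.9 steps/s cadence, 0.65 m
#' steps, heavy-tailed walking-bout lengths (power-law exponent 1.8 above
#' 10 s), lognormal rest gaps (median 5 min), a 14-h wear day starting at
#' 09:00, diary prompts in four fixed daily bins with imperfect response, and
#' a latent-logistic fatigue model with a wide between-subject spread.
#'
#' @param n_subjects,days cohort size and wear days per subject.
#' @param sampling_rate sampling rate in Hz.
#' @param cadence_hz,cadence_sd between-subject mean and SD of cadence
#'   (steps/s).
#' @param step_length_m,step_length_sd between-subject mean and SD of step
#'   length (m).
#' @param step_jitter_sd within-subject SD of individual step durations (s).
#' @param asymmetry_frac fractional left/right step-length asymmetry
#'   (right = mean*(1+f/2), left = mean*(1-f/2)).
#' @param bout_length_alpha,bout_length_xmin power-law exponent (>1) and
#'   lower bound (s) of walking-bout lengths.
#' @param bout_length_max truncation (s) applied to drawn bout lengths so a
#'   single bout cannot exceed the wear day.
#' @param nonwalk_lognorm_mu,nonwalk_lognorm_sigma lognormal parameters
#'   (log-seconds) of rest-gap lengths.
#' @param noise_sd_g white accelerometer noise SD per axis (g).
#' @param flip_probability probability that a whole day is recorded with the
#'   sensor upside down (all axes negated).
#' @param missing_frac fraction of each day's samples dropped in contiguous
#'   blocks.
#' @param missing_block_s typical missing-block length (s).
#' @param height_m,height_sd between-subject mean and SD of body height (m).
#' @param day_start_hour,day_hours wear window within each day.
#' @param pro_response_prob probability that a diary bin is answered.
#' @param item_missing_prob probability that an answered entry lacks one of
#'   the two scores.
#' @param coupling_beta effect (logit scale, per SD) of the windowed true
#'   gait feature on the latent fatigue of both scores.
#' @param coupling_feature which windowed truth feature drives the latent:
#'   `"step_time_mean"`, `"step_length_mean"` or `"n_bouts"`.
#' @param subject_intercept_sd SD (logit scale) of subject-level latent
#'   intercepts.
#' @param latent_intercept population latent intercept (logit scale);
#'   default `qlogis(2.5/6)` centres scores near 2.5/6.
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5, days = 1, sampling_rate = 100,
                       cadence_hz = 1.9, cadence_sd = 0.1,
                       step_length_m = 0.65, step_length_sd = 0.05,
                       step_jitter_sd = 0.01, asymmetry_frac = 0.05,
                       bout_length_alpha = 1.8, bout_length_xmin = 10,
                       bout_length_max = 3600,
                       nonwalk_lognorm_mu = log(300),
                       nonwalk_lognorm_sigma = 0.75,
                       noise_sd_g = 0.005, flip_probability = 0.1,
                       missing_frac = 0.02, missing_block_s = 300,
                       height_m = 1.70, height_sd = 0.09,
                       day_start_hour = 9, day_hours = 14,
                       pro_response_prob = 0.85, item_missing_prob = 0.05,
                       coupling_beta = 0, coupling_feature = "step_time_mean",
                       subject_intercept_sd = 1,
                       latent_intercept = qlogis(2.5 / 6),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$sampling_rate > 0, cfg$n_subjects >= 1, cfg$days >= 1)
  if (cfg$bout_length_alpha <= 1) {
    stop("bout_length_alpha must exceed 1 (power-law normalisation)",
         call. = FALSE)
  }
  stopifnot(cfg$flip_probability >= 0, cfg$flip_probability <= 1,
            cfg$missing_frac >= 0, cfg$missing_frac <= 1,
            cfg$cadence_sd >= 0, cfg$step_length_sd >= 0,
            cfg$step_jitter_sd >= 0, cfg$noise_sd_g >= 0,
            cfg$subject_intercept_sd >= 0,
            cfg$bout_length_xmin > 0,
            cfg$coupling_feature %in%
              c("step_time_mean", "step_length_mean", "n_bouts"))
  structure(cfg, class = "sim_config")
}

#' Draw from a continuous power law
#'
#' Inverse-CDF sampler for the Pareto density `p(x) ~ x^-alpha` on
#' `[xmin, Inf)`, the bout-length model whose exponent the alpha-parameter
#' estimator recovers.
#'
#' @param n number of draws.
#' @param alpha exponent (> 1).
#' @param xmin lower bound.
#' @return numeric vector of draws.
#' @export
rpowerlaw <- function(n, alpha, xmin) {
  stopifnot(alpha > 1, xmin > 0)
  xmin * runif(n)^(-1 / (alpha - 1))
}

# waveform for one walking bout. Returns acceleration (g) per axis plus the
# per-step truth. The vertical dynamic is a1*(-cos) + 0.25*a1*(-cos 2th) per
# step; a1 is set from the inverted-pendulum relation so the pipeline's
# double-integration recovers the injected step length.
synth_bout_signal <- function(step_durs, step_lens, height, fs, noise_sd) {
  n_steps <- length(step_durs)
  l <- 0.53 * height
  h <- l - sqrt(pmax(l^2 - step_lens^2 / 4, 0))
  total <- sum(step_durs)
  nsamp <- floor(total * fs)
  t <- seq_len(nsamp) / fs
  edges <- cumsum(c(0, step_durs))
  idx <- pmin(pmax(findInterval(t, edges, rightmost.closed = TRUE), 1), n_steps)
  th <- 2 * pi * (t - edges[idx]) / step_durs[idx]
  om <- 2 * pi / step_durs[idx]
  a1 <- h[idx] * om^2 / (2 * .G)
  vv <- -1 - a1 * cos(th) - 0.25 * a1 * cos(2 * th) +
    rnorm(nsamp, 0, noise_sd)
  ap <- 0.5 * a1 * sin(th) + rnorm(nsamp, 0, noise_sd)
  ml <- 0.3 * a1 * sin(th + pi / 4) + rnorm(nsamp, 0, noise_sd)
  list(vv = vv, ml = ml, ap = ap, nsamp = nsamp,
       ic_offsets = edges[seq_len(n_steps)])
}

# one subject-day timeline: alternating rest gaps and walking bouts filling
# the wear window. Returns a bout table with per-bout step truth.
sim_day_timeline <- function(cfg, cadence, step_len, day) {
  day_start <- day * 86400 + cfg$day_start_hour * 3600
  day_end <- day_start + cfg$day_hours * 3600
  bouts <- list()
  t <- day_start
  repeat {
    gap <- rlnorm(1, cfg$nonwalk_lognorm_mu, cfg$nonwalk_lognorm_sigma)
    t <- t + gap
    if (t >= day_end) break
    len <- min(rpowerlaw(1, cfg$bout_length_alpha, cfg$bout_length_xmin),
               cfg$bout_length_max, day_end - t)
    n_steps <- max(round(len * cadence), 4L)
    durs <- pmax(1 / cadence + rnorm(n_steps, 0, cfg$step_jitter_sd),
                 0.5 / cadence)
    lens <- step_len *
      (1 + c(1, -1) * cfg$asymmetry_frac / 2)[rep(1:2, length.out = n_steps)]
    bouts[[length(bouts) + 1]] <- tibble(
      start_s = t, end_s = t + sum(durs), drawn_length_s = len,
      step_durs = list(durs), step_lens = list(lens))
    t <- t + sum(durs)
    if (t >= day_end) break
  }
  if (!length(bouts)) return(tibble())
  out <- bind_rows(bouts)
  out$day <- day
  out[out$end_s <= day_end, , drop = FALSE]
}

#' Simulate a cohort of recordings, diaries and ground truth
#'
#' @param cfg a [sim_config()].
#' @param signal if `TRUE` (default) synthesise the full 100-Hz waveforms;
#'   `FALSE` generates only the timeline, diary and ground truth (fast, for
#'   bout-length and windowing studies that need no raw signal).
#' @return a list with elements
#'   \describe{
#'     \item{recordings}{named list of [accel_recording()] (when `signal`).}
#'     \item{pro}{diary tibble: `subject_id, timestamp, bin, pf_score,
#'       mf_score`.}
#'     \item{truth}{list with `bouts` (per-bout intervals and per-step truth),
#'       `subjects` (per-subject cadence, step length, height, latent
#'       intercepts), `pro_latent` (per-entry latent values), and
#'       `flipped_days`.}
#'   }
#' @export
simulate_cohort <- function(cfg, signal = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  subjects <- tibble(
    subject_id = sprintf("S%02d", seq_len(cfg$n_subjects)),
    cadence = pmax(rnorm(cfg$n_subjects, cfg$cadence_hz, cfg$cadence_sd), 0.5),
    step_length = pmax(rnorm(cfg$n_subjects, cfg$step_length_m,
                             cfg$step_length_sd), 0.3),
    height = pmax(rnorm(cfg$n_subjects, cfg$height_m, cfg$height_sd), 1.4),
    pf_intercept = cfg$latent_intercept +
      rnorm(cfg$n_subjects, 0, cfg$subject_intercept_sd),
    mf_intercept = cfg$latent_intercept +
      rnorm(cfg$n_subjects, 0, cfg$subject_intercept_sd))

  bouts <- list(); recs <- list(); flips <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sb <- list()
    for (d in seq_len(cfg$days) - 1L) {
      tl <- sim_day_timeline(cfg, subjects$cadence[s], subjects$step_length[s], d)
      if (nrow(tl)) sb[[length(sb) + 1]] <- tl
    }
    sb <- if (length(sb)) bind_rows(sb) else tibble()
    if (nrow(sb)) {
      sb$subject_id <- subjects$subject_id[s]
      sb$bout_id <- seq_len(nrow(sb))
      sb$ic_times <- purrr::map2(sb$start_s, sb$step_durs,
                                 ~ .x + cumsum(c(0, .y[-length(.y)])))
    }
    bouts[[s]] <- sb

    flip_days <- which(runif(cfg$days) < cfg$flip_probability) - 1L
    flips[[s]] <- flip_days
    if (signal) {
      recs[[s]] <- synth_subject_recording(cfg, subjects[s, ], sb, flip_days)
    }
  }
  bouts <- bind_rows(bouts)

  pro <- sim_pro_entries(cfg, subjects, bouts)

  truth <- list(
    bouts = bouts %>%
      select("subject_id", "bout_id", "day", "start_s", "end_s",
             "drawn_length_s", "ic_times", "step_durs", "step_lens"),
    subjects = subjects,
    pro_latent = pro$latent,
    flipped_days = setNames(flips, subjects$subject_id))
  out <- list(pro = pro$pro, truth = truth)
  if (signal) out$recordings <- setNames(recs, subjects$subject_id)
  out
}

# full-day waveform on the regular grid, with rest noise, walking bouts,
# missing blocks and optional whole-day flips
synth_subject_recording <- function(cfg, subj, sb, flip_days) {
  fs <- cfg$sampling_rate
  day_len <- round(cfg$day_hours * 3600 * fs)
  all_t <- c(); all_acc <- list()
  for (d in seq_len(cfg$days) - 1L) {
    day_start <- d * 86400 + cfg$day_start_hour * 3600
    vv <- -1 + rnorm(day_len, 0, cfg$noise_sd_g)
    ml <- rnorm(day_len, 0, cfg$noise_sd_g)
    ap <- rnorm(day_len, 0, cfg$noise_sd_g)
    if (nrow(sb)) {
      db <- sb[sb$day == d, , drop = FALSE]
      for (i in seq_len(nrow(db))) {
        w <- synth_bout_signal(db$step_durs[[i]], db$step_lens[[i]],
                               subj$height, fs, cfg$noise_sd_g)
        i0 <- round((db$start_s[i] - day_start) * fs)
        idx <- i0 + seq_len(w$nsamp)
        idx_ok <- idx >= 1 & idx <= day_len
        vv[idx[idx_ok]] <- w$vv[idx_ok]
        ml[idx[idx_ok]] <- w$ml[idx_ok]
        ap[idx[idx_ok]] <- w$ap[idx_ok]
      }
    }
    # contiguous missing blocks
    n_miss <- round(cfg$missing_frac * day_len)
    blk <- round(cfg$missing_block_s * fs)
    while (n_miss > 0) {
      len <- min(blk, n_miss)
      i0 <- sample.int(day_len - len, 1)
      vv[i0:(i0 + len - 1)] <- NA_real_
      ml[i0:(i0 + len - 1)] <- NA_real_
      ap[i0:(i0 + len - 1)] <- NA_real_
      n_miss <- n_miss - len
    }
    if (d %in% flip_days) {
      vv <- -vv; ml <- -ml; ap <- -ap
    }
    all_t <- c(all_t, day_start + seq_len(day_len) / fs)
    all_acc[[length(all_acc) + 1]] <- list(vv = vv, ml = ml, ap = ap)
  }
  accel_recording(
    t = all_t,
    vv = unlist(lapply(all_acc, `[[`, "vv")),
    ml = unlist(lapply(all_acc, `[[`, "ml")),
    ap = unlist(lapply(all_acc, `[[`, "ap")),
    sampling_rate = fs, subject_id = subj$subject_id)
}

# diary entries: four daily bins, response with probability
# pro_response_prob, completion uniform in bin; scores Binomial(6,
# plogis(intercept + subject effect + coupling * standardised windowed truth
# feature)) -- binomial sampling provides the 0-6 discretisation noise
sim_pro_entries <- function(cfg, subjects, bouts) {
  bin_starts <- c(morning = 9, early_afternoon = 13,
                  late_afternoon = 17, evening = 21)
  grid <- tidyr::expand_grid(
    subject_id = subjects$subject_id,
    day = seq_len(cfg$days) - 1L,
    bin = names(bin_starts))
  grid <- grid[runif(nrow(grid)) < cfg$pro_response_prob, , drop = FALSE]
  grid$timestamp <- grid$day * 86400 +
    (bin_starts[grid$bin] + runif(nrow(grid)) * 3) * 3600

  feat <- vapply(seq_len(nrow(grid)), function(i) {
    true_window_feature(bouts, grid$subject_id[i], grid$timestamp[i],
                        cfg$coupling_feature)
  }, numeric(1))
  sd_feat <- sd(feat, na.rm = TRUE)
  z <- if (!is.finite(sd_feat) || sd_feat == 0) {
    rep(0, length(feat))
  } else {
    as.numeric(scale(feat))
  }
  z[is.na(z)] <- 0

  grid <- left_join(grid, subjects, by = "subject_id")
  eta_pf <- grid$pf_intercept + cfg$coupling_beta * z
  eta_mf <- grid$mf_intercept + cfg$coupling_beta * z
  pf <- rbinom(nrow(grid), 6, plogis(eta_pf))
  mf <- rbinom(nrow(grid), 6, plogis(eta_mf))
  pf[runif(nrow(grid)) < cfg$item_missing_prob] <- NA_integer_
  mf[runif(nrow(grid)) < cfg$item_missing_prob] <- NA_integer_
  ord <- order(grid$subject_id, grid$timestamp)
  list(
    pro = tibble(subject_id = grid$subject_id, timestamp = grid$timestamp,
                 bin = grid$bin, pf_score = as.integer(pf),
                 mf_score = as.integer(mf))[ord, ],
    latent = tibble(subject_id = grid$subject_id, timestamp = grid$timestamp,
                    feature_z = z, eta_pf = eta_pf, eta_mf = eta_mf)[ord, ])
}

# windowed truth feature over bouts starting within 2 h before `ts`
true_window_feature <- function(bouts, subject_id, ts, feature) {
  if (!nrow(bouts)) return(NA_real_)
  b <- bouts[bouts$subject_id == subject_id &
               bouts$start_s >= ts - 7200 & bouts$start_s < ts, , drop = FALSE]
  if (!nrow(b)) return(NA_real_)
  switch(feature,
         step_time_mean = mean(unlist(b$step_durs)),
         step_length_mean = mean(unlist(b$step_lens)),
         n_bouts = as.numeric(nrow(b)))
}

#' Simulate feature windows directly (no raw signal)
#'
#' Fast generator of modelling-table rows for calibration and power studies
#' of the association and classification stages: standard-normal features,
#' one of which (`informative`) drives a latent logistic fatigue model with
#' subject random intercepts; scores are Binomial(6, plogis(latent)).
#'
#' @param n_subjects,windows_per_subject table dimensions.
#' @param n_features number of feature columns (`f1 ... fn`).
#' @param coupling_beta logit-scale effect of the informative feature.
#' @param informative index of the informative feature.
#' @param subject_intercept_sd SD of subject latent intercepts.
#' @param latent_intercept population latent intercept.
#' @param seed RNG seed.
#' @return tibble `subject_id, window_id, pf_score, mf_score, f1...fn`;
#'   `mf_score` is generated with no feature coupling (null labels).
#' @export
simulate_feature_windows <- function(n_subjects = 60, windows_per_subject = 10,
                                     n_features = 5, coupling_beta = 0,
                                     informative = 1,
                                     subject_intercept_sd = 1,
                                     latent_intercept = qlogis(2.5 / 6),
                                     seed = 1L) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- n_subjects * windows_per_subject
  subj <- rep(sprintf("S%03d", seq_len(n_subjects)), each = windows_per_subject)
  a_pf <- rnorm(n_subjects, 0, subject_intercept_sd)
  a_mf <- rnorm(n_subjects, 0, subject_intercept_sd)
  x <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(NULL, paste0("f", seq_len(n_features))))
  eta_pf <- latent_intercept + rep(a_pf, each = windows_per_subject) +
    coupling_beta * x[, informative]
  eta_mf <- latent_intercept + rep(a_mf, each = windows_per_subject)
  out <- tibble(subject_id = subj,
                window_id = rep(seq_len(windows_per_subject), n_subjects),
                pf_score = rbinom(n, 6, plogis(eta_pf)),
                mf_score = rbinom(n, 6, plogis(eta_mf)))
  dplyr::bind_cols(out, as_tibble(x))
}

#' Write a simulated cohort to disk
#'
#' Writes each recording in the CSV dialect of [load_recording()], the diary
#' via [write_pro_table()], and a ground-truth JSON sidecar per subject.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write ground-truth sidecars", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$recordings)) {
    write_recording(cohort$recordings[[sid]],
                    file.path(dir, paste0(sid, "_acc.csv")))
    tb <- cohort$truth$bouts
    tb <- tb[tb$subject_id == sid, ]
    jsonlite::write_json(
      list(bouts = tb[, c("bout_id", "start_s", "end_s")],
           ic_times = tb$ic_times,
           step_durs = tb$step_durs,
           step_lens = tb$step_lens,
           flipped_days = cohort$truth$flipped_days[[sid]]),
      file.path(dir, paste0(sid, "_truth.json")), digits = NA)
  }
  write_pro_table(cohort$pro, file.path(dir, "pro.csv"))
  invisible(dir)
}
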