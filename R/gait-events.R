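# Initial/final contact detection within walking bouts.
#
# Within a bout the vertical acceleration is linearly detrended, mean
# normalised, lowpass filtered (4th-order Butterworth, 20 Hz), integrated by
# cumulative trapezoid, and differentiated with a Gaussian
# continuous-wavelet-transform smoother. Initial contacts (IC, heel strike)
# are the local minima of that smoothed signal; final contacts (FC, toe off)
# are the local maxima of a further CWT differentiation. Only minima whose
# depth reaches 0.4 x the mean candidate depth, and maxima whose height
# reaches 0.25 x the mean candidate height, are retained. The first detected
# step of each bout is labelled a right step, alternating thereafter.

#' Detect IC and FC events within one walking bout
#'
#' @param rec an orientation-corrected [accel_recording()].
#' @param start_s,end_s bout interval in seconds on the recording clock.
#' @param scale Gaussian wavelet width in samples; defaults to
#'   `sampling_rate/10` (0.1 s at 100 Hz), a smoothing at step-frequency
#'   scale.
#' @param lowpass_hz,lowpass_order pre-filter cutoff (20 Hz) and order (4).
#' @param ic_frac,fc_frac relative peak-retention thresholds (0.4, 0.25).
#' @return list with numeric vectors `ic` and `fc` (event times in seconds,
#'   strictly increasing, inside the bout). Bouts too short for a stable
#'   filter pass return empty vectors.
#' @export
detect_ic_fc <- function(rec, start_s, end_s, scale = NULL,
                         lowpass_hz = 20, lowpass_order = 4,
                         ic_frac = 0.4, fc_frac = 0.25) {
  fs <- sampling_rate(rec)
  if (is.null(scale)) scale <- fs / 10
  idx <- time_index(rec$t, start_s, end_s)
  x <- rec$vv[idx]
  if (length(x) < max(6 * (lowpass_order + 1), 8 * scale) || anyNA(x)) {
    return(list(ic = numeric(), fc = numeric()))
  }
  x <- detrend_linear(x)
  x <- x - mean(x)
  x <- butter_filter(x, fs, lowpass_hz, lowpass_order, "low")
  v <- cum_integrate(x, fs)
  c1 <- cwt_diff(v, scale)
  ic_idx <- thresholded_peaks(c1, ic_frac, minima = TRUE)
  c2 <- cwt_diff(c1, scale)
  fc_idx <- thresholded_peaks(c2, fc_frac, minima = FALSE)
  list(ic = rec$t[idx[ic_idx]], fc = rec$t[idx[fc_idx]])
}

#' Alternating foot labels
#'
#' The first detected step of a bout is assigned to the right foot,
#' alternating thereafter.
#'
#' @param n number of initial contacts.
#' @return character vector `"R", "L", "R", ...` of length `n`.
#' @export
assign_feet <- function(n) {
  if (n <= 0) return(character())
  c("R", "L")[rep(1:2, length.out = n)]
}

#' Detect gait events for all walking bouts of a recording
#'
#' Runs [detect_ic_fc()] on each walking bout and drops bouts with fewer
#' than three detected steps (a step being the interval between consecutive
#' initial contacts).
#'
#' @param rec an orientation-corrected [accel_recording()].
#' @param bouts bout tibble from [assemble_bouts()].
#' @param min_steps bouts with fewer detected steps are removed (default 3).
#' @param ... passed to [detect_ic_fc()].
#' @return tibble with one row per retained walking bout: `bout_id`,
#'   `start_s`, `end_s`, list-columns `ic` and `fc` (event times) and `foot`
#'   (per-IC labels).
#' @export
detect_gait_events <- function(rec, bouts, min_steps = 3, ...) {
  wb <- bouts[bouts$kind == "walking", , drop = FALSE]
  if (!nrow(wb)) {
    return(tibble(bout_id = integer(), start_s = numeric(), end_s = numeric(),
                  ic = list(), fc = list(), foot = list()))
  }
  rows <- purrr::map(seq_len(nrow(wb)), function(i) {
    ev <- detect_ic_fc(rec, wb$start_s[i], wb$end_s[i], ...)
    n_steps <- max(length(ev$ic) - 1, 0)
    if (n_steps < min_steps) return(NULL)
    tibble(bout_id = wb$bout_id[i], start_s = wb$start_s[i],
           end_s = wb$end_s[i],
           ic = list(ev$ic), fc = list(ev$fc),
           foot = list(assign_feet(length(ev$ic))))
  })
  out <- bind_rows(purrr::compact(rows))
  if (!nrow(out)) {
    return(tibble(bout_id = integer(), start_s = numeric(), end_s = numeric(),
                  ic = list(), fc = list(), foot = list()))
  }
  out
}

#' Mask gait-initiation and outlier steps
#'
#' Applies the step-level exclusions to a per-step table: the first three and
#' last five steps of each bout are masked as gait initiation/termination,
#' and any step with step time outside (0.25, 1.25) s, step length outside
#' (0.23, 0.95) m, or swing time outside (0.23, 0.95) s is masked as an
#' outlier (boundary values are excluded). Masking never reorders or removes
#' rows; it sets the `valid` flag.
#'
#' @param steps per-step tibble from [bout_step_measures()] (needs `bout_id`,
#'   `step_index`, and the measure columns it provides).
#' @param init_head,init_tail number of steps masked at bout start and end.
#' @param step_time_range,step_length_range,swing_range open admissible
#'   intervals.
#' @return `steps` with a logical `valid` column.
#' @export
apply_step_exclusions <- function(steps, init_head = 3, init_tail = 5,
                                  step_time_range = c(0.25, 1.25),
                                  step_length_range = c(0.23, 0.95),
                                  swing_range = c(0.23, 0.95)) {
  if (!nrow(steps)) return(mutate(steps, valid = logical(0)))
  steps %>%
    group_by(.data$bout_id) %>%
    mutate(
      n_in_bout = dplyr::n(),
      valid = .data$step_index > init_head &
        .data$step_index <= .data$n_in_bout - init_tail) %>%
    ungroup() %>%
    mutate(
      valid = .data$valid &
        !is.na(.data$step_time) &
        .data$step_time > step_time_range[1] &
        .data$step_time < step_time_range[2] &
        (is.na(.data$step_length) |
           (.data$step_length > step_length_range[1] &
              .data$step_length < step_length_range[2])) &
        (is.na(.data$swing_time) |
           (.data$swing_time > swing_range[1] &
              .data$swing_time < swing_range[2]))) %>%
    select(-"n_in_bout")
}
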