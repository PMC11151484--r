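# Step-level (micro) gait measures.
#
# From the ordered IC/FC sequence of a bout:
#   stance_i = FC_{i+1} - IC_i      (foot on ground)
#   stride_i = IC_{i+2} - IC_i      (full gait cycle)
#   swing_i  = stride_i - stance_i  (foot in the air)
#   step_i   = IC_{i+1} - IC_i
# Step length uses the inverted-pendulum model: the pendulum length is 53%
# of body height and the vertical excursion h of the centre of mass between
# consecutive ICs gives step length = 2*sqrt(2*l*h - h^2). Step velocity is
# step length over step time. Bout-level variability is the SD over the
# bout's valid steps; asymmetry is |mean(left) - mean(right)|.

#' Temporal gait parameters from an IC/FC sequence
#'
#' @param ic,fc strictly increasing event times (s) of one bout.
#' @return a tibble with one row per step (consecutive IC pairs):
#'   `step_index`, `ic_time`, `step_time`, `stride_time`, `stance_time`,
#'   `swing_time` (the last measures are `NA` where the defining later event
#'   is missing). Fewer than three ICs give an empty table.
#' @export
temporal_params <- function(ic, fc) {
  n <- length(ic)
  if (n < 3) {
    return(tibble(step_index = integer(), ic_time = numeric(),
                  step_time = numeric(), stride_time = numeric(),
                  stance_time = numeric(), swing_time = numeric()))
  }
  fc <- fc[fc > ic[1]]
  # fc_after[i]: first FC at or after ic[i]
  fc_after <- vapply(seq_len(n), function(i) {
    j <- which(fc > ic[i])
    if (length(j)) fc[j[1]] else NA_real_
  }, numeric(1))
  ns <- n - 1
  step_time <- diff(ic)
  stride_time <- c(ic[seq_len(n - 2) + 2] - ic[seq_len(n - 2)],
                   NA_real_)[seq_len(ns)]
  stance_time <- c(fc_after[seq_len(n - 1) + 1] -
                     ic[seq_len(n - 1)])[seq_len(ns)]
  swing_time <- stride_time - stance_time
  tibble(step_index = seq_len(ns), ic_time = ic[seq_len(ns)],
         step_time = step_time, stride_time = stride_time,
         stance_time = stance_time, swing_time = swing_time)
}

#' Inverted-pendulum step length
#'
#' @param h vertical excursion of the centre of mass over the step (m).
#' @param height body height (m); the pendulum length is `0.53 * height`.
#' @return tibble with `step_length` (m; `NA` where `h >= 2l`, outside the
#'   model's range) and `suspect` (`TRUE` where `h >= l`, within range but
#'   physically implausible).
#' @export
step_length_ip <- function(h, height) {
  l <- 0.53 * height
  sl <- ifelse(h < 2 * l, 2 * sqrt(pmax(2 * l * h - h^2, 0)), NA_real_)
  tibble(step_length = sl, suspect = h >= l)
}

# per-step vertical excursion: double trapezoid integration of the vertical
# acceleration (m/s^2) with a 4th-order 0.1 Hz highpass after each
# integration to suppress drift; h = peak-to-trough of the position signal
# between consecutive ICs
step_heights <- function(rec, start_s, end_s, ic,
                         highpass_hz = 0.1, highpass_order = 4) {
  fs <- sampling_rate(rec)
  idx <- time_index(rec$t, start_s, end_s)
  x <- detrend_linear(rec$vv[idx]) * .G
  x <- butter_filter(x, fs, 20, 4, "low")
  v <- butter_filter(cum_integrate(x, fs), fs, highpass_hz, highpass_order,
                     "high")
  p <- butter_filter(cum_integrate(v, fs), fs, highpass_hz, highpass_order,
                     "high")
  t0 <- rec$t[idx[1]]
  vapply(seq_len(length(ic) - 1), function(i) {
    a <- max(1, round((ic[i] - t0) * fs))
    b <- min(length(p), round((ic[i + 1] - t0) * fs))
    if (b <= a) return(NA_real_)
    seg <- p[a:b]
    max(seg) - min(seg)
  }, numeric(1))
}

#' Per-step measures for all bouts of a recording
#'
#' Combines [temporal_params()], the inverted-pendulum step length and step
#' velocity, foot labels, and the step-level exclusions of
#' [apply_step_exclusions()].
#'
#' @param rec an orientation-corrected [accel_recording()].
#' @param events tibble from [detect_gait_events()].
#' @param subject_height body height in metres.
#' @param ... passed to [apply_step_exclusions()].
#' @return per-step tibble: `bout_id`, `step_index`, `foot`, `ic_time`, the
#'   four temporal measures, `h`, `step_length`, `step_velocity`, `suspect`,
#'   `valid`.
#' @export
bout_step_measures <- function(rec, events, subject_height, ...) {
  if (!nrow(events)) {
    return(apply_step_exclusions(
      tibble(bout_id = integer(), step_index = integer(), foot = character(),
             ic_time = numeric(), step_time = numeric(),
             stride_time = numeric(), stance_time = numeric(),
             swing_time = numeric(), h = numeric(), step_length = numeric(),
             step_velocity = numeric(), suspect = logical()), ...))
  }
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    ic <- events$ic[[i]]
    tp <- temporal_params(ic, events$fc[[i]])
    if (!nrow(tp)) return(NULL)
    h <- step_heights(rec, events$start_s[i], events$end_s[i], ic)
    sl <- step_length_ip(h, subject_height)
    tp %>%
      mutate(bout_id = events$bout_id[i],
             foot = events$foot[[i]][seq_len(nrow(tp))],
             h = h,
             step_length = sl$step_length,
             step_velocity = sl$step_length / .data$step_time,
             suspect = sl$suspect)
  })
  out <- bind_rows(purrr::compact(rows))
  if (!nrow(out)) {
    return(apply_step_exclusions(
      tibble(bout_id = integer(), step_index = integer(), foot = character(),
             ic_time = numeric(), step_time = numeric(),
             stride_time = numeric(), stance_time = numeric(),
             swing_time = numeric(), h = numeric(), step_length = numeric(),
             step_velocity = numeric(), suspect = logical()), ...))
  }
  apply_step_exclusions(
    select(out, "bout_id", "step_index", "foot", "ic_time", "step_time",
           "stride_time", "stance_time", "swing_time", "h", "step_length",
           "step_velocity", "suspect"), ...)
}

# SD over valid steps; NA when fewer than two
sd_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) NA_real_ else sd(x)
}

# |mean(left) - mean(right)|; NA when either foot is absent
asym_or_na <- function(x, foot) {
  ok <- !is.na(x)
  l <- x[ok & foot == "L"]; r <- x[ok & foot == "R"]
  if (!length(l) || !length(r)) return(NA_real_)
  abs(mean(l) - mean(r))
}

#' Bout-level micro gait characteristics
#'
#' Aggregates valid steps into the sixteen micro measures, grouped as pace
#' (step velocity, step length, SD of swing time), rhythm (stance, swing,
#' step, stride time), variability (SDs of step time, stance time, step
#' velocity, step length, stride time), asymmetry (step, swing, stance time)
#' and postural control (step-length asymmetry). One row per bout; column
#' names are `group__measure`.
#'
#' @param steps per-step tibble from [bout_step_measures()].
#' @return tibble with `bout_id`, `n_valid_steps` and the sixteen measures.
#' @export
micro_features_by_bout <- function(steps) {
  steps %>%
    filter(.data$valid) %>%
    group_by(.data$bout_id) %>%
    summarise(
      n_valid_steps = dplyr::n(),
      pace__step_velocity = mean(.data$step_velocity, na.rm = TRUE),
      pace__step_length = mean(.data$step_length, na.rm = TRUE),
      pace__swing_time_sd = sd_or_na(.data$swing_time),
      rhythm__stance_time = mean(.data$stance_time, na.rm = TRUE),
      rhythm__swing_time = mean(.data$swing_time, na.rm = TRUE),
      rhythm__step_time = mean(.data$step_time, na.rm = TRUE),
      rhythm__stride_time = mean(.data$stride_time, na.rm = TRUE),
      variability__step_time_sd = sd_or_na(.data$step_time),
      variability__stance_time_sd = sd_or_na(.data$stance_time),
      variability__step_velocity_sd = sd_or_na(.data$step_velocity),
      variability__step_length_sd = sd_or_na(.data$step_length),
      variability__stride_time_sd = sd_or_na(.data$stride_time),
      asymmetry__step_time_asym = asym_or_na(.data$step_time, .data$foot),
      asymmetry__swing_time_asym = asym_or_na(.data$swing_time, .data$foot),
      asymmetry__stance_time_asym = asym_or_na(.data$stance_time, .data$foot),
      postural_control__step_length_asym =
        asym_or_na(.data$step_length, .data$foot),
      .groups = "drop")
}
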