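# Activity-level (macro) gait measures.
#
# Walking volume (step counts, bout lengths, bout counts), non-walking
# volume (gap lengths and long-gap counts), pattern (power-law alpha of
# walking-bout lengths, mean walking and non-walking time), the per-sample
# acceleration vector magnitude, and bout-length variability as the
# lognormal maximum-likelihood shape parameter (S2; S2W for walking, S2S for
# non-walking bouts).

#' Power-law alpha parameter of bout lengths
#'
#' Maximum-likelihood exponent of a power law fitted to the bout lengths,
#' `alpha = 1 + n / sum(log(x / xmin))` with `xmin = min(x)`. Describes the
#' fragmentation of walking activity: larger alpha, more short bouts.
#'
#' @param x bout lengths in seconds (all > 0).
#' @return alpha, or `NA` when undefined (n < 2 or all lengths equal).
#' @export
alpha_parameter <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || any(x <= 0)) return(NA_real_)
  s <- sum(log(x / min(x)))
  if (s == 0) {
    message("alpha parameter undefined: all bout lengths equal")
    return(NA_real_)
  }
  1 + length(x) / s
}

#' Lognormal bout-length variability (S2)
#'
#' Maximum-likelihood estimate of the lognormal shape parameter,
#' `sqrt(mean((log x - mean(log x))^2))` (population form, divisor n).
#' Scale-invariant: `S2(c*x) = S2(x)` for any `c > 0`.
#'
#' @param x bout lengths in seconds (all > 0).
#' @return S2, or `NA` when n < 2.
#' @export
bout_length_variability <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || any(x <= 0)) return(NA_real_)
  lx <- log(x)
  sqrt(mean((lx - mean(lx))^2))
}

#' Acceleration vector magnitude
#'
#' Per-sample Euclidean norm of the triaxial acceleration,
#' `sqrt(vv^2 + ml^2 + ap^2)`.
#'
#' @param rec an [accel_recording()].
#' @param from_s,to_s optional interval (seconds, half-open); whole recording
#'   when omitted.
#' @param units `"g"` or `"ms2"` (multiplies by 9.80665).
#' @return numeric vector, one value per sample in the interval.
#' @export
vector_magnitude <- function(rec, from_s = -Inf, to_s = Inf,
                             units = c("g", "ms2")) {
  units <- match.arg(units)
  idx <- if (is.finite(from_s) || is.finite(to_s)) {
    time_index(rec$t, max(from_s, rec$t[1] - 1), min(to_s, Inf))
  } else {
    seq_len(nrow(rec))
  }
  vm <- sqrt(rec$vv[idx]^2 + rec$ml[idx]^2 + rec$ap[idx]^2)
  if (units == "ms2") vm <- vm * .G
  vm
}

#' Macro gait characteristics for one 2-h window
#'
#' Computes the scalar ("single") macro measures and the multi-valued series
#' the windowing stage pools. Bout-length series omit the mean statistic
#' when pooled (the means live in the pattern group as mean walking and
#' non-walking time).
#'
#' @param bouts bout tibble restricted to the window (see
#'   [bouts_before_pro()]).
#' @param steps per-step tibble for the window's walking bouts (used for
#'   step counts; may have zero rows).
#' @param rec the recording (for the vector magnitude series).
#' @param from_s,to_s the window interval in seconds.
#' @param vm_scope `"window"` (default: vector magnitude over all samples in
#'   the window) or `"walking"` (walking-bout samples only).
#' @return a list with `series` (named list of numeric vectors to pool:
#'   `walking_volume__steps_in_bouts`, `walking_volume__bout_length_s`
#'   (excl. mean), `nonwalking_volume__bout_length_s` (excl. mean),
#'   `vector_magnitude__vm_ms2`) and `single` (named scalars: bout counts,
#'   long-bout counts, alpha, mean walking/non-walking time, S2W, S2S).
#' @export
macro_features <- function(bouts, steps, rec, from_s, to_s,
                           vm_scope = c("window", "walking")) {
  vm_scope <- match.arg(vm_scope)
  walk <- bouts[bouts$kind == "walking", , drop = FALSE]
  nonwalk <- bouts[bouts$kind == "non_walking", , drop = FALSE]
  steps_per_bout <- if (nrow(steps)) {
    steps %>% group_by(.data$bout_id) %>%
      summarise(n = sum(.data$valid), .groups = "drop") %>% pull("n")
  } else {
    numeric()
  }
  vm <- if (vm_scope == "window") {
    vector_magnitude(rec, from_s, to_s, units = "ms2")
  } else {
    unlist(purrr::map2(walk$start_s, walk$end_s,
                       ~ vector_magnitude(rec, .x, .y, units = "ms2")))
  }
  vm <- vm[!is.na(vm)]
  list(
    series = list(
      walking_volume__steps_in_bouts = steps_per_bout,
      walking_volume__bout_length_s = walk$length_s,
      nonwalking_volume__bout_length_s = nonwalk$length_s,
      vector_magnitude__vm_ms2 = vm),
    series_excl_mean = c("walking_volume__bout_length_s",
                         "nonwalking_volume__bout_length_s"),
    single = c(
      walking_volume__n_walking_bouts = nrow(walk),
      walking_volume__n_bouts_ge_10min = sum(walk$length_s >= 600),
      nonwalking_volume__n_nonwalk_ge_20min = sum(nonwalk$length_s >= 1200),
      nonwalking_volume__n_nonwalk_ge_30min = sum(nonwalk$length_s >= 1800),
      nonwalking_volume__n_nonwalk_ge_50min = sum(nonwalk$length_s >= 3000),
      pattern__alpha = alpha_parameter(walk$length_s),
      pattern__mean_walking_time_s =
        if (nrow(walk)) mean(walk$length_s) else NA_real_,
      pattern__mean_nonwalking_time_s =
        if (nrow(nonwalk)) mean(nonwalk$length_s) else NA_real_,
      variability__s2w = bout_length_variability(walk$length_s),
      variability__s2s = bout_length_variability(nonwalk$length_s)))
}
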