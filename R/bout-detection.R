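# Walking-bout identification.
#
# The recording is lowpass filtered (2nd-order Butterworth, 17 Hz) and cut
# into 0.1-s non-overlapping windows. A window is "active" (upright and
# moving) iff the summed per-axis SDs reach 0.05 g AND the mean vertical
# acceleration is at most -0.77 g. SDs are insensitive to mean removal, so
# they are computed on the filtered signal; the mean test is evaluated on the
# gravity-retaining filtered signal, since thresholding a window mean at
# -0.77 g is only meaningful when gravity is kept. Active runs separated by
# fewer than 20 windows are merged (left to right, to a fixpoint), merged
# runs shorter than 20 windows (2 s) are discarded, and the complement of
# the retained walking bouts within valid (non-missing) data forms the
# non-walking bouts.

#' Flag active (upright-and-moving) 0.1-s windows
#'
#' @param rec an orientation-corrected [accel_recording()].
#' @param sd_threshold_g summed-SD threshold in g (default 0.05).
#' @param vv_mean_threshold_g upper bound on the window mean vertical
#'   acceleration in g (default -0.77).
#' @param lowpass_hz,lowpass_order pre-filter cutoff and order.
#' @return a tibble with one row per window: `window` (0-based index),
#'   `start_s`, `sd_sum`, `vv_mean`, `valid` (no missing samples) and
#'   `active`. Windows overlapping missing data are inactive by definition.
#' @export
flag_active_windows <- function(rec, sd_threshold_g = 0.05,
                                vv_mean_threshold_g = -0.77,
                                lowpass_hz = 17, lowpass_order = 2) {
  fs <- sampling_rate(rec)
  wlen <- round(0.1 * fs)
  n <- nrow(rec)
  nw <- floor(n / wlen)
  if (nw == 0) {
    return(tibble(window = integer(), start_s = numeric(),
                  sd_sum = numeric(), vv_mean = numeric(),
                  valid = logical(), active = logical()))
  }
  fvv <- butter_filter(rec$vv, fs, lowpass_hz, lowpass_order, "low")
  fml <- butter_filter(rec$ml, fs, lowpass_hz, lowpass_order, "low")
  fap <- butter_filter(rec$ap, fs, lowpass_hz, lowpass_order, "low")
  used <- nw * wlen
  shape <- function(x) matrix(x[seq_len(used)], nrow = wlen)
  mvv <- shape(fvv); mml <- shape(fml); map_ <- shape(fap)
  col_sd <- function(m) {
    mu <- colMeans(m)
    sqrt(colSums((m - rep(mu, each = wlen))^2) / (wlen - 1))
  }
  sd_sum <- col_sd(mvv) + col_sd(mml) + col_sd(map_)
  vv_mean <- colMeans(mvv)
  valid <- !is.na(sd_sum)
  # windows spanning a day boundary or time gap are not meaningful either
  tmat <- shape(rec$t)
  contiguous <- (tmat[wlen, ] - tmat[1, ]) < 2 * wlen / fs
  valid <- valid & contiguous
  active <- valid & sd_sum >= sd_threshold_g & vv_mean <= vv_mean_threshold_g
  tibble(window = seq_len(nw) - 1L,
         start_s = tmat[1, ],
         sd_sum = sd_sum, vv_mean = vv_mean,
         valid = valid, active = ifelse(is.na(active), FALSE, active))
}

# merge active runs separated by < merge_gap inactive windows, left to right,
# iterating to a fixpoint; gaps of exactly merge_gap windows are kept, and a
# gap containing invalid (missing-data) windows is never merged so bouts
# cannot span a recording gap
merge_active_runs <- function(active, merge_gap = 20, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(active))
  # a gap's length and validity never change when neighbouring runs merge,
  # so filling every eligible interior gap at once reaches the same fixpoint
  # as the one-at-a-time left-to-right sweep
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gaps <- which(!r$values & r$lengths < merge_gap)
  gaps <- gaps[gaps > 1 & gaps < length(r$values)]
  if (length(gaps)) {
    cv <- cumsum(!valid)
    n_invalid <- cv[ends[gaps]] - cv[starts[gaps]] +
      as.integer(!valid[starts[gaps]])
    all_valid <- n_invalid == 0
    for (g in gaps[all_valid]) active[starts[g]:ends[g]] <- TRUE
  }
  active
}

#' Assemble walking and non-walking bouts from window flags
#'
#' @param flags tibble from [flag_active_windows()].
#' @param min_windows minimum retained bout length in windows (default 20;
#'   bouts of exactly 20 windows are retained).
#' @param merge_gap_windows inactive gaps shorter than this many windows are
#'   merged (default 20; gaps of exactly 20 windows are not merged).
#' @param window_s window length in seconds (0.1).
#' @return a tibble of bouts: `kind` (walking/non_walking), `start_window`,
#'   `end_window` (0-based, half-open), `start_s`, `end_s`, `length_s`.
#'   Walking and non-walking bouts partition the valid window span.
#' @export
assemble_bouts <- function(flags, min_windows = 20, merge_gap_windows = 20,
                           window_s = 0.1) {
  if (!nrow(flags)) {
    return(tibble(kind = character(), start_window = integer(),
                  end_window = integer(), start_s = numeric(),
                  end_s = numeric(), length_s = numeric()))
  }
  active <- merge_active_runs(flags$active, merge_gap_windows, flags$valid)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_windows
  walk <- tibble(start_window = starts[keep] - 1L, end_window = ends[keep])
  # non-walking: complement of retained walking bouts over valid windows
  is_walk <- rep(FALSE, nrow(flags))
  for (i in seq_len(nrow(walk))) {
    is_walk[(walk$start_window[i] + 1):walk$end_window[i]] <- TRUE
  }
  nonwalk_flag <- flags$valid & !is_walk
  rn <- rle(nonwalk_flag)
  endsn <- cumsum(rn$lengths)
  startsn <- endsn - rn$lengths + 1
  nonwalk <- tibble(start_window = startsn[rn$values] - 1L,
                    end_window = endsn[rn$values])
  res <- bind_rows(
    if (nrow(walk)) mutate(walk, kind = "walking") else NULL,
    if (nrow(nonwalk)) mutate(nonwalk, kind = "non_walking") else NULL)
  if (!nrow(res)) {
    return(tibble(kind = character(), start_window = integer(),
                  end_window = integer(), start_s = numeric(),
                  end_s = numeric(), length_s = numeric()))
  }
  res %>%
    mutate(start_s = flags$start_s[.data$start_window + 1],
           end_s = flags$start_s[.data$end_window] + window_s,
           length_s = (.data$end_window - .data$start_window) * window_s) %>%
    arrange(.data$start_window) %>%
    mutate(bout_id = ifelse(.data$kind == "walking",
                            cumsum(.data$kind == "walking"), NA_integer_)) %>%
    select("bout_id", "kind", "start_window", "end_window", "start_s",
           "end_s", "length_s")
}

#' Detect walking bouts in a recording
#'
#' Convenience wrapper: [flag_active_windows()] then [assemble_bouts()].
#'
#' @inheritParams flag_active_windows
#' @param ... passed to [assemble_bouts()].
#' @return bout tibble (see [assemble_bouts()]).
#' @export
detect_bouts <- function(rec, ...) {
  assemble_bouts(flag_active_windows(rec), ...)
}

#' Bouts that began in the 2-h window before a diary entry
#'
#' Selection is by bout start: a bout starting inside
#' `[pro_timestamp - window_hours, pro_timestamp)` is included in full even
#' if it ends after the entry.
#'
#' @param bouts bout tibble.
#' @param pro_timestamp diary completion time (s, recording clock).
#' @param window_hours look-back length in hours (default 2).
#' @return the selected rows of `bouts`.
#' @export
bouts_before_pro <- function(bouts, pro_timestamp, window_hours = 2) {
  lo <- pro_timestamp - window_hours * 3600
  bouts[bouts$start_s >= lo & bouts$start_s < pro_timestamp, , drop = FALSE]
}
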