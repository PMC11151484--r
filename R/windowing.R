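# Pooling gait measures over the 2-h pre-diary windows and assembling the
# modelling table (one row per retained diary entry).

#' Pool a multi-valued measure into the statistic set
#'
#' Returns the nine pooled statistics: mean, SD, variance, sum, minimum,
#' maximum, median, and 25th/75th percentiles (linear interpolation between
#' order statistics, `quantile` type 7). SD and variance use the sample
#' (n-1) form; a single value gives SD and variance 0. An optional tenth
#' statistic, the number of pooled values, is off by default.
#'
#' @param x numeric values (NAs dropped).
#' @param excl_mean drop the mean from the returned set (used for bout-length
#'   series whose means are reported in the pattern group instead).
#' @param include_count append `count`, the number of pooled values.
#' @return named numeric vector; all statistics are `NA` for empty input.
#' @export
pool_statistics <- function(x, excl_mean = FALSE, include_count = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) {
    out <- c(mean = NA_real_, sd = NA_real_, variance = NA_real_,
             sum = NA_real_, min = NA_real_, max = NA_real_,
             median = NA_real_, p25 = NA_real_, p75 = NA_real_)
  } else {
    q <- unname(quantile(x, c(0.25, 0.75), type = 7))
    out <- c(mean = mean(x),
             sd = if (n == 1) 0 else sd(x),
             variance = if (n == 1) 0 else var(x),
             sum = sum(x), min = min(x), max = max(x),
             median = median(x), p25 = q[1], p75 = q[2])
  }
  if (excl_mean) out <- out[setdiff(names(out), "mean")]
  if (include_count) out <- c(out, count = as.numeric(n))
  out
}

#' Run the per-recording gait pipeline
#'
#' Orientation correction, walking-bout detection, gait-event detection,
#' per-step measures and bout-level micro features for one recording.
#'
#' @param rec an [accel_recording()].
#' @param height subject body height (m).
#' @param ... passed to [detect_ic_fc()] via [detect_gait_events()].
#' @return list with `rec` (orientation-corrected), `bouts`, `events`,
#'   `steps`, `micro` (bout-level micro features).
#' @export
process_recording <- function(rec, height, ...) {
  rec <- correct_orientation(rec)
  bouts <- detect_bouts(rec)
  events <- detect_gait_events(rec, bouts, ...)
  steps <- bout_step_measures(rec, events, height)
  micro <- micro_features_by_bout(steps)
  list(rec = rec, bouts = bouts, events = events, steps = steps,
       micro = micro)
}

# pooled feature vector for one diary entry
window_feature_row <- function(proc, ts, window_hours = 2,
                               vm_scope = "window",
                               include_count = FALSE) {
  wb <- bouts_before_pro(proc$bouts, ts, window_hours)
  walk <- wb[wb$kind == "walking", , drop = FALSE]
  if (!nrow(walk)) return(NULL)
  from_s <- ts - window_hours * 3600
  steps_w <- proc$steps[proc$steps$bout_id %in% walk$bout_id, , drop = FALSE]
  mac <- macro_features(wb, steps_w, proc$rec, from_s, ts,
                        vm_scope = vm_scope)
  vals <- c()
  for (nm in names(mac$series)) {
    st <- pool_statistics(mac$series[[nm]],
                          excl_mean = nm %in% mac$series_excl_mean,
                          include_count = include_count)
    vals <- c(vals, setNames(st, paste0("macro__", nm, "__", names(st))))
  }
  vals <- c(vals, setNames(mac$single,
                           paste0("macro__", names(mac$single), "__single")))
  micro_cols <- setdiff(names(proc$micro), c("bout_id", "n_valid_steps"))
  mic <- proc$micro[proc$micro$bout_id %in% walk$bout_id, , drop = FALSE]
  for (nm in micro_cols) {
    st <- pool_statistics(mic[[nm]], include_count = include_count)
    vals <- c(vals, setNames(st, paste0("micro__", nm, "__", names(st))))
  }
  vals
}

#' Assemble the modelling table
#'
#' Runs the full gait pipeline on every recording and pools macro and micro
#' measures over the `window_hours` preceding each diary entry. A row is
#' retained only if at least one walking bout began in its window and at
#' least one fatigue label is present; subjects with no retained rows are
#' absent from the result. Duplicate diary timestamps keep the first entry.
#'
#' @param recordings named list of [accel_recording()] (names = subject ids).
#' @param pro diary tibble (`subject_id, timestamp, bin, pf_score,
#'   mf_score`).
#' @param heights named numeric vector of body heights (m) per subject id.
#' @param window_hours look-back window length (default 2).
#' @param vm_scope vector-magnitude scope, `"window"` or `"walking"`.
#' @param include_count include the pooled-value count as a tenth statistic.
#' @param ... passed to [process_recording()].
#' @return a tibble of class `fatigue_dataset`: `subject_id, pro_timestamp,
#'   bin, pf_score, mf_score` plus one column per pooled feature
#'   (`domain__group__measure__statistic`).
#' @export
build_dataset <- function(recordings, pro, heights, window_hours = 2,
                          vm_scope = c("window", "walking"),
                          include_count = FALSE, ...) {
  vm_scope <- match.arg(vm_scope)
  rows <- list()
  for (sid in names(recordings)) {
    sp <- pro[pro$subject_id == sid, , drop = FALSE]
    sp <- sp[!is.na(sp$pf_score) | !is.na(sp$mf_score), , drop = FALSE]
    if (anyDuplicated(sp$timestamp)) {
      message("duplicate diary timestamps for ", sid, ": keeping first")
      sp <- sp[!duplicated(sp$timestamp), , drop = FALSE]
    }
    if (!nrow(sp)) next
    proc <- process_recording(recordings[[sid]], heights[[sid]], ...)
    for (i in seq_len(nrow(sp))) {
      vals <- window_feature_row(proc, sp$timestamp[i], window_hours,
                                 vm_scope, include_count)
      if (is.null(vals)) next
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(subject_id = sid, pro_timestamp = sp$timestamp[i],
               bin = sp$bin[i], pf_score = sp$pf_score[i],
               mf_score = sp$mf_score[i]),
        as_tibble(as.list(vals)))
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("fatigue_dataset", class(out))
  out
}

#' Feature-column metadata of a modelling table
#'
#' @param dataset a `fatigue_dataset` (or any tibble whose feature columns
#'   are named `domain__group__measure__statistic`).
#' @return tibble `feature, domain, group, measure, statistic`.
#' @export
feature_schema <- function(dataset) {
  fcols <- grep("^(macro|micro)__", names(dataset), value = TRUE)
  parts <- strsplit(fcols, "__", fixed = TRUE)
  tibble(feature = fcols,
         domain = vapply(parts, `[`, "", 1),
         group = vapply(parts, `[`, "", 2),
         measure = vapply(parts, `[`, "", 3),
         statistic = vapply(parts, `[`, "", 4))
}
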