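# Reading, writing and orienting accelerometer recordings and fatigue diaries.
#
# A recording is a tibble with one row per sample on a regular grid: columns
# `t` (seconds since the start of the recording), `day` (integer day index),
# and `vv`, `ml`, `ap` (acceleration in g along the body-frame vertical,
# medial-lateral and anterior-posterior axes). Missing wear periods are kept
# on the grid as NA samples so that downstream windowing can treat them as
# explicit gaps rather than silently interpolating across them.

#' Construct an accelerometer recording
#'
#' @param t sample times in seconds, strictly increasing on a regular grid.
#' @param vv,ml,ap acceleration in g along the vertical, medial-lateral and
#'   anterior-posterior body axes (`NA` marks missing wear time).
#' @param sampling_rate sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param day integer day index per sample; derived from `t` (86400 s days)
#'   when omitted.
#' @return a tibble of class `accel_recording` with attributes
#'   `sampling_rate` and `subject_id`.
#' @export
accel_recording <- function(t, vv, ml, ap, sampling_rate, subject_id = "S1",
                            day = NULL) {
  stopifnot(sampling_rate > 0, length(t) == length(vv),
            length(vv) == length(ml), length(ml) == length(ap))
  if (is.unsorted(t, strictly = TRUE)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  rng <- range(c(vv, ml, ap), na.rm = TRUE)
  if (any(abs(rng) > 8)) {
    stop("acceleration outside the +/-8 g device range", call. = FALSE)
  }
  if (is.null(day)) day <- floor(t / 86400)
  out <- tibble(t = t, day = as.integer(day), vv = vv, ml = ml, ap = ap)
  structure(out,
            class = c("accel_recording", class(out)),
            sampling_rate = sampling_rate,
            subject_id = subject_id)
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject %s, %d samples @ %g Hz, %d day(s), %.1f%% missing\n",
              attr(x, "subject_id"), nrow(x), attr(x, "sampling_rate"),
              length(unique(x$day)), 100 * mean(is.na(x$vv))))
  NextMethod()
}

#' Sampling rate of a recording
#' @param rec an `accel_recording`.
#' @return sampling rate in Hz.
#' @export
sampling_rate <- function(rec) attr(rec, "sampling_rate")

#' Read an accelerometer recording from delimited text
#'
#' Expects a header row and columns `timestamp, ax, ay, az` (any extra
#' columns, e.g. gyroscope channels, are ignored). Axes are relabelled into
#' the body frame via `axis_map`, and optionally converted from m/s^2 to g.
#'
#' @param path CSV file path.
#' @param axis_map named character vector mapping body axes to file columns,
#'   e.g. `c(vv = "ax", ml = "ay", ap = "az")`.
#' @param sampling_rate expected sampling rate in Hz; timestamps are checked
#'   against it.
#' @param subject_id subject identifier.
#' @param units `"g"` (default) or `"ms2"`; `"ms2"` inputs are divided by
#'   9.80665.
#' @param tol tolerance (fraction of the sample interval) for timestamp
#'   regularity.
#' @return an [accel_recording()].
#' @export
load_recording <- function(path, axis_map = c(vv = "ax", ml = "ay", ap = "az"),
                           sampling_rate = 100, subject_id = "S1",
                           units = c("g", "ms2"), tol = 0.01) {
  units <- match.arg(units)
  stopifnot(all(c("vv", "ml", "ap") %in% names(axis_map)))
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(dat) == 0) stop("empty recording file: ", path, call. = FALSE)
  need <- c("timestamp", unname(axis_map))
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols)) {
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  t <- suppressWarnings(as.numeric(dat$timestamp))
  bad <- which(is.na(t))
  for (col in unname(axis_map)) {
    v <- suppressWarnings(as.numeric(dat[[col]]))
    bad <- union(bad, which(is.na(v) & !is.na(dat[[col]])))
    dat[[col]] <- v
  }
  if (length(bad)) {
    stop("malformed rows at lines ",
         paste(head(sort(bad) + 1, 10), collapse = ", "), call. = FALSE)
  }
  dt <- diff(t)
  step <- 1 / sampling_rate
  # allow either contiguous samples or larger jumps (gaps between days);
  # reject timestamps that are irregular within a run
  irregular <- which(dt < step * (1 + tol) & abs(dt - step) > tol * step)
  if (length(irregular)) {
    stop("irregular timestamps near lines ",
         paste(head(irregular + 1, 10), collapse = ", "), call. = FALSE)
  }
  conv <- if (units == "ms2") 1 / .G else 1
  acc <- lapply(axis_map[c("vv", "ml", "ap")], function(col) dat[[col]] * conv)
  accel_recording(t, acc[[1]], acc[[2]], acc[[3]],
                  sampling_rate = sampling_rate, subject_id = subject_id)
}

#' Write a recording to CSV
#'
#' Inverse of [load_recording()] for the package's own dialect: columns
#' `timestamp, ax, ay, az` in g with `ax = vv`, `ay = ml`, `az = ap`.
#'
#' @param rec an `accel_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  readr::write_csv(
    tibble(timestamp = rec$t, ax = rec$vv, ay = rec$ml, az = rec$ap), path)
  invisible(path)
}

#' Read a diary of momentary fatigue scores
#'
#' Columns: `subject_id, timestamp, pf, mf`. Scores must be integers 0-6 or
#' missing; `timestamp` is seconds on the recording clock. The diary bin
#' (morning, early/late afternoon, evening) is derived from the time of day.
#'
#' @param path CSV path.
#' @return a tibble `subject_id, timestamp, bin, pf_score, mf_score`.
#' @export
load_pro_table <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("subject_id", "timestamp", "pf", "mf") %in% names(dat)))
  ok <- function(s) is.na(s) | (s >= 0 & s <= 6 & s == round(s))
  if (!all(ok(dat$pf) & ok(dat$mf))) {
    stop("fatigue scores must be integers in 0-6 or missing", call. = FALSE)
  }
  tibble(subject_id = as.character(dat$subject_id),
         timestamp = dat$timestamp,
         bin = pro_bin(dat$timestamp),
         pf_score = as.integer(dat$pf),
         mf_score = as.integer(dat$mf))
}

#' Write a diary table to CSV
#' @param pro tibble as returned by [load_pro_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pro_table <- function(pro, path) {
  readr::write_csv(
    tibble(subject_id = pro$subject_id, timestamp = pro$timestamp,
           pf = pro$pf_score, mf = pro$mf_score), path)
  invisible(path)
}

# diary bin from seconds-of-day: morning 09-12, early afternoon 13-16,
# late afternoon 17-20, evening 21-24
pro_bin <- function(timestamp) {
  hr <- (timestamp %% 86400) / 3600
  dplyr::case_when(
    hr >= 9 & hr < 12 ~ "morning",
    hr >= 13 & hr < 16 ~ "early_afternoon",
    hr >= 17 & hr < 20 ~ "late_afternoon",
    hr >= 21 ~ "evening",
    TRUE ~ NA_character_
  )
}

#' Correct upside-down sensor days
#'
#' The sensor is worn so that gravity gives the vertical axis a mean near
#' -1 g. For each day whose mean vertical acceleration is positive the sensor
#' was flipped, and all three axes of that day are negated (an upside-down
#' sensor inverts the vertical and anterior-posterior axes together; the
#' whole-body flip is applied for consistency). The operation is idempotent.
#'
#' @param rec an `accel_recording`.
#' @return the corrected recording, with a `flipped_days` attribute listing
#'   the day indices that were negated.
#' @export
correct_orientation <- function(rec) {
  flipped <- integer()
  for (d in unique(rec$day)) {
    idx <- which(rec$day == d & !is.na(rec$vv))
    if (!length(idx)) next
    if (mean(rec$vv[idx]) > 0) {
      sel <- rec$day == d
      rec$vv[sel] <- -rec$vv[sel]
      rec$ml[sel] <- -rec$ml[sel]
      rec$ap[sel] <- -rec$ap[sel]
      flipped <- c(flipped, d)
      message("orientation flip applied to subject ", attr(rec, "subject_id"),
              ", day ", d)
    }
  }
  attr(rec, "flipped_days") <- flipped
  rec
}
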