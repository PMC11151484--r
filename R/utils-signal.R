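# Signal-processing primitives shared by the bout and step detectors.
#
# All filters are zero-phase (forward-backward) Butterworth designs so that
# event times are not lagged by the filter; cutoffs are in Hz on signals
# sampled at `fs`.

#' Zero-phase Butterworth filter
#'
#' Applies an order-`order` digital Butterworth filter forwards and backwards
#' (`signal::filtfilt`), giving zero phase distortion. `NA` runs split the
#' signal: each contiguous non-missing segment is filtered independently and
#' missing samples stay missing, so information never leaks across a gap.
#' Segments too short for a stable forward-backward pass (shorter than six
#' filter lengths) are returned unfiltered.
#'
#' @param x numeric vector, possibly with `NA` gaps.
#' @param fs sampling rate in Hz.
#' @param cutoff_hz cutoff frequency in Hz.
#' @param order filter order.
#' @param type `"low"` or `"high"`.
#' @return filtered vector, same length and `NA` pattern as `x`.
#' @export
butter_filter <- function(x, fs, cutoff_hz, order = 2, type = "low") {
  stopifnot(fs > 0, cutoff_hz > 0, cutoff_hz < fs / 2)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = type)
  minlen <- 6 * (order + 1)
  out <- x
  for (seg in na_segments(x)) {
    idx <- seg[1]:seg[2]
    if (length(idx) >= minlen) {
      out[idx] <- signal::filtfilt(bf, x[idx])
    }
  }
  out
}

# index ranges (start, end) of maximal non-NA runs
na_segments <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  purrr::map2(starts[r$values], ends[r$values], c)
}

#' Smoothed differentiation by a Gaussian derivative wavelet
#'
#' Convolves `x` with a first-derivative-of-Gaussian kernel of width `scale`
#' samples, the continuous-wavelet-transform smoothing used by the step
#' detector. The kernel is normalised so a unit slope (per sample) maps to 1;
#' edges are handled by reflection so the output has no missing values.
#'
#' @param x numeric vector (no `NA`).
#' @param scale kernel standard deviation in samples.
#' @return the smoothed derivative of `x`, per sample.
#' @export
cwt_diff <- function(x, scale) {
  stopifnot(scale > 0, !anyNA(x))
  hw <- ceiling(4 * scale)
  n <- length(x)
  if (n < hw + 2) return(rep(0, n))
  u <- seq(-hw, hw)
  k <- (-u) * exp(-u^2 / (2 * scale^2))
  k <- k / sum(k * u)
  xp <- c(rev(x[2:(hw + 1)]), x, rev(x[(n - hw):(n - 1)]))
  y <- stats::filter(xp, rev(k), sides = 2)
  as.numeric(y[(hw + 1):(hw + n)])
}

# cumulative trapezoid integral of x sampled at fs
cum_integrate <- function(x, fs) {
  pracma::cumtrapz(seq_along(x) / fs, x)[, 1]
}

# linear detrend
detrend_linear <- function(x) {
  t <- seq_along(x)
  as.numeric(stats::lm.fit(cbind(1, t), x)$residuals)
}

# local extrema with the relative-height retention rule of the step detector:
# candidates from pracma::findpeaks on the (possibly negated) centred signal,
# retained iff height >= frac * mean(candidate heights). min_height guards
# against numerical-noise extrema on (near-)constant signals. Returns sorted
# indices.
thresholded_peaks <- function(x, frac, minima = FALSE, min_height = 1e-8) {
  xc <- x - mean(x)
  if (minima) xc <- -xc
  pk <- pracma::findpeaks(xc)
  if (is.null(pk)) return(integer())
  height <- pk[, 1]
  pk <- pk[height >= min_height, , drop = FALSE]
  if (!nrow(pk)) return(integer())
  height <- pk[, 1]
  keep <- height >= frac * mean(height)
  sort(pk[keep, 2])
}

# indices i with from_s <= t[i] < to_s, for sorted t (binary search)
time_index <- function(t, from_s, to_s) {
  a <- findInterval(from_s - 1e-9, t) + 1
  b <- findInterval(to_s - 1e-9, t)
  if (b < a) integer() else a:b
}
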