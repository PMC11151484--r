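# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_boxplot geom_line
#'   geom_rect geom_hline facet_wrap labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a per-feature association screen
#'
#' Bar chart of R-squared per feature group, significant features counted
#' twice (the group ranking rule).
#'
#' @param object a `fatigue_screen`.
#' @param r2 `"conditional"` or `"marginal"`.
#' @param ... passed to [rank_feature_groups()].
#' @return a ggplot.
#' @method autoplot fatigue_screen
#' @export
autoplot.fatigue_screen <- function(object, r2 = "conditional", ...) {
  rk <- rank_feature_groups(object, r2 = r2, ...)
  rk$group <- factor(rk$group, levels = rev(rk$group))
  ggplot(rk, aes(x = .data$rank_score, y = .data$group)) +
    geom_col(fill = "steelblue") +
    labs(x = paste(r2, "R² (significant features double-weighted)"),
         y = NULL) +
    theme_minimal()
}

#' Plot cross-validated classification accuracies
#'
#' Boxplots of per-fold balanced accuracy by classifier, dashed line at
#' chance (0.5).
#'
#' @param object a `fatigue_cv`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fatigue_cv
#' @export
autoplot.fatigue_cv <- function(object, ...) {
  ggplot(object, aes(x = .data$classifier, y = .data$balanced_accuracy)) +
    geom_boxplot(fill = "grey85") +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    facet_wrap(~scheme) +
    labs(x = NULL, y = "balanced accuracy") +
    theme_minimal()
}

#' Plot a stretch of a recording with detected walking bouts
#'
#' @param rec an [accel_recording()].
#' @param bouts optional bout tibble; walking bouts are shaded.
#' @param from_s,to_s interval to display (seconds).
#' @return a ggplot.
#' @export
plot_recording <- function(rec, bouts = NULL, from_s = min(rec$t),
                           to_s = min(rec$t) + 60) {
  d <- rec[rec$t >= from_s & rec$t <= to_s, , drop = FALSE]
  d <- tidyr::pivot_longer(as_tibble(d)[, c("t", "vv", "ml", "ap")],
                           c("vv", "ml", "ap"),
                           names_to = "axis", values_to = "acc_g")
  p <- ggplot(d, aes(x = .data$t, y = .data$acc_g, colour = .data$axis)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "acceleration (g)") +
    theme_minimal()
  if (!is.null(bouts)) {
    wb <- bouts[bouts$kind == "walking" & bouts$end_s >= from_s &
                  bouts$start_s <= to_s, , drop = FALSE]
    if (nrow(wb)) {
      p <- p + geom_rect(
        data = wb,
        aes(xmin = .data$start_s, xmax = .data$end_s),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange",
        inherit.aes = FALSE)
    }
  }
  p
}
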