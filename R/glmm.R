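# Per-feature mixed-model screening of gait-fatigue associations.
#
# Each digital gait measure is screened in its own binomial mixed model: the
# 0-6 fatigue score is treated as the number of successes out of 6 trials
# with a logit link, the standardised feature enters as the single fixed
# slope, and a subject random intercept absorbs repeated measures. The
# likelihood is maximised with adaptive Gauss-Hermite quadrature.
# Observations are weighted by the inverse frequency of their score so that
# under-represented scores are not under-predicted; weights are rescaled to
# mean 1 so the likelihood stays on the information scale of n observations
# (a constant rescale leaves the relative weighting untouched). Fit quality
# is summarised by marginal and conditional R-squared (latent-scale variance
# partition with the logistic distribution-specific variance pi^2/3).

#' Inverse-frequency score weights
#'
#' One weight per observation, `1 / count(score)` over the dataset, so each
#' score level contributes equally in total. The raw weights satisfy
#' `sum(weight * count(score)) = n`. By default they are rescaled to mean 1.
#'
#' @param scores integer scores (0-6).
#' @param normalise rescale to mean 1 (default `TRUE`).
#' @return numeric weights, one per observation.
#' @export
pro_score_weights <- function(scores, normalise = TRUE) {
  counts <- table(scores)
  w <- 1 / as.numeric(counts[as.character(scores)])
  if (normalise) w <- w * length(w) / sum(w)
  w
}

#' Marginal and conditional R-squared of a binomial-logit mixed model
#'
#' Latent-scale variance partition: with `vf` the variance of the
#' fixed-effect linear predictor, `vr` the summed random-intercept variances
#' and `vd = pi^2/3` the logistic distribution-specific variance,
#' marginal R2 = vf / (vf + vr + vd) (fixed effects only) and
#' conditional R2 = (vf + vr) / (vf + vr + vd) (fixed plus random).
#'
#' @param model a converged `glmerMod` with logit link.
#' @return named numeric `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(model) {
  eta_fixed <- predict(model, re.form = NA, type = "link")
  vf <- var(eta_fixed)
  vr <- sum(vapply(lme4::VarCorr(model), function(v) sum(diag(v)),
                   numeric(1)))
  vd <- pi^2 / 3
  tot <- vf + vr + vd
  if (tot <= 0) return(c(r2_marginal = 0, r2_conditional = 0))
  c(r2_marginal = vf / tot, r2_conditional = (vf + vr) / tot)
}

#' Fit the per-feature fatigue mixed model
#'
#' @param data tibble with the feature, score and subject columns.
#' @param feature name of the feature column (standardised internally; the
#'   slope is reported per SD of the feature).
#' @param score name of the score column (integers 0-6; `NA` rows dropped).
#' @param subject name of the subject-id column.
#' @param weighting `"inverse_frequency"` (default) or `"none"`.
#' @param nagq number of adaptive Gauss-Hermite quadrature points (10).
#' @param trials binomial trial count encoding the 0-6 scale (6).
#' @return an object of class `fatigue_glmm`: list with the `glmerMod` fit
#'   (`model`, `NULL` on failure) and a one-row `result` tibble (`feature`,
#'   `beta`, `se`, `p_value`, `r2_marginal`, `r2_conditional`, `converged`,
#'   `n_obs`, `n_subjects`).
#' @export
fit_glmm <- function(data, feature, score, subject = "subject_id",
                     weighting = c("inverse_frequency", "none"),
                     nagq = 10, trials = 6) {
  weighting <- match.arg(weighting)
  d <- tibble(y = data[[score]], x = data[[feature]],
              subj = factor(data[[subject]]))
  d <- d[!is.na(d$y) & !is.na(d$x), , drop = FALSE]
  fail <- function() {
    structure(list(
      model = NULL,
      result = tibble(feature = feature, beta = NA_real_, se = NA_real_,
                      p_value = NA_real_, r2_marginal = NA_real_,
                      r2_conditional = NA_real_, converged = FALSE,
                      n_obs = nrow(d), n_subjects = dplyr::n_distinct(d$subj))),
      class = "fatigue_glmm")
  }
  if (nrow(d) < 4 || dplyr::n_distinct(d$subj) < 2) return(fail())
  sx <- sd(d$x)
  if (!is.finite(sx) || sx == 0) return(fail())
  d$x <- (d$x - mean(d$x)) / sx
  d$w <- if (weighting == "inverse_frequency") {
    pro_score_weights(d$y)
  } else {
    rep(1, nrow(d))
  }
  warned <- FALSE
  m <- tryCatch(
    withCallingHandlers(
      lme4::glmer(cbind(y, trials - y) ~ x + (1 | subj), data = d,
                  family = stats::binomial(), weights = w, nAGQ = nagq),
      warning = function(w) {
        if (grepl("failed to converge|convergence", conditionMessage(w),
                  ignore.case = TRUE)) {
          warned <<- TRUE
        }
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(m)) return(fail())
  co <- tryCatch(stats::coef(summary(m)), error = function(e) NULL)
  if (is.null(co) || !"x" %in% rownames(co)) return(fail())
  converged <- !warned && m@optinfo$conv$opt == 0
  r2 <- if (converged) r2_nakagawa(m) else c(NA_real_, NA_real_)
  structure(list(
    model = m,
    result = tibble(feature = feature, beta = co["x", "Estimate"],
                    se = co["x", "Std. Error"],
                    p_value = co["x", "Pr(>|z|)"],
                    r2_marginal = unname(r2[1]),
                    r2_conditional = unname(r2[2]),
                    converged = converged, n_obs = nrow(d),
                    n_subjects = dplyr::n_distinct(d$subj))),
    class = "fatigue_glmm")
}

#' @export
print.fatigue_glmm <- function(x, ...) {
  cat("<fatigue_glmm>\n")
  print(x$result)
  invisible(x)
}

#' @method tidy fatigue_glmm
#' @export
tidy.fatigue_glmm <- function(x, ...) {
  dplyr::rename(x$result, term = "feature", estimate = "beta",
                std.error = "se", p.value = "p_value")[
                  , c("term", "estimate", "std.error", "p.value")]
}

#' @method glance fatigue_glmm
#' @export
glance.fatigue_glmm <- function(x, ...) {
  x$result[, c("r2_marginal", "r2_conditional", "converged", "n_obs",
               "n_subjects")]
}

#' Screen many features against one fatigue score
#'
#' Fits [fit_glmm()] for each feature and collects the per-feature results.
#'
#' @param data modelling table (e.g. from [build_dataset()] or
#'   [simulate_feature_windows()]).
#' @param features character vector of feature column names.
#' @param score score column name (`"pf_score"` or `"mf_score"`).
#' @param p_adjust multiple-testing correction applied across the screened
#'   features into a `p_adjusted` column; `"none"` (default, raw p-values
#'   only) or any method of [stats::p.adjust()] such as `"BH"`.
#' @param ... passed to [fit_glmm()].
#' @return tibble of class `fatigue_screen`, one row per feature.
#' @export
glmm_screen <- function(data, features, score, p_adjust = "none", ...) {
  out <- bind_rows(purrr::map(features,
                              ~ fit_glmm(data, .x, score, ...)$result))
  out$score <- score
  if (!identical(p_adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  class(out) <- c("fatigue_screen", class(out))
  out
}

#' Rank feature groups by mean R-squared with double-weighted significance
#'
#' The rank score of a group is the mean of its features' R-squared values
#' with statistically significant features (p < 0.05) counted twice.
#' Statistic rankings are computed the same way over pooled statistics.
#'
#' @param screen a `fatigue_screen`.
#' @param groups named character vector or tibble mapping `feature` to
#'   `group`; defaults to parsing `domain__group__measure__statistic`
#'   feature names via [feature_schema()].
#' @param r2 which R-squared to rank on (`"conditional"` or `"marginal"`).
#' @param by rank by feature `"group"` or by pooled `"statistic"`.
#' @return tibble `group` (or `statistic`), `rank_score`, `n_features`,
#'   `n_significant`, sorted best first.
#' @export
rank_feature_groups <- function(screen, groups = NULL,
                                r2 = c("conditional", "marginal"),
                                by = c("group", "statistic")) {
  r2 <- match.arg(r2)
  by <- match.arg(by)
  col <- paste0("r2_", r2)
  if (is.null(groups)) {
    sch <- feature_schema(tibble::as_tibble(setNames(
      as.list(rep(1, length(screen$feature))), screen$feature)))
    groups <- setNames(sch[[by]], sch$feature)
  } else if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$feature)
  }
  d <- screen %>%
    mutate(grp = unname(groups[.data$feature]),
           sig = !is.na(.data$p_value) & .data$p_value < 0.05) %>%
    filter(!is.na(.data[[col]]), !is.na(.data$grp))
  d %>%
    group_by(.data$grp) %>%
    summarise(
      rank_score = sum(.data[[col]] * (1 + .data$sig)) / sum(1 + .data$sig),
      n_features = dplyr::n(),
      n_significant = sum(.data$sig),
      .groups = "drop") %>%
    rename(!!by := "grp") %>%
    arrange(dplyr::desc(.data$rank_score))
}
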