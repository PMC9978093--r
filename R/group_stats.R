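## Group-level statistics on trial features: per-emotion Welch's t-tests
## between groups with Benjamini-Hochberg correction, pooled over trials
## (the analysis unit is the trial, not the participant).

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y numeric samples (each of size >= 2 with positive variance in
#'   at least one sample).
#' @return List `t, df, p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) stop("degenerate samples: zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance stars
#'
#' `"****"` p<0.0001, `"***"` p<0.001, `"**"` p<0.01, `"*"` p<0.05,
#' `"n.s."` otherwise.
#'
#' @param p numeric vector.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "n.s."), right = FALSE) |>
    as.character()
}

#' Per-emotion group summary and Welch/BH comparisons
#'
#' For every emotion and feature: group means +/- SD over kept trials, and
#' pairwise Welch's t-tests of each disorder group against the controls.
#' BH correction is applied within each feature across all emotion x
#' group-pair tests (the correction family is recorded in the output).
#' Group/emotion cells with fewer than 2 kept trials are excluded with a
#' warning.
#'
#' @param features trial feature table from [cohort_features()] (excluded
#'   trials are dropped automatically).
#' @param feature_cols features to analyse.
#' @return List: `summary` (emotion, feature, group, n_trials, mean, sd),
#'   `comparisons` (emotion, feature, pair, group means/SDs, t, df, p,
#'   p_adj, stars) and `bh_family`.
#' @export
emotion_feature_table <- function(features,
                                  feature_cols = c("fix_eyes", "fix_mouth",
                                                   "scan_path_length")) {
  if (!is.null(features$kept)) features <- features[features$kept, , drop = FALSE]
  groups <- unique(features$group)
  disorder <- setdiff(groups, "control")
  emotions <- unique(features$emotion)

  summary_rows <- list()
  comp_rows <- list()
  for (feat in feature_cols) {
    for (e in emotions) {
      sub <- features[features$emotion == e, , drop = FALSE]
      for (g in groups) {
        v <- sub[sub$group == g, feat]
        if (length(v) < 2) {
          warning("emotion '", e, "' has < 2 trials in group '", g, "'; excluded")
          next
        }
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          emotion = e, feature = feat, group = g, n_trials = length(v),
          mean = mean(v), sd = stats::sd(v),
          label = sprintf("%.2f±%.2f", mean(v), stats::sd(v)))
      }
      for (g in disorder) {
        vx <- sub[sub$group == "control", feat]
        vy <- sub[sub$group == g, feat]
        if (length(vx) < 2 || length(vy) < 2) next
        wt <- welch_t(vx, vy)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          emotion = e, feature = feat, pair = paste0("control-", g),
          mean_control = mean(vx), sd_control = stats::sd(vx),
          mean_group = mean(vy), sd_group = stats::sd(vy),
          t = wt$t, df = wt$df, p = wt$p)
      }
    }
  }
  comparisons <- do.call(rbind, comp_rows)
  comparisons$p_adj <- NA_real_
  for (feat in feature_cols) {
    sel <- comparisons$feature == feat
    comparisons$p_adj[sel] <- bh_adjust(comparisons$p[sel])
  }
  comparisons$stars <- significance_stars(comparisons$p_adj)
  list(summary = do.call(rbind, summary_rows),
       comparisons = comparisons,
       bh_family = "within feature, across all emotion x group-pair tests")
}
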