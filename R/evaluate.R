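## Nested leave-one-participant-out evaluation of the pipeline variants and
## the confusion/binomial reporting. Disorder = positive class, control =
## negative.

#' Restrict a cohort to a subset of groups
#' @param cohort a `gaze_cohort`.
#' @param groups group labels to keep (e.g. `c("control", "ASD")`).
#' @return A `gaze_cohort` with only those participants.
#' @export
subset_cohort <- function(cohort, groups) {
  keep <- cohort$manifest$group %in% groups
  manifest <- cohort$manifest[keep, , drop = FALSE]
  structure(list(manifest = manifest,
                 trials = cohort$trials[manifest$trial_id],
                 population = cohort$population, config = cohort$config),
            class = "gaze_cohort")
}

.binary_labels <- function(group) as.integer(group != "control")

#' Nested leave-one-participant-out evaluation
#'
#' For each fold one participant is held out; every fitted component --
#' feature scaling, learning-rate selection, the trial classifier and the
#' weighting forest -- sees only the remaining participants. The held-out
#' participant's trials are classified, aggregated by hard voting and by
#' the weighting forest, and recorded. Folds are seed-controlled and
#' independent.
#'
#' @param cohort a two-group `gaze_cohort`.
#' @param variant `"baseline"` (3-feature MLP) or `"cnn"` (heat-map CNN).
#' @param cfg a [train_config()].
#' @param forest_mode how the first-stage predictions that the weighting
#'   forest trains on are produced. `"oof_kfold"` (default): inner k-fold
#'   out-of-fold predictions by participant, so the forest's training rows
#'   have the same (out-of-sample) distribution as the held-out row it
#'   scores -- training on in-sample rows makes the forest calibrate to
#'   memorization-inflated prediction rates and biases it on weak-signal
#'   data. `"insample"`: the trial model predicts its own training
#'   participants. `"oof"`: full inner leave-one-participant-out (slowest).
#' @param oof_k number of inner folds for `"oof_kfold"`.
#' @param event_cfg,geom,hm_cfg stage configurations.
#' @param features,inputs optional precomputed [cohort_features()] /
#'   [cohort_model_inputs()] results (recomputed when `NULL`).
#' @return A `lopo_result`: `predictions` data frame (`participant_id,
#'   group, y_true, pred_hard, pred_forest, fold_failed`), per-fold
#'   `forests`, `fold_train_participants` (leakage audit trail) and the
#'   `variant`.
#' @export
nested_lopo <- function(cohort, variant = c("baseline", "cnn"),
                        cfg = train_config(),
                        forest_mode = c("oof_kfold", "insample", "oof"),
                        oof_k = 5L,
                        balance_folds = TRUE,
                        event_cfg = event_config(), geom = display_geometry(),
                        hm_cfg = heatmap_config(),
                        features = NULL, inputs = NULL) {
  variant <- match.arg(variant)
  forest_mode <- match.arg(forest_mode)
  manifest <- cohort$manifest
  groups <- unique(manifest$group)
  if (length(groups) != 2) stop("nested_lopo evaluates pairwise problems; got groups: ",
                                paste(groups, collapse = ", "))
  participants <- unique(manifest$participant_id)
  if (length(participants) < 3) stop("need >= 3 participants")
  plab <- .binary_labels(manifest$group[match(participants, manifest$participant_id)])
  if (length(unique(plab)) < 2) stop("both classes required")

  if (is.null(features)) features <- cohort_features(cohort, event_cfg, geom)
  cnn_arch <- NULL
  cols1_all <- NULL
  if (variant == "cnn") {
    if (is.null(inputs)) inputs <- cohort_model_inputs(cohort, hm_cfg)
    cnn_arch <- arch_config("cnn", input_side = inputs$config$output_size)
    cols1_all <- cpp_im2col(inputs$x, cnn_arch$C0, cnn_arch$S0, cnn_arch$S0,
                            cnn_arch$K, cnn_arch$K)
  }
  trial_pid <- features$participant_id
  trial_y <- .binary_labels(features$group)

  preds <- vector("list", length(participants))
  forests <- vector("list", length(participants))
  audits <- vector("list", length(participants))
  for (fi in seq_along(participants)) {
    p <- participants[fi]
    pool <- setdiff(participants, p)
    if (balance_folds) {
      ## subsample both classes to the same fixed size (smallest class minus
      ## one) so every fold's training pool has identical class composition
      ## and size regardless of the held-out participant's class; otherwise
      ## the fold-to-fold composition difference tilts the trial model's
      ## collapsed prior and the vote amplifies that tilt into a
      ## participant-level bias anti-correlated with the held-out label
      pl <- plab[match(pool, participants)]
      m <- min(table(factor(plab, levels = c(0, 1)))) - 1L
      if (m >= 1) {
        old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        set.seed(cfg$seed + 7919L * fi)
        pool <- unlist(lapply(c(0, 1), function(cl) {
          ids <- pool[pl == cl]
          if (length(ids) > m) sample(ids, m) else ids
        }))
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      }
    }
    tr <- trial_pid %in% pool
    fold <- list(participant_id = p,
                 y_true = plab[fi], pred_hard = NA_integer_,
                 pred_forest = NA_integer_, fold_failed = FALSE)
    if (length(unique(trial_y[tr])) < 2) {
      fold$fold_failed <- TRUE
    } else {
      fold_cfg <- cfg
      fold_cfg$seed <- cfg$seed + fi  # independent, reproducible folds
      if (variant == "baseline") {
        tr_kept <- tr & features$kept
        scaler <- fit_feature_scaler(features[tr_kept, , drop = FALSE])
        x_tr <- featurize_baseline(features[tr_kept, , drop = FALSE], scaler)
        model <- train_trial_model(x_tr, trial_y[tr_kept], trial_pid[tr_kept],
                                   arch_config("baseline"), fold_cfg)
        x_all <- featurize_baseline(features[c("fix_total", "n_saccades",
                                               "scan_path_length")], scaler)
      } else {
        model <- train_trial_model(inputs$x[, tr, drop = FALSE], trial_y[tr],
                                   trial_pid[tr], cnn_arch, fold_cfg,
                                   cols1 = .slice_cols1(cols1_all, which(tr),
                                                        cnn_arch$H1^2))
        x_all <- inputs$x
      }
      trial_pred <- if (variant == "cnn") {
        predict_trials(model, x_all, cols1 = cols1_all)
      } else {
        predict_trials(model, x_all)
      }
      pred_df <- data.frame(participant_id = trial_pid, face = features$face,
                            pred = trial_pred)
      if (forest_mode == "oof") {
        pred_df <- .oof_train_predictions(cohort, variant, fold_cfg, features,
                                          inputs, p, pred_df, pool)
      } else if (forest_mode == "oof_kfold") {
        pred_df <- .oof_kfold_predictions(cohort, variant, fold_cfg, features,
                                          inputs, p, pred_df, pool,
                                          k = oof_k,
                                          cols1_all = cols1_all,
                                          cnn_arch = cnn_arch)
      }
      vec_all <- prediction_vectors(pred_df, cohort$population)
      forest <- fit_weighting_forest(vec_all[pool, , drop = FALSE],
                                     plab[match(pool, participants)],
                                     seed = fold_cfg$seed)
      fold$pred_hard <- hard_vote(vec_all[p, ])
      fold$pred_forest <- predict_participant(forest, vec_all[p, ])
      forests[[fi]] <- forest
    }
    preds[[fi]] <- as.data.frame(fold)
    audits[[fi]] <- pool
  }
  predictions <- do.call(rbind, preds)
  predictions$group <- manifest$group[match(predictions$participant_id,
                                            manifest$participant_id)]
  structure(list(predictions = predictions,
                 forests = forests[!vapply(forests, is.null, logical(1))],
                 fold_train_participants = stats::setNames(audits, participants),
                 variant = variant),
            class = "lopo_result")
}

## inner k-fold out-of-fold first-stage predictions: pool participants are
## partitioned (stratified by class) into k groups; each group's trials are
## predicted by a model trained on the remaining groups
.oof_kfold_predictions <- function(cohort, variant, cfg, features, inputs,
                                   held_out, pred_df, pool, k = 5L,
                                   cols1_all = NULL, cnn_arch = NULL) {
  trial_pid <- features$participant_id
  trial_y <- .binary_labels(features$group)
  plab <- trial_y[match(pool, trial_pid)]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed + 104729L)
  grp <- integer(length(pool))
  for (cl in unique(plab)) {
    idx <- which(plab == cl)
    grp[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  for (g in seq_len(k)) {
    hold <- pool[grp == g]
    rest <- pool[grp != g]
    tr <- trial_pid %in% rest
    te <- trial_pid %in% hold
    if (!length(hold) || length(rest) < 2 ||
        length(unique(trial_y[tr])) < 2) next
    inner_cfg <- cfg
    inner_cfg$seed <- cfg$seed + 31L * g
    if (variant == "baseline") {
      tr_kept <- tr & features$kept
      scaler <- fit_feature_scaler(features[tr_kept, , drop = FALSE])
      x_tr <- featurize_baseline(features[tr_kept, , drop = FALSE], scaler)
      m <- train_trial_model(x_tr, trial_y[tr_kept], trial_pid[tr_kept],
                             arch_config("baseline"), inner_cfg)
      x_te <- featurize_baseline(features[te, c("fix_total", "n_saccades",
                                                "scan_path_length")], scaler)
      pred_df$pred[te] <- predict_trials(m, x_te)
    } else {
      m <- train_trial_model(inputs$x[, tr, drop = FALSE], trial_y[tr],
                             trial_pid[tr], cnn_arch, inner_cfg,
                             cols1 = .slice_cols1(cols1_all, which(tr),
                                                  cnn_arch$H1^2))
      pred_df$pred[te] <- predict_trials(m, inputs$x[, te, drop = FALSE],
                                         cols1 = .slice_cols1(cols1_all,
                                                              which(te),
                                                              cnn_arch$H1^2))
    }
  }
  pred_df
}

## out-of-fold first-stage predictions for the forest's training rows: each
## training participant's trials are predicted by a model that excluded them
.oof_train_predictions <- function(cohort, variant, cfg, features, inputs,
                                   held_out, pred_df, pool) {
  trial_pid <- features$participant_id
  trial_y <- .binary_labels(features$group)
  for (q in pool) {
    tr <- trial_pid %in% setdiff(pool, q)
    if (length(unique(trial_y[tr])) < 2) next
    if (variant == "baseline") {
      tr_kept <- tr & features$kept
      scaler <- fit_feature_scaler(features[tr_kept, , drop = FALSE])
      x_tr <- featurize_baseline(features[tr_kept, , drop = FALSE], scaler)
      m <- train_trial_model(x_tr, trial_y[tr_kept], trial_pid[tr_kept],
                             arch_config("baseline"), cfg)
      x_q <- featurize_baseline(features[trial_pid == q,
                                         c("fix_total", "n_saccades",
                                           "scan_path_length")], scaler)
    } else {
      m <- train_trial_model(inputs$x[, tr, drop = FALSE], trial_y[tr],
                             trial_pid[tr], arch_config("cnn"), cfg)
      x_q <- inputs$x[, trial_pid == q, drop = FALSE]
    }
    pred_df$pred[pred_df$participant_id == q] <- predict_trials(m, x_q)
  }
  pred_df
}

#' Confusion counts from per-participant predictions
#'
#' Disorder is the positive class. Failed folds (`NA` predictions) are
#' counted as errors so totals always reconcile.
#'
#' @param y_true,y_pred 0/1 vectors (`y_pred` may contain `NA`).
#' @return List with integer `TP, TN, FP, FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  err <- is.na(y_pred)
  y_pred[err] <- 1L - y_true[err]  # a failed fold is a guaranteed error
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Exact rational evaluation: accuracy = (TP+TN)/(TP+FP+TN+FN),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). A zero denominator
#' yields `NA` for that metric.
#'
#' @param counts list with `TP, TN, FP, FN`.
#' @return List `accuracy, sensitivity, specificity, n`.
#' @export
confusion_metrics <- function(counts) {
  with(counts, {
    n <- TP + TN + FP + FN
    list(accuracy = if (n > 0) (TP + TN) / n else NA_real_,
         sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
         specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
         n = n)
  })
}

#' Exact binomial test against a chance rate
#'
#' Exact tail probabilities of `Binomial(n_total, chance_rate)`. Two-sided
#' p-values double the smaller tail (capped at 1).
#'
#' @param n_correct,n_total correct count and total.
#' @param chance_rate chance success probability (default 0.5; the
#'   majority-class rate is a common alternative).
#' @param sidedness `"two.sided"` or `"greater"`.
#' @return The p-value.
#' @export
binomial_vs_chance <- function(n_correct, n_total, chance_rate = 0.5,
                               sidedness = c("two.sided", "greater")) {
  sidedness <- match.arg(sidedness)
  if (n_total < 1 || n_correct < 0 || n_correct > n_total ||
      chance_rate <= 0 || chance_rate >= 1) {
    stop("invalid binomial test inputs")
  }
  upper <- stats::pbinom(n_correct - 1, n_total, chance_rate, lower.tail = FALSE)
  if (sidedness == "greater") return(upper)
  lower <- stats::pbinom(n_correct, n_total, chance_rate)
  min(1, 2 * min(lower, upper))
}

#' Metrics report for a LOPO run
#'
#' @param result a [nested_lopo()] result.
#' @param aggregation `"forest"` or `"hard"`.
#' @param chance_rate chance rate for the binomial test.
#' @return List with the confusion `counts`, `accuracy`, `sensitivity`,
#'   `specificity`, `binomial_p` and the per-participant prediction table.
#' @export
metrics_report <- function(result, aggregation = c("forest", "hard"),
                           chance_rate = 0.5) {
  aggregation <- match.arg(aggregation)
  pred <- result$predictions
  y_pred <- if (aggregation == "forest") pred$pred_forest else pred$pred_hard
  counts <- confusion_counts(pred$y_true, y_pred)
  m <- confusion_metrics(counts)
  n_correct <- counts$TP + counts$TN
  c(list(counts = counts), m,
    list(binomial_p = binomial_vs_chance(n_correct, m$n, chance_rate),
         predictions = pred))
}
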