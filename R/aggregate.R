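## Participant-level aggregation of per-trial predictions: majority (hard)
## voting, and the weighted alternative -- a random forest over the ordered
## per-stimulus prediction vector, which implicitly weights stimuli
## (emotions) by their diagnostic informativeness.

#' Hard (majority) vote over a participant's trial predictions
#'
#' Ties -- possible only for even-length vectors (the 32-trial child set) --
#' go to the positive (disorder) class.
#'
#' @param v complete integer 0/1 vector of per-trial predictions.
#' @return 0 or 1.
#' @export
hard_vote <- function(v) {
  if (anyNA(v)) stop("prediction vector has missing entries")
  as.integer(sum(v) * 2 >= length(v))
}

#' Build per-participant prediction vectors ordered by face number
#'
#' @param predictions data frame with `participant_id`, `face` and `pred`
#'   (0/1) columns, one row per trial.
#' @param population `"adult"` or `"child"` (fixes vector length and order).
#' @return Matrix, rows = participants, columns = faces in ascending face
#'   number (`face_1` ...); error if any participant's vector is
#'   incomplete.
#' @export
prediction_vectors <- function(predictions, population) {
  faces <- sort(face_emotion_map(population)$face)
  pids <- unique(predictions$participant_id)
  m <- matrix(NA_integer_, length(pids), length(faces),
              dimnames = list(pids, paste0("face_", faces)))
  idx <- cbind(match(predictions$participant_id, pids),
               match(predictions$face, faces))
  m[idx] <- predictions$pred
  if (anyNA(m)) stop("incomplete prediction vectors (missing faces)")
  m
}

#' Fit the stimulus-weighting random forest
#'
#' A random forest (500 trees, Gini impurity, unlimited depth, seeded) over
#' the participants x faces matrix of binary trial predictions, with the
#' participant diagnosis as target. When every feature is constant the
#' forest cannot split and the model degrades to a majority-class rule.
#'
#' @param vectors matrix from [prediction_vectors()].
#' @param labels 0/1 participant labels (1 = disorder); both classes must
#'   be present.
#' @param ntree number of trees.
#' @param seed RNG seed for the forest.
#' @return A `weighting_forest` with normalized per-face `importance`
#'   (sums to 1).
#' @export
fit_weighting_forest <- function(vectors, labels, ntree = 500L, seed = 42L) {
  stopifnot(nrow(vectors) == length(labels))
  if (nrow(vectors) < 2) stop("need >= 2 training participants")
  if (length(unique(labels)) < 2) stop("training labels contain a single class")
  y <- factor(labels, levels = c(0, 1))
  constant <- all(apply(vectors, 2, function(col) length(unique(col)) == 1))
  if (constant) {
    maj <- as.integer(sum(labels) * 2 >= length(labels))
    imp <- rep(1 / ncol(vectors), ncol(vectors))
    names(imp) <- colnames(vectors)
    return(structure(list(rf = NULL, fallback = maj, importance = imp,
                          faces = colnames(vectors)),
                     class = "weighting_forest"))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  ## balanced stratified bootstrap: leave-one-out folds are imbalanced in
  ## the direction opposite to the held-out class, and an unbalanced
  ## bootstrap would bias the forest toward the fold's majority class
  m <- min(table(y))
  rf <- randomForest::randomForest(x = as.data.frame(vectors), y = y,
                                   ntree = ntree, strata = y,
                                   sampsize = c(m, m))
  imp <- rf$importance[, "MeanDecreaseGini"]
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  names(imp) <- colnames(vectors)
  structure(list(rf = rf, fallback = NULL, importance = imp,
                 faces = colnames(vectors)),
            class = "weighting_forest")
}

#' Participant-level prediction from the weighting forest
#'
#' @param forest a [fit_weighting_forest()] model.
#' @param v complete 0/1 vector (or 1-row matrix) ordered by face number.
#' @return 0 or 1.
#' @export
predict_participant <- function(forest, v) {
  v <- matrix(as.numeric(v), nrow = 1)
  if (ncol(v) != length(forest$faces)) stop("prediction vector length mismatch")
  if (!is.null(forest$fallback)) return(forest$fallback)
  colnames(v) <- forest$faces
  as.integer(as.character(stats::predict(forest$rf, as.data.frame(v))))
}

#' Average forest importances across cross-validation folds
#'
#' Arithmetic per-face mean of the normalized importances of the per-fold
#' forests, annotated with each face's presented emotion.
#'
#' @param forests list of `weighting_forest` objects (or numeric importance
#'   vectors) with identical face sets.
#' @param population `"adult"` or `"child"`.
#' @return Data frame `face, emotion, mean_importance` (importances sum
#'   to 1), ordered by face number.
#' @export
average_importances <- function(forests, population) {
  stopifnot(length(forests) >= 1)
  imps <- lapply(forests, function(f) if (inherits(f, "weighting_forest")) f$importance else f)
  len <- unique(vapply(imps, length, integer(1)))
  if (length(len) != 1) stop("inconsistent importance lengths across folds")
  mean_imp <- Reduce(`+`, imps) / length(imps)
  fmap <- face_emotion_map(population)
  if (nrow(fmap) != len) stop("importance length does not match the stimulus set")
  data.frame(face = fmap$face,
             emotion = fmap$emotion,
             mean_importance = as.numeric(mean_imp))
}
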