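#' I-VT event detection configuration
#'
#' @param velocity_threshold_deg_s saccade threshold; samples whose
#'   point-to-point angular velocity *strictly exceeds* this value are
#'   labelled saccades, all others fixations (100 deg/s default).
#' @param max_gap_interpolation_ms velocity is computed across invalid-sample
#'   gaps no longer than this; longer gaps break the trace (75 ms default,
#'   the vendor-typical value).
#' @return An `event_config` list.
#' @export
event_config <- function(velocity_threshold_deg_s = 100,
                         max_gap_interpolation_ms = 75) {
  stopifnot(velocity_threshold_deg_s > 0, max_gap_interpolation_ms >= 0)
  structure(list(velocity_threshold_deg_s = velocity_threshold_deg_s,
                 max_gap_interpolation_ms = max_gap_interpolation_ms),
            class = "event_config")
}

#' Cyclopean gaze points from a binocular sample table
#'
#' Combines the two eyes into one gaze point per sample: the mean of both
#' eyes when both are valid, the valid eye when only one is, and `NA` when
#' neither eye was detected.
#'
#' @param trial data frame with columns `lx, ly, rx, ry, lvalid, rvalid`
#'   (normalized coordinates, logical validity flags).
#' @return An n x 2 matrix of points; rows are `NA` for invalid samples.
#' @export
cyclopean_points <- function(trial) {
  lv <- as.logical(trial$lvalid)
  rv <- as.logical(trial$rvalid)
  n <- nrow(trial)
  x <- rep(NA_real_, n)
  y <- rep(NA_real_, n)
  both <- lv & rv
  x[both] <- (trial$lx[both] + trial$rx[both]) / 2
  y[both] <- (trial$ly[both] + trial$ry[both]) / 2
  lo <- lv & !rv
  x[lo] <- trial$lx[lo]; y[lo] <- trial$ly[lo]
  ro <- rv & !lv
  x[ro] <- trial$rx[ro]; y[ro] <- trial$ry[ro]
  cbind(x = x, y = y)
}

## per-sample angular velocity vs. the previous valid sample within the
## bridging gap; NA where undefined (invalid sample, first of a broken run)
.sample_velocities <- function(points, t_ms, config, geom) {
  n <- nrow(points)
  valid <- !is.na(points[, 1])
  vel <- rep(NA_real_, n)
  vi <- which(valid)
  if (length(vi) >= 2) {
    a <- vi[-length(vi)]
    b <- vi[-1]
    dt <- (t_ms[b] - t_ms[a]) / 1000
    ok <- (t_ms[b] - t_ms[a]) <= config$max_gap_interpolation_ms & dt > 0
    if (any(ok)) {
      vel[b[ok]] <- angular_velocity(points[a[ok], , drop = FALSE],
                                     points[b[ok], , drop = FALSE],
                                     dt[ok], geom)
    }
  }
  vel
}

#' I-VT classification of gaze samples
#'
#' Velocity-Threshold Identification: each valid sample is labelled
#' `"saccade"` if its angular velocity relative to the previous valid sample
#' (within the gap-bridging window) strictly exceeds the threshold, and
#' `"fixation"` otherwise. Samples with no gaze point are `"invalid"`. Valid
#' samples with no defined velocity (the first of the trace or the first
#' after a long gap) inherit the label of the next labelled sample, so a
#' fixation that opens the trial is counted from its first sample.
#'
#' @param points n x 2 matrix of cyclopean points (`NA` rows = invalid).
#' @param t_ms sample timestamps in ms, strictly increasing.
#' @param config an [event_config()].
#' @param geom a [display_geometry()].
#' @return Character vector of per-sample labels in
#'   `{"fixation", "saccade", "invalid"}`.
#' @export
classify_events_ivt <- function(points, t_ms, config = event_config(),
                                geom = display_geometry()) {
  n <- nrow(points)
  if (n == 0) stop("empty sample sequence")
  if (n >= 2 && any(diff(t_ms) <= 0)) stop("timestamps must be strictly increasing")
  labels <- rep("invalid", n)
  valid <- !is.na(points[, 1])
  vel <- .sample_velocities(points, t_ms, config, geom)
  defined <- valid & !is.na(vel)
  labels[defined] <- ifelse(vel[defined] > config$velocity_threshold_deg_s,
                            "saccade", "fixation")
  ## backward-fill labels onto valid samples with undefined velocity
  pending <- which(valid & !defined)
  if (length(pending)) {
    nxt <- rep("fixation", n)  # default when no labelled successor exists
    last <- "fixation"
    for (i in n:1) {
      if (defined[i]) last <- labels[i]
      nxt[i] <- last
    }
    labels[pending] <- nxt[pending]
  }
  labels
}

#' Count fixation-labelled samples inside an AOI polygon
#'
#' Boundary points count as inside (deterministic tie rule). The count is a
#' *sample* count: at 120 Hz over 5 s trials the per-AOI magnitudes are on
#' the 0-600 scale.
#'
#' @param labels per-sample labels from [classify_events_ivt()].
#' @param points n x 2 point matrix aligned with `labels`.
#' @param aoi polygon as a k x 2 matrix of normalized vertices (any
#'   orientation; need not be closed).
#' @return Integer count.
#' @export
count_fixation_samples_in_aoi <- function(labels, points, aoi) {
  stopifnot(length(labels) == nrow(points))
  sel <- labels == "fixation" & !is.na(points[, 1])
  if (!any(sel)) return(0L)
  sum(.points_in_polygon(points[sel, 1], points[sel, 2], aoi))
}

## boundary-inclusive point-in-polygon; axis-aligned rectangles (the common
## AOI shape) short-circuit to a bbox test, anything else goes to pracma
.points_in_polygon <- function(x, y, poly) {
  ux <- unique(poly[, 1]); uy <- unique(poly[, 2])
  if (nrow(poly) == 4 && length(ux) == 2 && length(uy) == 2) {
    return(x >= min(ux) & x <= max(ux) & y >= min(uy) & y <= max(uy))
  }
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

#' Count saccade events
#'
#' A saccade event is a maximal contiguous run of saccade-labelled samples.
#'
#' @param labels per-sample labels.
#' @return Integer number of runs.
#' @export
count_saccades <- function(labels) {
  r <- rle(labels)
  sum(r$values == "saccade")
}

#' Scan-path length of a trial
#'
#' Mean Euclidean gaze displacement per consecutive valid sample pair, in
#' normalized screen units: distances are accumulated over pairs of
#' *consecutive* samples that are both valid (an invalid sample breaks the
#' chain) and divided by the number of such pairs. Returns 0 when no valid
#' pair exists.
#'
#' @param points n x 2 matrix of gaze points (`NA` rows = invalid).
#' @return Non-negative scalar.
#' @export
scan_path_length <- function(points) {
  if (nrow(points) == 0) stop("empty sample sequence")
  v <- !is.na(points[, 1])
  if (nrow(points) < 2) return(0)
  pair <- v[-length(v)] & v[-1]
  if (!any(pair)) return(0)
  dx <- diff(points[, 1])[pair]
  dy <- diff(points[, 2])[pair]
  sum(sqrt(dx^2 + dy^2)) / sum(pair)
}

#' Trial-level gaze features
#'
#' Runs the full event stage on one trial: cyclopean combination, I-VT
#' labelling, AOI fixation-sample counts, saccade count, scan-path length
#' and the valid-sample fraction.
#'
#' @param trial gaze sample data frame (`t_ms, lx, ly, rx, ry, lvalid,
#'   rvalid`).
#' @param aoi named list of AOI polygons (`eyes`, `nose`, `mouth`), each a
#'   k x 2 matrix in normalized coordinates.
#' @param config an [event_config()].
#' @param geom a [display_geometry()].
#' @return A one-row data frame with columns `fix_eyes, fix_nose, fix_mouth,
#'   fix_total, n_saccades, scan_path_length, valid_fraction`.
#' @export
trial_features <- function(trial, aoi, config = event_config(),
                           geom = display_geometry()) {
  pts <- cyclopean_points(trial)
  labels <- classify_events_ivt(pts, trial$t_ms, config, geom)
  counts <- vapply(aoi[c("eyes", "nose", "mouth")], function(poly) {
    as.integer(count_fixation_samples_in_aoi(labels, pts, poly))
  }, integer(1))
  data.frame(fix_eyes = counts[["eyes"]],
             fix_nose = counts[["nose"]],
             fix_mouth = counts[["mouth"]],
             fix_total = sum(labels == "fixation"),
             n_saccades = count_saccades(labels),
             scan_path_length = scan_path_length(pts),
             valid_fraction = mean(!is.na(pts[, 1])))
}

#' Trial validity filter
#'
#' A trial is kept iff its scan-path length is strictly positive (a zero
#' scan path means the gaze never moved, i.e. tracking failed or the
#' participant used peripheral vision) and at least 40% of its gaze samples
#' are valid.
#'
#' @param features data frame with `scan_path_length` and `valid_fraction`
#'   columns (one row per trial).
#' @param min_valid_fraction retention threshold, default 0.40.
#' @return `features` with added logical column `kept` and character column
#'   `exclusion_reason` (`NA` for kept trials; `"valid_fraction"` or
#'   `"scan_path_length"` otherwise, validity checked first).
#' @export
filter_trials <- function(features, min_valid_fraction = 0.40) {
  reason <- rep(NA_character_, nrow(features))
  low_valid <- features$valid_fraction < min_valid_fraction
  zero_path <- features$scan_path_length <= 0
  reason[zero_path] <- "scan_path_length"
  reason[low_valid] <- "valid_fraction"
  features$kept <- !(low_valid | zero_path)
  features$exclusion_reason <- reason
  features
}
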