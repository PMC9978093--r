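## Synthetic gaze-cohort generator.
##
## Gaze is modelled as a two-state process over AOI anchors: fixation epochs
## (isotropic Gaussian jitter about an anchor inside an AOI, truncated to the
## display) alternate with saccadic relocations occurring independently per
## sample pair at the configured rate. A relocation draws its destination
## AOI from the profile's dwell distribution; a relocation within the same
## AOI is a ballistic step of Rayleigh-distributed length (mean =
## `saccade_amplitude`) reflected into the AOI rectangle, while a relocation
## to a different AOI lands uniformly inside it. Samples are invalidated
## i.i.d. at `invalid_sample_rate` (both eyes lost); otherwise one eye is
## occasionally lost on its own.

.DWELL_REGIONS <- c("eyes", "nose", "mouth", "other")

.check_rate_field <- function(x, name, emotions, lo = 0, hi = Inf) {
  if (is.null(names(x))) {
    if (length(x) != 1) stop(name, " must be a scalar or per-emotion named vector")
    x <- stats::setNames(rep(as.numeric(x), length(emotions)), emotions)
  } else {
    if (!all(emotions %in% names(x))) {
      stop(name, " is missing emotions: ",
           paste(setdiff(emotions, names(x)), collapse = ", "))
    }
    x <- x[emotions]
  }
  if (any(x < lo | x > hi)) stop(name, " out of range [", lo, ", ", hi, "]")
  x
}

#' Group-level gaze-generating profile
#'
#' Parameters of the generative gaze model for one participant group.
#' `fixation_jitter_sd`, `saccades_per_second` and `invalid_sample_rate`
#' may be scalars or per-emotion named vectors, so group contrasts can be
#' confined to specific emotions.
#'
#' @param group_label `"control"`, `"ASD"` or `"Sz"`.
#' @param per_emotion_dwell named list: emotion -> named numeric over
#'   `eyes, nose, mouth, other`, each summing to 1 (tolerance 1e-9).
#' @param fixation_jitter_sd per-sample Gaussian jitter SD about the
#'   fixation anchor, in normalized screen units.
#' @param saccades_per_second expected relocation rate (>= 0).
#' @param saccade_amplitude mean length of within-AOI relocations,
#'   normalized units.
#' @param invalid_sample_rate probability a sample loses both eyes.
#' @return A `gaze_profile` object.
#' @export
gaze_profile <- function(group_label,
                         per_emotion_dwell,
                         fixation_jitter_sd,
                         saccades_per_second,
                         saccade_amplitude,
                         invalid_sample_rate) {
  stopifnot(group_label %in% c("control", "ASD", "Sz"))
  emotions <- names(per_emotion_dwell)
  if (is.null(emotions) || !length(emotions)) stop("per_emotion_dwell must be a named list")
  per_emotion_dwell <- lapply(per_emotion_dwell, function(d) {
    if (!all(.DWELL_REGIONS %in% names(d))) {
      stop("dwell must name regions: ", paste(.DWELL_REGIONS, collapse = ", "))
    }
    d <- d[.DWELL_REGIONS]
    if (any(d < 0)) stop("dwell fractions must be non-negative")
    if (abs(sum(d) - 1) > 1e-9) stop("dwell fractions must sum to 1 (got ", sum(d), ")")
    d
  })
  structure(list(
    group_label = group_label,
    per_emotion_dwell = per_emotion_dwell,
    fixation_jitter_sd = .check_rate_field(fixation_jitter_sd, "fixation_jitter_sd", emotions),
    saccades_per_second = .check_rate_field(saccades_per_second, "saccades_per_second", emotions),
    saccade_amplitude = as.numeric(saccade_amplitude),
    invalid_sample_rate = .check_rate_field(invalid_sample_rate, "invalid_sample_rate", emotions, 0, 1)
  ), class = "gaze_profile")
}

#' Cohort simulation configuration
#'
#' @param groups named list `group_label -> list(profile =, n =)` giving the
#'   generating profile and participant count per group.
#' @param population `"adult"` (21 trials, 7 emotions) or `"child"`
#'   (32 trials, 4 emotions).
#' @param sampling_rate_hz,trial_duration_s recording geometry; the product
#'   must equal 600 samples at the defaults.
#' @param display `(width, height)` in pixels.
#' @param seed integer master seed; the cohort is a pure function of the
#'   config including this seed.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(groups, population = c("adult", "child"),
                          sampling_rate_hz = 120, trial_duration_s = 5,
                          display = c(1920L, 1080L), seed = 1L) {
  population <- match.arg(population)
  emotions <- population_emotions(population)
  trials <- nrow(face_emotion_map(population))
  if (trials %% length(emotions) != 0) {
    stop("trials_per_participant must be divisible by the number of emotions")
  }
  for (g in groups) {
    stopifnot(inherits(g$profile, "gaze_profile"), g$n >= 1)
    missing_e <- setdiff(emotions, names(g$profile$per_emotion_dwell))
    if (length(missing_e)) {
      stop("profile for ", g$profile$group_label,
           " lacks dwell for: ", paste(missing_e, collapse = ", "))
    }
  }
  structure(list(groups = groups, population = population,
                 emotions = emotions, trials_per_participant = trials,
                 sampling_rate_hz = sampling_rate_hz,
                 trial_duration_s = trial_duration_s,
                 n_samples = as.integer(round(sampling_rate_hz * trial_duration_s)),
                 display = as.integer(display), seed = as.integer(seed)),
            class = "cohort_config")
}

## uniform point(s) inside an axis-aligned AOI rectangle (from its bbox)
.aoi_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
    ymin = min(poly[, 2]), ymax = max(poly[, 2]))
}

.runif_in <- function(bb) {
  c(stats::runif(1, bb["xmin"], bb["xmax"]), stats::runif(1, bb["ymin"], bb["ymax"]))
}

## reflect a point into [lo, hi] (single bounce is enough at our step sizes)
.reflect1 <- function(v, lo, hi) {
  if (v < lo) v <- lo + (lo - v)
  if (v > hi) v <- hi - (v - hi)
  min(max(v, lo), hi)
}

#' Simulate one gaze trial
#'
#' @param profile a [gaze_profile()].
#' @param emotion emotion label; must be present in the profile's dwell map.
#' @param aoi named list of AOI polygons for the presented stimulus
#'   (`eyes`, `nose`, `mouth`); the `other` region is the full display.
#' @param config a [cohort_config()].
#' @param seed integer; identical seeds give bit-identical trials.
#' @return Gaze sample data frame with columns
#'   `t_ms, lx, ly, rx, ry, lvalid, rvalid`.
#' @export
simulate_trial <- function(profile, emotion, aoi, config, seed) {
  dwell <- profile$per_emotion_dwell[[emotion]]
  if (is.null(dwell)) stop("profile has no dwell fractions for emotion '", emotion, "'")
  n <- config$n_samples
  dt <- 1 / config$sampling_rate_hz
  jitter_sd <- profile$fixation_jitter_sd[[emotion]]
  lambda <- profile$saccades_per_second[[emotion]]
  q <- profile$invalid_sample_rate[[emotion]]
  amp <- profile$saccade_amplitude

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  bbs <- lapply(aoi, .aoi_bbox)
  bbs$other <- c(xmin = 0, xmax = 1, ymin = 0, ymax = 1)
  regions <- .DWELL_REGIONS

  ## anchor process
  pos <- matrix(0, n, 2)
  region <- sample(regions, 1, prob = dwell)
  anchor <- .runif_in(bbs[[region]])
  p_jump <- min(1, lambda * dt)
  jump <- c(FALSE, stats::runif(n - 1) < p_jump)
  for (i in seq_len(n)) {
    if (jump[i]) {
      new_region <- sample(regions, 1, prob = dwell)
      if (new_region == region) {
        step <- amp * sqrt(pi / 2) * sqrt(-2 * log(stats::runif(1)))  # Rayleigh, mean = amp
        theta <- stats::runif(1, 0, 2 * pi)
        bb <- bbs[[region]]
        anchor <- c(.reflect1(anchor[1] + step * cos(theta), bb["xmin"], bb["xmax"]),
                    .reflect1(anchor[2] + step * sin(theta), bb["ymin"], bb["ymax"]))
      } else {
        region <- new_region
        anchor <- .runif_in(bbs[[region]])
      }
    }
    pos[i, ] <- anchor
  }
  if (jitter_sd > 0) {
    pos <- pos + matrix(stats::rnorm(2 * n, sd = jitter_sd), n, 2)
    pos[, 1] <- pmin(pmax(pos[, 1], 0), 1)
    pos[, 2] <- pmin(pmax(pos[, 2], 0), 1)
  }

  ## validity: both eyes lost at rate q, a single eye lost at 5% otherwise
  both_lost <- stats::runif(n) < q
  one_lost <- !both_lost & stats::runif(n) < 0.05
  lost_left <- stats::runif(n) < 0.5
  lvalid <- !both_lost & !(one_lost & lost_left)
  rvalid <- !both_lost & !(one_lost & !lost_left)

  dx <- 0.004  # interocular report offset; cancels in the cyclopean mean
  lx <- ifelse(lvalid & rvalid, pos[, 1] - dx, pos[, 1])
  rx <- ifelse(lvalid & rvalid, pos[, 1] + dx, pos[, 1])
  data.frame(t_ms = (seq_len(n) - 1) * 1000 / config$sampling_rate_hz,
             lx = ifelse(lvalid, pmin(pmax(lx, 0), 1), NA_real_),
             ly = ifelse(lvalid, pos[, 2], NA_real_),
             rx = ifelse(rvalid, pmin(pmax(rx, 0), 1), NA_real_),
             ry = ifelse(rvalid, pos[, 2], NA_real_),
             lvalid = lvalid, rvalid = rvalid)
}

#' Simulate a full cohort
#'
#' One record per participant with the configured number of trials: each
#' participant sees every face of the population's stimulus set exactly once
#' (hence a balanced 3-per-emotion or 8-per-emotion design) in a
#' participant-specific shuffled presentation order.
#'
#' @param config a [cohort_config()].
#' @return A `gaze_cohort` list with `manifest` (data frame: participant_id,
#'   group, trial_id, face, emotion, stimulus_id, presentation_order) and
#'   `trials` (named list of gaze sample data frames, keyed by trial_id).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  fmap <- face_emotion_map(config$population)
  geom_by_face <- lapply(fmap$face, stimulus_geometry, population = config$population)
  names(geom_by_face) <- as.character(fmap$face)

  manifest <- list()
  trials <- list()
  pid <- 0L
  for (g in config$groups) {
    for (k in seq_len(g$n)) {
      pid <- pid + 1L
      participant <- sprintf("P%03d", pid)
      order_idx <- sample.int(nrow(fmap))
      trial_seeds <- sample.int(2147483646L, nrow(fmap))
      for (j in seq_along(order_idx)) {
        face <- fmap$face[order_idx[j]]
        sg <- geom_by_face[[as.character(face)]]
        trial_id <- sprintf("%s_T%02d", participant, j)
        trials[[trial_id]] <- simulate_trial(g$profile, sg$emotion, sg$aoi,
                                             config, trial_seeds[j])
        manifest[[length(manifest) + 1L]] <- data.frame(
          participant_id = participant, group = g$profile$group_label,
          trial_id = trial_id, face = face, emotion = sg$emotion,
          stimulus_id = sg$stimulus_id, presentation_order = j)
      }
    }
  }
  structure(list(manifest = do.call(rbind, manifest), trials = trials,
                 population = config$population, config = config),
            class = "gaze_cohort")
}

#' Semi-analytic expectation of trial features under a profile
#'
#' Expected trial-level features implied by the generative model, used as
#' the calibration target the simulator is tested against. Fixation-sample
#' and validity terms are closed-form; the mean saccadic jump length is
#' estimated from the anchor-relocation chain alone (seeded, independent of
#' the full sample-level generator).
#'
#' @param profile a [gaze_profile()].
#' @param emotion emotion label.
#' @param aoi AOI polygon list of a representative stimulus.
#' @param config a [cohort_config()].
#' @param geom a [display_geometry()].
#' @return List with `fix_total`, `fix_eyes`, `fix_mouth`, `n_saccades`,
#'   `scan_path_length`, `valid_fraction`.
#' @export
expected_trial_features <- function(profile, emotion, aoi, config,
                                    geom = display_geometry()) {
  n <- config$n_samples
  dt <- 1 / config$sampling_rate_hz
  dwell <- profile$per_emotion_dwell[[emotion]]
  s <- profile$fixation_jitter_sd[[emotion]]
  lambda <- profile$saccades_per_second[[emotion]]
  q <- profile$invalid_sample_rate[[emotion]]
  p_jump <- min(1, lambda * dt)

  ## displacement equivalent of the velocity threshold (x axis, centre)
  thr_deg <- 100 * dt
  thr_norm <- 2 * geom$viewing_distance_mm * tan(thr_deg / 2 * pi / 180) /
    geom$physical_width_mm
  eps <- if (s > 0) exp(-thr_norm^2 / (4 * s^2)) else 0  # jitter-pair leakage

  e_valid <- n * (1 - q)
  e_jump_obs <- (n - 1) * p_jump * (1 - q)^2
  e_fix <- (e_valid - e_jump_obs) * (1 - eps)

  ## mean jump length from the relocation chain only
  j_mean <- .mean_jump_length(dwell, aoi, profile$saccade_amplitude)
  e_sp <- p_jump * j_mean + (1 - p_jump) * s * sqrt(pi)

  list(fix_total = e_fix,
       fix_eyes = e_fix * dwell[["eyes"]],
       fix_mouth = e_fix * dwell[["mouth"]],
       n_saccades = e_jump_obs + eps * (e_valid - e_jump_obs) * 0.5,
       scan_path_length = e_sp,
       valid_fraction = 1 - q)
}

.mean_jump_length <- function(dwell, aoi, amp, n_jumps = 2000L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(987654L)
  bbs <- lapply(aoi, .aoi_bbox)
  bbs$other <- c(xmin = 0, xmax = 1, ymin = 0, ymax = 1)
  regions <- .DWELL_REGIONS
  region <- sample(regions, 1, prob = dwell)
  anchor <- .runif_in(bbs[[region]])
  total <- 0
  for (i in seq_len(n_jumps)) {
    new_region <- sample(regions, 1, prob = dwell)
    if (new_region == region) {
      step <- amp * sqrt(pi / 2) * sqrt(-2 * log(stats::runif(1)))
      theta <- stats::runif(1, 0, 2 * pi)
      bb <- bbs[[region]]
      new_anchor <- c(.reflect1(anchor[1] + step * cos(theta), bb["xmin"], bb["xmax"]),
                      .reflect1(anchor[2] + step * sin(theta), bb["ymin"], bb["ymax"]))
    } else {
      region <- new_region
      new_anchor <- .runif_in(bbs[[region]])
    }
    total <- total + sqrt(sum((new_anchor - anchor)^2))
    anchor <- new_anchor
  }
  total / n_jumps
}
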