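## Default group profiles, calibrated against the published group x emotion
## summary statistics (mean AOI fixation-sample counts and scan-path
## orderings) of the adult and child cohorts.

## group x emotion means the defaults are calibrated to: eye and mouth
## fixation-sample counts (out of 600) and scan-path length per trial
.ADULT_TARGETS <- local({
  e <- c("surprise", "happiness", "anger", "sadness", "neutral", "fear", "disgust")
  list(
    emotions = e,
    eyes = rbind(control = c(288.33, 266.68, 299.69, 243.73, 291.38, 253.91, 228.74),
                 ASD     = c(234.23, 206.18, 210.11, 187.35, 200.11, 189.00, 172.00),
                 Sz      = c(140.35, 146.67, 143.73, 142.50, 161.62, 153.38, 118.41)),
    mouth = rbind(control = c(37.64, 31.62, 23.94, 37.95, 27.05, 45.12, 68.74),
                  ASD     = c(62.63, 65.21, 43.80, 73.67, 48.09, 73.17, 86.21),
                  Sz      = c(39.00, 39.79, 25.50, 41.63, 37.48, 43.88, 57.21)),
    scan_path = rbind(control = c(0.05, 0.06, 0.06, 0.06, 0.05, 0.05, 0.06),
                      ASD     = c(0.09, 0.12, 0.12, 0.12, 0.12, 0.13, 0.13),
                      Sz      = c(0.15, 0.20, 0.22, 0.16, 0.18, 0.15, 0.20))
  )
})

.CHILD_TARGETS <- local({
  e <- c("surprise", "happiness", "anger", "sadness")
  list(
    emotions = e,
    eyes = rbind(control = c(300.01, 275.83, 285.29, 280.54),
                 ASD     = c(268.62, 253.12, 243.84, 267.56)),
    mouth = rbind(control = c(51.76, 57.28, 51.50, 47.78),
                  ASD     = c(50.81, 54.22, 53.64, 56.52)),
    scan_path = rbind(control = c(0.06, 0.06, 0.05, 0.07),
                      ASD     = c(0.05, 0.05, 0.07, 0.06))
  )
})

## group-level process parameters: invalid rate, saccade rate, within-AOI
## saccade amplitude, base jitter SD. Chosen once so that jitter stays well
## below the 100 deg/s displacement threshold at 120 Hz while preserving the
## published scan-path orderings (Sz > ASD > control in adults).
.GROUP_PARAMS <- list(
  adult = list(control = list(q = 0.03, lambda = 1.5, amp = 0.10, s0 = 0.0020),
               ASD     = list(q = 0.05, lambda = 2.5, amp = 0.14, s0 = 0.0030),
               Sz      = list(q = 0.07, lambda = 3.5, amp = 0.18, s0 = 0.0042)),
  child = list(control = list(q = 0.04, lambda = 1.5, amp = 0.10, s0 = 0.0022),
               ASD     = list(q = 0.04, lambda = 1.6, amp = 0.11, s0 = 0.0021))
)

## expected fixation-sample count implied by the process parameters
.expected_fix_total <- function(n, dt, q, lambda, s, geom = display_geometry()) {
  p_jump <- min(1, lambda * dt)
  thr_norm <- 2 * geom$viewing_distance_mm * tan(100 * dt / 2 * pi / 180) /
    geom$physical_width_mm
  eps <- if (s > 0) exp(-thr_norm^2 / (4 * s^2)) else 0
  (n * (1 - q) - (n - 1) * p_jump * (1 - q)^2) * (1 - eps)
}

#' Default group gaze profiles
#'
#' Profiles calibrated to the published group-by-emotion summary statistics:
#' dwell fractions are set so expected eye- and mouth-AOI fixation-sample
#' counts match the reported group means, and per-emotion jitter follows the
#' reported scan-path pattern, giving the adult orderings eye counts
#' control > ASD > Sz and scan-path Sz > ASD > control in every emotion.
#' Child group contrasts are much smaller, concentrated in anger-trial eye
#' dwell.
#'
#' @param population `"adult"` (control, ASD, Sz) or `"child"`
#'   (control, ASD).
#' @return Named list of [gaze_profile()] objects.
#' @export
default_profiles <- function(population = c("adult", "child")) {
  if (!is.character(population) || !population[1] %in% c("adult", "child")) {
    stop("unknown population '", population[1], "'; valid options: \"adult\", \"child\"")
  }
  population <- population[1]
  targets <- if (population == "adult") .ADULT_TARGETS else .CHILD_TARGETS
  params <- .GROUP_PARAMS[[population]]
  emotions <- targets$emotions
  n <- 600L
  dt <- 1 / 120

  profiles <- lapply(names(params), function(g) {
    p <- params[[g]]
    sp_row <- targets$scan_path[g, ]
    s_e <- stats::setNames(p$s0 * sp_row / mean(sp_row), emotions)
    dwell <- stats::setNames(vector("list", length(emotions)), emotions)
    for (i in seq_along(emotions)) {
      e_fix <- .expected_fix_total(n, dt, p$q, p$lambda, s_e[i])
      d_eyes <- min(0.85, targets$eyes[g, i] / e_fix)
      d_mouth <- min(0.9 - d_eyes, targets$mouth[g, i] / e_fix)
      rem <- 1 - d_eyes - d_mouth
      dwell[[emotions[i]]] <- c(eyes = d_eyes, nose = 0.45 * rem,
                                mouth = d_mouth, other = 0.55 * rem)
    }
    gaze_profile(group_label = g,
                 per_emotion_dwell = dwell,
                 fixation_jitter_sd = s_e,
                 saccades_per_second = p$lambda,
                 saccade_amplitude = p$amp,
                 invalid_sample_rate = p$q)
  })
  names(profiles) <- names(params)
  profiles
}

#' Null profiles: all groups share one generating process
#'
#' Every group label is assigned a copy of the default control profile, so
#' any downstream classification signal is spurious. Used for calibration
#' checks of the evaluation machinery.
#'
#' @param population `"adult"` or `"child"`.
#' @param groups group labels to emit (default `c("control", "ASD")`).
#' @return Named list of identical-process [gaze_profile()] objects.
#' @export
null_profiles <- function(population = c("adult", "child"),
                          groups = c("control", "ASD")) {
  base <- default_profiles(population)$control
  stats::setNames(lapply(groups, function(g) {
    p <- base
    p$group_label <- g
    p
  }), groups)
}

#' Profiles with group signal confined to a subset of emotions
#'
#' Two groups that share one generating process on all emotions except the
#' named informative ones, where the second group gets a different saccade
#' rate, jitter and eye dwell. The resulting cohort carries diagnostic
#' signal only on the trials of the informative emotions, emulating the
#' situation where specific expressions drive group differences.
#'
#' @param population `"adult"` or `"child"`.
#' @param informative_emotions character vector, e.g. `"neutral"`.
#' @param effect multiplier applied to the case group's saccade rate and
#'   jitter on informative emotions (default 3).
#' @return Named list with `control` and `ASD` profiles.
#' @export
emotion_signal_profiles <- function(population = c("adult", "child"),
                                    informative_emotions = "neutral",
                                    effect = 3) {
  population <- match.arg(population)
  emotions <- population_emotions(population)
  stopifnot(all(informative_emotions %in% emotions))
  base <- default_profiles(population)$control
  case <- base
  case$group_label <- "ASD"
  lam <- base$saccades_per_second
  jit <- base$fixation_jitter_sd
  lam[informative_emotions] <- lam[informative_emotions] * effect
  jit[informative_emotions] <- jit[informative_emotions] * effect
  case$saccades_per_second <- lam
  case$fixation_jitter_sd <- jit
  for (e in informative_emotions) {
    d <- case$per_emotion_dwell[[e]]
    shift <- 0.6 * d[["eyes"]]
    d[["eyes"]] <- d[["eyes"]] - shift
    d[["other"]] <- d[["other"]] + shift
    case$per_emotion_dwell[[e]] <- d
  }
  list(control = base, ASD = case)
}
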