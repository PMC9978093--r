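test_that("profile validation enforces dwell and rate invariants", {
  dwell <- list(surprise = c(eyes = 0.5, nose = 0.2, mouth = 0.1, other = 0.2))
  expect_s3_class(gaze_profile("control", dwell, 0.002, 2, 0.1, 0.05),
                  "gaze_profile")
  bad <- list(surprise = c(eyes = 0.5, nose = 0.2, mouth = 0.1, other = 0.3))
  expect_error(gaze_profile("control", bad, 0.002, 2, 0.1, 0.05), "sum to 1")
  expect_error(gaze_profile("control", dwell, 0.002, 2, 0.1, 1.5), "range")
  expect_error(gaze_profile("bogus", dwell, 0.002, 2, 0.1, 0.05))
  # per-emotion rate vectors must name every emotion
  expect_error(gaze_profile("control", dwell, c(happiness = 0.002), 2, 0.1, 0.05),
               "missing emotions")
})

test_that("default profiles exist per population; unknown population errors", {
  ad <- default_profiles("adult")
  expect_named(ad, c("control", "ASD", "Sz"))
  ch <- default_profiles("child")
  expect_named(ch, c("control", "ASD"))
  for (p in c(ad, ch)) {
    for (d in p$per_emotion_dwell) expect_equal(sum(d), 1, tolerance = 1e-9)
  }
  expect_error(default_profiles("infant"), "adult")
})

test_that("expected feature orderings reproduce the published group contrasts", {
  ad <- default_profiles("adult")
  cfg <- cohort_config(list(list(profile = ad$control, n = 1)), "adult")
  for (e in population_emotions("adult")) {
    aoi <- stimulus_geometry(face_emotion_map("adult")$face[
      face_emotion_map("adult")$emotion == e][1], "adult")$aoi
    ex <- lapply(ad, expected_trial_features, emotion = e, aoi = aoi, config = cfg)
    # eye fixation-sample counts: control > ASD > Sz
    expect_gt(ex$control$fix_eyes, ex$ASD$fix_eyes)
    expect_gt(ex$ASD$fix_eyes, ex$Sz$fix_eyes)
    # scan-path length: Sz > ASD > control
    expect_gt(ex$Sz$scan_path_length, ex$ASD$scan_path_length)
    expect_gt(ex$ASD$scan_path_length, ex$control$scan_path_length)
  }
})

test_that("simulated trials are deterministic and respect degenerate settings", {
  ad <- default_profiles("adult")
  cfg <- cohort_config(list(list(profile = ad$control, n = 1)), "adult")
  sg <- stimulus_geometry(1, "adult")
  t1 <- simulate_trial(ad$control, "surprise", sg$aoi, cfg, 99)
  t2 <- simulate_trial(ad$control, "surprise", sg$aoi, cfg, 99)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 600)
  expect_true(all(diff(t1$t_ms) > 0))
  expect_error(simulate_trial(ad$control, "boredom", sg$aoi, cfg, 1), "boredom")

  # invalid_sample_rate = 0: every sample has at least one valid eye
  p0 <- ad$control
  p0$invalid_sample_rate[] <- 0
  tr <- simulate_trial(p0, "surprise", sg$aoi, cfg, 5)
  expect_false(anyNA(cyclopean_points(tr)))

  # stationary gaze: eyes dwell 1, no jitter, no saccades, all valid
  stat <- gaze_profile("control",
    stats::setNames(rep(list(c(eyes = 1, nose = 0, mouth = 0, other = 0)), 7),
                    population_emotions("adult")),
    fixation_jitter_sd = 0, saccades_per_second = 0,
    saccade_amplitude = 0.1, invalid_sample_rate = 0)
  tr <- simulate_trial(stat, "surprise", sg$aoi, cfg, 4)
  pts <- cyclopean_points(tr)
  expect_equal(scan_path_length(pts), 0)
  lab <- classify_events_ivt(pts, tr$t_ms)
  expect_equal(count_fixation_samples_in_aoi(lab, pts, sg$aoi$eyes), 600)
})

test_that("cohorts are balanced, complete and deterministic under the seed", {
  ad <- default_profiles("adult")
  cfg <- cohort_config(list(list(profile = ad$control, n = 2),
                            list(profile = ad$ASD, n = 2)), "adult", seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(length(unique(co$manifest$participant_id)), 4)
  expect_equal(nrow(co$manifest), 4 * 21)
  per_emotion <- table(co$manifest$participant_id, co$manifest$emotion)
  expect_true(all(per_emotion == 3))
  co2 <- simulate_cohort(cfg)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$trials, co2$trials)

  ch <- default_profiles("child")
  cfg_c <- cohort_config(list(list(profile = ch$control, n = 2)), "child", seed = 3)
  co_c <- simulate_cohort(cfg_c)
  expect_equal(nrow(co_c$manifest), 2 * 32)
  expect_true(all(table(co_c$manifest$participant_id, co_c$manifest$emotion) == 8))
})

test_that("generated features recover the profile's analytic expectations", {
  ad <- default_profiles("adult")
  cfg <- cohort_config(list(list(profile = ad$control, n = 1)), "adult")
  sg <- stimulus_geometry(1, "adult")  # a surprise stimulus
  for (g in c("control", "Sz")) {
    fs <- vapply(1:220, function(s) {
      unlist(trial_features(simulate_trial(ad[[g]], "surprise", sg$aoi, cfg, s),
                            sg$aoi))
    }, numeric(7))
    m <- rowMeans(fs)
    ex <- expected_trial_features(ad[[g]], "surprise", sg$aoi, cfg)
    expect_lt(abs(m[["fix_eyes"]] / ex$fix_eyes - 1), 0.15)
    expect_lt(abs(m[["fix_total"]] / ex$fix_total - 1), 0.10)
    expect_lt(abs(m[["scan_path_length"]] / ex$scan_path_length - 1), 0.25)
    expect_lt(abs(m[["valid_fraction"]] - ex$valid_fraction), 0.02)
  }
})

test_that("cohort config rejects impossible designs", {
  ad <- default_profiles("adult")
  p_missing <- ad$control
  p_missing$per_emotion_dwell$neutral <- NULL
  expect_error(cohort_config(list(list(profile = p_missing, n = 2)), "adult"),
               "lacks dwell")
})
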