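# Shared fixtures: all built in code at test time.

# gaze sample table from an n x 2 point matrix (both eyes at the point;
# NA rows become fully invalid samples)
trace_from_points <- function(points, dt_ms = 1000 / 120) {
  n <- nrow(points)
  valid <- !is.na(points[, 1])
  data.frame(t_ms = (seq_len(n) - 1) * dt_ms,
             lx = points[, 1], ly = points[, 2],
             rx = points[, 1], ry = points[, 2],
             lvalid = valid, rvalid = valid)
}

# normalized x displacement whose visual angle (centred, on-axis) is
# `deg` degrees, on the default display geometry
norm_dx_for_angle <- function(deg, geom = display_geometry()) {
  2 * geom$viewing_distance_mm * tan(deg / 2 * pi / 180) / geom$physical_width_mm
}

# brute-force scan-path oracle: mean distance over consecutive valid pairs
scan_path_bruteforce <- function(points) {
  tot <- 0
  k <- 0
  for (i in seq_len(nrow(points) - 1)) {
    if (!is.na(points[i, 1]) && !is.na(points[i + 1, 1])) {
      tot <- tot + sqrt(sum((points[i + 1, ] - points[i, ])^2))
      k <- k + 1
    }
  }
  if (k == 0) 0 else tot / k
}

# small two-group adult cohort for pipeline tests
small_cohort <- function(n_per_group = 4, groups = c("control", "Sz"),
                         seed = 11, profiles = NULL) {
  if (is.null(profiles)) profiles <- default_profiles("adult")[groups]
  cfg <- cohort_config(lapply(groups, function(g) {
    list(profile = profiles[[g]], n = n_per_group)
  }), "adult", seed = seed)
  simulate_cohort(cfg)
}

# fast training configuration for pipeline tests
fast_cfg <- function(seed = 1, epochs = 40L, patience = 8L) {
  train_config(max_epochs = epochs, early_stop_patience = patience,
               lr_grid = 1e-2, seed = seed)
}
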