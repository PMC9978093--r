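test_that("cyclopean point combines eyes per validity", {
  tr <- data.frame(lx = c(0.4, 0.2, 0.3), ly = c(0.5, 0.9, 0.3),
                   rx = c(0.6, 0.7, 0.8), ry = c(0.5, 0.1, 0.8),
                   lvalid = c(TRUE, TRUE, FALSE),
                   rvalid = c(TRUE, FALSE, FALSE))
  p <- cyclopean_points(tr)
  expect_equal(p[1, ], c(x = 0.5, y = 0.5))
  expect_equal(p[2, ], c(x = 0.2, y = 0.9))
  expect_true(all(is.na(p[3, ])))
})

test_that("angular velocity matches the trigonometric oracle", {
  geom <- display_geometry()
  # two points 11.35 mm apart, centred on-axis: angle = 2*atan(5.675/650)
  half_mm <- 11.35 / 2
  dx <- half_mm / geom$physical_width_mm
  p1 <- c(0.5 - dx, 0.5)
  p2 <- c(0.5 + dx, 0.5)
  expected_deg <- 2 * atan(half_mm / geom$viewing_distance_mm) * 180 / pi
  v <- angular_velocity(p1, p2, 1 / 120, geom)
  expect_equal(v, expected_deg * 120, tolerance = 1e-10)
  expect_gt(v, 119); expect_lt(v, 121)
  # symmetry and dt scaling
  expect_equal(angular_velocity(p2, p1, 1 / 120, geom), v)
  expect_equal(angular_velocity(p1, p2, 1 / 60, geom), v / 2)
  # degenerate cases
  expect_equal(angular_velocity(p1, p1, 1 / 120, geom), 0)
  expect_error(angular_velocity(p1, p2, 0, geom), "positive")
})

test_that("I-VT labels: threshold is strictly 'exceeds'", {
  geom <- display_geometry()
  t_ms <- (0:2) * 1000 / 120
  # displacement giving exactly 100 deg/s over one 120 Hz interval;
  # perturb a hair below / above to keep float round-off out of the tie
  dx_at <- norm_dx_for_angle(100 / 120)
  mk <- function(f) rbind(c(0.5 - f * dx_at / 2, 0.5),
                          c(0.5 + f * dx_at / 2, 0.5),
                          c(0.5 + f * dx_at / 2, 0.5))
  lab <- classify_events_ivt(mk(1 - 1e-9), t_ms, event_config(), geom)
  expect_equal(lab[2], "fixation")  # at (not above) threshold: fixation
  lab <- classify_events_ivt(mk(1 + 1e-6), t_ms, event_config(), geom)
  expect_equal(lab[2], "saccade")   # strictly exceeding: saccade
})

test_that("I-VT on a step trajectory yields one saccade run; first sample inherits", {
  geom <- display_geometry()
  n <- 60
  pts <- matrix(rep(c(0.3, 0.5), each = n), n, 2)
  pts[31:n, 1] <- 0.3 + norm_dx_for_angle(5)  # one instantaneous 5 deg jump
  t_ms <- (seq_len(n) - 1) * 1000 / 120
  lab <- classify_events_ivt(pts, t_ms, event_config(), geom)
  expect_equal(count_saccades(lab), 1)
  expect_equal(which(lab == "saccade"), 31L)
  expect_equal(lab[1], "fixation")  # inherited from its successor
  # stationary trace: all fixation
  lab0 <- classify_events_ivt(matrix(0.5, 10, 2), (0:9) * 8.33, event_config(), geom)
  expect_true(all(lab0 == "fixation"))
  expect_error(classify_events_ivt(matrix(numeric(0), 0, 2), numeric(0)), "empty")
})

test_that("label partition covers all samples and invalid gaps break velocity", {
  geom <- display_geometry()
  set.seed(42)
  n <- 600
  pts <- matrix(runif(2 * n, 0.3, 0.7), n, 2)
  pts[sample(n, 80), ] <- NA
  t_ms <- (seq_len(n) - 1) * 1000 / 120
  lab <- classify_events_ivt(pts, t_ms, event_config(), geom)
  expect_equal(sum(lab == "invalid"), sum(is.na(pts[, 1])))
  expect_equal(length(lab), n)
  expect_setequal(unique(lab), c("fixation", "saccade", "invalid"))
  # a gap longer than max_gap_interpolation_ms breaks the velocity chain:
  # the sample after it inherits its successor's label instead
  pts2 <- matrix(0.5, 30, 2)
  pts2[5:15, ] <- NA  # 11 samples ~ 92 ms gap
  lab2 <- classify_events_ivt(pts2, (0:29) * 8.333, event_config(), geom)
  expect_equal(lab2[16], "fixation")
})

test_that("velocity threshold monotonicity: lower threshold, never fewer saccade samples", {
  geom <- display_geometry()
  set.seed(7)
  pts <- matrix(0.5 + cumsum(rnorm(120, sd = 0.004)), 60, 2)
  pts <- pmin(pmax(pts, 0), 1)
  t_ms <- (0:59) * 1000 / 120
  counts <- vapply(c(200, 100, 50, 20, 5), function(thr) {
    sum(classify_events_ivt(pts, t_ms, event_config(thr), geom) == "saccade")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("AOI fixation-sample counts: brute force, boundary, vertex order", {
  square <- cbind(c(0.4, 0.6, 0.6, 0.4), c(0.4, 0.4, 0.6, 0.6))
  pts <- cbind(seq(0.35, 0.65, length.out = 10), rep(0.5, 10))
  labels <- rep("fixation", 10)
  inside <- pts[, 1] >= 0.4 & pts[, 1] <= 0.6
  expect_equal(count_fixation_samples_in_aoi(labels, pts, square), sum(inside))
  # only fixation samples count
  labels[which(inside)[1]] <- "saccade"
  expect_equal(count_fixation_samples_in_aoi(labels, pts, square), sum(inside) - 1)
  # boundary point counts as inside
  expect_equal(count_fixation_samples_in_aoi("fixation", cbind(0.4, 0.4), square), 1)
  # vertex ordering must not matter (reversed orientation)
  expect_equal(count_fixation_samples_in_aoi(rep("fixation", 10), pts, square),
               count_fixation_samples_in_aoi(rep("fixation", 10), pts, square[4:1, ]))
  # non-rectangular polygon path (triangle)
  tri <- cbind(c(0.4, 0.6, 0.5), c(0.4, 0.4, 0.6))
  expect_equal(count_fixation_samples_in_aoi(rep("fixation", 2),
                                             rbind(c(0.5, 0.45), c(0.9, 0.9)), tri), 1)
  expect_equal(count_fixation_samples_in_aoi(rep("fixation", 1), cbind(0.1, 0.1), square), 0)
})

test_that("saccade events are maximal runs", {
  expect_equal(count_saccades(c("fixation", "saccade", "saccade", "fixation",
                                "saccade", "fixation")), 2)
  expect_equal(count_saccades(rep("saccade", 5)), 1)
  expect_equal(count_saccades(rep("fixation", 5)), 0)
})

test_that("scan-path length follows the valid-pair definition", {
  expect_equal(scan_path_length(matrix(0.5, 50, 2)), 0)
  expect_equal(scan_path_length(rbind(c(0, 0), c(0.3, 0.4))), 0.5)
  pts <- rbind(c(0, 0), c(0.3, 0.4), c(NA, NA), c(0.1, 0.1), c(0.1, 0.2))
  expect_equal(scan_path_length(pts), 0.3)  # (0.5 + 0.1) / 2
  expect_equal(scan_path_length(rbind(c(NA, NA), c(NA, NA))), 0)
  expect_equal(scan_path_length(matrix(0.2, 1, 2)), 0)
})

test_that("scan-path equals brute force on random traces with validity masks", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(2:40, 1)
    pts <- matrix(runif(2 * n), n, 2)
    drop <- runif(n) < runif(1, 0, 0.6)
    pts[drop, ] <- NA
    expect_equal(scan_path_length(pts), scan_path_bruteforce(pts))
  }
})

test_that("trial filter applies both exclusion rules", {
  f <- data.frame(scan_path_length = c(0.05, 0, 0.02, 0),
                  valid_fraction = c(0.95, 0.80, 0.35, 0.20))
  out <- filter_trials(f)
  expect_equal(out$kept, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$exclusion_reason,
               c(NA, "scan_path_length", "valid_fraction", "valid_fraction"))
})
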