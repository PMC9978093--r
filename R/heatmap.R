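## Gaze-retention heat maps and CNN model inputs.
##
## The heat map is binary at native resolution (visited pixels = 1), blurred
## with a normalized Gaussian (sigma in native pixels, reflective boundary),
## centre-cropped to the largest square centred on the stimulus face box,
## area-downsampled to 34x34 and min-max scaled. The stimulus channel goes
## through the identical crop/downsample without blurring. Because blur,
## crop and area-downsampling are all linear, the pipeline precomposes them
## into two small operators per stimulus and evaluates the 34x34 map
## directly from the hit coordinates; this equals the naive full-resolution
## path exactly (asserted in the test suite).

#' Heat-map configuration
#'
#' @param sigma_px Gaussian blur SD in native pixels (default 10).
#' @param native_resolution `(width, height)` of the recording display.
#' @param output_size side of the square model input (default 34).
#' @return A `heatmap_config` list. Channel order of the model input is
#'   (stimulus, heat map).
#' @export
heatmap_config <- function(sigma_px = 10, native_resolution = c(1920L, 1080L),
                           output_size = 34L) {
  stopifnot(sigma_px > 0, output_size >= 2)
  structure(list(sigma_px = sigma_px,
                 native_resolution = as.integer(native_resolution),
                 output_size = as.integer(output_size)),
            class = "heatmap_config")
}

## normalized point -> integer pixel (row, col), clamped to the image
.point_pixels <- function(points, resolution) {
  w <- resolution[1]; h <- resolution[2]
  ok <- !is.na(points[, 1])
  px <- pmin(pmax(floor(points[ok, 1] * w) + 1L, 1L), w)
  py <- pmin(pmax(floor(points[ok, 2] * h) + 1L, 1L), h)
  cbind(row = py, col = px)
}

#' Binary gaze hit map
#'
#' Pixels visited by any valid gaze sample are set to 1, all others 0
#' (idempotent for repeated visits).
#'
#' @param points n x 2 matrix of normalized gaze points (`NA` rows skipped).
#' @param resolution `(width, height)` in pixels.
#' @return `height x width` binary matrix.
#' @export
build_hit_map <- function(points, resolution = c(1920L, 1080L)) {
  img <- matrix(0, resolution[2], resolution[1])
  pix <- .point_pixels(points, resolution)
  if (nrow(pix)) img[pix] <- 1
  img
}

## 1-D Gaussian scatter matrix with whole-sample reflective boundary;
## every column sums to 1 so mass is conserved exactly
.blur_operators <- new.env(parent = emptyenv())

.gauss_scatter_matrix <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  if (!is.null(.blur_operators[[key]])) return(.blur_operators[[key]])
  r <- ceiling(5 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  src <- seq_len(n)
  for (o in -r:r) {
    dst <- src + o
    dst <- ifelse(dst < 1, 2 - dst, dst)
    dst <- ifelse(dst > n, 2 * n - dst, dst)
    dst <- pmin(pmax(dst, 1L), n)
    idx <- cbind(dst, src)
    K[idx] <- K[idx] + k[o + r + 1]
  }
  .blur_operators[[key]] <- K
  K
}

#' Gaussian blur of an image
#'
#' Separable convolution with a normalized discrete Gaussian (support
#' truncated at 5 sigma and renormalized) with reflective boundary
#' handling; total image mass is conserved.
#'
#' @param img numeric matrix.
#' @param sigma_px blur SD in pixels.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma_px = 10) {
  stopifnot(sigma_px > 0)
  Kr <- .gauss_scatter_matrix(nrow(img), sigma_px)
  Kc <- .gauss_scatter_matrix(ncol(img), sigma_px)
  Kr %*% img %*% t(Kc)
}

## area-average downsampling matrix (out x n); rows are overlap weights
.downsample_matrix <- function(n, out) {
  key <- sprintf("ds_%d_%d", n, out)
  if (!is.null(.blur_operators[[key]])) return(.blur_operators[[key]])
  W <- matrix(0, out, n)
  step <- n / out
  for (i in seq_len(out)) {
    a <- (i - 1) * step
    b <- i * step
    j0 <- floor(a) + 1L
    j1 <- ceiling(b)
    for (j in j0:min(j1, n)) {
      W[i, j] <- max(0, min(b, j) - max(a, j - 1)) / step
    }
  }
  .blur_operators[[key]] <- W
  W
}

#' Centre-square crop window over a face bounding box
#'
#' The largest square centred on the face box centre that fits inside the
#' image.
#'
#' @param face_box 2 x 2 matrix, rows `(xmin, ymin)` and `(xmax, ymax)` in
#'   normalized coordinates.
#' @param resolution `(width, height)` pixels.
#' @return List with integer vectors `rows` and `cols`.
#' @export
crop_window <- function(face_box, resolution = c(1920L, 1080L)) {
  w <- resolution[1]; h <- resolution[2]
  cx <- mean(face_box[, 1]) * w
  cy <- mean(face_box[, 2]) * h
  half <- floor(min(cx, w - cx, cy, h - cy))
  side <- max(2L, as.integer(2 * half))
  r0 <- as.integer(round(cy - half)); c0 <- as.integer(round(cx - half))
  r0 <- min(max(r0, 0L), h - side); c0 <- min(max(c0, 0L), w - side)
  list(rows = (r0 + 1L):(r0 + side), cols = (c0 + 1L):(c0 + side))
}

.minmax01 <- function(m) {
  rng <- range(m)
  # near-zero spread (incl. float noise on a constant channel) maps to 0
  if (rng[2] - rng[1] <= 1e-12 * max(1, abs(rng[2]))) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Assemble the two-channel model input (reference path)
#'
#' Crops both channels identically to the face-centred square,
#' area-downsamples to the configured output size and min-max scales each
#' channel to `[0,1]` (a constant channel maps to 0). Channel 1 is the
#' stimulus, channel 2 the blurred heat map.
#'
#' @param blurred blurred heat map at native resolution.
#' @param stimulus_image grayscale stimulus at the same resolution.
#' @param face_box face bounding box (see [crop_window()]).
#' @param config a [heatmap_config()].
#' @return Array of dim `c(2, output_size, output_size)`.
#' @export
assemble_model_input <- function(blurred, stimulus_image, face_box,
                                 config = heatmap_config()) {
  if (!all(dim(blurred) == dim(stimulus_image))) {
    stop("heat map and stimulus resolutions differ")
  }
  cw <- crop_window(face_box, rev(dim(blurred)))
  s <- config$output_size
  Wr <- .downsample_matrix(length(cw$rows), s)
  Wc <- .downsample_matrix(length(cw$cols), s)
  heat <- Wr %*% blurred[cw$rows, cw$cols] %*% t(Wc)
  stim <- Wr %*% stimulus_image[cw$rows, cw$cols] %*% t(Wc)
  out <- array(0, c(2, s, s))
  out[1, , ] <- .minmax01(stim)
  out[2, , ] <- .minmax01(heat)
  out
}

## Precomposed per-stimulus operators: model heat channel = Ar %*% H %*% t(Ac)
## where H is the binary hit map; plus the fixed stimulus channel.
.stim_ops_cache <- new.env(parent = emptyenv())

stimulus_operators <- function(face, population, config = heatmap_config()) {
  key <- sprintf("%s_%d_%g_%d", population, face, config$sigma_px, config$output_size)
  if (!is.null(.stim_ops_cache[[key]])) return(.stim_ops_cache[[key]])
  st <- render_stimulus(face, population, config$native_resolution)
  w <- config$native_resolution[1]; h <- config$native_resolution[2]
  cw <- crop_window(st$face_box, c(w, h))
  s <- config$output_size
  Wr <- .downsample_matrix(length(cw$rows), s)
  Wc <- .downsample_matrix(length(cw$cols), s)
  Kr <- .gauss_scatter_matrix(h, config$sigma_px)
  Kc <- .gauss_scatter_matrix(w, config$sigma_px)
  ops <- list(
    Ar = Wr %*% Kr[cw$rows, , drop = FALSE],
    Ac = Wc %*% Kc[cw$cols, , drop = FALSE],
    stim_channel = .minmax01(Wr %*% st$image[cw$rows, cw$cols] %*% t(Wc)),
    face_box = st$face_box
  )
  .stim_ops_cache[[key]] <- ops
  ops
}

#' Model input for one trial (fast path)
#'
#' Exactly equivalent to [build_hit_map()] + [gaussian_blur()] +
#' [assemble_model_input()], but evaluated through precomposed per-stimulus
#' linear operators.
#'
#' @param trial gaze sample data frame.
#' @param face stimulus face number.
#' @param population `"adult"` or `"child"`.
#' @param config a [heatmap_config()].
#' @return Array of dim `c(2, output_size, output_size)`.
#' @export
trial_model_input <- function(trial, face, population,
                              config = heatmap_config()) {
  ops <- stimulus_operators(face, population, config)
  pts <- cyclopean_points(trial)
  pix <- unique(.point_pixels(pts, config$native_resolution))
  s <- config$output_size
  heat <- if (nrow(pix)) {
    ops$Ar[, pix[, "row"], drop = FALSE] %*% t(ops$Ac[, pix[, "col"], drop = FALSE])
  } else {
    matrix(0, s, s)
  }
  out <- array(0, c(2, s, s))
  out[1, , ] <- ops$stim_channel
  out[2, , ] <- .minmax01(heat)
  out
}

#' Model inputs for a whole cohort
#'
#' @param cohort a `gaze_cohort`.
#' @param config a [heatmap_config()].
#' @return List: `x`, a `d x n_trials` matrix of flattened 2-channel inputs
#'   (column order matches `cohort$manifest` rows), and `index`, the
#'   manifest.
#' @export
cohort_model_inputs <- function(cohort, config = heatmap_config()) {
  s <- config$output_size
  d <- 2L * s * s
  n <- nrow(cohort$manifest)
  x <- matrix(0, d, n)
  for (i in seq_len(n)) {
    row <- cohort$manifest[i, ]
    x[, i] <- as.numeric(trial_model_input(cohort$trials[[row$trial_id]],
                                           row$face, cohort$population, config))
  }
  list(x = x, index = cohort$manifest, config = config)
}
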