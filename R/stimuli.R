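## Schematic synthetic face stimuli.
##
## The photographic stimuli of the emotion-identification task are
## copyrighted, so the package renders schematic grayscale faces: a head
## ellipse with eyes/brows, a nose and an emotion-dependent mouth, plus
## per-stimulus geometric jitter so AOIs genuinely vary between images.
## Coordinates are normalized to [0,1]^2, origin top-left, y downward.

#' Face-number to emotion mapping of the stimulus sets
#'
#' The adult set has 21 faces (3 per emotion over surprise, happiness,
#' anger, sadness, neutral, fear, disgust); the child set has 32 faces
#' (8 per emotion over surprise, happiness, anger, sadness).
#'
#' @param population `"adult"` or `"child"`.
#' @return Data frame with columns `face` (integer) and `emotion`.
#' @export
face_emotion_map <- function(population = c("adult", "child")) {
  population <- match.arg(population)
  if (population == "adult") {
    m <- list(surprise = c(1, 7, 14), happiness = c(3, 9, 11),
              anger = c(13, 15, 21), sadness = c(4, 16, 19),
              neutral = c(2, 8, 17), fear = c(5, 10, 20),
              disgust = c(6, 12, 18))
  } else {
    m <- list(surprise = c(3, 8, 10, 12, 19, 22, 25, 32),
              happiness = c(5, 7, 9, 14, 21, 23, 26, 30),
              anger = c(1, 6, 13, 15, 18, 24, 27, 29),
              sadness = c(2, 4, 11, 16, 17, 20, 28, 31))
  }
  df <- data.frame(face = unlist(m, use.names = FALSE),
                   emotion = rep(names(m), lengths(m)))
  df[order(df$face), , drop = FALSE]
}

#' Ordered emotion labels of a stimulus population
#' @param population `"adult"` or `"child"`.
#' @return Character vector (7 adult / 4 child emotions).
#' @export
population_emotions <- function(population = c("adult", "child")) {
  population <- match.arg(population)
  if (population == "adult") {
    c("surprise", "happiness", "anger", "sadness", "neutral", "fear", "disgust")
  } else {
    c("surprise", "happiness", "anger", "sadness")
  }
}

## deterministic per-stimulus jitter in [-1,1], independent of the global RNG
.stim_hash <- function(id, k) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
  x <- numeric(k)
  state <- (h %% 2147483647) + 1
  for (i in seq_len(k)) {
    state <- (1103515245 * (state %% 65536) + 12345) %% 2147483648
    x[i] <- state / 2147483647 * 2 - 1
  }
  x
}

.rect <- function(x0, x1, y0, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Stimulus geometry: AOI polygons and face box for one face
#'
#' AOIs follow the task convention: the eyes region extends up to the
#' eyebrows; nose and mouth regions sit below it, the mouth box sized to
#' the emotion-dependent mouth. Each stimulus gets small deterministic
#' jitter so AOIs differ between images of the same emotion.
#'
#' @param face face number.
#' @param population `"adult"` or `"child"`.
#' @return List with `stimulus_id`, `emotion`, `face_box` (2 x 2 matrix of
#'   `(xmin,ymin)/(xmax,ymax)`) and `aoi` (named list of 4 x 2 polygon
#'   matrices for `eyes`, `nose`, `mouth`).
#' @export
stimulus_geometry <- function(face, population = c("adult", "child")) {
  population <- match.arg(population)
  fmap <- face_emotion_map(population)
  emotion <- fmap$emotion[match(face, fmap$face)]
  if (is.na(emotion)) stop("unknown face number for population ", population)
  id <- sprintf("%s_face%02d", population, face)
  j <- .stim_hash(id, 6) * 0.012
  cx <- 0.5 + j[1]
  eye_y <- 0.40 + j[2]
  mouth_y <- 0.62 + j[3]
  mouth_w <- switch(emotion,
                    happiness = 0.075, surprise = 0.050, anger = 0.060,
                    sadness = 0.060, fear = 0.055, disgust = 0.065,
                    neutral = 0.055) + j[4] * 0.3
  mouth_h <- switch(emotion,
                    happiness = 0.030, surprise = 0.055, anger = 0.015,
                    sadness = 0.022, fear = 0.040, disgust = 0.028,
                    neutral = 0.018) + abs(j[5]) * 0.2
  mouth_top <- mouth_y - mouth_h - 0.035
  aoi <- list(
    eyes = .rect(cx - 0.115, cx + 0.115, eye_y - 0.095, eye_y + 0.065),
    nose = .rect(cx - 0.050, cx + 0.050, eye_y + 0.065,
                 max(mouth_top, eye_y + 0.075)),  # never overlaps the mouth box
    mouth = .rect(cx - mouth_w - 0.02, cx + mouth_w + 0.02,
                  mouth_top, mouth_y + mouth_h + 0.035)
  )
  face_box <- rbind(c(cx - 0.145, 0.18 + j[6]), c(cx + 0.145, 0.86 + j[6]))
  list(stimulus_id = id, emotion = emotion, face_box = face_box,
       aoi = aoi, cx = cx, eye_y = eye_y, mouth_y = mouth_y,
       mouth_w = mouth_w, mouth_h = mouth_h)
}

.stim_cache <- new.env(parent = emptyenv())

#' Render a schematic grayscale stimulus image
#'
#' @param face face number.
#' @param population `"adult"` or `"child"`.
#' @param resolution `(width, height)` in pixels; default 1920 x 1080.
#' @return List as [stimulus_geometry()] plus `image`, an `height x width`
#'   matrix of intensities in `[0,1]` (row = y from top).
#' @export
render_stimulus <- function(face, population = c("adult", "child"),
                            resolution = c(1920L, 1080L)) {
  population <- match.arg(population)
  key <- sprintf("%s_%d_%dx%d", population, face, resolution[1], resolution[2])
  if (!is.null(.stim_cache[[key]])) return(.stim_cache[[key]])
  g <- stimulus_geometry(face, population)
  w <- resolution[1]; h <- resolution[2]
  xs <- ((seq_len(w)) - 0.5) / w
  ys <- ((seq_len(h)) - 0.5) / h
  X <- matrix(xs, nrow = h, ncol = w, byrow = TRUE)
  Y <- matrix(ys, nrow = h, ncol = w)
  img <- matrix(0.15, nrow = h, ncol = w)
  ellipse <- function(cx, cy, a, b) ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
  ## head
  img[ellipse(g$cx, 0.52, 0.145, 0.34)] <- 0.85
  ## eyebrows (angled down-in for anger, raised for surprise/fear)
  brow_dy <- switch(g$emotion, anger = 0.012, surprise = -0.015,
                    fear = -0.012, 0)
  for (s in c(-1, 1)) {
    img[ellipse(g$cx + s * 0.055, g$eye_y - 0.055 + brow_dy, 0.038, 0.008)] <- 0.25
    img[ellipse(g$cx + s * 0.055, g$eye_y, 0.032, 0.030)] <- 0.95       # sclera
    img[ellipse(g$cx + s * 0.055, g$eye_y, 0.012, 0.016)] <- 0.10       # iris
  }
  ## nose
  img[ellipse(g$cx, g$eye_y + 0.13, 0.018, 0.045)] <- 0.55
  ## mouth
  img[ellipse(g$cx, g$mouth_y, g$mouth_w, g$mouth_h)] <- 0.20
  out <- c(g, list(image = img))
  .stim_cache[[key]] <- out
  out
}

#' Write AOI definitions for a stimulus set as YAML
#'
#' One YAML file per stimulus under `dir`, each holding the stimulus id,
#' emotion, face box and the three AOI polygons as lists of `[x, y]` pairs.
#'
#' @param population `"adult"` or `"child"`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_aoi_yaml <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmap <- face_emotion_map(population)
  paths <- vapply(fmap$face, function(f) {
    g <- stimulus_geometry(f, population)
    obj <- list(stimulus_id = g$stimulus_id,
                emotion = g$emotion,
                face_box = lapply(seq_len(2), function(i) as.numeric(g$face_box[i, ])),
                aoi = lapply(g$aoi, function(p) {
                  lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))
                }))
    path <- file.path(dir, paste0(g$stimulus_id, ".yaml"))
    yaml::write_yaml(obj, path, precision = 15L)
    path
  }, character(1))
  invisible(paths)
}

#' Read an AOI YAML file
#' @param path file written by [write_aoi_yaml()].
#' @return List with `stimulus_id`, `emotion`, `face_box` matrix and `aoi`
#'   polygon matrices.
#' @export
read_aoi_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$face_box <- do.call(rbind, obj$face_box)
  obj$aoi <- lapply(obj$aoi, function(p) {
    m <- do.call(rbind, p)
    colnames(m) <- c("x", "y")
    m
  })
  obj
}
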