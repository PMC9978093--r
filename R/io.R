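#' Write a cohort to disk
#'
#' Layout: `manifest.csv`, one gaze TSV per trial under `gaze/` (columns
#' `t_ms, lx, ly, rx, ry, lvalid, rvalid`, normalized coordinates, origin
#' top-left), AOI YAML per stimulus under `aoi/`, and a small `cohort.yaml`
#' with population and seed.
#'
#' @param cohort a `gaze_cohort` from [simulate_cohort()].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "gaze"), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$manifest, file.path(dir, "manifest.csv"))
  for (id in names(cohort$trials)) {
    data.table::fwrite(cohort$trials[[id]],
                       file.path(dir, "gaze", paste0(id, ".tsv")), sep = "\t")
  }
  write_aoi_yaml(cohort$population, file.path(dir, "aoi"))
  yaml::write_yaml(list(population = cohort$population,
                        seed = cohort$config$seed),
                   file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' Read one gaze TSV
#'
#' @param path TSV path.
#' @param col_map optional named character vector mapping the canonical
#'   column names (`t_ms, lx, ly, rx, ry, lvalid, rvalid`) to the column
#'   names used in the file, for vendor-exported tables.
#' @return Gaze sample data frame with canonical columns.
#' @export
read_gaze_tsv <- function(path, col_map = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  canonical <- c("t_ms", "lx", "ly", "rx", "ry", "lvalid", "rvalid")
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(df))
    if (length(missing_src)) stop("columns not in file: ", paste(missing_src, collapse = ", "))
    df <- df[, unname(col_map[canonical]), drop = FALSE]
    names(df) <- canonical
  }
  if (!all(canonical %in% names(df))) {
    stop("gaze table lacks columns: ", paste(setdiff(canonical, names(df)), collapse = ", "))
  }
  df$lvalid <- as.logical(df$lvalid)
  df$rvalid <- as.logical(df$rvalid)
  df
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @return A `gaze_cohort` list.
#' @export
read_cohort <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "cohort.yaml"))
  manifest <- as.data.frame(data.table::fread(file.path(dir, "manifest.csv")))
  trials <- lapply(manifest$trial_id, function(id) {
    read_gaze_tsv(file.path(dir, "gaze", paste0(id, ".tsv")))
  })
  names(trials) <- manifest$trial_id
  structure(list(manifest = manifest, trials = trials,
                 population = meta$population,
                 config = list(seed = meta$seed)),
            class = "gaze_cohort")
}

#' Trial feature table for a whole cohort
#'
#' Runs the event stage on every trial and applies the validity filter
#' (scan-path length > 0 and valid fraction >= 40%).
#'
#' @param cohort a `gaze_cohort`.
#' @param config an [event_config()].
#' @param geom a [display_geometry()].
#' @return Data frame: manifest columns plus `fix_eyes, fix_nose, fix_mouth,
#'   fix_total, n_saccades, scan_path_length, valid_fraction, kept,
#'   exclusion_reason`.
#' @export
cohort_features <- function(cohort, config = event_config(),
                            geom = display_geometry()) {
  aois <- .cohort_aois(cohort)
  feats <- lapply(seq_len(nrow(cohort$manifest)), function(i) {
    row <- cohort$manifest[i, ]
    trial_features(cohort$trials[[row$trial_id]],
                   aois[[row$stimulus_id]], config, geom)
  })
  out <- cbind(cohort$manifest, do.call(rbind, feats))
  filter_trials(out)
}

## stimulus_id -> AOI polygon list, from the bundled stimulus geometry
.cohort_aois <- function(cohort) {
  fmap <- face_emotion_map(cohort$population)
  aois <- lapply(fmap$face, function(f) stimulus_geometry(f, cohort$population)$aoi)
  names(aois) <- vapply(fmap$face, function(f) {
    stimulus_geometry(f, cohort$population)$stimulus_id
  }, character(1))
  aois
}
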