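#' Read a motion-capture marker CSV
#'
#' Expects the long export schema `time, pigeon_id, marker, x, y, z` (meters;
#' missing cells empty). Validates monotone timestamps per bird and marker and
#' reports per-bird data loss in the `"loss"` attribute.
#'
#' @param path CSV file path.
#' @return A data.frame of marker samples.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "pigeon_id", "marker", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("marker file must have columns: ", paste(need, collapse = ", "))
  for (col in c("x", "y", "z")) df[[col]] <- as.numeric(df[[col]])
  key <- interaction(df$pigeon_id, df$marker, drop = TRUE)
  for (k in levels(key)) {
    tk <- df$time[key == k]
    if (is.unsorted(tk, strictly = TRUE))
      stop("non-monotone timestamps for ", k)
  }
  miss <- is.na(df$x) | is.na(df$y) | is.na(df$z)
  loss <- tapply(miss, df$pigeon_id, mean)
  attr(df, "loss") <- loss
  df
}

#' Write a marker data.frame as CSV
#'
#' @param markers Marker data.frame (see [read_markers()] for the schema).
#' @param path Output path.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(markers, path, row.names = FALSE)
  invisible(path)
}

#' Reshape long marker data into per-marker arrays for one bird
#'
#' @param markers Long marker data.frame.
#' @param pigeon_id Bird to extract.
#' @param head_markers,back_markers Marker labels of the two clusters.
#' @return List with `t`, `head` (n x 4 x 3 array) and `back`.
#' @export
marker_arrays <- function(markers, pigeon_id,
                          head_markers = paste0("h", 1:4),
                          back_markers = paste0("b", 1:4)) {
  mk <- markers[markers$pigeon_id == pigeon_id, ]
  t <- sort(unique(mk$time))
  n <- length(t)
  grab <- function(labels) {
    a <- array(NA_real_, c(n, length(labels), 3))
    for (k in seq_along(labels)) {
      rows <- mk[mk$marker == labels[k], ]
      i <- match(rows$time, t)
      a[i, k, 1] <- rows$x; a[i, k, 2] <- rows$y; a[i, k, 3] <- rows$z
    }
    a
  }
  list(t = t, head = grab(head_markers), back = grab(back_markers))
}

#' Analysis configuration
#'
#' Defaults are the analysis constants used throughout: 10 degree foveal
#' margin around the
#' 75 degree foveal axis, 300 ms minimum foveation, 200 ms onset exclusion,
#' saccades >5 degrees at >60 deg/s for >=50 ms, 4 cm peck height, 6 s
#' feeding gap, 0.6 / 0.2 / 2 m/s locomotion thresholds with 70 ms minimum,
#' 5 degree heatmap cells, 120 s before-cue window and 10,000 permutations.
#'
#' @param ... Named overrides.
#' @return Named list of settings.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1,
    rounds = NULL, flocks = c("A", "B"),   # synthetic design subset
    smooth_window_s = 0.1,                  # NULL = no smoothing
    max_gap_s = 0.2,
    margin_deg = 10, fovea_azimuth = 75,
    min_foveation_s = 0.3, onset_exclusion_s = 0.2,
    before_cue_window_s = 120,
    conspecific_radius = 0.15,
    n_perm = 10000,
    out_dir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys match [run_config()] fields.
#' @return A config list.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}
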