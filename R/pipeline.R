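#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline. Defaults are
#' the validated operating point for these reporters: 10 min frames,
#' 1 um/px, nucleus diameter 12 px, 10 um maximum link distance with no
#' gap closing, 480 min minimum track duration, mitotic slope threshold
#' 300 (16-bit units/frame), a 50\% mVenus drop for G1/S, and a 3-frame
#' persistent rise above the lowest maintained level for S/G2.
#'
#' Conventions: pixel centres, origin top-left, x rightward / y downward,
#' frames 0-based, durations on closed frame intervals
#' (`(n - 1) * frame_interval`).
#'
#' @param sim Optional [sim_config()]; when present [run_pipeline()]
#'   simulates its input movie, otherwise `paths$venus` / `paths$red`
#'   must point to TIFF stacks.
#' @param paths Named list of input paths (`venus`, `red`, optionally
#'   `labels` for precomputed segmentation).
#' @param construct `"PIP_H2A"` or `"PIP_FUCCI"`.
#' @param frame_interval Minutes per frame.
#' @param pixel_size Microns per pixel.
#' @param nucleus_diameter Detector diameter parameter, px.
#' @param max_link_dist Maximum frame-to-frame displacement, um.
#' @param min_track_minutes Minimum track duration, minutes.
#' @param slope_thresh Mitotic-spike slope threshold.
#' @param peak_max_width Maximum cytokinesis peak width, frames.
#' @param drop_fraction G1/S drop fraction of the plateau.
#' @param rise_window S/G2 persistence window, frames.
#' @param snapshot_k MAD multiplier for snapshot classification.
#' @param seed Integer seed for any stochastic stage.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(sim = NULL, paths = list(),
                            construct = c("PIP_H2A", "PIP_FUCCI"),
                            frame_interval = 10, pixel_size = 1.0,
                            nucleus_diameter = 12, max_link_dist = 10,
                            min_track_minutes = 480, slope_thresh = 300,
                            peak_max_width = 3, drop_fraction = 0.5,
                            rise_window = 3, snapshot_k = 3, seed = 1L) {
  construct <- match.arg(construct)
  if (!is.null(sim)) {
    sim <- validate_sim_config(unclass(sim))
    construct <- sim$construct
    frame_interval <- sim$frame_interval
    pixel_size <- sim$pixel_size
    nucleus_diameter <- sim$nucleus_diameter
  }
  cfg <- list(sim = sim, paths = paths, construct = construct,
              frame_interval = frame_interval, pixel_size = pixel_size,
              nucleus_diameter = nucleus_diameter,
              max_link_dist = max_link_dist,
              min_track_minutes = min_track_minutes,
              slope_thresh = slope_thresh,
              peak_max_width = peak_max_width,
              drop_fraction = drop_fraction, rise_window = rise_window,
              snapshot_k = snapshot_k, seed = as.integer(seed))
  stopifnot(cfg$frame_interval > 0, cfg$pixel_size > 0,
            cfg$max_link_dist > 0, cfg$min_track_minutes >= 0,
            cfg$slope_thresh >= 0,
            cfg$drop_fraction > 0, cfg$drop_fraction < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> channel sum -> segmentation ->
#' tracking -> track selection -> cytokinesis delimitation -> phase
#' calling -> descriptive statistics, writing each stage's table into
#' `out_dir` together with a JSON run manifest (config hash, seed,
#' per-stage counts). Re-running with the same config and seed is
#' byte-identical. A stage failure aborts with the stage name; outputs
#' written so far stay on disk next to an `INCOMPLETE` marker.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory results: `tracks`,
#'   `segments`, `phase_calls`, `group_stats`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  stage <- "init"
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("fuccitrace")),
                   stages = list())
  result <- tryCatch({
    if (!is.null(config$sim)) {
      stage <- "simulate"
      lineage <- sample_lineage(config$sim)
      traces <- reporter_traces(lineage)
      movie <- render_movie(lineage, traces)
      venus <- movie$venus; red <- movie$red
      manifest$stages$simulate <- list(
        cells = nrow(lineage$cells),
        completed_cycles = sum(lineage$cells$completed))
    } else {
      stage <- "read"
      venus <- read_stack(config$paths$venus)
      red <- read_stack(config$paths$red)
    }
    stage <- "sum"
    summed <- sum_channels(venus, red)
    stage <- "segment"
    if (!is.null(config$paths$labels)) {
      labels <- read_labels(config$paths$labels)
    } else {
      labels <- segment_movie(summed, diameter = config$nucleus_diameter)
    }
    manifest$stages$segment <- list(
      frames = length(labels),
      detections = sum(vapply(labels, function(l) length(unique(l[l > 0])),
                              1L)))
    stage <- "track"
    dets <- detections_from_labels(labels, venus, red, config$pixel_size)
    tracks <- build_tracks(dets, config$frame_interval,
                           config$max_link_dist)
    manifest$stages$track <- list(tracks = length(unique(tracks$track_id)))
    stage <- "select"
    t_in <- length(unique(tracks$track_id))
    kept <- filter_min_duration(tracks, config$min_track_minutes)
    c1 <- attr(kept, "filter_counts")
    if (config$construct == "PIP_H2A") {
      kept <- filter_mitosis_slope(kept, config$slope_thresh)
      c2 <- attr(kept, "filter_counts")
    } else c2 <- c(kept = unname(c1["kept"]), removed = 0)
    manifest$stages$select <- list(
      tracks_in = t_in,
      after_duration = unname(c1["kept"]),
      removed_duration = unname(c1["removed"]),
      after_slope = unname(c2["kept"]),
      removed_slope = unname(c2["removed"]))
    export_track_table(kept, file.path(out_dir, "track_table.csv"))
    stage <- "cycles"
    segments <- cycle_segments(kept, config$frame_interval,
                               config$min_track_minutes,
                               max_width = config$peak_max_width)
    utils::write.csv(segments, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
    stage <- "call"
    calls <- call_segments(kept, segments, config$frame_interval)
    utils::write.csv(calls, file.path(out_dir, "phase_calls.csv"),
                     row.names = FALSE)
    manifest$stages$call <- list(
      cycles = nrow(calls),
      clean = sum(calls$flags == ""))
    stage <- "stats"
    clean <- calls[calls$flags == "" & !is.na(calls$total_h), ,
                   drop = FALSE]
    if (nrow(clean)) {
      gs <- describe_phases(clean[, c("G1_h", "S_h", "G2M_h", "total_h")])
    } else {
      gs <- data.frame(phase = character(0), n = integer(0),
                       q1 = numeric(0), median = numeric(0),
                       q3 = numeric(0))
    }
    utils::write.csv(gs, file.path(out_dir, "group_stats.csv"),
                     row.names = FALSE)
    list(tracks = kept, segments = segments, phase_calls = calls,
         group_stats = gs)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(marker)
  result$manifest <- manifest
  invisible(result)
}
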