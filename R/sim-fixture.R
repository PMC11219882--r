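#' Write a complete synthetic fixture to disk
#'
#' Persists a simulated scene in the package's on-disk formats:
#' per-channel multi-page 16-bit TIFF (`venus.tif`, `red.tif`), the truth
#' label movie as integer TIFF (`labels.tif`), truth tables and traces as
#' CSV (`truth_cells.csv`, `truth_positions.csv`, `traces.csv`) and the
#' configuration as JSON (`sim_config.json`). Everything round-trips
#' losslessly through the package readers.
#'
#' @param lineage A [sample_lineage()] result.
#' @param traces [reporter_traces()] output.
#' @param movie [render_movie()] output (may cover a frame subset).
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(lineage, traces, movie, path) {
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  ok <- file.access(path, mode = 2) == 0
  if (!ok) stop("cannot write to ", path)
  write_stack(movie$venus, file.path(path, "venus.tif"))
  write_stack(movie$red, file.path(path, "red.tif"))
  write_labels(movie$labels, file.path(path, "labels.tif"))
  utils::write.csv(lineage$cells[, c("cell_id", "parent_id", "birth_frame",
                                     "g1s_frame", "sg2_frame",
                                     "division_frame")],
                   file.path(path, "truth_cells.csv"), row.names = FALSE)
  utils::write.csv(lineage$positions,
                   file.path(path, "truth_positions.csv"), row.names = FALSE)
  tr <- traces
  names(tr) <- c("cell_id", "frame", "venus_mean", "venus_max",
                 "red_mean", "red_max")
  utils::write.csv(tr, file.path(path, "traces.csv"), row.names = FALSE)
  write_config(lineage$config, file.path(path, "sim_config.json"))
  invisible(path)
}

#' Read fixture components back
#'
#' @param path Fixture directory written by [write_fixture()].
#' @return A list: `venus`, `red`, `labels` (frame lists), `cells`,
#'   `positions`, `traces` (data.frames), `config`.
#' @export
read_fixture <- function(path) {
  list(venus = read_stack(file.path(path, "venus.tif")),
       red = read_stack(file.path(path, "red.tif")),
       labels = read_labels(file.path(path, "labels.tif")),
       cells = utils::read.csv(file.path(path, "truth_cells.csv")),
       positions = utils::read.csv(file.path(path, "truth_positions.csv")),
       traces = utils::read.csv(file.path(path, "traces.csv")),
       config = read_config(file.path(path, "sim_config.json")))
}
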