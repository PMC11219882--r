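#' Extract per-frame detections from a label movie
#'
#' Computes one detection per labelled region and frame: centroid (um),
#' area, and mean/max intensity per reporter channel.
#'
#' @param labels Label movie (list of integer matrices).
#' @param venus,red Matching intensity movies (lists of matrices).
#' @param pixel_size Microns per pixel.
#' @param frames Optional 0-based frame indices (defaults to
#'   `0:(length(labels)-1)`).
#' @return A data.frame with columns `frame`, `label`, `x_um`, `y_um`,
#'   `area_px2`, `venus_mean`, `venus_max`, `red_mean`, `red_max`.
#' @export
detections_from_labels <- function(labels, venus, red, pixel_size = 1.0,
                                   frames = NULL) {
  stopifnot(length(labels) == length(venus), length(labels) == length(red))
  if (is.null(frames)) frames <- seq_along(labels) - 1L
  out <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[[k]]
    idx <- which(lab > 0)
    if (!length(idx)) next
    l <- lab[idx]
    rc <- arrayInd(idx, dim(lab))
    v <- venus[[k]][idx]; r <- red[[k]][idx]
    ids <- sort(unique(l))
    g <- match(l, ids)
    n <- tabulate(g)
    out[[k]] <- data.frame(
      frame = frames[k],
      label = ids,
      x_um = (rowsum(rc[, 2] - 1, g)[, 1] / n) * pixel_size,
      y_um = (rowsum(rc[, 1] - 1, g)[, 1] / n) * pixel_size,
      area_px2 = n,
      venus_mean = rowsum(v, g)[, 1] / n,
      venus_max = as.numeric(tapply(v, g, max)),
      red_mean = rowsum(r, g)[, 1] / n,
      red_max = as.numeric(tapply(r, g, max))
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_track_table()[, -1]
  rownames(res) <- NULL
  res
}

#' Optimal one-to-one frame linking
#'
#' Links detections between two consecutive frames by solving the linear
#' assignment problem with squared-displacement cost, with unassignment
#' allowed: the cost matrix is padded with birth/death entries at
#' `max_dist^2`, and links longer than `max_dist` are forbidden. This is
#' the frame-to-frame step of LAP-style particle tracking.
#'
#' @param dets_a,dets_b Detection data.frames (need `x_um`, `y_um`).
#' @param max_dist Maximum link displacement in um (default 10).
#' @return A two-column matrix `(i, j)` of linked row indices into
#'   `dets_a` and `dets_b`; zero rows if nothing links.
#' @export
link_frames <- function(dets_a, dets_b, max_dist = 10) {
  if (max_dist <= 0) stop("max_dist must be positive")
  n <- nrow(dets_a); m <- nrow(dets_b)
  if (n == 0 || m == 0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  d2 <- outer(dets_a$x_um, dets_b$x_um, "-")^2 +
    outer(dets_a$y_um, dets_b$y_um, "-")^2
  BIG <- 1e9
  U <- max_dist^2
  C <- matrix(BIG, n + m, n + m)
  feas <- d2 <= max_dist^2
  sub <- C[1:n, 1:m, drop = FALSE]
  sub[feas] <- d2[feas]
  C[1:n, 1:m] <- sub
  for (i in 1:n) C[i, m + i] <- U
  for (j in 1:m) C[n + j, j] <- U
  C[(n + 1):(n + m), (m + 1):(m + n)] <- 0
  sol <- cpp_lap(C)
  links <- cbind(i = 1:n, j = sol[1:n])
  links[links[, 2] <= m, , drop = FALSE]
}

#' Build gap-free tracks from per-frame detections
#'
#' Applies [link_frames()] over every consecutive frame pair. Tracks are
#' structurally gap-free: an unmatched detection starts a new track, a
#' track whose detection finds no partner in the next frame ends there
#' (no gap closing). At a division the mother's track continues into the
#' nearest daughter by ordinary assignment and the other daughter starts
#' a new track.
#'
#' @param detections Output of [detections_from_labels()] (or a
#'   compatible data.frame).
#' @param frame_interval Minutes per frame (stored as an attribute).
#' @param max_dist Maximum link displacement in um.
#' @return A track table: the detections with a `track_id` column
#'   prepended, ordered by track then frame; `frame_interval` attached as
#'   an attribute.
#' @export
build_tracks <- function(detections, frame_interval = 10, max_dist = 10) {
  if (nrow(detections) == 0) {
    out <- empty_track_table()
    attr(out, "frame_interval") <- frame_interval
    return(out)
  }
  frames <- sort(unique(detections$frame))
  if (any(diff(frames) <= 0)) stop("non-monotone frame indices")
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  track_id <- integer(nrow(detections))
  next_track <- 1L
  prev_rows <- by_frame[[as.character(frames[1])]]
  track_id[prev_rows] <- seq_along(prev_rows)
  next_track <- length(prev_rows) + 1L
  for (k in seq_along(frames)[-1]) {
    cur_rows <- by_frame[[as.character(frames[k])]]
    linked <- rep(FALSE, length(cur_rows))
    # only link across strictly consecutive frames (no gap closing)
    if (frames[k] - frames[k - 1] == 1 && length(prev_rows)) {
      L <- link_frames(detections[prev_rows, , drop = FALSE],
                       detections[cur_rows, , drop = FALSE], max_dist)
      if (nrow(L)) {
        track_id[cur_rows[L[, "j"]]] <- track_id[prev_rows[L[, "i"]]]
        linked[L[, "j"]] <- TRUE
      }
    }
    n_new <- sum(!linked)
    if (n_new) {
      track_id[cur_rows[!linked]] <- next_track + seq_len(n_new) - 1L
      next_track <- next_track + n_new
    }
    prev_rows <- cur_rows
  }
  out <- cbind(track_id = track_id, detections)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval") <- frame_interval
  out
}

empty_track_table <- function() {
  data.frame(track_id = integer(0), frame = integer(0), label = integer(0),
             x_um = numeric(0), y_um = numeric(0), area_px2 = numeric(0),
             venus_mean = numeric(0), venus_max = numeric(0),
             red_mean = numeric(0), red_max = numeric(0))
}

track_table_columns <- function() names(empty_track_table())

#' Track durations in minutes
#'
#' Duration of a gap-free track spanning `n` frames is
#' `(n - 1) * frame_interval` (closed interval convention).
#'
#' @param tracks A track table.
#' @param frame_interval Minutes per frame; defaults to the table's
#'   attribute.
#' @return Named numeric vector of durations, one per track id.
#' @export
track_durations <- function(tracks,
                            frame_interval = attr(tracks, "frame_interval")) {
  if (is.null(frame_interval)) stop("frame_interval not supplied")
  n <- table(tracks$track_id)
  stats::setNames((as.numeric(n) - 1) * frame_interval, names(n))
}

#' Write / read the CSV track-table dialect
#'
#' Columns: `track_id, frame, label, x_um, y_um, area_px2, venus_mean,
#' venus_max, red_mean, red_max`. Reading validates the schema (an error
#' names any missing column) and the gap-free invariant (an error
#' identifies the offending track and frames). A header-only file is a
#' valid empty table.
#'
#' @param tracks A track table.
#' @param path CSV path.
#' @param frame_interval Frame interval (minutes) re-attached on read.
#' @return `export_track_table()` returns `path` invisibly;
#'   `read_track_table()` returns the validated track table.
#' @export
export_track_table <- function(tracks, path) {
  utils::write.csv(tracks[, track_table_columns(), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname export_track_table
#' @export
read_track_table <- function(path, frame_interval = 10) {
  tab <- utils::read.csv(path)
  missing_cols <- setdiff(track_table_columns(), names(tab))
  if (length(missing_cols))
    stop("track table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab)) {
    tab <- tab[order(tab$track_id, tab$frame), , drop = FALSE]
    gaps <- tapply(tab$frame, tab$track_id, function(f) any(diff(f) != 1))
    if (any(gaps)) {
      bad <- names(gaps)[which(gaps)[1]]
      f <- tab$frame[tab$track_id == as.integer(bad)]
      stop("track ", bad, " has a frame gap (frames ",
           paste(range(f), collapse = ".."), " with ", length(f),
           " rows); tracks must be gap-free")
    }
  }
  rownames(tab) <- NULL
  attr(tab, "frame_interval") <- frame_interval
  tab
}
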