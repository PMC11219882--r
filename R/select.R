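#' Remove tracks shorter than a minimum duration
#'
#' Tracks under 480 min are discarded by default: they cannot contain a
#' full cell cycle, since no cycle shorter than 500 min has been observed
#' in these cells. The threshold is strict ("under"): a track of exactly
#' `min_minutes` is kept.
#'
#' @param tracks A track table (see [build_tracks()]).
#' @param min_minutes Minimum duration in minutes (default 480).
#' @param frame_interval Minutes per frame; defaults to the table's
#'   attribute.
#' @return The filtered track table; removal counts are attached as
#'   `attr(, "filter_counts")` (`kept`, `removed`).
#' @export
filter_min_duration <- function(tracks, min_minutes = 480,
                                frame_interval = attr(tracks, "frame_interval")) {
  if (nrow(tracks) == 0) return(tracks)
  dur <- track_durations(tracks, frame_interval)
  keep_ids <- as.integer(names(dur)[dur >= min_minutes])
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval") <- frame_interval
  attr(out, "filter_counts") <- c(kept = length(keep_ids),
                                  removed = length(dur) - length(keep_ids))
  out
}

#' Keep tracks showing a mitotic intensity spike
#'
#' A track that follows a nucleus through mitosis shows an acute jump in
#' the histone-reporter channel as chromatids condense; candidate
#' full-cycle tracks are those with at least one consecutive-frame
#' difference of the red max intensity strictly exceeding `thresh`
#' (per-frame, 16-bit scale) in absolute value.
#'
#' @param tracks A track table.
#' @param thresh Slope threshold (default 300); strict inequality.
#' @param channel Column holding the filtered intensity
#'   (default `"red_max"`, the exported max intensity).
#' @return Filtered track table with `attr(, "filter_counts")`.
#' @export
filter_mitosis_slope <- function(tracks, thresh = 300, channel = "red_max") {
  if (!channel %in% names(tracks))
    stop("missing channel column: ", channel)
  if (nrow(tracks) == 0) return(tracks)
  has_spike <- tapply(tracks[[channel]], tracks$track_id,
                      function(x) length(x) > 1 && any(abs(diff(x)) > thresh))
  keep_ids <- as.integer(names(has_spike)[has_spike])
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval") <- attr(tracks, "frame_interval")
  attr(out, "filter_counts") <- c(kept = length(keep_ids),
                                  removed = length(has_spike) - length(keep_ids))
  out
}

#' Detect cytokinesis peaks in a red mean-intensity trace
#'
#' Cytokinesis appears as an acute, narrow spike of the histone reporter's
#' mean intensity. Peaks are local maxima whose prominence is at least
#' `prominence` (default: 3x the trace's median absolute frame-to-frame
#' deviation -- data-adaptive, since no absolute criterion generalises
#' across imaging settings) and whose full width at half prominence is at
#' most `max_width` frames (default 3), rejecting broad intensity drifts.
#'
#' @param x Numeric trace (red mean intensity), >= 5 frames.
#' @param prominence Minimum peak prominence; `NULL` for the default.
#' @param max_width Maximum full width at half prominence, frames.
#' @return Integer vector of 0-based peak positions within the trace,
#'   ordered.
#' @export
detect_cytokinesis_peaks <- function(x, prominence = NULL, max_width = 3) {
  n <- length(x)
  if (n < 5) stop("trace must have at least 5 frames")
  if (is.null(prominence)) {
    mad_step <- stats::median(abs(diff(x)))
    # noise floor (3x the typical frame-to-frame step) plus a scale
    # guard relative to the trace's own peak amplitude: a genuine
    # mitotic spike towers over the baseline, while noise bumps and the
    # reporter's G1/S coupling step barely clear the pure noise floor
    prominence <- max(3 * mad_step, 0.25 * (max(x) - stats::median(x)))
    if (prominence <= 0) prominence <- .Machine$double.eps
  }
  # local maxima, plateau-aware: strictly greater than the previous
  # different value and at least the next value
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) cand <- c(cand, i)
  }
  peaks <- integer(0)
  for (p in cand) {
    # prominence: lowest saddle between this peak and a higher one
    lv <- x[seq_len(p - 1)]
    higher_l <- which(lv > x[p])
    left_min <- if (length(higher_l)) min(x[(max(higher_l) + 1):(p - 1)])
                else min(lv)
    rv <- x[(p + 1):n]
    higher_r <- which(rv > x[p])
    right_min <- if (length(higher_r)) min(x[(p + 1):(p + min(higher_r) - 1)])
                 else min(rv)
    prom <- x[p] - max(left_min, right_min)
    if (prom < prominence) next
    half <- x[p] - prom / 2
    li <- p
    while (li > 1 && x[li - 1] >= half) li <- li - 1
    ri <- p
    while (ri < n && x[ri + 1] >= half) ri <- ri + 1
    if ((ri - li + 1) > max_width) next
    peaks <- c(peaks, p)
  }
  as.integer(peaks - 1L)
}

#' Extract candidate full-cycle segments between cytokinesis peaks
#'
#' Each consecutive pair of cytokinesis peaks delimits one candidate cell
#' cycle. Pairs closer than `min_minutes` are reported with a `TOO_SHORT`
#' QC flag instead of being silently dropped; a trace with fewer than two
#' peaks yields no segments and an `EDGE_TRUNCATED` flag. This replaces
#' by-eye confirmation that a track spans two division events with
#' explicit bookkeeping.
#'
#' @param track_id Track identifier carried into the report.
#' @param peaks 0-based peak frames from [detect_cytokinesis_peaks()]
#'   (relative to the same origin as `frame_offset`).
#' @param frame_interval Minutes per frame.
#' @param min_minutes Minimum cycle duration (default 480).
#' @param frame_offset Added to peak indices to express segment bounds in
#'   absolute movie frames (default 0).
#' @return A data.frame of segments: `track_id`, `start_frame`,
#'   `end_frame`, `duration_min`, `qc_flags` (`""` for clean segments).
#' @export
extract_full_cycles <- function(track_id, peaks, frame_interval = 10,
                                min_minutes = 480, frame_offset = 0) {
  seg <- function(s, e, flag) data.frame(
    track_id = track_id,
    start_frame = s + frame_offset, end_frame = e + frame_offset,
    duration_min = (e - s) * frame_interval, qc_flags = flag,
    stringsAsFactors = FALSE)
  if (length(peaks) < 2) {
    if (length(peaks) == 1) {
      # not a segment: one division seen, cycle truncated by the movie edge
      return(data.frame(track_id = track_id,
                        start_frame = peaks[1] + frame_offset,
                        end_frame = NA_integer_, duration_min = NA_real_,
                        qc_flags = "EDGE_TRUNCATED",
                        stringsAsFactors = FALSE))
    }
    return(seg(0, 0, "")[0, , drop = FALSE])
  }
  out <- vector("list", length(peaks) - 1)
  for (k in seq_len(length(peaks) - 1)) {
    s <- peaks[k]; e <- peaks[k + 1]
    dur <- (e - s) * frame_interval
    out[[k]] <- seg(s, e, if (dur >= min_minutes) "" else "TOO_SHORT")
  }
  do.call(rbind, out)
}

#' Segment report for a whole track table
#'
#' Runs peak detection and cycle extraction on every track's red mean
#' trace.
#'
#' @param tracks A track table.
#' @param frame_interval Minutes per frame.
#' @param min_minutes Minimum cycle duration in minutes.
#' @param prominence,max_width Passed to [detect_cytokinesis_peaks()].
#' @return A data.frame of cycle segments over all tracks (absolute
#'   frames), including flagged ones.
#' @export
cycle_segments <- function(tracks,
                           frame_interval = attr(tracks, "frame_interval"),
                           min_minutes = 480,
                           prominence = NULL, max_width = 3) {
  ids <- unique(tracks$track_id)
  out <- list()
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 5) next
    pk <- detect_cytokinesis_peaks(tr$red_mean, prominence, max_width)
    if (length(pk) == 1) {
      out[[length(out) + 1L]] <- data.frame(
        track_id = id, start_frame = tr$frame[1] + pk[1],
        end_frame = NA_integer_, duration_min = NA_real_,
        qc_flags = "EDGE_TRUNCATED", stringsAsFactors = FALSE)
      next
    }
    segs <- extract_full_cycles(id, pk, frame_interval, min_minutes,
                                frame_offset = tr$frame[1])
    if (nrow(segs)) out[[length(out) + 1L]] <- segs
  }
  if (!length(out))
    return(data.frame(track_id = integer(0), start_frame = integer(0),
                      end_frame = integer(0), duration_min = numeric(0),
                      qc_flags = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
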