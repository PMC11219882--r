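#' Percentile-normalise a fluorescence trace
#'
#' Subtracts the 5th-percentile value and divides by the 95th-5th
#' percentile range (linear-interpolation quantiles), mapping the bulk of
#' the trace into \[0, 1\] while staying monotone (order-preserving), so
#' every downstream call is invariant to affine rescaling of the raw
#' intensities. Also estimates a noise scale as the median absolute
#' deviation of frame-to-frame differences.
#'
#' @param x Numeric trace, >= 5 frames.
#' @return List: `values` (normalised trace), `noise_scale` (MAD of
#'   diffs, same normalised units), `lo`, `hi` (the raw percentiles). A
#'   constant trace returns all zeros with `noise_scale` 0.
#' @export
normalize_trace <- function(x) {
  if (length(x) < 5) stop("trace must have at least 5 frames")
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
  rng <- q[2] - q[1]
  if (rng < .Machine$double.eps * max(1, abs(q[2]))) {
    return(list(values = rep(0, length(x)), noise_scale = 0,
                lo = q[1], hi = q[2]))
  }
  v <- (x - q[1]) / rng
  list(values = v,
       noise_scale = stats::mad(diff(v), constant = 1),
       lo = q[1], hi = q[2])
}

#' Call the G1/S transition from an mVenus trace
#'
#' The G1/S transition is the point after the mVenus signal drops over
#' 50\%: on the 3-frame median-smoothed normalised trace, the reference
#' plateau is the running maximum since the cycle start (so the G2
#' re-rise cannot distort the G1 reference), and the call is the first
#' frame at which the smoothed signal falls to half the plateau or below.
#'
#' @param venus Numeric mVenus trace over one cycle (cytokinesis to
#'   cytokinesis).
#' @param frames 0-based absolute frame indices (default
#'   `seq_along(venus) - 1`).
#' @param drop_fraction Fraction of the plateau defining the drop
#'   (default 0.5).
#' @param min_plateau Minimum normalised plateau before a drop may be
#'   called (guards flat traces; default 0.2).
#' @return List: `frame` (the called frame, `NA` if none), `flag`
#'   (`""` or `"NO_G1S"`), `plateau` (normalised running-max level at the
#'   call), `noise_scale`.
#' @export
call_g1s <- function(venus, frames = seq_along(venus) - 1,
                     drop_fraction = 0.5, min_plateau = 0.2) {
  nz <- normalize_trace(venus)
  sm <- stats::runmed(nz$values, 3)
  plateau <- cummax(sm)
  eps <- 1e-9
  hit <- which(plateau >= min_plateau &
                 sm <= drop_fraction * plateau + eps)
  if (!length(hit)) {
    return(list(frame = NA_integer_, flag = "NO_G1S",
                plateau = max(plateau), noise_scale = nz$noise_scale))
  }
  i <- hit[1]
  list(frame = as.integer(frames[i]), flag = "",
       plateau = plateau[i], noise_scale = nz$noise_scale)
}

#' Call the S/G2 transition from an mVenus trace
#'
#' The S/G2 transition is the point when mVenus begins rising above its
#' lowest maintained level again. The lowest maintained level `L` is the
#' minimum of the 3-frame rolling median of the normalised trace over
#' \[g1s, cycle end\]; the call is the first frame after that minimum at
#' which the rolling median exceeds `L + delta` and stays above it for at
#' least `rise_window` consecutive frames. The margin
#' `delta = max(0.1 * plateau, 3 * noise_scale)` ignores both small
#' fluctuations around the floor and single-frame noise spikes.
#'
#' @param venus mVenus trace over the full cycle.
#' @param g1s_frame The called G1/S frame (absolute).
#' @param frames 0-based absolute frame indices matching `venus`.
#' @param plateau,noise_scale Values returned by [call_g1s()].
#' @param delta Rise margin in normalised units; `NULL` for the default.
#' @param rise_window Persistence requirement in frames (default 3).
#' @return List: `frame` (`NA` if none), `flag` (`""` or `"NO_SG2"`),
#'   `level` (the lowest maintained level).
#' @export
call_sg2 <- function(venus, g1s_frame, frames = seq_along(venus) - 1,
                     plateau = 1, noise_scale = 0, delta = NULL,
                     rise_window = 3) {
  if (is.na(g1s_frame))
    return(list(frame = NA_integer_, flag = "NO_SG2", level = NA_real_))
  nz <- normalize_trace(venus)
  sel <- which(frames >= g1s_frame)
  w <- nz$values[sel]
  if (length(w) < 3)
    return(list(frame = NA_integer_, flag = "NO_SG2", level = NA_real_))
  rm3 <- stats::runmed(w, 3)
  L <- min(rm3)
  i0 <- which.min(rm3)
  if (is.null(delta)) delta <- max(0.1 * plateau, 3 * noise_scale)
  n <- length(rm3)
  for (i in seq(i0 + 1, length.out = max(0, n - i0))) {
    if (i + rise_window - 1 > n) break
    if (all(rm3[i:(i + rise_window - 1)] > L + delta)) {
      return(list(frame = as.integer(frames[sel][i]), flag = "",
                  level = L))
    }
  }
  list(frame = NA_integer_, flag = "NO_SG2", level = L)
}

#' Phase lengths from called transition frames
#'
#' `G1 = (g1s - start) dt`, `S = (sg2 - g1s) dt`, `G2M = (end - sg2) dt`,
#' `total = (end - start) dt`, converted to hours. The three phases sum
#' to the total exactly because they are computed from the same frame
#' indices.
#'
#' @param start,g1s,sg2,end Frame indices with `start < g1s < sg2 < end`.
#' @param frame_interval Minutes per frame.
#' @return List with `G1_h`, `S_h`, `G2M_h`, `total_h`.
#' @export
phase_lengths <- function(start, g1s, sg2, end, frame_interval = 10) {
  if (!(start < g1s && g1s < sg2 && sg2 < end))
    stop("phase ordering violated: need start < g1s < sg2 < end (got ",
         start, ", ", g1s, ", ", sg2, ", ", end, ")")
  h <- frame_interval / 60
  list(G1_h = (g1s - start) * h, S_h = (sg2 - g1s) * h,
       G2M_h = (end - sg2) * h, total_h = (end - start) * h)
}

#' Call a full cycle from an H2A-construct trace segment
#'
#' Convenience wrapper: given the venus trace of one cycle segment
#' (cytokinesis to cytokinesis), calls G1/S and S/G2 and derives phase
#' lengths.
#'
#' @param venus mVenus trace over the segment.
#' @param frames Absolute 0-based frames of the segment.
#' @param frame_interval Minutes per frame.
#' @param ... Passed to [call_g1s()] / [call_sg2()].
#' @return A one-row data.frame: `start_frame`, `g1s_frame`, `sg2_frame`,
#'   `end_frame`, `G1_h`, `S_h`, `G2M_h`, `total_h`, `flags`.
#' @export
call_cycle <- function(venus, frames = seq_along(venus) - 1,
                       frame_interval = 10, ...) {
  g1 <- call_g1s(venus, frames, ...)
  s2 <- call_sg2(venus, g1$frame, frames, plateau = g1$plateau,
                 noise_scale = g1$noise_scale)
  start <- frames[1]; end <- frames[length(frames)]
  flags <- paste(c(g1$flag, s2$flag)[c(g1$flag, s2$flag) != ""],
                 collapse = ";")
  ok <- !is.na(g1$frame) && !is.na(s2$frame) &&
    start < g1$frame && g1$frame < s2$frame && s2$frame < end
  if (ok) {
    pl <- phase_lengths(start, g1$frame, s2$frame, end, frame_interval)
  } else {
    pl <- list(G1_h = NA_real_, S_h = NA_real_, G2M_h = NA_real_,
               total_h = NA_real_)
    if (flags == "") flags <- "ORDER_VIOLATION"
  }
  data.frame(start_frame = start, g1s_frame = g1$frame,
             sg2_frame = s2$frame, end_frame = end,
             G1_h = pl$G1_h, S_h = pl$S_h, G2M_h = pl$G2M_h,
             total_h = pl$total_h, flags = flags,
             stringsAsFactors = FALSE)
}

#' Phase calls for every clean cycle segment of a track table
#'
#' @param tracks A track table (post-filtering).
#' @param segments Output of [cycle_segments()].
#' @param frame_interval Minutes per frame.
#' @return A data.frame of phase calls, one row per clean segment, with
#'   `cycle_id` and `track_id` prepended.
#' @export
call_segments <- function(tracks, segments,
                          frame_interval = attr(tracks, "frame_interval")) {
  segs <- segments[segments$qc_flags == "", , drop = FALSE]
  out <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, ]
    tr <- tracks[tracks$track_id == s$track_id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    sel <- tr$frame >= s$start_frame & tr$frame <= s$end_frame
    cc <- call_cycle(tr$venus_mean[sel], tr$frame[sel], frame_interval)
    out[[k]] <- cbind(cycle_id = k, track_id = s$track_id, cc)
  }
  if (!length(out))
    return(data.frame(cycle_id = integer(0), track_id = integer(0),
                      start_frame = integer(0), g1s_frame = integer(0),
                      sg2_frame = integer(0), end_frame = integer(0),
                      G1_h = numeric(0), S_h = numeric(0),
                      G2M_h = numeric(0), total_h = numeric(0),
                      flags = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call one FUCCI-mode cycle with inclusion rules
#'
#' In the FUCCI construct the geminin-mCherry reporter collapses at
#' cytokinesis, so divisions are detected as single-frame drops of at
#' least 50\% of the preceding mCherry level. The cycle runs from a
#' mother division to the next division; cycles are excluded (with a
#' reason, not an error) when the mother division is under `min_start_h`
#' hours after recording start (`TOO_EARLY`, cells still acclimating) or
#' under `min_remaining_h` hours before recording end (`TOO_LATE`, cycle
#' may not complete). G1/S and S/G2 are called from the mVenus trace with
#' the same rules as the H2A mode.
#'
#' @param venus,cherry Aligned traces over the recording.
#' @param frames Absolute 0-based frames.
#' @param frame_interval Minutes per frame.
#' @param recording_start,recording_end First and last frame of the
#'   recording (defaults: range of `frames`).
#' @param mother_division Optionally supply the mother-division frame
#'   instead of detecting it.
#' @param min_start_h,min_remaining_h Inclusion windows in hours
#'   (defaults 5 and 20).
#' @return A list: `status` (`"ok"` or `"excluded"`), `reason`
#'   (`""`, `"TOO_EARLY"`, `"TOO_LATE"`, `"NO_DIVISION"`, `"NO_END"`),
#'   and for included cycles `calls` (the [call_cycle()] row).
#' @export
call_fucci_cycle <- function(venus, cherry, frames = seq_along(venus) - 1,
                             frame_interval = 10,
                             recording_start = min(frames),
                             recording_end = max(frames),
                             mother_division = NULL,
                             min_start_h = 5, min_remaining_h = 20) {
  drops <- cherry_division_frames(cherry, frames)
  start <- if (!is.null(mother_division)) mother_division
           else if (length(drops)) drops[1] else NA_integer_
  if (is.na(start))
    return(list(status = "excluded", reason = "NO_DIVISION", calls = NULL))
  h <- frame_interval / 60
  if ((start - recording_start) * h < min_start_h)
    return(list(status = "excluded", reason = "TOO_EARLY", calls = NULL))
  if ((recording_end - start) * h < min_remaining_h)
    return(list(status = "excluded", reason = "TOO_LATE", calls = NULL))
  nxt <- drops[drops > start]
  if (!length(nxt))
    return(list(status = "excluded", reason = "NO_END", calls = NULL))
  end <- nxt[1]
  sel <- frames >= start & frames <= end
  calls <- call_cycle(venus[sel], frames[sel], frame_interval)
  list(status = "ok", reason = "", calls = calls)
}

# frames at which mCherry drops >= `frac` of its previous value in a
# single step (candidate division frames); the previous value must be
# appreciable (> 20% of the trace max) to ignore flicker near zero
cherry_division_frames <- function(cherry, frames = seq_along(cherry) - 1,
                                   frac = 0.5) {
  if (length(cherry) < 2) return(integer(0))
  prev <- cherry[-length(cherry)]
  cur <- cherry[-1]
  hit <- prev > 0.2 * max(cherry) & (prev - cur) >= frac * prev
  as.integer(frames[-1][hit])
}

#' Background model for snapshot classification
#'
#' @param image Intensity matrix of one channel.
#' @param labels Label matrix; pixels with label 0 are background.
#' @return Named numeric `c(median =, mad =)` of the background pixels
#'   (MAD is the scaled `stats::mad`).
#' @export
snapshot_background <- function(image, labels) {
  bgpix <- image[labels == 0]
  c(median = stats::median(bgpix), mad = stats::mad(bgpix))
}

#' Classify a snapshot into cell-cycle phase fractions
#'
#' A nucleus is positive for a channel when its mean intensity exceeds
#' the channel's background median plus `k` background MADs. Colour
#' combinations map to phases: mVenus+ only is G1/G0, mCherry+ only is S,
#' double-positive is G2/M. Double-negative nuclei (the 1-3 frame early-S
#' gap) are reported separately as `indeterminate` and excluded from the
#' three-class fractions by default; set `fold_indeterminate = "S"` to
#' count them as S (they are biologically early-S).
#'
#' @param venus_mean,cherry_mean Per-nucleus mean intensities.
#' @param venus_bg,cherry_bg Background models
#'   (`c(median =, mad =)`), e.g. from [snapshot_background()], or plain
#'   scalar thresholds.
#' @param k MAD multiplier (default 3).
#' @param fold_indeterminate `"none"` (default) or `"S"`.
#' @return List: `class` (per-nucleus factor: `G1G0`, `S`, `G2M`,
#'   `indeterminate`), `fractions` (named, sums to 1 over classified
#'   nuclei), `n_classified`, `n_indeterminate`.
#' @export
classify_snapshot <- function(venus_mean, cherry_mean, venus_bg, cherry_bg,
                              k = 3, fold_indeterminate = c("none", "S")) {
  fold_indeterminate <- match.arg(fold_indeterminate)
  thr <- function(bg) {
    if (length(bg) >= 2) unname(bg["median"] + k * bg["mad"]) else unname(bg)
  }
  if (length(venus_mean) == 0) {
    return(list(class = factor(character(0),
                               levels = c("G1G0", "S", "G2M",
                                          "indeterminate")),
                fractions = c(G1G0 = NaN, S = NaN, G2M = NaN),
                n_classified = 0L, n_indeterminate = 0L))
  }
  vpos <- venus_mean > thr(venus_bg)
  cpos <- cherry_mean > thr(cherry_bg)
  cls <- ifelse(vpos & !cpos, "G1G0",
         ifelse(!vpos & cpos, "S",
         ifelse(vpos & cpos, "G2M", "indeterminate")))
  if (fold_indeterminate == "S") cls[cls == "indeterminate"] <- "S"
  cls <- factor(cls, levels = c("G1G0", "S", "G2M", "indeterminate"))
  counts <- table(cls)
  n_cl <- sum(counts[c("G1G0", "S", "G2M")])
  fr <- if (n_cl > 0) as.numeric(counts[c("G1G0", "S", "G2M")]) / n_cl
        else rep(NaN, 3)
  list(class = cls,
       fractions = stats::setNames(fr, c("G1G0", "S", "G2M")),
       n_classified = as.integer(n_cl),
       n_indeterminate = as.integer(counts[["indeterminate"]]))
}
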