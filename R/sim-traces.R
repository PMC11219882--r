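#' Noiseless per-cell reporter traces
#'
#' Evaluates the deterministic reporter model for every usable cell on its
#' visible frames. The mVenus (PIP-degron) channel rises exponentially to
#' its G1 plateau, collapses with the configured halving time starting
#' exactly at the true G1/S frame (reaching under 10\% of the plateau in
#' under 30 min), sits at the floor through S, then re-rises linearly from
#' the true S/G2 frame until division (capped at 90\% of the plateau so
#' daughters start near where mothers end and no spurious half-drop is
#' created at cytokinesis).
#'
#' The red channel depends on the construct:
#' * `PIP_H2A`: constitutive H2A-mScarlet at `scarlet_baseline`, modulated
#'   inversely to the normalised mVenus signal
#'   (`- scarlet_inverse_coupling * venus_norm`), with an acute one-frame
#'   spike to `scarlet_spike_factor * scarlet_baseline` on the mother's
#'   final frame (chromatid condensation at mitosis). The spike's
#'   frame-to-frame max-intensity increment always exceeds 300 on the
#'   16-bit scale, so full-cycle tracks survive the mitotic slope filter.
#' * `PIP_FUCCI`: geminin-mCherry is zero through G1, ramps up starting
#'   `cherry_onset_delay` after the true G1/S frame (leaving a 1--3 frame
#'   window where both reporters are dim -- the early-S gap), saturates at
#'   `cherry_plateau`, and disappears at division (daughters restart at
#'   zero, a >=90\% single-step drop along a continuing track).
#'
#' "Max" channels are the mean channels scaled by the rendered blob's
#' peak-to-mean ratio, keeping trace-level and pixel-level analyses
#' consistent.
#'
#' @param lineage A [sample_lineage()] result.
#' @param config The same [sim_config()] used for the lineage (defaults to
#'   `lineage$config`).
#' @return A data.frame with columns `cell_id`, `frame`, `venus_mean`,
#'   `venus_max`, `red_mean`, `red_max` (noiseless, background-free).
#'   Cells with a cycle shorter than 3 frames are flagged unusable in
#'   `lineage$cells` and omitted; their ids are attached as
#'   `attr(, "skipped_cells")`.
#' @export
reporter_traces <- function(lineage, config = lineage$config) {
  cfg <- validate_sim_config(unclass(config))
  cells <- lineage$cells
  pk <- blob_peak_to_mean()
  dt <- cfg$frame_interval
  skipped <- cells$cell_id[!cells$usable]

  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    if (!ci$usable) next
    frames <- visible_frames(ci, cfg)
    if (!length(frames)) next
    venus <- venus_trace(frames, ci, cfg)
    red <- if (cfg$construct == "PIP_H2A") {
      scarlet_trace(frames, venus, ci, cfg)
    } else {
      cherry_trace(frames, ci, cfg)
    }
    res[[i]] <- data.frame(
      cell_id = ci$cell_id, frame = frames,
      venus_mean = venus, venus_max = venus * pk,
      red_mean = red, red_max = red * pk
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "skipped_cells") <- skipped
  out
}

visible_frames <- function(cell, cfg) {
  lo <- max(cell$birth_frame, 0L)
  hi <- min(cell$division_frame - 1L, cfg$n_frames - 1L)
  if (hi < lo) integer(0) else lo:hi
}

# deterministic mVenus waveform for one cell (frames absolute, 0-based)
venus_trace <- function(frames, cell, cfg) {
  dt <- cfg$frame_interval
  v0 <- 0.75 * cfg$venus_plateau
  cap <- 0.9 * cfg$venus_plateau
  t_birth <- (frames - cell$birth_frame) * dt
  v <- cfg$venus_plateau + (v0 - cfg$venus_plateau) *
    exp(-t_birth / cfg$venus_rise_tau)
  v_at_g1s <- cfg$venus_plateau + (v0 - cfg$venus_plateau) *
    exp(-(cell$g1s_frame - cell$birth_frame) * dt / cfg$venus_rise_tau)
  inS <- frames >= cell$g1s_frame
  v[inS] <- pmax(cfg$venus_floor, v_at_g1s *
    2^(-(frames[inS] - cell$g1s_frame) * dt / cfg$venus_decay_halftime))
  inG2 <- frames >= cell$sg2_frame
  v[inG2] <- pmin(cap, cfg$venus_floor +
                    cfg$venus_g2_rise_rate * (frames[inG2] - cell$sg2_frame) * dt)
  v
}

scarlet_trace <- function(frames, venus, cell, cfg) {
  vn <- (venus - cfg$venus_floor) / (cfg$venus_plateau - cfg$venus_floor)
  vn <- pmin(pmax(vn, 0), 1)
  s <- cfg$scarlet_baseline - cfg$scarlet_inverse_coupling * vn
  # acute mitotic spike on the mother's last visible frame
  s[frames == cell$division_frame - 1L] <-
    cfg$scarlet_spike_factor * cfg$scarlet_baseline
  s
}

cherry_trace <- function(frames, cell, cfg) {
  dt <- cfg$frame_interval
  onset <- cell$g1s_frame + cfg$cherry_onset_delay / dt
  ramp <- pmax(0, (frames - onset) * dt) * cfg$cherry_ramp_rate
  pmin(ramp, cfg$cherry_plateau)
}

#' Add measurement noise to noiseless traces
#'
#' Applies the configured noise model at trace level (the same model the
#' renderer applies per pixel): a multiplicative lognormal factor
#' `exp(noise_mult_sigma * Z)` per cell per frame, an additive Gaussian
#' read-noise term, and the constant background offset. Used for fast
#' phase-call recovery experiments without rendering movies.
#'
#' @param traces Output of [reporter_traces()].
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed + 1`).
#' @return Traces with the same columns, noisy and background-offset.
#' @export
add_trace_noise <- function(traces, config, seed = config$seed + 1L) {
  cfg <- validate_sim_config(unclass(config))
  set.seed(as.integer(seed))
  n <- nrow(traces)
  out <- traces
  for (col in c("venus_mean", "venus_max", "red_mean", "red_max")) {
    m <- exp(stats::rnorm(n, 0, cfg$noise_mult_sigma))
    out[[col]] <- pmax(0, traces[[col]] * m +
                         stats::rnorm(n, 0, cfg$noise_read_sigma) +
                         cfg$background_level)
  }
  out
}
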