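#' Simulation configuration for synthetic reporter movies
#'
#' Builds a validated configuration object for the synthetic time-lapse
#' generator. Defaults describe a freely cycling primary intestinal
#' epithelial monolayer imaged every 10 minutes for 48 h at 1 um/px on a
#' 512x512 field, carrying either the PIP-H2A construct (PIP-degron mVenus
#' plus constitutive H2A-mScarlet) or the PIP-FUCCI construct (PIP-degron
#' mVenus plus geminin-mCherry).
#'
#' Phase lengths are drawn from independent lognormals parameterised by
#' median (hours) and log-sigma; the default medians (G1 8.3, S 6.0,
#' G2/M 2.5 h) and dispersions reproduce the quartiles observed for this
#' cell type (G1 \[6.2, 11.3\], S \[5.5, 6.5\], G2/M \[2.2, 3.0\] h).
#'
#' @param construct `"PIP_H2A"` or `"PIP_FUCCI"`.
#' @param frame_interval Minutes between frames (default 10).
#' @param duration Movie duration in minutes (default 2880 = 48 h); must be
#'   an integer multiple of `frame_interval`.
#' @param image_size Integer vector `c(height, width)` in pixels.
#' @param pixel_size Microns per pixel.
#' @param nucleus_diameter Apparent nucleus diameter in pixels.
#' @param n_founders Number of founder cells seeded at movie start.
#' @param phase_medians Named numeric `c(G1=, S=, G2M=)`, hours.
#' @param phase_dispersions Named numeric, lognormal sigma per phase.
#' @param venus_plateau,venus_floor mVenus G1 plateau and S-phase floor
#'   (16-bit intensity units).
#' @param venus_rise_tau Exponential time constant (minutes) of the G1
#'   mVenus rise towards the plateau.
#' @param venus_decay_halftime Halving time (minutes) of the mVenus drop at
#'   S entry; must complete to under 10\% of the plateau within 30 min.
#' @param venus_g2_rise_rate Linear mVenus re-rise during G2, intensity
#'   units per minute (capped at 90\% of the plateau).
#' @param scarlet_baseline,scarlet_spike_factor,scarlet_inverse_coupling
#'   H2A-mScarlet baseline, mitotic spike multiplier, and amplitude of the
#'   inverse-to-mVenus modulation.
#' @param cherry_ramp_rate mCherry ramp during S/G2, intensity units/min.
#' @param cherry_onset_delay Minutes after the true G1/S transition before
#'   the mCherry ramp starts; must span 1--3 frames at the configured
#'   interval (produces the early-S dual-dim gap).
#' @param cherry_plateau Saturation level of the mCherry ramp.
#' @param motion_sigma Random-walk step (um per frame) of nucleus centroids.
#' @param division_separation Distance (um) between daughter centroids at
#'   cytokinesis.
#' @param noise_read_sigma Additive Gaussian read noise sigma.
#' @param noise_mult_sigma Lognormal multiplicative noise sigma (unitless).
#' @param background_level Constant background offset.
#' @param oligomycin_scenario Optional named per-phase multipliers applied
#'   to `phase_medians` (e.g. `c(G1 = 13/6.7, S = 3.3/2.3, G2M = 3.3/2.3)`),
#'   emulating respiration inhibition as pure phase stretching.
#' @param seed Integer seed; all randomness in the simulator flows from it.
#'
#' @return An object of class `sim_config` (a validated named list with a
#'   derived `n_frames` field; frames are 0-based).
#' @export
sim_config <- function(construct = c("PIP_H2A", "PIP_FUCCI"),
                       frame_interval = 10,
                       duration = 2880,
                       image_size = c(512L, 512L),
                       pixel_size = 1.0,
                       nucleus_diameter = 12,
                       n_founders = 30L,
                       phase_medians = c(G1 = 8.3, S = 6.0, G2M = 2.5),
                       phase_dispersions = c(G1 = 0.45, S = 0.124, G2M = 0.23),
                       venus_plateau = 20000,
                       venus_floor = 200,
                       venus_rise_tau = 30,
                       venus_decay_halftime = 2.5,
                       venus_g2_rise_rate = 300,
                       scarlet_baseline = 8000,
                       scarlet_spike_factor = 2.5,
                       scarlet_inverse_coupling = 2000,
                       cherry_ramp_rate = 100,
                       cherry_onset_delay = 20,
                       cherry_plateau = 15000,
                       motion_sigma = 0.3,
                       division_separation = 12,
                       noise_read_sigma = 50,
                       noise_mult_sigma = 0.02,
                       background_level = 400,
                       oligomycin_scenario = NULL,
                       seed = 1L) {
  construct <- match.arg(construct)
  cfg <- list(
    construct = construct,
    frame_interval = as.numeric(frame_interval),
    duration = as.numeric(duration),
    image_size = as.integer(image_size),
    pixel_size = as.numeric(pixel_size),
    nucleus_diameter = as.numeric(nucleus_diameter),
    n_founders = as.integer(n_founders),
    phase_medians = phase_medians,
    phase_dispersions = phase_dispersions,
    venus_plateau = venus_plateau,
    venus_floor = venus_floor,
    venus_rise_tau = venus_rise_tau,
    venus_decay_halftime = venus_decay_halftime,
    venus_g2_rise_rate = venus_g2_rise_rate,
    scarlet_baseline = scarlet_baseline,
    scarlet_spike_factor = scarlet_spike_factor,
    scarlet_inverse_coupling = scarlet_inverse_coupling,
    cherry_ramp_rate = cherry_ramp_rate,
    cherry_onset_delay = cherry_onset_delay,
    cherry_plateau = cherry_plateau,
    motion_sigma = motion_sigma,
    division_separation = division_separation,
    noise_read_sigma = noise_read_sigma,
    noise_mult_sigma = noise_mult_sigma,
    background_level = background_level,
    oligomycin_scenario = oligomycin_scenario,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$frame_interval <= 0)
    stop("frame_interval must be positive")
  if (cfg$duration <= 0)
    stop("degenerate config: zero-length movie (duration must be > 0)")
  if (abs(cfg$duration %% cfg$frame_interval) > 1e-9)
    stop("duration must be an integer multiple of frame_interval")
  for (nm in c("G1", "S", "G2M")) {
    if (!nm %in% names(cfg$phase_medians) || cfg$phase_medians[[nm]] <= 0)
      stop("phase_medians must contain strictly positive ", nm)
    if (!nm %in% names(cfg$phase_dispersions) || cfg$phase_dispersions[[nm]] <= 0)
      stop("phase_dispersions must contain strictly positive ", nm)
  }
  if (!(cfg$venus_plateau > cfg$venus_floor && cfg$venus_floor >= 0))
    stop("require venus_plateau > venus_floor >= 0")
  # decay to < 10% of plateau must complete within 30 minutes
  if (cfg$venus_decay_halftime * log2(10) > 30)
    stop("venus_decay_halftime too slow: mVenus must fall below 10% of its ",
         "plateau within 30 min (halftime <= ", round(30 / log2(10), 2),
         " min)")
  delay_frames <- cfg$cherry_onset_delay / cfg$frame_interval
  if (delay_frames < 1 - 1e-9 || delay_frames > 3 + 1e-9)
    stop("cherry_onset_delay must span 1-3 frames at the configured interval")
  if (cfg$n_founders < 1)
    stop("n_founders must be >= 1")
  if (!is.null(cfg$oligomycin_scenario)) {
    bad <- setdiff(names(cfg$oligomycin_scenario), c("G1", "S", "G2M"))
    if (length(bad))
      stop("unknown phase in oligomycin_scenario: ", paste(bad, collapse = ", "))
  }
  cfg$n_frames <- as.integer(round(cfg$duration / cfg$frame_interval)) + 1L
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> construct:", x$construct,
      "| frames:", x$n_frames, "x", x$frame_interval, "min",
      "| field:", paste(x$image_size, collapse = "x"), "px",
      "| founders:", x$n_founders, "| seed:", x$seed, "\n")
  med <- effective_phase_medians(x)
  cat("  phase medians (h): G1", med[["G1"]], " S", med[["S"]],
      " G2M", med[["G2M"]], "\n")
  invisible(x)
}

# medians after applying any perturbation scenario
effective_phase_medians <- function(cfg) {
  med <- cfg$phase_medians
  if (!is.null(cfg$oligomycin_scenario)) {
    for (nm in names(cfg$oligomycin_scenario))
      med[[nm]] <- med[[nm]] * cfg$oligomycin_scenario[[nm]]
  }
  med
}

# Ratio between a rendered Gaussian blob's peak and its mean over the
# nucleus disk (sigma = diameter/4, radius = diameter/2, so r = 2*sigma):
#   mean/peak = (2 sigma^2 / r^2) * (1 - exp(-r^2 / (2 sigma^2)))
#             = (1 - exp(-2)) / 2
# Used to keep trace "max" channels and rendered pixel maxima consistent.
blob_peak_to_mean <- function() 2 / (1 - exp(-2))

# deterministic per-cell sub-stream seed derived from the master seed
cell_seed <- function(master, cell_id) {
  as.integer((as.double(master) * 48271 + as.double(cell_id) * 16807) %%
               2147483647)
}
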