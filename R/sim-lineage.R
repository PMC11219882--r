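#' Sample a ground-truth cell lineage
#'
#' Draws a branching lineage of cycling cells over the configured movie.
#' Founders start at uniformly random positions within their cycle (so the
#' population is unsynchronised, as in a freely cycling monolayer); every
#' cell draws independent lognormal G1, S and G2/M durations, divides into
#' two daughters, and the process continues until the movie ends. Phase
#' boundaries are discretised to frames with every phase at least one frame
#' long, so `birth < g1s < sg2 < division` holds for every cell and the
#' three phase durations sum exactly to the division-to-division duration.
#'
#' Nucleus centroids perform a random walk (sigma `motion_sigma` um/frame)
#' with soft pairwise repulsion so neighbouring nuclei never overlap by
#' more than ~30\% of a diameter; daughters are placed
#' `division_separation/2` um either side of the mother along a random
#' axis.
#'
#' A cell is "alive" on frames `[birth_frame, division_frame - 1]`; its
#' daughters' `birth_frame` equals its `division_frame`. The acute mitotic
#' events therefore occur on a mother's final frame.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `lineage_truth`: a list with
#'   * `cells`: one row per cell (`cell_id`, `parent_id`, `birth_frame`,
#'     `g1s_frame`, `sg2_frame`, `division_frame`, `completed`, `usable`);
#'   * `positions`: one row per cell per visible frame (`cell_id`, `frame`,
#'     `x_um`, `y_um`, `label`);
#'   * `config`: the configuration used.
#'   Frames are 0-based; founders may have negative `birth_frame`.
#' @export
sample_lineage <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  last_frame <- cfg$n_frames - 1L
  med_h <- effective_phase_medians(cfg)
  sig <- cfg$phase_dispersions
  dt <- cfg$frame_interval

  draw_phases_frames <- function() {
    # lognormal: median * exp(sigma * Z), in minutes, then >=1 frame each
    z <- stats::rnorm(3)
    mins <- c(med_h[["G1"]] * 60 * exp(sig[["G1"]] * z[1]),
              med_h[["S"]]  * 60 * exp(sig[["S"]]  * z[2]),
              med_h[["G2M"]] * 60 * exp(sig[["G2M"]] * z[3]))
    pmax(1L, as.integer(round(mins / dt)))
  }

  cells <- list()
  queue <- new.env(parent = emptyenv())
  queue$next_id <- 1L
  pending <- list()
  for (i in seq_len(cfg$n_founders)) {
    pending[[length(pending) + 1L]] <-
      list(parent = NA_integer_, birth = NA_integer_, founder = TRUE)
  }

  angles <- numeric(0)
  while (length(pending)) {
    item <- pending[[1L]]
    pending[[1L]] <- NULL
    id <- queue$next_id
    queue$next_id <- id + 1L
    set.seed(cell_seed(cfg$seed, id))
    ph <- draw_phases_frames()
    if (item$founder) {
      total <- sum(ph)
      birth <- -as.integer(floor(stats::runif(1) * total))
    } else {
      birth <- item$birth
    }
    g1s <- birth + ph[1]
    sg2 <- g1s + ph[2]
    division <- sg2 + ph[3]
    angle <- stats::runif(1, 0, 2 * pi)
    completed <- division <= last_frame
    cells[[id]] <- data.frame(
      cell_id = id, parent_id = item$parent,
      birth_frame = birth, g1s_frame = g1s, sg2_frame = sg2,
      division_frame = division, completed = completed,
      usable = (division - birth) >= 3L
    )
    angles[id] <- angle
    if (completed) {
      pending[[length(pending) + 1L]] <-
        list(parent = id, birth = division, founder = FALSE)
      pending[[length(pending) + 1L]] <-
        list(parent = id, birth = division, founder = FALSE)
    }
  }
  cells <- do.call(rbind, cells)

  positions <- simulate_positions(cells, angles, cfg)
  structure(list(cells = cells, positions = positions, config = cfg),
            class = "lineage_truth")
}

# random-walk + soft-repulsion centroid dynamics; deterministic for a seed
simulate_positions <- function(cells, angles, cfg) {
  last_frame <- cfg$n_frames - 1L
  W <- cfg$image_size[2] * cfg$pixel_size
  H <- cfg$image_size[1] * cfg$pixel_size
  # centroids stay a full diameter inside the field so no nucleus is
  # truncated by the border (the scene emulates the interior of a larger
  # stitched monolayer)
  r_um <- cfg$nucleus_diameter * cfg$pixel_size
  min_sep <- 0.7 * cfg$nucleus_diameter * cfg$pixel_size

  set.seed(cell_seed(cfg$seed, 0L))
  n_cells <- nrow(cells)
  founder_xy <- cbind(stats::runif(n_cells, r_um, W - r_um),
                      stats::runif(n_cells, r_um, H - r_um))

  alive_from <- pmax(cells$birth_frame, 0L)
  alive_to <- pmin(cells$division_frame - 1L, last_frame)

  pos <- matrix(NA_real_, n_cells, 2)
  out <- vector("list", cfg$n_frames)
  for (f in 0:last_frame) {
    newly <- which(alive_from == f | (f == 0L & alive_from < 0L))
    for (id in newly) {
      if (is.na(cells$parent_id[id])) {
        pos[id, ] <- founder_xy[id, ]
      } else {
        p <- cells$parent_id[id]
        mother <- if (any(!is.na(pos[p, ]))) pos[p, ] else founder_xy[p, ]
        # daughters of one division get opposite signs along the same axis
        sibs <- which(!is.na(cells$parent_id) & cells$parent_id == p)
        side <- if (id == sibs[1]) 1 else -1
        a <- angles[p]
        pos[id, ] <- mother + side * (cfg$division_separation / 2) *
          c(cos(a), sin(a))
      }
    }
    alive <- which(alive_from <= f & alive_to >= f)
    cont <- setdiff(alive, newly)
    if (length(cont)) {
      pos[cont, ] <- pos[cont, ] +
        matrix(stats::rnorm(2 * length(cont), 0, cfg$motion_sigma),
               ncol = 2)
    }
    if (length(alive)) {
      # soft repulsion with boundary clamping inside the loop, so a cell
      # pushed against the field edge cannot silently re-overlap its
      # neighbour after a final clamp
      for (it in 1:8) {
        pos[alive, 1] <- pmin(pmax(pos[alive, 1], r_um), W - r_um)
        pos[alive, 2] <- pmin(pmax(pos[alive, 2], r_um), H - r_um)
        if (length(alive) == 1) break
        d <- as.matrix(stats::dist(pos[alive, , drop = FALSE]))
        bad <- which(d < min_sep & upper.tri(d), arr.ind = TRUE)
        if (!nrow(bad)) break
        for (k in seq_len(nrow(bad))) {
          i <- alive[bad[k, 1]]; j <- alive[bad[k, 2]]
          v <- pos[j, ] - pos[i, ]
          nv <- sqrt(sum(v^2))
          if (nv < 1e-9) { v <- c(1, 0); nv <- 1 }
          push <- (min_sep - nv) / 2 + 1e-6
          pos[i, ] <- pos[i, ] - v / nv * push
          pos[j, ] <- pos[j, ] + v / nv * push
        }
      }
      pos[alive, 1] <- pmin(pmax(pos[alive, 1], r_um), W - r_um)
      pos[alive, 2] <- pmin(pmax(pos[alive, 2], r_um), H - r_um)
      out[[f + 1L]] <- data.frame(
        cell_id = alive, frame = f,
        x_um = pos[alive, 1], y_um = pos[alive, 2], label = alive
      )
    }
  }
  do.call(rbind, out)
}

#' Sample phase durations directly
#'
#' Draws `n` independent (G1, S, G2M) duration triplets from the
#' configured lognormals (median x exp(sigma Z)), without building a
#' lineage -- the continuous-time distribution underlying
#' [sample_lineage()] before frame discretisation. Applies any
#' perturbation scenario in the config.
#'
#' @param config A [sim_config()].
#' @param n Number of cells to draw.
#' @param seed Seed (defaults to `config$seed`).
#' @return A data.frame with numeric columns `G1`, `S`, `G2M` in hours.
#' @export
sample_phase_lengths <- function(config, n, seed = config$seed) {
  cfg <- validate_sim_config(unclass(config))
  med <- effective_phase_medians(cfg)
  sig <- cfg$phase_dispersions
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(3 * n), ncol = 3)
  data.frame(G1 = med[["G1"]] * exp(sig[["G1"]] * z[, 1]),
             S = med[["S"]] * exp(sig[["S"]] * z[, 2]),
             G2M = med[["G2M"]] * exp(sig[["G2M"]] * z[, 3]))
}

#' Count cells alive at a frame
#'
#' @param lineage A [sample_lineage()] result.
#' @param frame 0-based frame index.
#' @return Integer count of nuclei present on that frame.
#' @export
cells_alive <- function(lineage, frame) {
  with(lineage$cells,
       sum(pmax(birth_frame, 0L) <= frame & (division_frame - 1L) >= frame &
             birth_frame <= frame))
}

#' @export
print.lineage_truth <- function(x, ...) {
  cat("<lineage_truth>", nrow(x$cells), "cells,",
      sum(x$cells$completed), "completed cycles,",
      x$config$n_frames, "frames\n")
  invisible(x)
}
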