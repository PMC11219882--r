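test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(duration = 0), "zero-length")
  expect_error(sim_config(duration = 95), "integer multiple")
  expect_error(sim_config(phase_medians = c(G1 = -1, S = 6, G2M = 2.5)),
               "strictly positive")
  expect_error(sim_config(venus_floor = 30000), "venus_plateau")
  expect_error(sim_config(venus_decay_halftime = 15), "30 min")
  expect_error(sim_config(cherry_onset_delay = 45), "1-3 frames")
  expect_identical(sim_config()$n_frames, 289L)
})

test_that("zero-dispersion lineage has fixed phase durations", {
  cfg <- sim_config(n_founders = 8, phase_dispersions =
                      c(G1 = 1e-9, S = 1e-9, G2M = 1e-9),
                    image_size = c(256L, 256L), seed = 5)
  lin <- sample_lineage(cfg)
  g1_min <- (lin$cells$g1s_frame - lin$cells$birth_frame) * 10
  expect_true(all(abs(g1_min - 8.3 * 60) <= 5))   # half a frame
  s_min <- (lin$cells$sg2_frame - lin$cells$g1s_frame) * 10
  expect_true(all(abs(s_min - 6.0 * 60) <= 5))
})

test_that("lineage is deterministic and structurally consistent", {
  cfg <- tiny_config()
  lin1 <- sample_lineage(cfg)
  lin2 <- sample_lineage(cfg)
  expect_identical(lin1$cells, lin2$cells)
  expect_identical(lin1$positions, lin2$positions)

  cells <- lin1$cells
  expect_true(all(cells$birth_frame < cells$g1s_frame))
  expect_true(all(cells$g1s_frame < cells$sg2_frame))
  expect_true(all(cells$sg2_frame < cells$division_frame))
  # phase durations sum exactly to the cycle duration
  expect_identical(
    (cells$g1s_frame - cells$birth_frame) +
      (cells$sg2_frame - cells$g1s_frame) +
      (cells$division_frame - cells$sg2_frame),
    cells$division_frame - cells$birth_frame)
  # daughters born at the parent's division frame
  kids <- cells[!is.na(cells$parent_id), ]
  expect_identical(kids$birth_frame,
                   cells$division_frame[match(kids$parent_id,
                                              cells$cell_id)])
})

test_that("sampled phase lengths match the configured lognormal", {
  cfg <- sim_config()
  d <- sample_phase_lengths(cfg, 10000, seed = 2)
  q <- quantile(d$G1, c(0.25, 0.5, 0.75), names = FALSE)
  expect_lt(abs(q[2] - 8.3) / 8.3, 0.02)
  expect_lt(abs(q[1] - 6.2) / 6.2, 0.05)
  expect_lt(abs(q[3] - 11.3) / 11.3, 0.05)
  # perturbation scenario stretches medians multiplicatively
  cfg2 <- sim_config(oligomycin_scenario = c(G1 = 13 / 6.7))
  d2 <- sample_phase_lengths(cfg2, 10000, seed = 2)
  expect_lt(abs(median(d2$G1) - 8.3 * 13 / 6.7) / (8.3 * 13 / 6.7), 0.02)
})

test_that("noiseless reporter traces follow the construct model", {
  # explicit halftime example: one halving per 10-min frame at S entry
  cfg <- sim_config(n_founders = 2, image_size = c(256L, 256L),
                    venus_decay_halftime = 9, seed = 9,
                    noise_mult_sigma = 0, noise_read_sigma = 0)
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  cells <- lin$cells[lin$cells$completed & lin$cells$birth_frame >= 0, ]
  expect_gt(nrow(cells), 0)
  for (k in seq_len(nrow(cells))) {
    ci <- cells[k, ]
    v <- tr[tr$cell_id == ci$cell_id, ]
    at <- function(f) v[v$frame == f, ]
    # decay: below half the G1 level one frame after the true G1/S
    expect_lte(at(ci$g1s_frame + 1)$venus_mean,
               0.5 * cfg$venus_plateau + 1e-6)
    # mitotic spike: red max jumps by far more than the slope threshold
    spike <- at(ci$division_frame - 1)$red_max -
      at(ci$division_frame - 2)$red_max
    expect_gt(spike, 300)
    # spike is the global per-cycle maximum of the red trace
    expect_equal(which.max(v$red_mean), nrow(v))
  }
})

test_that("FUCCI traces show the early-S dual-dim gap", {
  cfg <- sim_config(construct = "PIP_FUCCI", n_founders = 3,
                    image_size = c(256L, 256L), seed = 21,
                    noise_mult_sigma = 0, noise_read_sigma = 0)
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  delay_frames <- cfg$cherry_onset_delay / cfg$frame_interval
  cells <- lin$cells[lin$cells$g1s_frame >= 0 &
                       lin$cells$sg2_frame <= cfg$n_frames - 1, ]
  gap_seen <- FALSE
  for (k in seq_len(nrow(cells))) {
    ci <- cells[k, ]
    v <- tr[tr$cell_id == ci$cell_id, ]
    gap <- v[v$frame > ci$g1s_frame &
               v$frame <= ci$g1s_frame + delay_frames, ]
    if (!nrow(gap)) next
    gap_seen <- TRUE
    expect_true(all(gap$venus_mean < 0.1 * cfg$venus_plateau))
    expect_true(all(gap$red_mean < 0.1 * cfg$cherry_plateau))
    # cherry collapses at division: daughter restarts at zero
    post <- v[v$frame > ci$sg2_frame, ]
    if (nrow(post)) expect_true(all(post$red_mean >= 0))
  }
  expect_true(gap_seen)
})

test_that("rendering matches the closed-form noiseless model", {
  # empty scene: frames are exactly the background, labels all zero
  cfg <- sim_config(n_founders = 1, duration = 20, seed = 1,
                    image_size = c(64L, 64L),
                    noise_mult_sigma = 0, noise_read_sigma = 0)
  lin <- sample_lineage(cfg)
  lin$positions <- lin$positions[0, ]
  tr <- reporter_traces(lin)[0, ]
  mv <- render_movie(lin, tr, cfg)
  expect_true(all(vapply(mv$venus, function(m)
    all(m == cfg$background_level), TRUE)))
  expect_true(all(vapply(mv$labels, function(m) all(m == 0L), TRUE)))

  # one static nucleus at a pixel centre: peak = background + mean * pk
  lin2 <- sample_lineage(cfg)
  lin2$cells <- data.frame(cell_id = 1L, parent_id = NA_integer_,
                           birth_frame = 0L, g1s_frame = 40L,
                           sg2_frame = 80L, division_frame = 100L,
                           completed = FALSE, usable = TRUE)
  lin2$positions <- data.frame(cell_id = 1L, frame = 0:2, x_um = 32,
                               y_um = 32, label = 1L)
  tr2 <- reporter_traces(lin2, cfg)
  tr2 <- tr2[tr2$frame <= 2, ]
  mv2 <- render_movie(lin2, tr2, cfg, frames = 0:2)
  pk <- tr2$venus_mean[1] * 2 / (1 - exp(-2))
  expect_equal(mv2$venus[[1]][33, 33], round(cfg$background_level + pk),
               tolerance = 1e-8)

  # per-frame truth label count equals cells alive
  cfg3 <- tiny_config()
  lin3 <- sample_lineage(cfg3)
  tr3 <- reporter_traces(lin3)
  mv3 <- render_movie(lin3, tr3, frames = c(0L, 20L, 40L))
  for (i in seq_along(mv3$frames)) {
    f <- mv3$frames[i]
    expect_identical(length(unique(mv3$labels[[i]][mv3$labels[[i]] > 0])),
                     as.integer(cells_alive(lin3, f)))
  }
})

test_that("fixtures round-trip losslessly", {
  cfg <- sim_config(n_founders = 2, image_size = c(64L, 64L),
                    duration = 100, seed = 13)
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  mv <- render_movie(lin, tr)
  dir <- withr::local_tempdir()
  write_fixture(lin, tr, mv, dir)
  fx <- read_fixture(dir)
  expect_identical(fx$labels, lapply(mv$labels, function(m) {
    storage.mode(m) <- "integer"; m
  }))
  expect_equal(fx$venus, mv$venus, ignore_attr = TRUE)
  # truth table row count equals total alive cell-frames
  expect_identical(nrow(fx$positions), nrow(lin$positions))
  expect_identical(fx$config$seed, cfg$seed)
  expect_equal(fx$config$phase_medians, cfg$phase_medians)
  expect_equal(fx$config$noise_mult_sigma, cfg$noise_mult_sigma)
})
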