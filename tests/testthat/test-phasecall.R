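# deterministic single-cycle venus waveform: plateau, exponential drop at
# g1s, floor through S, linear re-rise from sg2
toy_cycle <- function(n = 120, g1s = 50, sg2 = 90, plateau = 20000,
                      floor = 200, halftime_frames = 1) {
  f <- 0:(n - 1)
  v <- rep(plateau, n)
  dec <- f >= g1s
  v[dec] <- pmax(floor, plateau * 2^(-(f[dec] - g1s) / halftime_frames))
  ris <- f >= sg2
  v[ris] <- pmin(0.9 * plateau, floor + 3000 * (f[ris] - sg2))
  v
}

test_that("normalize_trace is a monotone affine-invariant map", {
  set.seed(2)
  x <- toy_cycle() + rnorm(120, 0, 100)
  nz <- normalize_trace(x)
  nz2 <- normalize_trace(3.7 * x + 1234)
  expect_equal(nz$values, nz2$values, tolerance = 1e-12)
  expect_equal(nz$noise_scale, nz2$noise_scale, tolerance = 1e-12)
  expect_identical(order(x), order(nz$values))

  cz <- normalize_trace(rep(5, 50))
  expect_true(all(cz$values == 0))
  expect_identical(cz$noise_scale, 0)

  # noiseless G1 plateau normalises to >= 0.9
  nz3 <- normalize_trace(toy_cycle())
  expect_gte(median(nz3$values[1:40]), 0.9)

  expect_error(normalize_trace(1:4), "5 frames")
})

test_that("call_g1s implements the half-drop rule", {
  # exactly one halving per frame: first sub-50% frame is g1s + 1
  v <- toy_cycle(g1s = 50, halftime_frames = 1)
  g <- call_g1s(v)
  expect_identical(g$frame, 51L)
  expect_identical(g$flag, "")

  # constant trace: no call
  expect_identical(call_g1s(rep(7, 60))$flag, "NO_G1S")

  # affine rescaling leaves the call unchanged
  expect_identical(call_g1s(0.2 * v + 900)$frame, 51L)

  # absolute frames respected
  expect_identical(call_g1s(v, frames = 100:219)$frame, 151L)
})

test_that("call_sg2 implements the lowest-maintained-level rule", {
  v <- toy_cycle(g1s = 50, sg2 = 90)
  g <- call_g1s(v)
  s <- call_sg2(v, g$frame, plateau = g$plateau,
                noise_scale = g$noise_scale)
  expect_lte(abs(s$frame - 90), 1)
  expect_identical(s$flag, "")

  # flat after g1s: no call
  v2 <- v; v2[v2 > 200 & seq_along(v2) > 55] <- 200
  v2[56:120] <- 200
  s2 <- call_sg2(v2, 51, plateau = 1, noise_scale = 0)
  expect_identical(s2$flag, "NO_SG2")

  # a single-frame spike of 5x the noise scale is ignored (persistence):
  # the call stays at the genuine rise, not the spike
  v3 <- v; v3[70] <- v3[70] + 0.5 * 20000
  s3 <- call_sg2(v3, g$frame, plateau = g$plateau, noise_scale = 0.1)
  expect_gt(abs(s3$frame - 69), 1)
  expect_gte(s3$frame, 90)
})

test_that("phase_lengths computes exact arithmetic and validates order", {
  pl <- phase_lengths(30, 80, 116, 131, 10)
  expect_equal(pl$G1_h, 50 / 6)
  expect_equal(pl$S_h, 6)
  expect_equal(pl$G2M_h, 2.5)
  expect_equal(pl$total_h, 101 / 6)
  expect_equal(pl$G1_h + pl$S_h + pl$G2M_h, pl$total_h)
  expect_error(phase_lengths(30, 80, 80, 131), "ordering")
})

test_that("calls are recovered within one frame on simulated cycles", {
  cfg <- trace_config()
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  by_cell <- split(tr, tr$cell_id)
  cells <- lin$cells
  ids <- cells$cell_id[!is.na(cells$parent_id) & cells$completed]
  errs <- list(g1s = c(), sg2 = c())
  for (cid in ids) {
    seg <- stitch_cycle(lin, by_cell, cid)
    if (is.null(seg)) next
    cc <- call_cycle(seg$venus_mean, seg$frame, cfg$frame_interval)
    if (cc$flags != "") next
    ci <- cells[cells$cell_id == cid, ]
    errs$g1s <- c(errs$g1s, cc$g1s_frame - ci$g1s_frame)
    errs$sg2 <- c(errs$sg2, cc$sg2_frame - ci$sg2_frame)
    # the per-cycle identity holds by construction
    expect_equal(cc$G1_h + cc$S_h + cc$G2M_h, cc$total_h)
  }
  expect_gte(length(errs$g1s), 50)
  expect_true(all(abs(errs$g1s) <= 1))
  expect_true(all(abs(errs$sg2) <= 1))
})

test_that("noisier traces never call transitions more accurately", {
  cfg <- trace_config()
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  cells <- lin$cells
  ids <- head(cells$cell_id[!is.na(cells$parent_id) & cells$completed], 60)
  med_err <- c()
  for (sigma in c(0, 0.02, 0.08, 0.2)) {
    cfg_n <- tiny_config(noise_mult_sigma = sigma, noise_read_sigma = 50)
    ntr <- add_trace_noise(tr, cfg_n, seed = 500)
    by_cell <- split(ntr, ntr$cell_id)
    errs <- c()
    for (cid in ids) {
      seg <- stitch_cycle(lin, by_cell, cid)
      if (is.null(seg)) next
      cc <- call_cycle(seg$venus_mean, seg$frame, cfg$frame_interval)
      ci <- cells[cells$cell_id == cid, ]
      if (!is.na(cc$g1s_frame))
        errs <- c(errs, abs(cc$g1s_frame - ci$g1s_frame))
    }
    med_err <- c(med_err, median(errs))
  }
  expect_true(all(diff(med_err) >= 0))
})

test_that("FUCCI cycles apply the acclimation and completion windows", {
  cfg <- sim_config(construct = "PIP_FUCCI", n_founders = 25,
                    image_size = c(512L, 512L), seed = 31,
                    noise_mult_sigma = 0, noise_read_sigma = 0)
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  by_cell <- split(tr, tr$cell_id)
  cells <- lin$cells
  last <- cfg$n_frames - 1
  n_ok <- 0; n_early <- 0; n_late <- 0
  for (cid in cells$cell_id[!is.na(cells$parent_id) & cells$completed]) {
    seg <- stitch_cycle(lin, by_cell, cid, pad = 1)
    if (is.null(seg)) next
    ci <- cells[cells$cell_id == cid, ]
    res <- call_fucci_cycle(seg$venus_mean, seg$red_mean, seg$frame,
                            cfg$frame_interval, recording_start = 0,
                            recording_end = last)
    start_h <- ci$birth_frame * 10 / 60
    left_h <- (last - ci$birth_frame) * 10 / 60
    if (start_h < 5) {
      expect_identical(res$reason, "TOO_EARLY")
      n_early <- n_early + 1
    } else if (left_h < 20) {
      expect_identical(res$reason, "TOO_LATE")
      n_late <- n_late + 1
    } else if (res$status == "ok" && res$calls$flags == "") {
      expect_lte(abs(res$calls$start_frame - ci$birth_frame), 1)
      expect_lte(abs(res$calls$end_frame - ci$division_frame), 1)
      expect_lte(abs(res$calls$g1s_frame - ci$g1s_frame), 1)
      expect_lte(abs(res$calls$sg2_frame - ci$sg2_frame), 1)
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok, 10)
  expect_gte(n_late, 1)
})

test_that("snapshot classification maps colours to phases", {
  bgv <- c(median = 500, mad = 50)
  bgc <- c(median = 450, mad = 40)
  cl <- classify_snapshot(c(9000, 520, 9000, 510),
                          c(400, 8000, 8000, 430), bgv, bgc)
  expect_identical(as.character(cl$class),
                   c("G1G0", "S", "G2M", "indeterminate"))
  expect_equal(sum(cl$fractions), 1)
  expect_identical(cl$n_indeterminate, 1L)
  # fold-into-S option
  cl2 <- classify_snapshot(c(9000, 520, 9000, 510),
                           c(400, 8000, 8000, 430), bgv, bgc,
                           fold_indeterminate = "S")
  expect_identical(cl2$n_indeterminate, 0L)
  expect_equal(cl2$fractions[["S"]], 0.5)
  # zero nuclei: empty report
  cl3 <- classify_snapshot(numeric(0), numeric(0), bgv, bgc)
  expect_identical(cl3$n_classified, 0L)
})

test_that("snapshot fractions recover a known phase mix", {
  set.seed(60)
  n <- 400
  mix <- sample(c("G1G0", "S", "G2M"), n, replace = TRUE,
                prob = c(0.6, 0.3, 0.1))
  venus <- ifelse(mix %in% c("G1G0", "G2M"), 9000, 0) + rnorm(n, 500, 50)
  cherry <- ifelse(mix %in% c("S", "G2M"), 8000, 0) + rnorm(n, 450, 40)
  cl <- classify_snapshot(venus, cherry, c(median = 500, mad = 50),
                          c(median = 450, mad = 40))
  p_hat <- as.numeric(table(mix)[c("G1G0", "S", "G2M")]) / n
  # recovered fractions within binomial 95% bounds of the generating mix
  for (k in 1:3) {
    se <- sqrt(p_hat[k] * (1 - p_hat[k]) / n)
    expect_lte(abs(cl$fractions[k] - p_hat[k]), 1.96 * se + 1e-9)
  }
})
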