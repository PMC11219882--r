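dets <- function(x, y, frame = 0L) {
  n <- length(x)
  data.frame(frame = rep_len(frame, n), label = seq_len(n), x_um = x,
             y_um = y, area_px2 = rep_len(100, n),
             venus_mean = rep_len(1000, n), venus_max = rep_len(2000, n),
             red_mean = rep_len(500, n), red_max = rep_len(800, n))
}

test_that("link_frames honours the maximum displacement", {
  a <- dets(10, 10)
  expect_identical(nrow(link_frames(a, dets(15, 10, 1L), 10)), 1L)  # 5 um
  expect_identical(nrow(link_frames(a, dets(21, 10, 1L), 10)), 0L)  # 11 um
  expect_identical(nrow(link_frames(a, dets(numeric(0), numeric(0)), 10)),
                   0L)
  expect_error(link_frames(a, a, 0), "positive")
})

test_that("link_frames equals the brute-force optimal assignment", {
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    a <- dets(runif(n, 0, 30), runif(n, 0, 30))
    b <- dets(runif(m, 0, 30), runif(m, 0, 30), 1L)
    got <- canon_links(link_frames(a, b, 10))
    want <- canon_links(brute_force_links(a, b, 10))
    expect_identical(got, want)
  }
})

test_that("build_tracks produces gap-free tracks with division handling", {
  # static single cell: exactly one track spanning all frames
  d <- do.call(rbind, lapply(0:9, function(f) dets(50, 50, f)))
  tt <- build_tracks(d, 10, 10)
  expect_identical(length(unique(tt$track_id)), 1L)
  expect_identical(nrow(tt), 10L)

  # one division at frame 5: mother continues into the nearer daughter,
  # the farther daughter starts a second track
  rows <- list()
  for (f in 0:4) rows[[f + 1]] <- dets(50, 50, f)
  for (f in 5:9) {
    rows[[f + 1]] <- dets(c(50 - 4, 50 + 6), c(50, 50), f)
  }
  tt2 <- build_tracks(do.call(rbind, rows), 10, 10)
  expect_identical(length(unique(tt2$track_id)), 2L)
  mother <- tt2$track_id[tt2$frame == 0]
  cont <- tt2[tt2$track_id == mother & tt2$frame == 5, ]
  expect_equal(cont$x_um, 46)   # nearer daughter

  # deleted detection: the track ends and a new one starts (no closing)
  d3 <- d[d$frame != 5, ]
  tt3 <- build_tracks(d3, 10, 10)
  expect_identical(length(unique(tt3$track_id)), 2L)
  ends <- tapply(tt3$frame, tt3$track_id, range)
  expect_identical(unname(ends[[1]]), c(0L, 4L))
  expect_identical(unname(ends[[2]]), c(6L, 9L))

  # no track ever contains a gap or an over-long displacement
  for (tt_chk in list(tt, tt2, tt3)) {
    for (id in unique(tt_chk$track_id)) {
      tr <- tt_chk[tt_chk$track_id == id, ]
      expect_true(all(diff(tr$frame) == 1))
      if (nrow(tr) > 1)
        expect_true(all(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) <= 10))
    }
  }

  expect_error(build_tracks(transform(d, frame = rev(frame))), NA)
  expect_identical(nrow(build_tracks(d[0, ], 10, 10)), 0L)
})

test_that("tracking covers full cycles on a rendered movie", {
  cfg <- tiny_config(seed = 8)
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  mv <- render_movie(lin, tr)
  labs <- segment_movie(sum_channels(mv$venus, mv$red),
                        cfg$nucleus_diameter)
  d <- detections_from_labels(labs, mv$venus, mv$red, cfg$pixel_size)
  tt <- build_tracks(d, cfg$frame_interval, 10)
  # every detection in exactly one track
  expect_identical(nrow(tt), nrow(d))
  expect_false(any(duplicated(tt[, c("frame", "label")])))
})

test_that("full cycles are covered by single tracks when divisions are wide", {
  # the coverage guarantee holds for divisions >= 3 diameters apart
  cfg <- tiny_config(seed = 15, n_founders = 3, duration = 1500,
                     division_separation = 36)
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  mv <- render_movie(lin, tr)
  labs <- segment_movie(sum_channels(mv$venus, mv$red),
                        cfg$nucleus_diameter)
  d <- detections_from_labels(labs, mv$venus, mv$red, cfg$pixel_size)
  tt <- build_tracks(d, cfg$frame_interval, 10)
  spans <- lapply(split(tt$frame, tt$track_id), range)
  cells <- lin$cells
  full <- cells[!is.na(cells$parent_id) & cells$completed &
                  cells$birth_frame >= 1, ]
  expect_gt(nrow(full), 0)
  covered <- vapply(seq_len(nrow(full)), function(k) {
    any(vapply(spans, function(s)
      s[1] <= full$birth_frame[k] - 1 &&
        s[2] >= full$division_frame[k] - 1, TRUE))
  }, TRUE)
  expect_gte(mean(covered), 0.95)
})
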