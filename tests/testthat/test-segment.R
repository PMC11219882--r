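# render a frame with nuclei at given (x, y) um and given mean intensity
render_blob_frame <- function(xy, means, size = 96L, diameter = 12) {
  cfg <- sim_config(n_founders = 1, image_size = c(size, size),
                    duration = 10, nucleus_diameter = diameter,
                    noise_mult_sigma = 0, noise_read_sigma = 0, seed = 1)
  lin <- sample_lineage(cfg)
  n <- nrow(xy)
  lin$cells <- data.frame(cell_id = seq_len(n), parent_id = NA_integer_,
                          birth_frame = 0L, g1s_frame = 5L,
                          sg2_frame = 10L, division_frame = 15L,
                          completed = FALSE, usable = TRUE)
  lin$positions <- data.frame(cell_id = seq_len(n), frame = 0L,
                              x_um = xy[, 1], y_um = xy[, 2],
                              label = seq_len(n))
  traces <- data.frame(cell_id = seq_len(n), frame = 0L,
                       venus_mean = means, venus_max = means * 2.313,
                       red_mean = 0, red_max = 0)
  render_movie(lin, traces, cfg, frames = 0L)
}

test_that("sum_channels follows the saturating-sum definition", {
  a <- matrix(c(100, 60000, 0, 300), 2, 2)
  b <- matrix(c(200, 20000, 0, 0), 2, 2)
  s <- sum_channels(a, b)
  expect_equal(s[1, 1], 300)
  expect_equal(s[2, 1], 65535)     # saturation policy
  expect_equal(sum_channels(a, matrix(0, 2, 2)), a)   # identity
  expect_error(sum_channels(a, matrix(0, 3, 2)), "shape mismatch")
  # list form
  s2 <- sum_channels(list(a, a), list(b, b))
  expect_equal(s2[[2]], s)
})

test_that("the default detector finds isolated rendered nuclei", {
  mv <- render_blob_frame(cbind(40, 40), 15000)
  lab <- segment_frame(sum_channels(mv$venus, mv$red)[[1]], 12)
  expect_identical(length(unique(lab[lab > 0])), 1L)
  idx <- which(lab == 1, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, 2] - 1) - 40), 1)   # centroid within 1 px
  expect_lt(abs(mean(idx[, 1] - 1) - 40), 1)

  # two blobs three diameters apart -> two labels
  mv2 <- render_blob_frame(cbind(c(30, 66), c(48, 48)), c(15000, 4000))
  lab2 <- segment_frame(sum_channels(mv2$venus, mv2$red)[[1]], 12)
  expect_identical(length(unique(lab2[lab2 > 0])), 2L)

  # flat frame -> no labels, no error
  flat <- matrix(400, 96, 96)
  expect_true(all(segment_frame(flat, 12) == 0L))
})

test_that("segment_frame is translation-equivariant on interior nuclei", {
  mv <- render_blob_frame(cbind(c(40, 60), c(40, 62)), c(12000, 15000),
                          size = 128L)
  img <- sum_channels(mv$venus, mv$red)[[1]]
  lab <- segment_frame(img, 12)
  dr <- 7L; dc <- 3L
  shifted <- matrix(400, 128, 128)
  shifted[(1 + dr):128, (1 + dc):128] <- img[1:(128 - dr), 1:(128 - dc)]
  lab_s <- segment_frame(shifted, 12)
  back <- matrix(0L, 128, 128)
  back[1:(128 - dr), 1:(128 - dc)] <- lab_s[(1 + dr):128, (1 + dc):128]
  # same segmentation after undoing the shift
  ag <- segmentation_agreement(back, lab)
  expect_identical(ag$missed, 0L)
  expect_identical(ag$spurious, 0L)
  expect_equal(ag$agreement_fraction, 1)
})

test_that("agreement accounting follows the IoU >= 0.5 greedy matching", {
  truth <- matrix(0L, 60, 60)
  # 4 disks of radius 5
  centers <- rbind(c(12, 12), c(12, 45), c(45, 12), c(45, 45))
  for (k in 1:4) {
    for (r in 1:60) for (c in 1:60)
      if ((r - centers[k, 1])^2 + (c - centers[k, 2])^2 <= 25)
        truth[r, c] <- k
  }
  # identity
  ag <- segmentation_agreement(truth, truth)
  expect_equal(ag$agreement_fraction, 1)
  expect_identical(ag$missed, 0L); expect_identical(ag$spurious, 0L)

  # drop one region: 3/4 matched
  pred <- truth; pred[pred == 4L] <- 0L
  ag2 <- segmentation_agreement(pred, truth)
  expect_equal(ag2$agreement_fraction, 0.75)
  expect_identical(ag2$missed, 1L)

  # 2-px shifts of every mask keep IoU >= 0.5 hence full agreement:
  # first confirm the IoU bound by direct computation on a disk pair
  disk <- function(cx, cy, R, n = 80) {
    m <- matrix(FALSE, n, n)
    for (r in 1:n) for (c in 1:n)
      if ((r - cy)^2 + (c - cx)^2 <= R^2) m[r, c] <- TRUE
    m
  }
  d0 <- disk(40, 40, 6); d2 <- disk(42, 40, 6)
  iou <- sum(d0 & d2) / sum(d0 | d2)
  expect_gte(iou, 0.5)
  shifted <- matrix(0L, 60, 60)
  shifted[, 1:58] <- truth[, 3:60]
  ag3 <- segmentation_agreement(shifted, truth)
  expect_equal(ag3$agreement_fraction, 1)

  # empty inputs allowed
  expect_identical(
    segmentation_agreement(matrix(0L, 5, 5), matrix(0L, 5, 5))$matched, 0L)
  expect_error(segmentation_agreement(matrix(0L, 5, 5), matrix(0L, 6, 5)),
               "shape")
})

test_that("labels never overlap and stay within area bounds", {
  cfg <- tiny_config()
  lin <- sample_lineage(cfg)
  tr <- reporter_traces(lin)
  mv <- render_movie(lin, tr, frames = c(10L, 30L, 50L))
  labs <- segment_movie(sum_channels(mv$venus, mv$red),
                        cfg$nucleus_diameter)
  A <- pi * (cfg$nucleus_diameter / 2)^2
  for (lab in labs) {
    areas <- tabulate(lab[lab > 0])
    areas <- areas[areas > 0]
    expect_true(all(areas >= 0.25 * A & areas <= 4 * A))
    expect_lte(sum(areas), length(lab))
  }
})
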