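#' Render a 2-channel synthetic movie plus ground-truth label movie
#'
#' Draws every nucleus as an isotropic Gaussian blob
#' (`sigma = nucleus_diameter / 4` px) whose peak is scaled so the mean
#' intensity over the nucleus disk equals the cell's per-frame trace
#' value; blobs are summed into the frame, the constant background is
#' added, then multiplicative lognormal noise and additive Gaussian read
#' noise are applied and intensities clipped to the 16-bit range
#' \[0, 65535\]. The truth label movie paints a disk of the configured
#' diameter at each centroid with the cell's label id; where disks touch,
#' each pixel goes to the nearer centroid.
#'
#' Centroids outside the field are clipped to the boundary for rendering;
#' affected (cell, frame) pairs are reported in `attr(, "clipped")`.
#'
#' @param lineage A [sample_lineage()] result.
#' @param traces Noiseless traces from [reporter_traces()].
#' @param config The matching [sim_config()].
#' @param frames Optional 0-based frame subset to render (defaults to all).
#' @return A list of class `frame_stack_set`: `venus` and `red` are
#'   lists of H x W numeric matrices (one per rendered frame), `labels`
#'   the matching list of integer label matrices, plus `frames` (0-based
#'   indices) and `config`.
#' @export
render_movie <- function(lineage, traces, config = lineage$config,
                         frames = NULL) {
  cfg <- validate_sim_config(unclass(config))
  if (is.null(frames)) frames <- 0:(cfg$n_frames - 1L)
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  sigma <- cfg$nucleus_diameter / 4
  radius <- cfg$nucleus_diameter / 2
  pk <- blob_peak_to_mean()
  half <- ceiling(4 * sigma)

  pos <- lineage$positions
  key <- paste(traces$cell_id, traces$frame)
  venus_lut <- stats::setNames(traces$venus_mean, key)
  red_lut <- stats::setNames(traces$red_mean, key)

  set.seed(cell_seed(cfg$seed, -1L))
  venus_out <- vector("list", length(frames))
  red_out <- vector("list", length(frames))
  lab_out <- vector("list", length(frames))
  clipped <- list()

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    pf <- pos[pos$frame == f, , drop = FALSE]
    ch1 <- matrix(0, H, W)
    ch2 <- matrix(0, H, W)
    lab <- matrix(0L, H, W)
    dbuf <- matrix(Inf, H, W)
    for (k in seq_len(nrow(pf))) {
      ck <- paste(pf$cell_id[k], f)
      vm <- venus_lut[[ck]]; rm_ <- red_lut[[ck]]
      if (is.null(vm) || is.na(vm)) next
      # pixel coordinates (column-major matrix: row = y, col = x)
      x <- pf$x_um[k] / cfg$pixel_size
      y <- pf$y_um[k] / cfg$pixel_size
      if (x < 0 || x > W - 1 || y < 0 || y > H - 1) {
        clipped[[length(clipped) + 1L]] <-
          data.frame(cell_id = pf$cell_id[k], frame = f)
        x <- min(max(x, 0), W - 1)
        y <- min(max(y, 0), H - 1)
      }
      cx <- round(x); cy <- round(y)
      rows <- max(1, cy + 1 - half):min(H, cy + 1 + half)
      cols <- max(1, cx + 1 - half):min(W, cx + 1 + half)
      dy2 <- ((rows - 1) - y)^2
      dx2 <- ((cols - 1) - x)^2
      blob <- exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
      ch1[rows, cols] <- ch1[rows, cols] + vm * pk * blob
      ch2[rows, cols] <- ch2[rows, cols] + rm_ * pk * blob
      d2 <- outer(dy2, dx2, "+")
      hit <- d2 <= radius^2 & d2 < dbuf[rows, cols]
      if (any(hit)) {
        sub <- lab[rows, cols]; sub[hit] <- pf$label[k]
        lab[rows, cols] <- sub
        subd <- dbuf[rows, cols]; subd[hit] <- d2[hit]
        dbuf[rows, cols] <- subd
      }
    }
    for (ch in c("ch1", "ch2")) {
      img <- get(ch) + cfg$background_level
      if (cfg$noise_mult_sigma > 0)
        img <- img * exp(matrix(stats::rnorm(H * W, 0, cfg$noise_mult_sigma),
                                H, W))
      if (cfg$noise_read_sigma > 0)
        img <- img + matrix(stats::rnorm(H * W, 0, cfg$noise_read_sigma),
                            H, W)
      assign(ch, pmin(pmax(round(img), 0), 65535))
    }
    venus_out[[fi]] <- ch1
    red_out[[fi]] <- ch2
    lab_out[[fi]] <- lab
  }
  out <- list(venus = venus_out, red = red_out, labels = lab_out,
              frames = frames, config = cfg)
  attr(out, "clipped") <- if (length(clipped)) do.call(rbind, clipped)
                          else NULL
  class(out) <- "frame_stack_set"
  out
}

#' @export
print.frame_stack_set <- function(x, ...) {
  cat("<frame_stack_set>", length(x$frames), "frames,",
      paste(dim(x$venus[[1]]), collapse = "x"), "px, 2 channels + labels\n")
  invisible(x)
}
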