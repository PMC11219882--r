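#' Sum the two reporter channels
#'
#' Nuclei are visible in at least one reporter channel at every cell-cycle
#' stage, so the per-pixel sum of the two channels gives a pan-nuclear
#' signal suitable for segmentation. The sum saturates at the 16-bit
#' maximum (65535).
#'
#' @param ch1,ch2 Matching matrices, 3D arrays, or lists of matrices.
#' @return The per-pixel saturating sum, same shape as the inputs.
#' @export
sum_channels <- function(ch1, ch2) {
  if (is.list(ch1) && !is.matrix(ch1)) {
    if (!is.list(ch2) || length(ch1) != length(ch2))
      stop("channel shape mismatch: different frame counts")
    return(Map(sum_channels, ch1, ch2))
  }
  if (!identical(dim(ch1), dim(ch2)))
    stop("channel shape mismatch: ", paste(dim(ch1), collapse = "x"),
         " vs ", paste(dim(ch2), collapse = "x"))
  pmin(ch1 + ch2, 65535)
}

# separable Gaussian smoothing with edge renormalisation
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  smooth_dim <- function(m) {
    n <- nrow(m)
    band <- matrix(0, n, n)
    for (j in -half:half) {
      idx <- seq_len(n)
      tgt <- idx + j
      ok <- tgt >= 1 & tgt <= n
      band[cbind(idx[ok], tgt[ok])] <- k[j + half + 1]
    }
    band <- band / rowSums(band)  # renormalise truncated edge kernels
    band %*% m
  }
  t(smooth_dim(t(smooth_dim(img))))
}

# Otsu's threshold on a 256-bin histogram of the image
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-12) return(Inf)  # flat frame: nothing above threshold
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * 256) + 1, 1), 256),
                nbins = 256)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  lo + k / 256 * (hi - lo)
}

# local maxima of a smooth surface over a (2r+1)^2 window, found by
# repeated 3x3 grayscale dilation; touching maxima (plateaus) are merged
# into single markers
local_max_markers <- function(surface, mask, radius) {
  H <- nrow(surface); W <- ncol(surface)
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  mx <- surface
  for (it in seq_len(max(1L, radius))) {
    m0 <- mx
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      mx <- pmax(mx, shift(m0, dr, dc))
    }
  }
  cand <- (surface >= mx - 1e-9) & mask & surface > 0
  cpp_label4(matrix(as.integer(cand), H, W))
}

#' Segment one frame into nucleus labels
#'
#' Default deterministic detector standing in for a trained segmentation
#' model, tuned to nuclei that image as blobs of the configured
#' diameter:
#' 1. Gaussian smoothing (`sigma = diameter/6`) and background
#'    subtraction (median of the frame border pixels);
#' 2. foreground mask by Otsu's threshold on the square-root
#'    (variance-stabilised) image, so dim S-phase and bright G1 nuclei
#'    threshold alike;
#' 3. centre detection as local maxima of a difference-of-Gaussians
#'    blob response (`sigma = d/6` vs `1.6 d/6`), which cancels a bright
#'    neighbour's smooth tail;
#' 4. a matched-model residual pass: fitted blobs
#'    (`A exp(-r^2 / (2 (d/4)^2 + 2 (d/6)^2))`) of all detected centres
#'    are subtracted and remaining maxima become additional centres --
#'    this recovers a dim nucleus pressed against a much brighter one,
#'    which leaves no maximum of its own in either intensity or DoG;
#' 5. each mask pixel goes to the centre with the largest predicted
#'    contribution (a power-diagram split of touching nuclei), cut at
#'    the contribution level a blob reaches at radius `diameter/2`;
#' 6. regions with area outside \[0.25 A, 4 A\], `A = pi (d/2)^2`, are
#'    discarded.
#'
#' Any other detector can be plugged in via `detector`
#' (a `function(image, diameter) -> label matrix`), e.g. to wrap an
#' external learned segmenter for real recordings.
#'
#' @param image 2D numeric matrix (one frame).
#' @param diameter Expected nucleus diameter in pixels (default 12).
#' @param detector Optional replacement detector function.
#' @return Integer label matrix: 0 background, positive nucleus ids.
#' @export
segment_frame <- function(image, diameter = 12, detector = NULL) {
  if (!is.matrix(image)) stop("image must be a single 2D frame")
  if (!is.null(detector)) return(detector(image, diameter))
  H <- nrow(image); W <- ncol(image)
  sm <- gaussian_smooth(image, diameter / 6)
  border <- c(sm[1, ], sm[H, ], sm[, 1], sm[, W])
  bg <- stats::median(border)
  corr <- sm - bg
  # 16-bit input: contrast below one intensity unit is numerical dust
  if (max(corr) < 1) return(matrix(0L, H, W))
  rt <- sqrt(pmax(corr, 0))
  thr <- otsu_threshold(rt)
  mask <- rt > thr
  if (!any(mask)) return(matrix(0L, H, W))
  dog <- gaussian_smooth(image, diameter / 6) -
    gaussian_smooth(image, 1.6 * diameter / 6)
  markers <- local_max_markers(dog, mask, max(2L, floor(diameter / 4)))
  centers <- marker_centers(markers, dog)
  sigma_eff2 <- (diameter / 4)^2 + (diameter / 6)^2
  if (nrow(centers)) {
    # residual pass: subtract fitted blobs, look for leftover nuclei
    resid <- corr - blob_model(centers, corr, H, W, sigma_eff2)
    rmark <- local_max_markers(resid, mask & resid > thr^2,
                               max(2L, floor(diameter / 4)))
    rcent <- marker_centers(rmark, resid)
    if (nrow(rcent)) {
      d2min <- apply(rcent, 1, function(p)
        min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2))
      rcent <- rcent[d2min > (0.55 * diameter)^2, , drop = FALSE]
      if (nrow(rcent)) {
        # amplitude from the original image at the recovered centre
        rcent[, 3] <- corr[cbind(rcent[, 1], rcent[, 2])]
        centers <- rbind(centers, rcent)
      }
    }
    centers[, 3] <- corr[cbind(centers[, 1], centers[, 2])]
  }
  lab <- assign_to_centers(centers, mask, H, W, sigma_eff2, diameter)
  area_filter(lab, a_min = 0.25 * pi * (diameter / 2)^2,
              a_max = 4 * pi * (diameter / 2)^2)
}

# one (row, col, height) triple per marker component: its highest pixel
marker_centers <- function(markers, surface) {
  ids <- unique(markers[markers > 0])
  out <- matrix(0, length(ids), 3)
  for (k in seq_along(ids)) {
    idx <- which(markers == ids[k])
    best <- idx[which.max(surface[idx])]
    rc <- arrayInd(best, dim(markers))
    out[k, ] <- c(rc[1], rc[2], surface[best])
  }
  out
}

# sum of fitted Gaussian blobs over the frame (local windows)
blob_model <- function(centers, corr, H, W, sigma_eff2) {
  model <- matrix(0, H, W)
  half <- ceiling(3.5 * sqrt(sigma_eff2))
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]
    A <- corr[r0, c0]
    rows <- max(1, r0 - half):min(H, r0 + half)
    cols <- max(1, c0 - half):min(W, c0 + half)
    model[rows, cols] <- model[rows, cols] +
      A * exp(-outer((rows - r0)^2, (cols - c0)^2, "+") /
                (2 * sigma_eff2))
  }
  model
}

# power-diagram pixel assignment: each mask pixel joins the centre with
# the largest predicted blob contribution, provided that contribution
# exceeds the blob's own value at the nucleus-disk edge
assign_to_centers <- function(centers, mask, H, W, sigma_eff2, diameter) {
  lab <- matrix(0L, H, W)
  if (!nrow(centers)) return(lab)
  f_edge <- exp(-(diameter / 2)^2 / (2 * sigma_eff2))
  best <- matrix(0, H, W)
  half <- ceiling(0.75 * diameter)
  for (k in seq_len(nrow(centers))) {
    r0 <- centers[k, 1]; c0 <- centers[k, 2]; A <- centers[k, 3]
    if (A <= 0) next
    rows <- max(1, r0 - half):min(H, r0 + half)
    cols <- max(1, c0 - half):min(W, c0 + half)
    contrib <- A * exp(-outer((rows - r0)^2, (cols - c0)^2, "+") /
                         (2 * sigma_eff2))
    sub_best <- best[rows, cols]
    sub_lab <- lab[rows, cols]
    take <- mask[rows, cols] & contrib > sub_best &
      contrib >= f_edge * A
    sub_best[take] <- contrib[take]
    sub_lab[take] <- k
    best[rows, cols] <- sub_best
    lab[rows, cols] <- sub_lab
  }
  lab
}

area_filter <- function(lab, a_min, a_max) {
  if (!any(lab > 0)) return(lab)
  areas <- tabulate(lab[lab > 0])
  bad <- which(areas < a_min | areas > a_max)
  if (length(bad)) lab[lab %in% bad] <- 0L
  # compact label ids
  keep <- sort(unique(lab[lab > 0]))
  if (length(keep)) {
    remap <- integer(max(keep))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

#' Segment a whole movie
#'
#' @param stack List of frames (matrices), a 3D array, or the summed
#'   channel from [sum_channels()].
#' @inheritParams segment_frame
#' @return A list of integer label matrices (a label movie). Label ids
#'   are only unique within a frame.
#' @export
segment_movie <- function(stack, diameter = 12, detector = NULL) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  if (is.matrix(stack)) stack <- list(stack)
  lapply(stack, segment_frame, diameter = diameter, detector = detector)
}

#' Predicted-vs-truth segmentation agreement for one frame
#'
#' Greedy one-to-one matching of predicted to truth regions by descending
#' intersection-over-union; a pair counts as matched iff IoU >= 0.5.
#' `agreement_fraction` is matched / number of truth regions -- the
#' programmatic analogue of recording model vs human-corrected nucleus
#' counts during segmenter training.
#'
#' @param predicted,truth Integer label matrices of the same shape.
#' @return List with `matched`, `missed`, `spurious`,
#'   `agreement_fraction`.
#' @export
segmentation_agreement <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop("predicted and truth frames must have the same shape")
  p_ids <- setdiff(unique(as.integer(predicted)), 0L)
  t_ids <- setdiff(unique(as.integer(truth)), 0L)
  if (!length(t_ids)) {
    return(list(matched = 0L, missed = 0L, spurious = length(p_ids),
                agreement_fraction = NaN))
  }
  if (!length(p_ids)) {
    return(list(matched = 0L, missed = length(t_ids), spurious = 0L,
                agreement_fraction = 0))
  }
  sel <- predicted > 0 & truth > 0
  if (any(sel)) {
    ov <- table(pred = predicted[sel], truth = truth[sel])
    p_area <- tabulate(predicted[predicted > 0], nbins = max(p_ids))
    t_area <- tabulate(truth[truth > 0], nbins = max(t_ids))
    pairs <- which(ov > 0, arr.ind = TRUE)
    pl <- as.integer(rownames(ov))[pairs[, 1]]
    tl <- as.integer(colnames(ov))[pairs[, 2]]
    inter <- ov[pairs]
    iou <- inter / (p_area[pl] + t_area[tl] - inter)
    ord <- order(-iou, pl, tl)
    used_p <- logical(max(p_ids)); used_t <- logical(max(t_ids))
    matched <- 0L
    for (k in ord) {
      if (iou[k] < 0.5) break
      if (used_p[pl[k]] || used_t[tl[k]]) next
      used_p[pl[k]] <- TRUE; used_t[tl[k]] <- TRUE
      matched <- matched + 1L
    }
  } else matched <- 0L
  list(matched = matched,
       missed = length(t_ids) - matched,
       spurious = length(p_ids) - matched,
       agreement_fraction = matched / length(t_ids))
}

#' Agreement report over a whole movie
#'
#' @param predicted,truth Label movies (lists of matrices).
#' @return A data.frame with one row per frame: `frame`, `matched`,
#'   `missed`, `spurious`, `agreement_fraction`.
#' @export
agreement_report <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  rows <- Map(function(p, t, f) {
    a <- segmentation_agreement(p, t)
    data.frame(frame = f, matched = a$matched, missed = a$missed,
               spurious = a$spurious,
               agreement_fraction = a$agreement_fraction)
  }, predicted, truth, seq_along(predicted) - 1L)
  do.call(rbind, rows)
}
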