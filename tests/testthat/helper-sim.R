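# Shared fixtures: built in code, small enough for fast tests.

# small noiseless scene used across segmentation/tracking tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_founders = 4, image_size = c(128L, 128L), duration = 600,
         noise_mult_sigma = 0, noise_read_sigma = 0, seed = 42),
    list(...))
  do.call(sim_config, args)
}

# trace-level scene with many completed cycles (never rendered)
trace_config <- function(...) {
  sim_config(n_founders = 60, image_size = c(512L, 512L), duration = 2880,
             seed = 101, ...)
}

# Stitch the cycle of `cell_id` (a non-founder) into a single trace
# segment running from the parent's division spike (frame pdiv - 1) to
# the cell's own division spike (frame cdiv - 1), optionally extended by
# `pad` frames on each side (into the parent's trace and a daughter's).
# Returns NULL when the cycle is not fully visible.
stitch_cycle <- function(lineage, traces_by_cell, cell_id, pad = 0) {
  cells <- lineage$cells
  ci <- cells[cells$cell_id == cell_id, ]
  if (is.na(ci$parent_id) || !ci$completed) return(NULL)
  pdiv <- ci$birth_frame            # equals parent's division frame
  cdiv <- ci$division_frame
  lo <- pdiv - 1 - pad
  hi <- cdiv - 1 + pad
  if (lo < 0 || hi > lineage$config$n_frames - 1) return(NULL)
  par <- traces_by_cell[[as.character(ci$parent_id)]]
  own <- traces_by_cell[[as.character(cell_id)]]
  if (is.null(par) || is.null(own)) return(NULL)
  pieces <- list(par[par$frame >= lo & par$frame <= pdiv - 1, ],
                 own[own$frame >= pdiv & own$frame <= hi, ])
  if (pad > 0) {
    kids <- cells$cell_id[!is.na(cells$parent_id) &
                            cells$parent_id == cell_id]
    if (!length(kids)) return(NULL)
    kid <- traces_by_cell[[as.character(kids[1])]]
    if (is.null(kid)) return(NULL)
    pieces[[3]] <- kid[kid$frame >= cdiv & kid$frame <= hi, ]
  }
  seg <- do.call(rbind, pieces)
  seg <- seg[order(seg$frame), ]
  if (any(diff(seg$frame) != 1)) return(NULL)
  seg
}

# brute-force linking oracle: enumerate every partial injective matching
# between feasible pairs, minimising sum(d^2) + U * (n + m - 2 * L)
brute_force_links <- function(dets_a, dets_b, max_dist) {
  n <- nrow(dets_a); m <- nrow(dets_b)
  d2 <- outer(dets_a$x_um, dets_b$x_um, "-")^2 +
    outer(dets_a$y_um, dets_b$y_um, "-")^2
  U <- max_dist^2
  best <- list(cost = Inf, links = NULL)
  recurse <- function(i, used, links, cost) {
    if (i > n) {
      total <- cost + U * (n - nrow(links)) + U * (m - nrow(links))
      if (total < best$cost) best <<- list(cost = total, links = links)
      return(invisible())
    }
    recurse(i + 1, used, links, cost)       # row i unassigned
    for (j in seq_len(m)) {
      if (used[j] || d2[i, j] > U) next
      u2 <- used; u2[j] <- TRUE
      recurse(i + 1, u2, rbind(links, c(i, j)), cost + d2[i, j])
    }
  }
  recurse(1, rep(FALSE, m), matrix(integer(0), ncol = 2), 0)
  lk <- best$links
  if (nrow(lk)) lk[order(lk[, 1]), , drop = FALSE] else lk
}

# normalise a link matrix for comparison
canon_links <- function(L) {
  L <- matrix(as.integer(L), ncol = 2)
  L[order(L[, 1]), , drop = FALSE]
}
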