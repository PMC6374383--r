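#' Refine the offset between two overlapping tiles
#'
#' Searches integer offsets within `search_radius` of the nominal offset for
#' the placement of `tile_b` (relative to `tile_a`'s origin) that maximizes the
#' normalized cross-correlation of the overlap region, then refines the peak to
#' sub-pixel precision by quadratic interpolation. Confidence is the peak
#' correlation, in [-1, 1]; it is invariant to affine rescaling of either
#' tile's intensities.
#'
#' @param tile_a,tile_b numeric matrices (a single channel of each tile).
#' @param nominal_offset (x, y) pixel offset of `tile_b`'s origin in `tile_a`'s
#'   frame, from the nominal grid layout.
#' @param search_radius maximum deviation from the nominal offset, px.
#' @param min_overlap_px minimum number of overlapping pixels required to score
#'   an offset.
#' @return list with `offset` (real (x, y)), `confidence`, and the integer
#'   `grid_offset` at the correlation peak. Flat (zero-variance) overlap yields
#'   the nominal offset with confidence 0 and a warning.
#' @export
estimate_offset <- function(tile_a, tile_b, nominal_offset, search_radius = 5L,
                            min_overlap_px = 64L) {
  if (is.array(tile_a) && length(dim(tile_a)) == 3L) tile_a <- tile_a[, , 1L]
  if (is.array(tile_b) && length(dim(tile_b)) == 3L) tile_b <- tile_b[, , 1L]
  stopifnot(is.matrix(tile_a), is.matrix(tile_b), length(nominal_offset) == 2L)
  ha <- nrow(tile_a); wa <- ncol(tile_a)
  hb <- nrow(tile_b); wb <- ncol(tile_b)
  r <- as.integer(search_radius)
  dxs <- (nominal_offset[1L] - r):(nominal_offset[1L] + r)
  dys <- (nominal_offset[2L] - r):(nominal_offset[2L] + r)
  score <- matrix(NA_real_, length(dys), length(dxs))
  for (iy in seq_along(dys)) for (ix in seq_along(dxs)) {
    ox <- dxs[ix]; oy <- dys[iy]
    ax0 <- max(0L, ox); ax1 <- min(wa - 1L, ox + wb - 1L)
    ay0 <- max(0L, oy); ay1 <- min(ha - 1L, oy + hb - 1L)
    if (ax1 < ax0 || ay1 < ay0) next
    if ((ax1 - ax0 + 1L) * (ay1 - ay0 + 1L) < min_overlap_px) next
    pa <- tile_a[(ay0 + 1L):(ay1 + 1L), (ax0 + 1L):(ax1 + 1L)]
    pb <- tile_b[(ay0 - oy + 1L):(ay1 - oy + 1L), (ax0 - ox + 1L):(ax1 - ox + 1L)]
    if (stats::var(as.numeric(pa)) == 0 || stats::var(as.numeric(pb)) == 0) {
      score[iy, ix] <- 0
      next
    }
    score[iy, ix] <- ncc(pa, pb)
  }
  if (all(is.na(score)) || max(score, na.rm = TRUE) == 0) {
    warning("overlap strip has zero variance; returning nominal offset with confidence 0")
    return(list(offset = as.numeric(nominal_offset), confidence = 0,
                grid_offset = as.numeric(nominal_offset)))
  }
  peak <- which(score == max(score, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  iy <- peak[1L]; ix <- peak[2L]
  best <- c(dxs[ix], dys[iy])
  sub <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (!is.finite(den) || den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
  }
  dx_sub <- if (ix > 1L && ix < ncol(score) &&
                all(is.finite(score[iy, (ix - 1L):(ix + 1L)])))
    sub(score[iy, ix - 1L], score[iy, ix], score[iy, ix + 1L]) else 0
  dy_sub <- if (iy > 1L && iy < nrow(score) &&
                all(is.finite(score[(iy - 1L):(iy + 1L), ix])))
    sub(score[iy - 1L, ix], score[iy, ix], score[iy + 1L, ix]) else 0
  list(offset = c(best[1L] + dx_sub, best[2L] + dy_sub),
       confidence = score[iy, ix],
       grid_offset = as.numeric(best))
}

#' Refine a whole tile layout against the nominal grid
#'
#' Tiles are placed row-major; each tile's origin is estimated against its left
#' and top neighbors with [estimate_offset()], and conflicting estimates are
#' resolved by a confidence-weighted average. The first tile is fixed at
#' (0, 0). Refined origins are clamped to within `search_radius` of nominal.
#'
#' @param tiles row-major list of (y, x, channel) arrays or matrices.
#' @param layout list with `nominal_origins` (n x 2, (x, y)) and `grid`
#'   (rows, cols), as produced by [tile_section()].
#' @param search_radius search radius in px.
#' @param channel channel index used for matching.
#' @return the layout with `refined_origins` and `confidences` added.
#' @export
refine_layout <- function(tiles, layout, search_radius = 5L, channel = 1L) {
  rows <- layout$grid[1L]; cols <- layout$grid[2L]
  nominal <- layout$nominal_origins
  n <- rows * cols
  stopifnot(length(tiles) == n)
  chan <- function(t) {
    x <- tiles[[t]]
    if (is.matrix(x)) x else x[, , channel]
  }
  refined <- matrix(0, n, 2L)
  confs <- numeric(n)
  confs[1L] <- 1
  for (t in seq_len(n)[-1L]) {
    i <- (t - 1L) %/% cols  # row, 0-based
    j <- (t - 1L) %% cols   # col, 0-based
    cand <- matrix(0, 0L, 2L); wts <- numeric(0)
    for (nb in c(if (j > 0L) t - 1L, if (i > 0L) t - cols)) {
      rel_nom <- nominal[t, ] - nominal[nb, ]
      est <- estimate_offset(chan(nb), chan(t), rel_nom, search_radius)
      cand <- rbind(cand, refined[nb, ] + est$offset)
      wts <- c(wts, max(est$confidence, 0))
    }
    if (sum(wts) == 0) {
      refined[t, ] <- nominal[t, ]
      confs[t] <- 0
    } else {
      refined[t, ] <- colSums(cand * wts) / sum(wts)
      confs[t] <- max(wts)
    }
    refined[t, ] <- pmin(pmax(refined[t, ], nominal[t, ] - search_radius),
                         nominal[t, ] + search_radius)
  }
  layout$refined_origins <- refined
  layout$confidences <- confs
  layout
}

#' Stitch tiles into a single section image
#'
#' Places each tile at its (refined or true) origin on a canvas sized to the
#' union bounding box. Overlaps are combined per blend mode: `feather` weights
#' each tile's contribution by its distance to its own border (a linear ramp
#' across the overlap, weights normalized to sum to 1), `overwrite` lets the
#' later tile win. Blending happens in floating point; the result is
#' re-quantized (round half up) at the end. Fractional origins are rounded to
#' the nearest pixel for placement.
#'
#' @param tiles row-major list of (y, x, channel) arrays or matrices.
#' @param origins n x 2 matrix of (x, y) pixel origins (e.g.
#'   `layout$refined_origins` or `layout$true_origins`).
#' @param blend `"feather"` or `"overwrite"`.
#' @param channels optional channel names for the output.
#' @param pixel_size,thickness optional metadata for the output section.
#' @param canvas_size optional (height, width); the stitched image is cropped
#'   or zero-padded to this size so every section of a stack comes out with
#'   identical dimensions regardless of rounding in the refined origins.
#' @return a [section_image()].
#' @export
stitch <- function(tiles, origins, blend = c("feather", "overwrite"),
                   channels = NULL, pixel_size = NA_real_,
                   thickness = NA_real_, canvas_size = NULL) {
  blend <- match.arg(blend)
  stopifnot(length(tiles) >= 1L, nrow(origins) == length(tiles))
  tiles <- lapply(tiles, function(x)
    if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x)
  nch <- dim(tiles[[1L]])[3L]
  origins <- round_half_up(origins)
  origins[, 1L] <- origins[, 1L] - min(origins[, 1L])
  origins[, 2L] <- origins[, 2L] - min(origins[, 2L])
  hs <- vapply(tiles, function(x) dim(x)[1L], 1L)
  ws <- vapply(tiles, function(x) dim(x)[2L], 1L)
  W <- as.integer(max(origins[, 1L] + ws))
  H <- as.integer(max(origins[, 2L] + hs))
  # connectivity: every tile must overlap the union of previously placed tiles
  if (length(tiles) > 1L) for (t in seq_along(tiles)[-1L]) {
    prev <- seq_len(t - 1L)
    ov <- any(origins[t, 1L] < origins[prev, 1L] + ws[prev] &
              origins[prev, 1L] < origins[t, 1L] + ws[t] &
              origins[t, 2L] < origins[prev, 2L] + hs[prev] &
              origins[prev, 2L] < origins[t, 2L] + hs[t])
    if (!ov) stop("tile ", t, " does not overlap any previously placed tile")
  }
  out <- array(0, dim = c(H, W, nch))
  if (blend == "overwrite") {
    for (t in seq_along(tiles)) {
      ri <- (origins[t, 2L] + 1L):(origins[t, 2L] + hs[t])
      ci <- (origins[t, 1L] + 1L):(origins[t, 1L] + ws[t])
      out[ri, ci, ] <- tiles[[t]]
    }
  } else {
    den <- matrix(0, H, W)
    for (t in seq_along(tiles)) {
      h <- hs[t]; w <- ws[t]
      wy <- pmin(seq_len(h), h:1)
      wx <- pmin(seq_len(w), w:1)
      wt <- outer(wy, wx, pmin)
      ri <- (origins[t, 2L] + 1L):(origins[t, 2L] + h)
      ci <- (origins[t, 1L] + 1L):(origins[t, 1L] + w)
      for (k in seq_len(nch))
        out[ri, ci, k] <- out[ri, ci, k] + wt * tiles[[t]][, , k]
      den[ri, ci] <- den[ri, ci] + wt
    }
    den[den == 0] <- 1
    for (k in seq_len(nch)) out[, , k] <- out[, , k] / den
  }
  out <- round_half_up(out)
  if (!is.null(canvas_size)) {
    fixed <- array(0, dim = c(canvas_size[1L], canvas_size[2L], nch))
    hh <- min(H, canvas_size[1L]); ww <- min(W, canvas_size[2L])
    fixed[seq_len(hh), seq_len(ww), ] <- out[seq_len(hh), seq_len(ww), , drop = FALSE]
    out <- fixed
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(nch))
  section_image(out, channels, pixel_size, thickness)
}
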