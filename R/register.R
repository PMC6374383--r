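#' Phase correlation between two equally-shaped images
#'
#' Returns the integer translation (with optional sub-pixel refinement) `t`
#' such that `moving` shifted by `t` best matches `fixed`, found at the peak of
#' the inverse FFT of the normalized cross-power spectrum. Shifts are wrapped
#' to the centred range; an optional `max_shift` masks the correlation surface.
#'
#' @param fixed,moving numeric matrices of identical shape.
#' @param max_shift maximum absolute shift considered in either axis, px
#'   (`NULL` = unbounded).
#' @param subpixel refine the peak by separable quadratic interpolation.
#' @return list with `tx`, `ty` (px) and `peak` (height of the correlation
#'   peak, in [0, 1] for well-matched content).
#' @export
phase_correlate <- function(fixed, moving, max_shift = NULL, subpixel = TRUE) {
  stopifnot(is.matrix(fixed), is.matrix(moving),
            all(dim(fixed) == dim(moving)))
  H <- nrow(fixed); W <- ncol(fixed)
  Ff <- stats::fft(fixed)
  Fm <- stats::fft(moving)
  R <- Ff * Conj(Fm)
  R <- R / (Mod(R) + 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / (H * W)
  sy <- c(0:(H - 1)); sy[sy > H / 2] <- sy[sy > H / 2] - H
  sx <- c(0:(W - 1)); sx[sx > W / 2] <- sx[sx > W / 2] - W
  rm <- r
  if (!is.null(max_shift)) {
    rm[abs(sy) > max_shift, ] <- -Inf
    rm[, abs(sx) > max_shift] <- -Inf
  }
  peak <- which(rm == max(rm), arr.ind = TRUE)[1L, ]
  i <- peak[1L]; j <- peak[2L]
  ty <- sy[i]; tx <- sx[j]
  if (subpixel) {
    wrap <- function(k, n) ((k - 1L) %% n) + 1L
    sub1 <- function(vm, v0, vp) {
      den <- vm - 2 * v0 + vp
      if (!is.finite(den) || den >= 0) return(0)
      max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
    }
    ty <- ty + sub1(r[wrap(i - 1L, H), j], r[i, j], r[wrap(i + 1L, H), j])
    tx <- tx + sub1(r[i, wrap(j - 1L, W)], r[i, j], r[i, wrap(j + 1L, W)])
  }
  list(tx = tx, ty = ty, peak = r[i, j])
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma)
}

pad_to <- function(img, PH, PW) {
  out <- matrix(0, PH, PW)
  out[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  out
}

# Cache the fixed-side FFTs used by the masked-NCC surface.
prep_ncc_fixed <- function(f1, m1, PH, PW) {
  list(F1 = stats::fft(pad_to(f1, PH, PW)),
       F11 = stats::fft(pad_to(f1 * f1, PH, PW)),
       M1 = stats::fft(pad_to(m1, PH, PW)),
       PH = PH, PW = PW)
}

# Exact normalized cross-correlation of f1 (mask m1) against f2 (mask m2) at
# every integer shift, computed with FFTs over the zero-padded grid so the
# statistics at each shift use only genuinely overlapping pixels.
masked_ncc_surface <- function(prep, f2, m2, n_min = 64) {
  PH <- prep$PH; PW <- prep$PW
  F2c <- Conj(stats::fft(pad_to(f2, PH, PW)))
  F22c <- Conj(stats::fft(pad_to(f2 * f2, PH, PW)))
  M2c <- Conj(stats::fft(pad_to(m2, PH, PW)))
  icor <- function(A, Bc) Re(stats::fft(A * Bc, inverse = TRUE)) / (PH * PW)
  n <- icor(prep$M1, M2c)
  sf <- icor(prep$F1, M2c)
  sm <- icor(prep$M1, F2c)
  sff <- icor(prep$F11, M2c)
  smm <- icor(prep$M1, F22c)
  sfm <- icor(prep$F1, F2c)
  ok <- n >= n_min
  n[!ok] <- 1
  num <- sfm - sf * sm / n
  v1 <- pmax(sff - sf^2 / n, 0)
  v2 <- pmax(smm - sm^2 / n, 0)
  den <- sqrt(v1 * v2)
  ncc <- ifelse(ok & den > 1e-9, num / den, NA_real_)
  matrix(pmin(pmax(ncc, -1), 1), PH, PW)
}

# Peak of a correlation surface restricted to |shift| <= max_shift, with
# separable quadratic sub-pixel refinement.
surface_peak <- function(surf, max_shift, subpixel = TRUE) {
  PH <- nrow(surf); PW <- ncol(surf)
  sy <- 0:(PH - 1); sy[sy > PH / 2] <- sy[sy > PH / 2] - PH
  sx <- 0:(PW - 1); sx[sx > PW / 2] <- sx[sx > PW / 2] - PW
  m <- surf
  m[abs(sy) > max_shift, ] <- NA
  m[, abs(sx) > max_shift] <- NA
  if (all(is.na(m))) return(list(tx = 0, ty = 0, peak = -Inf))
  top <- max(m, na.rm = TRUE)
  peak <- which(m == top, arr.ind = TRUE)[1L, ]
  i <- peak[1L]; j <- peak[2L]
  ty <- sy[i]; tx <- sx[j]
  if (subpixel) {
    wrap <- function(k, nn) ((k - 1L) %% nn) + 1L
    sub1 <- function(vm, v0, vp) {
      if (anyNA(c(vm, v0, vp))) return(0)
      dn <- vm - 2 * v0 + vp
      if (!is.finite(dn) || dn >= 0) return(0)
      max(-0.5, min(0.5, 0.5 * (vm - vp) / dn))
    }
    ty <- ty + sub1(surf[wrap(i - 1L, PH), j], surf[i, j], surf[wrap(i + 1L, PH), j])
    tx <- tx + sub1(surf[i, wrap(j - 1L, PW)], surf[i, j], surf[i, wrap(j + 1L, PW)])
  }
  list(tx = tx, ty = ty, peak = top)
}

#' Rigidly register one image onto another
#'
#' Finds the rigid transform (translation + rotation about the image centre)
#' that maps `moving` into `fixed`'s frame. Both images are lightly Gaussian
#' smoothed; rotation is searched coarsely at `coarse_step` degree steps over
#' `[-max_rotation, max_rotation]`, with the translation at each candidate
#' angle found by FFT-based search of the exact masked normalized
#' cross-correlation surface (statistics at each shift computed over only the
#' genuinely overlapping pixels, so border clipping and rotation fill do not
#' bias the estimate); the best angle is then refined locally and the
#' translation refined to sub-pixel precision. The returned score is the peak
#' normalized cross-correlation. Whitened phase correlation
#' ([phase_correlate()]) remains available as a fast path for clean data, but
#' it degrades under heavy noise, so the registration search uses the NCC
#' surface.
#'
#' If the score falls below `confidence_floor`, the identity transform is
#' returned with score 0, a warning is emitted and the pair is flagged for
#' manual review.
#'
#' @param fixed,moving numeric matrices of identical shape with nonzero
#'   variance (typically the DAPI channel).
#' @param max_rotation rotation search bound, degrees.
#' @param max_translation translation search bound, px (`NULL` = quarter of the
#'   smaller image dimension).
#' @param coarse_step coarse rotation step, degrees.
#' @param confidence_floor minimum acceptable correlation score.
#' @param smooth_sigma Gaussian pre-smoothing sigma, px.
#' @param overlap_ratio minimum fraction of the image area two placements must
#'   share to be considered; guards against spurious high correlations on tiny
#'   overlaps of self-similar content (fields of look-alike nuclei).
#' @param polish jointly refine (tx, ty, theta) on the continuous correlation
#'   objective after the surface search.
#' @param fixed_mask optional logical matrix marking the valid pixels of
#'   `fixed` (e.g. when the fixed image is itself a resampled section with
#'   zero-filled borders); masked-out pixels are excluded from all statistics.
#' @return list with `transform` (a [rigid_transform()]), `score`, `flagged`.
#' @export
register_pair <- function(fixed, moving, max_rotation = 10,
                          max_translation = NULL, coarse_step = 0.5,
                          confidence_floor = 0.1, smooth_sigma = 1,
                          overlap_ratio = 0.5, polish = TRUE,
                          fixed_mask = NULL) {
  stopifnot(is.matrix(fixed), is.matrix(moving),
            all(dim(fixed) == dim(moving)))
  if (stats::var(as.numeric(fixed)) == 0 || stats::var(as.numeric(moving)) == 0)
    stop("zero-variance input image; cannot register")
  if (is.null(max_translation)) max_translation <- floor(min(dim(fixed)) / 4)
  H <- nrow(fixed); W <- ncol(fixed)
  max_translation <- min(max_translation, H - 1, W - 1)
  fs <- gaussian_smooth(fixed, smooth_sigma)
  ms <- gaussian_smooth(moving, smooth_sigma)
  # pad enough to make the correlation linear within the search bound, rounded
  # up to an FFT-friendly composite size
  PH <- stats::nextn(H + max_translation, c(2, 3, 5))
  PW <- stats::nextn(W + max_translation, c(2, 3, 5))
  fmask <- if (is.null(fixed_mask)) matrix(1, H, W) else (fixed_mask > 0) * 1
  prep <- prep_ncc_fixed(fs * fmask, fmask, PH, PW)
  n_min <- max(64, overlap_ratio * sum(fmask))
  ones <- matrix(1, H, W)

  objective <- function(theta, subpixel = FALSE) {
    if (theta == 0) {
      mr <- ms; mk <- ones
    } else {
      rot <- rigid_transform(0, 0, theta)
      mr <- warp_rigid(ms, rot)
      mk <- (warp_rigid(ones, rot) > 0.999) * 1
    }
    surf <- masked_ncc_surface(prep, mr * mk, mk, n_min)
    surface_peak(surf, max_translation, subpixel = subpixel)
  }
  if (max_rotation > 0) {
    angles <- seq(-max_rotation, max_rotation, by = coarse_step)
    peaks <- vapply(angles, function(a) objective(a)$peak, numeric(1))
    best <- which.max(peaks)
    lo <- max(-max_rotation, angles[best] - coarse_step)
    hi <- min(max_rotation, angles[best] + coarse_step)
    opt <- stats::optimize(function(a) objective(a)$peak,
                           lower = lo, upper = hi, maximum = TRUE, tol = 5e-3)
    # keep the coarse winner if refinement wandered off a flat objective
    theta <- if (opt$objective >= peaks[best]) opt$maximum else angles[best]
  } else theta <- 0
  pk <- objective(theta, subpixel = TRUE)
  trans <- rigid_transform(pk$tx, pk$ty, theta)
  score <- pk$peak
  if (polish && is.finite(score) && score >= confidence_floor) {
    # joint local refinement of (tx, ty, theta) on the continuous NCC
    # objective; box-constrained to the surface peak's neighbourhood
    ones <- matrix(1, H, W)
    nccw <- function(p) {
      tr <- rigid_transform(p[1L], p[2L], p[3L])
      w <- warp_rigid(ms, tr)
      v <- (warp_rigid(ones, tr) > 0.999) & (fmask > 0)
      if (sum(v) < n_min) return(2)
      -ncc(w[v], fs[v])
    }
    start <- c(pk$tx, pk$ty, theta)
    opt <- stats::optim(start, nccw, method = "L-BFGS-B",
                        lower = start - c(1.5, 1.5, 0.75),
                        upper = start + c(1.5, 1.5, 0.75),
                        control = list(factr = 1e10, maxit = 40))
    if (-opt$value >= -nccw(start))
      trans <- rigid_transform(opt$par[1L], opt$par[2L], opt$par[3L])
  }
  # the score is the (smoothed-image) correlation at the final pose
  warped <- warp_rigid(ms, trans)
  vmask <- (warp_rigid(matrix(1, H, W), trans) > 0.999) & (fmask > 0)
  score <- if (sum(vmask) >= n_min) ncc(warped[vmask], fs[vmask]) else 0
  if (!is.finite(score) || score < confidence_floor) {
    warning(sprintf("registration score %.3f below confidence floor %.2f; returning identity (flagged)",
                    score, confidence_floor))
    return(list(transform = rt_identity(), score = 0, flagged = TRUE))
  }
  list(transform = trans, score = score, flagged = FALSE)
}

#' Align an ordered stack of serial sections
#'
#' Registers the sections sequentially on the named channel (DAPI by default),
#' derives an absolute transform per section relative to the reference
#' section, and resamples every channel of every section once with its
#' absolute transform (bilinear, out-of-bounds filled with 0). Flagged pairs
#' (score below the confidence floor) contribute an identity transform and are
#' recorded, never dropped.
#'
#' Two reference modes are available. `"previous"` registers each section
#' against its immediate predecessor and chains the pairwise transforms;
#' simple, but per-pair errors accumulate as a random walk along the stack.
#' `"running_mean"` registers each section against the mean of the last
#' `running_window` already-aligned sections, which damps that drift and is
#' the recommended mode for long stacks; the reported pairwise transforms are
#' then derived from consecutive absolute transforms.
#'
#' @param sections ordered list of [section_image()] objects, uniform shape.
#' @param channel registration channel name.
#' @param reference_index 1-based index of the reference section whose frame
#'   defines the aligned stack.
#' @param reference_mode `"previous"` (chain consecutive pairs) or
#'   `"running_mean"` (register against the mean of previously aligned
#'   sections).
#' @param running_window number of aligned sections averaged in
#'   `"running_mean"` mode.
#' @param max_abs_translation,max_abs_rotation known bound on each section's
#'   absolute misplacement (px, degrees) — a property of the acquisition: how
#'   far a section can land from its nominal pose on the slide. When given,
#'   the chained absolute transforms are checked against the bound (plus an
#'   internal drift allowance of 5 px / 5 degrees). The first violating
#'   section marks a wrong pairwise correspondence — the failure mode of
#'   consecutive sections that share only a few look-alike nuclei — and the
#'   whole downstream block is re-anchored: the next few raw sections are
#'   registered directly against the last in-bounds aligned section, the
#'   best-scoring of those defines a single rigid correction, and the
#'   correction is applied to every downstream absolute transform (their good
#'   relative transforms are preserved exactly). `NULL` disables the check.
#' @inheritParams register_pair
#' @return object of class `alignment_result`: `pairwise` (element `i` maps
#'   section `i` onto section `i - 1`; element 1 is `NULL`), `absolute`,
#'   `scores`, `flagged`, `reference_index`, and `aligned` (the resampled
#'   sections).
#' @export
align_stack <- function(sections, channel = "DAPI", reference_index = 1L,
                        max_rotation = 10, max_translation = NULL,
                        coarse_step = 0.5, confidence_floor = 0.1,
                        smooth_sigma = 1, overlap_ratio = 0.5,
                        reference_mode = c("previous", "running_mean"),
                        running_window = 5L, polish = TRUE,
                        max_abs_translation = NULL,
                        max_abs_rotation = NULL) {
  reference_mode <- match.arg(reference_mode)
  n <- length(sections)
  stopifnot(n >= 2L, reference_index >= 1L, reference_index <= n,
            running_window >= 1L)
  shp <- dim(sections[[1L]]$data)[1:2]
  for (s in sections) stopifnot(all(dim(s$data)[1:2] == shp))

  reg <- function(fixed, moving, fixed_mask = NULL) {
    register_pair(fixed, moving, fixed_mask = fixed_mask,
                  max_rotation = max_rotation,
                  max_translation = max_translation,
                  coarse_step = coarse_step,
                  confidence_floor = confidence_floor,
                  smooth_sigma = smooth_sigma,
                  overlap_ratio = overlap_ratio,
                  polish = polish)
  }

  pairwise <- vector("list", n)
  absolute <- vector("list", n)
  scores <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  absolute[[reference_index]] <- rt_identity()

  if (reference_mode == "previous") {
    for (i in 2L:n) {
      res <- reg(get_channel(sections[[i - 1L]], channel),
                 get_channel(sections[[i]], channel))
      pairwise[[i]] <- res$transform
      scores[i] <- res$score
      flagged[i] <- res$flagged
    }
    if (reference_index < n) for (i in (reference_index + 1L):n)
      absolute[[i]] <- rt_compose(absolute[[i - 1L]], pairwise[[i]])
    if (reference_index > 1L) for (i in (reference_index - 1L):1L)
      absolute[[i]] <- rt_compose(absolute[[i + 1L]], rt_inverse(pairwise[[i + 1L]]))

    if (!is.null(max_abs_translation)) {
      slack_t <- 5
      slack_r <- 5
      # trigger on translation only: a wrong correspondence jumps the chain by
      # tens of px, while honest drift stays within a few px of the bound;
      # rotation drifts too slowly to discriminate and would false-trigger
      trigger_ok <- function(t) {
        abs(t$tx) <= max_abs_translation + slack_t &&
          abs(t$ty) <= max_abs_translation + slack_t
      }
      bound_ok <- function(t) {
        ok <- trigger_ok(t)
        if (!is.null(max_abs_rotation))
          ok <- ok && abs(t$theta) <= max_abs_rotation + slack_r
        ok
      }
      reanchor <- function(idx) {
        # idx: section indices downstream of the reference, in chain order.
        # A wrong pairwise link offsets the whole downstream block by one
        # rigid transform; the first bound-violating section marks the broken
        # link. Candidate corrections come from registering the next few raw
        # sections directly against the last in-bounds aligned section; a
        # correction is applied only when two independent candidates agree
        # (wrong correspondences rarely agree with each other) or a single
        # candidate is unambiguous, and it is applied to the whole downstream
        # block so the good relative transforms there are preserved exactly.
        for (round in seq_len(3L)) {
          ok <- vapply(absolute[idx], trigger_ok, TRUE)
          if (all(ok)) break
          pos <- which(!ok)[1L]
          i0 <- idx[pos]
          anchor <- if (pos == 1L) reference_index else idx[pos - 1L]
          anchor_img <- warp_rigid(get_channel(sections[[anchor]], channel),
                                   absolute[[anchor]])
          anchor_mask <- warp_rigid(matrix(1, shp[1L], shp[2L]),
                                    absolute[[anchor]]) > 0.999
          cands <- list()
          for (k in idx[pos:min(pos + 2L, length(idx))]) {
            r <- suppressWarnings(register_pair(
              anchor_img, get_channel(sections[[k]], channel),
              max_rotation = if (is.null(max_abs_rotation))
                max_rotation else max_abs_rotation + slack_r,
              max_translation = max_abs_translation + slack_t,
              coarse_step = coarse_step,
              confidence_floor = confidence_floor,
              smooth_sigma = smooth_sigma,
              overlap_ratio = overlap_ratio,
              polish = polish, fixed_mask = anchor_mask))
            if (!r$flagged && bound_ok(r$transform))
              cands[[length(cands) + 1L]] <-
                list(k = k, score = r$score,
                     corr = rt_compose(r$transform,
                                       rt_inverse(absolute[[k]])))
          }
          corr <- NULL
          if (length(cands) >= 2L) {
            for (a in seq_len(length(cands) - 1L)) for (b in (a + 1L):length(cands)) {
              d <- rt_compose(cands[[a]]$corr, rt_inverse(cands[[b]]$corr))
              if (abs(d$tx) <= 2 && abs(d$ty) <= 2 && abs(d$theta) <= 1) {
                pick <- if (cands[[a]]$score >= cands[[b]]$score) a else b
                corr <- cands[[pick]]$corr
                break
              }
            }
          }
          if (is.null(corr) && length(cands) >= 1L) {
            top <- which.max(vapply(cands, `[[`, 1, "score"))
            if (cands[[top]]$score >= 0.5) corr <- cands[[top]]$corr
          }
          flagged[i0] <<- TRUE  # record that this link needed repair
          if (is.null(corr)) break  # no trustworthy repair; leave chain as is
          for (j in idx[pos:length(idx)])
            absolute[[j]] <<- rt_compose(corr, absolute[[j]])
        }
      }
      if (reference_index < n) reanchor((reference_index + 1L):n)
      if (reference_index > 1L) reanchor((reference_index - 1L):1L)
    }
    # pairwise reported consistently with the chain actually used
    for (i in 2L:n)
      pairwise[[i]] <- rt_compose(rt_inverse(absolute[[i - 1L]]), absolute[[i]])
  } else {
    # register each section against the mean of its nearest already-aligned
    # neighbours; the fixed image lives in the reference frame, so the result
    # is the section's absolute transform directly
    aligned_ch <- vector("list", n)
    aligned_mk <- vector("list", n)
    ones <- matrix(1, shp[1L], shp[2L])
    aligned_ch[[reference_index]] <- get_channel(sections[[reference_index]], channel)
    aligned_mk[[reference_index]] <- ones
    walk <- function(idx) {
      for (i in idx) {
        done <- if (i > reference_index) (i - 1L):max(reference_index, i - running_window)
                else (i + 1L):min(reference_index, i + running_window)
        ref_img <- Reduce(`+`, aligned_ch[done]) / length(done)
        ref_mask <- Reduce(`+`, aligned_mk[done]) / length(done) > 0.999
        res <- reg(ref_img, get_channel(sections[[i]], channel),
                   fixed_mask = ref_mask)
        absolute[[i]] <<- res$transform
        scores[i] <<- res$score
        flagged[i] <<- res$flagged
        aligned_ch[[i]] <<- warp_rigid(get_channel(sections[[i]], channel),
                                       absolute[[i]])
        aligned_mk[[i]] <<- (warp_rigid(ones, absolute[[i]]) > 0.999) * 1
      }
    }
    if (reference_index < n) walk((reference_index + 1L):n)
    if (reference_index > 1L) walk((reference_index - 1L):1L)
    for (i in 2L:n)
      pairwise[[i]] <- rt_compose(rt_inverse(absolute[[i - 1L]]), absolute[[i]])
  }

  aligned <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sections[[i]]
    data <- s$data
    if (!(i == reference_index)) {
      for (k in seq_along(s$channels))
        data[, , k] <- warp_rigid(s$data[, , k], absolute[[i]])
    }
    aligned[[i]] <- section_image(data, s$channels, s$pixel_size,
                                  s$thickness, s$index)
  }
  structure(list(pairwise = pairwise, absolute = absolute, scores = scores,
                 flagged = flagged, reference_index = as.integer(reference_index),
                 aligned = aligned),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: %d sections, reference %d, %d flagged pair(s)\n",
              length(x$absolute), x$reference_index, sum(x$flagged)))
  invisible(x)
}

#' Serialize / read alignment transforms
#'
#' @param result an `alignment_result`.
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
write_transforms <- function(result, path) {
  tolist <- function(t) if (is.null(t)) NULL else
    list(tx = t$tx, ty = t$ty, theta = t$theta)
  jsonlite::write_json(list(
    reference_index = result$reference_index,
    pairwise = lapply(result$pairwise, tolist),
    absolute = lapply(result$absolute, tolist),
    scores = result$scores,
    flagged = result$flagged
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  fromlist <- function(t) if (is.null(t)) NULL else
    rigid_transform(t$tx, t$ty, t$theta)
  list(reference_index = x$reference_index,
       pairwise = lapply(x$pairwise, fromlist),
       absolute = lapply(x$absolute, fromlist),
       scores = unlist(lapply(x$scores, function(s) if (is.null(s)) NA_real_ else s)),
       flagged = unlist(x$flagged))
}

#' Fuse a re-probed imaging round onto the first round of the same section
#'
#' After antibody elution and re-staining, the same physical section is imaged
#' again; both rounds share the DAPI counterstain. The second round is rigidly
#' registered to the first on DAPI, its non-DAPI channels are resampled into
#' the first round's frame, and the channel sets are concatenated, so a section
#' can carry more than four fluorescent channels. Duplicated channel names from
#' the second round are suffixed with `"_r2"`.
#'
#' Unlike stack alignment, a registration score below the confidence floor is
#' an error here: re-probe fusion must not silently misalign.
#'
#' @param round1,round2 [section_image()] objects of the same physical section.
#' @param dapi_channel name of the shared nuclear channel.
#' @inheritParams register_pair
#' @return a [section_image()] with round 1's channels followed by round 2's
#'   non-DAPI channels, plus attributes `fuse_transform` and `fuse_score`.
#' @export
fuse_reprobe <- function(round1, round2, dapi_channel = "DAPI",
                         max_rotation = 10, max_translation = NULL,
                         confidence_floor = 0.1, smooth_sigma = 1,
                         overlap_ratio = 0.5) {
  stopifnot(inherits(round1, "section_image"), inherits(round2, "section_image"),
            dapi_channel %in% round1$channels,
            dapi_channel %in% round2$channels,
            all(dim(round1$data)[1:2] == dim(round2$data)[1:2]))
  res <- register_pair(get_channel(round1, dapi_channel),
                       get_channel(round2, dapi_channel),
                       max_rotation = max_rotation,
                       max_translation = max_translation,
                       confidence_floor = confidence_floor,
                       smooth_sigma = smooth_sigma,
                       overlap_ratio = overlap_ratio)
  if (res$flagged)
    stop("re-probe registration failed (score below confidence floor); refusing to fuse")
  keep <- setdiff(round2$channels, dapi_channel)
  new_names <- ifelse(keep %in% round1$channels, paste0(keep, "_r2"), keep)
  h <- dim(round1$data)[1L]; w <- dim(round1$data)[2L]
  data <- array(0, dim = c(h, w, length(round1$channels) + length(keep)))
  data[, , seq_along(round1$channels)] <- round1$data
  for (k in seq_along(keep)) {
    src <- get_channel(round2, keep[k])
    data[, , length(round1$channels) + k] <- warp_rigid(src, res$transform)
  }
  out <- section_image(data, c(round1$channels, new_names), round1$pixel_size,
                       round1$thickness, round1$index)
  attr(out, "fuse_transform") <- res$transform
  attr(out, "fuse_score") <- res$score
  out
}
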