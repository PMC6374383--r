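#' Intensity bins for label-retention grading
#'
#' Label-retaining cells (LRCs) are graded on the 8-bit GFP scale into three
#' classes: low `[0, 100)`, mid `[100, 200)` and high `[200, 255]`. Bins are
#' half-open with the uppermost bin closed, so 100 is mid and 200 is high
#' ("200+"). Every representable intensity maps to exactly one bin.
#'
#' @param edges strictly increasing bin edges; `length(edges) - 1` bins.
#' @param full_scale largest representable intensity (255 for 8-bit).
#' @param labels bin labels; default low/mid/high for 3 bins.
#' @return object of class `intensity_bins`.
#' @export
intensity_bins <- function(edges = c(0, 100, 200, 255), full_scale = 255,
                           labels = NULL) {
  stopifnot(length(edges) >= 2L, all(diff(edges) > 0),
            edges[1L] >= 0, edges[length(edges)] <= full_scale)
  nb <- length(edges) - 1L
  if (is.null(labels))
    labels <- if (nb == 3L) c("low", "mid", "high") else paste0("bin", seq_len(nb))
  stopifnot(length(labels) == nb)
  structure(list(edges = as.numeric(edges), labels = labels,
                 full_scale = full_scale),
            class = "intensity_bins")
}

#' Classify intensities into label-retention bins
#'
#' @param intensity numeric vector of intensities in `[edges[1], edges[last]]`.
#' @param bins an [intensity_bins()].
#' @return factor of bin labels, one per input value.
#' @examples
#' classify_bin(c(50, 150, 220))  # low mid high
#' @export
classify_bin <- function(intensity, bins = intensity_bins()) {
  stopifnot(inherits(bins, "intensity_bins"))
  e <- bins$edges
  if (any(intensity < e[1L] | intensity > e[length(e)]))
    stop("intensity outside [", e[1L], ", ", e[length(e)], "]")
  i <- findInterval(intensity, e, rightmost.closed = TRUE)
  factor(bins$labels[i], levels = bins$labels)
}

#' Segment nuclei in a volume by thresholding and 3-D connected components
#'
#' Binarizes the chosen channel (foreground = intensity strictly above the
#' threshold), labels 3-D connected components under 26-connectivity, discards
#' components smaller than `min_volume_voxels`, and computes per-object voxel
#' count, centroid (0-based voxel indices and micrometres) and mean intensity
#' in every channel of the volume.
#'
#' @param volume an `if_volume`.
#' @param channel channel to segment (DAPI for nuclei).
#' @param threshold a fixed numeric threshold, or `"otsu"` for automatic
#'   threshold selection on the channel histogram.
#' @param min_volume_voxels smallest object retained, voxels.
#' @return object of class `labeled_objects`: `label_volume` (integer (z, y, x)
#'   array, labels contiguous from 1), `objects` (data frame: id, voxel_count,
#'   centroids, `mean_<channel>` columns), `threshold_used`, `channel`,
#'   `min_volume_voxels`. An all-background channel yields zero objects.
#' @export
segment_nuclei <- function(volume, channel = "DAPI", threshold = "otsu",
                           min_volume_voxels = 1L) {
  stopifnot(inherits(volume, "if_volume"), min_volume_voxels >= 1L)
  arr <- get_volume_channel(volume, channel)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(arr) else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    as.numeric(threshold)
  }
  mask <- arr > thr
  dims <- dim(arr)
  empty_objects <- data.frame(id = integer(0), voxel_count = integer(0),
                              z_vox = numeric(0), y_vox = numeric(0),
                              x_vox = numeric(0))
  if (!any(mask)) {
    return(structure(list(label_volume = array(0L, dims),
                          objects = add_channel_means(empty_objects, volume,
                                                      array(0L, dims)),
                          threshold_used = thr, channel = channel,
                          min_volume_voxels = as.integer(min_volume_voxels)),
                     class = "labeled_objects"))
  }
  labels <- array(.label_cc_3d(as.vector(mask), as.integer(dims)), dims)
  counts <- tabulate(labels)
  keep <- which(counts >= min_volume_voxels)
  relabel <- integer(length(counts))
  relabel[keep] <- seq_along(keep)
  nz <- labels != 0L
  labels[nz] <- relabel[labels[nz]]
  if (length(keep) == 0L) {
    objects <- empty_objects
  } else {
    idx <- which(labels != 0L, arr.ind = TRUE)
    lab <- labels[labels != 0L]
    vc <- tabulate(lab, nbins = length(keep))
    cz <- tapply(idx[, 1L] - 1, lab, mean)
    cy <- tapply(idx[, 2L] - 1, lab, mean)
    cx <- tapply(idx[, 3L] - 1, lab, mean)
    objects <- data.frame(id = seq_along(keep), voxel_count = vc,
                          z_vox = as.numeric(cz), y_vox = as.numeric(cy),
                          x_vox = as.numeric(cx))
  }
  vs <- volume$voxel_size
  objects$x_um <- (objects$x_vox + 0.5) * unname(vs["x"])
  objects$y_um <- (objects$y_vox + 0.5) * unname(vs["y"])
  objects$z_um <- (objects$z_vox + 0.5) * unname(vs["z"])
  objects <- add_channel_means(objects, volume, labels)
  structure(list(label_volume = labels, objects = objects,
                 threshold_used = thr, channel = channel,
                 min_volume_voxels = as.integer(min_volume_voxels)),
            class = "labeled_objects")
}

add_channel_means <- function(objects, volume, labels) {
  n <- nrow(objects)
  lab <- labels[labels != 0L]
  for (k in seq_along(volume$channel_names)) {
    col <- paste0("mean_", volume$channel_names[k])
    if (n == 0L) { objects[[col]] <- numeric(0); next }
    ch <- get_volume_channel(volume, k)
    objects[[col]] <- as.numeric(tapply(ch[labels != 0L], lab, mean))
  }
  objects
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("labeled_objects: %d object(s) from channel %s (threshold %.4g, min volume %d voxels)\n",
              nrow(x$objects), x$channel, x$threshold_used,
              x$min_volume_voxels))
  invisible(x)
}

#' Otsu threshold of an 8-bit intensity array
#'
#' @param arr numeric array of intensities on the 0-255 scale.
#' @return threshold on the same scale.
#' @export
otsu_threshold <- function(arr) {
  EBImage::otsu(EBImage::Image(as.vector(arr) / 255,
                               dim = c(length(arr), 1L)),
                range = c(0, 1), levels = 256L) * 255
}

#' Count label-retaining sub-populations and grade them by intensity
#'
#' Every segmented nucleus counts toward `total_nuclei`. Nuclei whose mean
#' intensity in the label channel reaches `lrc_floor` are label-retaining cells
#' (LRCs); these are graded into the intensity bins and reported as counts and
#' nearest-integer percentages of the LRC total. Bin counts always sum to
#' `lrc_total`, which never exceeds `total_nuclei`.
#'
#' @param objects a `labeled_objects` (from [segment_nuclei()] on the nuclear
#'   channel) or its `objects` data frame.
#' @param lrc_channel label channel name (mean column `mean_<lrc_channel>`).
#' @param lrc_floor minimum mean label intensity for a nucleus to count as an
#'   LRC. Any signal above a zero background (>= 1 on the 8-bit scale) counts
#'   by default.
#' @param bins an [intensity_bins()].
#' @return object of class `cell_count_report`: `total_nuclei`, `lrc_total`,
#'   `per_bin` (named counts), `per_bin_pct` (nearest-integer percentages of
#'   `lrc_total`), `per_bin_frac` (raw fractions), `thresholds_used`
#'   (bin edges), `lrc_floor`, `flag_no_lrc`.
#' @export
count_subpopulations <- function(objects, lrc_channel = "GFP", lrc_floor = 1,
                                 bins = intensity_bins()) {
  df <- if (inherits(objects, "labeled_objects")) objects$objects else objects
  col <- paste0("mean_", lrc_channel)
  if (!col %in% names(df)) stop("no column '", col, "' in the object table")
  total <- nrow(df)
  means <- df[[col]]
  is_lrc <- !is.na(means) & means >= lrc_floor
  lrc_total <- sum(is_lrc)
  nb <- length(bins$labels)
  if (lrc_total > 0L) {
    clipped <- pmin(pmax(means[is_lrc], bins$edges[1L]),
                    bins$edges[length(bins$edges)])
    per_bin <- table(classify_bin(clipped, bins))
    per_bin <- stats::setNames(as.integer(per_bin), bins$labels)
  } else {
    per_bin <- stats::setNames(integer(nb), bins$labels)
  }
  report <- structure(list(
    total_nuclei = total,
    lrc_total = lrc_total,
    per_bin = per_bin,
    per_bin_pct = bin_percentages(per_bin),
    per_bin_frac = if (lrc_total > 0L) per_bin / lrc_total else
      stats::setNames(rep(0, nb), bins$labels),
    thresholds_used = bins$edges,
    lrc_floor = lrc_floor,
    flag_no_lrc = lrc_total == 0L
  ), class = "cell_count_report")
  stopifnot(sum(report$per_bin) == report$lrc_total,
            report$lrc_total <= report$total_nuclei)
  report
}

#' Nearest-integer percentages of bin counts
#'
#' @param counts named integer vector of per-bin counts.
#' @return integer percentages of `sum(counts)` (0s when the total is 0).
#' @examples
#' bin_percentages(c(low = 40, mid = 31, high = 20))  # 44 34 22
#' @export
bin_percentages <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(stats::setNames(rep(0L, length(counts)), names(counts)))
  stats::setNames(as.integer(round_half_up(counts / total * 100)),
                  names(counts))
}

#' @export
print.cell_count_report <- function(x, ...) {
  cat(sprintf("cell_count_report: %d nuclei, %d LRCs\n",
              x$total_nuclei, x$lrc_total))
  for (b in names(x$per_bin))
    cat(sprintf("  %-5s %4d  (%d%%)\n", b, x$per_bin[[b]], x$per_bin_pct[[b]]))
  if (x$flag_no_lrc) cat("  [no LRCs found; percentages reported as 0]\n")
  invisible(x)
}

#' Mean object count over three segmentation thresholds
#'
#' Counts 3-D objects at three increasing thresholds (high, medium, low
#' stringency) and returns the arithmetic mean of the three counts, a more
#' stable estimate of the cell number than any single threshold.
#'
#' @param volume an `if_volume`.
#' @param channel channel to segment.
#' @param thresholds exactly three strictly increasing intensity thresholds.
#' @param min_volume_voxels smallest object retained, voxels.
#' @return list with `mean_count`, `counts` (per threshold) and `thresholds`.
#' @export
multi_threshold_count <- function(volume, channel = "DAPI", thresholds,
                                  min_volume_voxels = 1L) {
  if (length(thresholds) != 3L) stop("exactly three thresholds are required")
  if (any(diff(thresholds) < 0)) stop("thresholds must be non-decreasing")
  counts <- vapply(thresholds, function(t)
    nrow(segment_nuclei(volume, channel, t, min_volume_voxels)$objects), 1)
  list(mean_count = mean(counts), counts = counts,
       thresholds = as.numeric(thresholds))
}

#' Default minimum object volume from the smallest expected nucleus
#'
#' Volume (in voxels) of a sphere of the given radius at the stated voxel
#' geometry; used to suppress noise specks deterministically.
#'
#' @param radius_um smallest expected nucleus radius, um.
#' @param pixel_size lateral voxel size, um.
#' @param thickness axial voxel size, um.
#' @return integer voxel count (at least 1).
#' @export
min_nucleus_volume_voxels <- function(radius_um, pixel_size, thickness) {
  v <- (4 / 3) * pi * radius_um^3 / (pixel_size^2 * thickness)
  max(1L, as.integer(floor(v)))
}

#' Write per-object and summary quantification reports
#'
#' @param objects a `labeled_objects`.
#' @param report a `cell_count_report`.
#' @param dir output directory; writes `objects.csv` (one row per object, with
#'   its bin) and `summary.json`.
#' @param lrc_channel,bins as passed to [count_subpopulations()].
#' @return invisibly, `dir`.
#' @export
write_report <- function(objects, report, dir, lrc_channel = "GFP",
                         bins = intensity_bins()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- objects$objects
  col <- paste0("mean_", lrc_channel)
  if (nrow(df) > 0L && col %in% names(df)) {
    clipped <- pmin(pmax(df[[col]], bins$edges[1L]),
                    bins$edges[length(bins$edges)])
    df$bin <- ifelse(df[[col]] >= report$lrc_floor,
                     as.character(classify_bin(clipped, bins)), "non_lrc")
  }
  utils::write.csv(df, file.path(dir, "objects.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    total_nuclei = report$total_nuclei,
    lrc_total = report$lrc_total,
    per_bin = as.list(report$per_bin),
    per_bin_pct = as.list(report$per_bin_pct),
    per_bin_frac = as.list(report$per_bin_frac),
    thresholds_used = report$thresholds_used,
    lrc_floor = report$lrc_floor,
    flag_no_lrc = report$flag_no_lrc
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
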