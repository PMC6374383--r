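#' Configuration for the synthetic serial-section phantom
#'
#' Describes a 3-D tissue of spherical nuclei that is physically sectioned,
#' imaged in two fluorescence channels (DAPI: all nuclei; GFP: label-retention
#' signal) and corrupted the way real acquisition is: per-section rigid
#' misplacement, overlapping mosaic tiles, background and additive noise.
#' Per-cell GFP follows the pulse-chase dilution law: intensity halves with
#' every division (see [dilution_intensity()]).
#'
#' Defaults reflect the acquisition the pipeline targets: 2 um sections,
#' 0.44 um pixels, 10% tile overlap, 8-bit intensities with an initial label
#' intensity of 255.
#'
#' @param tissue_extent (x, y, z) tissue size in micrometres.
#' @param n_cells number of nuclei.
#' @param nucleus_radius_range (min, max) nucleus radius in micrometres.
#' @param section_thickness physical section thickness in micrometres.
#' @param pixel_size lateral pixel pitch in micrometres.
#' @param divisions_max per-cell division count is sampled uniformly from the
#'   integers 0..`divisions_max`.
#' @param initial_intensity 8-bit GFP intensity of an undivided (fully
#'   label-retaining) cell.
#' @param dapi_intensity_range (min, max) 8-bit DAPI intensity; each nucleus
#'   draws its own counterstain brightness uniformly from this range, the way
#'   chromatin density varies between real nuclei. A degenerate range (equal
#'   endpoints) gives every nucleus the same brightness.
#' @param background_level additive constant background (8-bit units) on every
#'   channel. The GFP background of fully diluted cells is not a measured
#'   quantity; it is exposed here as a parameter.
#' @param noise_sd standard deviation of additive Gaussian noise (8-bit units).
#' @param misalignment_range (max |tx| px, max |ty| px, max |theta| degrees) of
#'   the per-section rigid misplacement; section 1 is never perturbed and
#'   serves as the reference.
#' @param tile_grid (rows, cols) mosaic grid, or `NULL` for whole-section
#'   acquisition.
#' @param tile_overlap_fraction fractional overlap between adjacent tiles.
#' @param tile_jitter_px max absolute integer jitter of true tile origins
#'   around the nominal grid (tile 1 is never jittered).
#' @param edge_softness_px width in pixels of the linear intensity falloff at
#'   the nucleus rim; 0 gives hard-edged spheres whose interior voxels carry
#'   the exact per-cell intensity.
#' @param non_touching if `TRUE`, nuclei are placed by rejection sampling so no
#'   two spheres come within `min_separation` of touching.
#' @param min_separation minimum surface-to-surface gap between nuclei in
#'   micrometres (only used when `non_touching`).
#' @param seed integer seed; the same configuration and seed give bit-identical
#'   output.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(tissue_extent = c(70.4, 70.4, 40),
                           n_cells = 60L,
                           nucleus_radius_range = c(3, 4.5),
                           section_thickness = 2,
                           pixel_size = 0.44,
                           divisions_max = 6L,
                           initial_intensity = 255,
                           dapi_intensity_range = c(150, 230),
                           background_level = 5,
                           noise_sd = 3,
                           misalignment_range = c(5, 5, 2),
                           tile_grid = NULL,
                           tile_overlap_fraction = 0.10,
                           tile_jitter_px = 0L,
                           edge_softness_px = 1,
                           non_touching = TRUE,
                           min_separation = 1,
                           seed = 1L) {
  stopifnot(length(tissue_extent) == 3L, all(tissue_extent > 0),
            n_cells >= 0L,
            length(nucleus_radius_range) == 2L,
            all(nucleus_radius_range > 0),
            nucleus_radius_range[1L] <= nucleus_radius_range[2L],
            section_thickness > 0, pixel_size > 0,
            divisions_max >= 0L,
            initial_intensity >= 0,
            length(dapi_intensity_range) == 2L, all(dapi_intensity_range >= 0),
            dapi_intensity_range[1L] <= dapi_intensity_range[2L],
            background_level >= 0, noise_sd >= 0,
            length(misalignment_range) == 3L, all(misalignment_range >= 0),
            tile_overlap_fraction > 0, tile_overlap_fraction < 1,
            tile_jitter_px >= 0L, edge_softness_px >= 0,
            min_separation >= 0)
  if (n_cells > 0L && nucleus_radius_range[2L] >= min(tissue_extent) / 2)
    stop("nucleus radii must be smaller than half the smallest tissue extent")
  if (!is.null(tile_grid)) stopifnot(length(tile_grid) == 2L, all(tile_grid >= 1L))
  structure(list(
    tissue_extent = as.numeric(tissue_extent),
    n_cells = as.integer(n_cells),
    nucleus_radius_range = as.numeric(nucleus_radius_range),
    section_thickness = as.numeric(section_thickness),
    pixel_size = as.numeric(pixel_size),
    divisions_max = as.integer(divisions_max),
    initial_intensity = as.numeric(initial_intensity),
    dapi_intensity_range = as.numeric(dapi_intensity_range),
    background_level = as.numeric(background_level),
    noise_sd = as.numeric(noise_sd),
    misalignment_range = as.numeric(misalignment_range),
    tile_grid = if (is.null(tile_grid)) NULL else as.integer(tile_grid),
    tile_overlap_fraction = as.numeric(tile_overlap_fraction),
    tile_jitter_px = as.integer(tile_jitter_px),
    edge_softness_px = as.numeric(edge_softness_px),
    non_touching = isTRUE(non_touching),
    min_separation = as.numeric(min_separation),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Label intensity after repeated division
#'
#' Histone-bound GFP label is diluted by half at every cell division, so after
#' `divisions` rounds a cell retains `initial * 0.5^divisions`. The value is
#' real-valued; quantization to 8-bit happens only at image rasterization.
#'
#' @param initial starting intensity (>= 0).
#' @param divisions non-negative integer division count (vectorized).
#' @return real-valued retained intensity.
#' @examples
#' dilution_intensity(255, 0:3)  # 255 127.5 63.75 31.875
#' @export
dilution_intensity <- function(initial, divisions) {
  if (any(initial < 0)) stop("initial intensity must be >= 0")
  if (any(divisions < 0) || any(divisions != floor(divisions)))
    stop("divisions must be non-negative integers")
  initial * 0.5^divisions
}

# Sample non-overlapping sphere centres (um) by rejection.
place_cells <- function(config) {
  n <- config$n_cells
  ext <- config$tissue_extent
  rr <- config$nucleus_radius_range
  radius <- stats::runif(n, rr[1L], rr[2L])
  centroid <- matrix(NA_real_, n, 3L)
  if (n == 0L) return(list(centroid = centroid, radius = radius))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      p <- c(stats::runif(1, radius[i], ext[1L] - radius[i]),
             stats::runif(1, radius[i], ext[2L] - radius[i]),
             stats::runif(1, radius[i], ext[3L] - radius[i]))
      if (!config$non_touching || i == 1L) { ok <- TRUE } else {
        # projection-safe: slab projection turns spheres into per-slab disks,
        # and 26-connectivity links adjacent slabs, so cells whose z ranges
        # come within two slab thicknesses of touching must also be separated
        # laterally; otherwise axial separation alone suffices
        prev <- seq_len(i - 1L)
        dxy <- sqrt((centroid[prev, 1L] - p[1L])^2 +
                    (centroid[prev, 2L] - p[2L])^2)
        dz <- abs(centroid[prev, 3L] - p[3L])
        rsum <- radius[prev] + radius[i] + config$min_separation
        ok <- all(dxy > rsum | dz > rsum + 2 * config$section_thickness)
      }
      if (ok) { centroid[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed) stop("could not place ", n, " non-touching nuclei in the ",
                      "given tissue extent; reduce n_cells or radii")
  }
  list(centroid = centroid, radius = radius)
}

# Rasterize one slab: maximum-intensity projection of the analytic nucleus
# profile through [z0, z1), drawn in the (already misplaced) section frame.
render_section <- function(cells, s, config, transform, W, H) {
  th <- config$section_thickness
  px <- config$pixel_size
  z0 <- (s - 1) * th; z1 <- s * th
  dapi <- matrix(0, H, W)
  gfp <- matrix(0, H, W)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  for (i in seq_len(nrow(cells$centroid))) {
    cz <- cells$centroid[i, 3L]; r <- cells$radius[i]
    dz <- max(z0 - cz, cz - z1, 0)
    if (dz >= r) next
    r_eff_px <- sqrt(r^2 - dz^2) / px
    # um position -> 0-based pixel coordinate (pixel j covers [j*px, (j+1)*px))
    c_ref <- cells$centroid[i, 1:2] / px - 0.5
    c_sec <- rt_apply(transform, matrix(c_ref, 1L), ctr)
    cx <- c_sec[1L]; cy <- c_sec[2L]
    xlo <- max(0L, floor(cx - r_eff_px - 1)); xhi <- min(W - 1L, ceiling(cx + r_eff_px + 1))
    ylo <- max(0L, floor(cy - r_eff_px - 1)); yhi <- min(H - 1L, ceiling(cy + r_eff_px + 1))
    if (xlo > xhi || ylo > yhi) next
    xs <- xlo:xhi; ys <- ylo:yhi
    d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
    f <- if (config$edge_softness_px > 0) {
      pmin(1, pmax(0, (r_eff_px - d) / config$edge_softness_px))
    } else {
      (d <= r_eff_px) * 1
    }
    ri <- ys + 1L; ci <- xs + 1L
    dapi[ri, ci] <- pmax(dapi[ri, ci], f * cells$dapi[i])
    gfp[ri, ci] <- pmax(gfp[ri, ci], f * cells$intensity[i])
  }
  list(DAPI = dapi, GFP = gfp)
}

#' Generate a synthetic serial-section dataset with ground truth
#'
#' Builds a 3-D tissue of spherical nuclei, assigns each cell a division count
#' and the corresponding diluted GFP intensity, slices the tissue into
#' `ceiling(extent_z / thickness)` slabs, and renders each slab as a two-channel
#' (DAPI, GFP) section image: maximum-intensity projection of the analytic
#' nucleus profile through the slab, rasterized at `pixel_size`, rendered in
#' the section's own (rigidly misplaced) frame, with background and Gaussian
#' noise added and values quantized to 8-bit (round half up, clip).
#'
#' The returned truth records everything that was applied: per-cell geometry,
#' division counts and true (unquantized) intensities, the per-section rigid
#' transforms, and true tile origins when a mosaic grid is configured.
#' A recorded section transform `P` maps reference-frame pixel coordinates to
#' that section's frame, so an aligner should recover its inverse as the
#' section's absolute transform.
#'
#' @param config a [phantom_config()].
#' @return list with elements `sections` (list of [section_image()]), `truth`
#'   (class `phantom_truth`: `cells` data frame, `section_transforms`,
#'   `tile_nominal_origins`, `tile_offsets`, `n_sections`, `image_size`), and
#'   `tiles` (per-section tilings, or `NULL` when no grid is configured).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  ext <- config$tissue_extent
  px <- config$pixel_size
  W <- max(1L, as.integer(round(ext[1L] / px)))
  H <- max(1L, as.integer(round(ext[2L] / px)))
  n_sections <- as.integer(ceiling(ext[3L] / config$section_thickness))
  if (ext[3L] < config$section_thickness)
    warning("tissue thinner than one section; emitting a single section")

  placed <- place_cells(config)
  n <- config$n_cells
  divisions <- if (n > 0L)
    sample.int(config$divisions_max + 1L, n, replace = TRUE) - 1L else integer(0)
  intensity <- dilution_intensity(config$initial_intensity, divisions)
  dapi <- stats::runif(n, config$dapi_intensity_range[1L],
                       config$dapi_intensity_range[2L])
  cells <- list(centroid = placed$centroid, radius = placed$radius,
                divisions = divisions, intensity = intensity, dapi = dapi)

  mr <- config$misalignment_range
  transforms <- vector("list", n_sections)
  transforms[[1L]] <- rt_identity()
  if (n_sections > 1L) for (s in 2L:n_sections) {
    transforms[[s]] <- rigid_transform(stats::runif(1, -mr[1L], mr[1L]),
                                       stats::runif(1, -mr[2L], mr[2L]),
                                       stats::runif(1, -mr[3L], mr[3L]))
  }

  sections <- vector("list", n_sections)
  for (s in seq_len(n_sections)) {
    ch <- render_section(cells, s, config, transforms[[s]], W, H)
    data <- array(0, dim = c(H, W, 2L))
    for (k in 1:2) {
      img <- ch[[k]] + config$background_level
      if (config$noise_sd > 0)
        img <- img + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
      data[, , k] <- quantize8(img)
    }
    sections[[s]] <- section_image(data, c("DAPI", "GFP"), px,
                                   config$section_thickness, s)
  }

  tiles <- NULL
  tile_nominal <- NULL
  tile_true <- NULL
  if (!is.null(config$tile_grid)) {
    tiles <- vector("list", n_sections)
    tile_nominal <- vector("list", n_sections)
    tile_true <- vector("list", n_sections)
    n_tiles <- prod(config$tile_grid)
    for (s in seq_len(n_sections)) {
      jitter <- matrix(0L, n_tiles, 2L)
      if (config$tile_jitter_px > 0L && n_tiles > 1L) {
        j <- config$tile_jitter_px
        jitter[-1L, ] <- matrix(
          sample.int(2L * j + 1L, 2L * (n_tiles - 1L), replace = TRUE) - j - 1L,
          n_tiles - 1L, 2L)
      }
      tiles[[s]] <- tile_section(sections[[s]], config$tile_grid,
                                 config$tile_overlap_fraction, jitter)
      tile_nominal[[s]] <- tiles[[s]]$nominal_origins
      tile_true[[s]] <- tiles[[s]]$true_origins
    }
  }

  cells_df <- data.frame(
    id = seq_len(n),
    x = placed$centroid[, 1L], y = placed$centroid[, 2L],
    z = placed$centroid[, 3L],
    radius = placed$radius,
    divisions = divisions,
    true_intensity = intensity,
    dapi_intensity = dapi
  )
  truth <- structure(list(cells = cells_df,
                          section_transforms = transforms,
                          tile_nominal_origins = tile_nominal,
                          tile_offsets = tile_true,
                          n_sections = n_sections,
                          image_size = c(W, H),
                          config = config),
                     class = "phantom_truth")
  list(sections = sections, truth = truth, tiles = tiles)
}

#' Split a section into overlapping mosaic tiles
#'
#' Tiles are laid out on a (rows x cols) grid so that adjacent tiles share at
#' least `overlap_fraction` of their width (height). The tile size is the
#' smallest integer `w` with `cols * w - (cols - 1) * overlap_fraction * w >=
#' width`, and nominal origins are spread evenly from 0 to `width - w`. With a
#' `jitter` matrix, true origins are the nominal ones plus the (integer)
#' jitter, clamped to the section; the tiles returned are the crops at the true
#' origins, so reassembling them at their true origins reproduces the section
#' bit-exactly.
#'
#' @param section a [section_image()], matrix, or (y, x, channel) array.
#' @param grid integer (rows, cols).
#' @param overlap_fraction fractional overlap in (0, 1).
#' @param jitter optional n_tiles x 2 integer matrix of (dx, dy) perturbations,
#'   tiles ordered row-major.
#' @return list with `tiles` (row-major list of (y, x, channel) arrays),
#'   `nominal_origins` and `true_origins` (n_tiles x 2 matrices of 0-based
#'   (x, y) pixel origins), `tile_size` (w, h), `grid`, `overlap_fraction`.
#' @export
tile_section <- function(section, grid, overlap_fraction = 0.10, jitter = NULL) {
  stopifnot(length(grid) == 2L, all(grid >= 1L),
            overlap_fraction > 0, overlap_fraction < 1)
  data <- if (inherits(section, "section_image")) section$data else section
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  H <- dim(data)[1L]; W <- dim(data)[2L]
  rows <- as.integer(grid[1L]); cols <- as.integer(grid[2L])
  tw <- as.integer(ceiling(W / (cols - (cols - 1) * overlap_fraction)))
  th <- as.integer(ceiling(H / (rows - (rows - 1) * overlap_fraction)))
  if (tw < 2L || th < 2L) stop("tile smaller than 2 px; coarsen the grid")
  ox <- if (cols == 1L) 0L else
    as.integer(round_half_up((0:(cols - 1L)) * (W - tw) / (cols - 1L)))
  oy <- if (rows == 1L) 0L else
    as.integer(round_half_up((0:(rows - 1L)) * (H - th) / (rows - 1L)))
  n_tiles <- rows * cols
  nominal <- cbind(x = rep(ox, times = rows), y = rep(oy, each = cols))
  if (is.null(jitter)) jitter <- matrix(0L, n_tiles, 2L)
  stopifnot(nrow(jitter) == n_tiles, ncol(jitter) == 2L)
  true_or <- nominal + jitter
  true_or[, 1L] <- pmin(pmax(true_or[, 1L], 0L), W - tw)
  true_or[, 2L] <- pmin(pmax(true_or[, 2L], 0L), H - th)
  tiles <- lapply(seq_len(n_tiles), function(t) {
    x0 <- true_or[t, 1L]; y0 <- true_or[t, 2L]
    data[(y0 + 1L):(y0 + th), (x0 + 1L):(x0 + tw), , drop = FALSE]
  })
  list(tiles = tiles, nominal_origins = nominal, true_origins = true_or,
       tile_size = c(w = tw, h = th), grid = c(rows, cols),
       overlap_fraction = overlap_fraction)
}

#' Write a phantom dataset to disk
#'
#' Sections go out as multi-page TIFFs with a `manifest.json` (see
#' [write_sections()]); the full ground truth is serialized to `truth.json`.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_phantom <- function(phantom, dir) {
  write_sections(phantom$sections, dir)
  tr <- phantom$truth
  truth_json <- list(
    cells = tr$cells,
    section_transforms = lapply(tr$section_transforms,
                                function(t) list(tx = t$tx, ty = t$ty, theta = t$theta)),
    tile_nominal_origins = tr$tile_nominal_origins,
    tile_offsets = tr$tile_offsets,
    n_sections = tr$n_sections,
    image_size = tr$image_size
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
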