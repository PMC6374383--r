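#' Assemble aligned sections into an anisotropic-voxel volume
#'
#' Stacks the sections in order along z. The lateral voxel size is the pixel
#' pitch; the axial voxel size is the physical section thickness, so the z
#' extent in micrometres is always `n_sections * thickness`. Data are stored
#' with axis order (channel, z, y, x) in every contract of this package.
#'
#' @param sections ordered list of [section_image()] objects with uniform
#'   shapes and channels.
#' @param thickness section thickness, um (z voxel size).
#' @param pixel_size lateral pixel pitch, um; defaults to the sections' own.
#' @param provenance optional list recorded alongside the data (e.g. manifest
#'   and transform file references).
#' @return object of class `if_volume` with elements `data` (4-D array
#'   (channel, z, y, x)), `voxel_size` (named x, y, z, um), `channel_names`,
#'   `provenance`.
#' @export
assemble <- function(sections, thickness, pixel_size = NULL,
                     provenance = list()) {
  if (length(sections) == 0L) stop("cannot assemble an empty section list")
  ref <- sections[[1L]]
  stopifnot(inherits(ref, "section_image"), thickness > 0)
  if (is.null(pixel_size)) pixel_size <- ref$pixel_size
  d <- dim(ref$data)
  for (i in seq_along(sections)) {
    if (!all(dim(sections[[i]]$data) == d))
      stop("section ", i, " has shape ",
           paste(dim(sections[[i]]$data), collapse = "x"),
           ", expected ", paste(d, collapse = "x"))
    if (!identical(sections[[i]]$channels, ref$channels))
      stop("section ", i, " has different channels")
  }
  n <- length(sections)
  data <- array(0, dim = c(d[3L], n, d[1L], d[2L]))
  for (i in seq_len(n)) for (k in seq_len(d[3L]))
    data[k, i, , ] <- sections[[i]]$data[, , k]
  vol <- structure(list(data = data,
                        voxel_size = c(x = pixel_size, y = pixel_size,
                                       z = thickness),
                        channel_names = ref$channels,
                        provenance = provenance),
                   class = "if_volume")
  stopifnot(abs(z_extent_um(vol) - n * thickness) < 1e-9)
  vol
}

#' @export
print.if_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("if_volume: %d channel(s) [%s], %d x %d x %d (z,y,x) voxels\n",
              d[1L], paste(x$channel_names, collapse = ", "),
              d[2L], d[3L], d[4L]))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g um (x,y,z); z extent %.6g um\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"],
              z_extent_um(x)))
  invisible(x)
}

#' Axial extent of a volume in micrometres
#'
#' @param volume an `if_volume`.
#' @return `n_sections * section_thickness`, um.
#' @export
z_extent_um <- function(volume) {
  stopifnot(inherits(volume, "if_volume"))
  dim(volume$data)[2L] * unname(volume$voxel_size["z"])
}

#' Tissue depth reconstructable per microscope slide
#'
#' Serial sections are collected as ribbons floated onto slides; the depth of
#' tissue a slide carries is `ribbons * sections_per_ribbon * thickness` (with
#' the reference protocol, 3 ribbons of 25 sections at 2 um: 150 um per slide).
#'
#' @param ribbons ribbons per slide.
#' @param sections_per_ribbon sections per ribbon.
#' @param thickness section thickness, um.
#' @return depth in micrometres.
#' @export
slide_capacity_um <- function(ribbons = 3, sections_per_ribbon = 25,
                              thickness = 2) {
  stopifnot(ribbons >= 1, sections_per_ribbon >= 1, thickness > 0)
  ribbons * sections_per_ribbon * thickness
}

#' Extract one channel of a volume as a (z, y, x) array
#'
#' @param volume an `if_volume`.
#' @param channel channel name or index.
#' @return 3-D numeric array (z, y, x).
#' @export
get_volume_channel <- function(volume, channel) {
  stopifnot(inherits(volume, "if_volume"))
  if (is.character(channel)) {
    i <- match(channel, volume$channel_names)
    if (is.na(i)) stop("channel '", channel, "' not found; available: ",
                       paste(volume$channel_names, collapse = ", "))
  } else i <- as.integer(channel)
  array(volume$data[i, , , ], dim = dim(volume$data)[2:4])
}

#' Write / read a volume as per-channel multi-page TIFFs plus a JSON sidecar
#'
#' Each channel becomes `channel_<name>.tif` (one page per z slice);
#' `volume.json` records voxel size, channel names and provenance. The
#' round-trip is bit-exact for 8- and 16-bit data. Reading a directory whose
#' sidecar is missing succeeds with a warning and unknown (NA) voxel size.
#'
#' @param volume an `if_volume`.
#' @param dir directory to write into / read from.
#' @param bits bits per sample, 8 or 16.
#' @return `write_stack`: invisibly `dir`; `read_stack`: an `if_volume`.
#' @export
write_stack <- function(volume, dir, bits = 8L) {
  stopifnot(inherits(volume, "if_volume"), bits %in% c(8L, 16L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  full <- if (bits == 8L) 255 else 65535
  d <- dim(volume$data)
  files <- sprintf("channel_%s.tif", volume$channel_names)
  for (k in seq_len(d[1L])) {
    pages <- lapply(seq_len(d[2L]), function(z)
      pmin(pmax(matrix(volume$data[k, z, , ], d[3L], d[4L]) / full, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, files[k]), bits.per.sample = bits)
  }
  jsonlite::write_json(list(voxel_size = as.list(volume$voxel_size),
                            channel_names = volume$channel_names,
                            files = files, n_sections = d[2L], bits = bits,
                            provenance = volume$provenance),
                       file.path(dir, "volume.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  sidecar <- file.path(dir, "volume.json")
  tifs <- sort(list.files(dir, pattern = "^channel_.*\\.tif$"))
  if (length(tifs) == 0L) stop("no channel TIFFs found in ", dir)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    files <- meta$files
    channels <- meta$channel_names
    voxel <- c(x = meta$voxel_size$x, y = meta$voxel_size$y,
               z = meta$voxel_size$z)
    bits <- meta$bits
    prov <- if (is.null(meta$provenance)) list() else meta$provenance
  } else {
    warning("volume.json sidecar missing; voxel size unknown")
    files <- tifs
    channels <- sub("^channel_(.*)\\.tif$", "\\1", tifs)
    voxel <- c(x = NA_real_, y = NA_real_, z = NA_real_)
    bits <- 8L
    prov <- list()
  }
  full <- if (bits == 8L) 255 else 65535
  first <- tiff::readTIFF(file.path(dir, files[1L]), all = TRUE)
  if (!is.list(first)) first <- list(first)
  nz <- length(first)
  ny <- nrow(first[[1L]]); nx <- ncol(first[[1L]])
  data <- array(0, dim = c(length(files), nz, ny, nx))
  for (k in seq_along(files)) {
    pages <- if (k == 1L) first else {
      p <- tiff::readTIFF(file.path(dir, files[k]), all = TRUE)
      if (!is.list(p)) list(p) else p
    }
    for (z in seq_len(nz)) data[k, z, , ] <- round(pages[[z]] * full)
  }
  structure(list(data = data, voxel_size = voxel, channel_names = channels,
                 provenance = prov),
            class = "if_volume")
}
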