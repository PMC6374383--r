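#' Multi-channel 2-D section image
#'
#' Container for one physical serial section: a (height, width, channel) raster
#' plus acquisition metadata. Pixel values are stored as numeric on the 8-bit
#' scale (0-255) unless stated otherwise.
#'
#' @param data numeric array (y, x, channel) or a matrix (single channel).
#' @param channels character vector of channel names (e.g. `c("DAPI", "GFP")`).
#' @param pixel_size lateral pixel pitch in micrometres.
#' @param thickness physical section thickness in micrometres.
#' @param index 1-based position of the section in the cutting order.
#' @return an object of class `section_image`.
#' @export
section_image <- function(data, channels, pixel_size = NA_real_,
                          thickness = NA_real_, index = NA_integer_) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (missing(channels)) channels <- paste0("ch", seq_len(dim(data)[3L]))
  stopifnot(length(channels) == dim(data)[3L], !anyDuplicated(channels))
  structure(list(data = data, channels = as.character(channels),
                 pixel_size = pixel_size, thickness = thickness,
                 index = as.integer(index)),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("section_image %d x %d px, %d channel(s) [%s], pixel %.3g um, thickness %.3g um\n",
              d[2L], d[1L], d[3L], paste(x$channels, collapse = ", "),
              x$pixel_size, x$thickness))
  invisible(x)
}

#' Extract one channel of a section as a matrix
#'
#' @param section a `section_image`.
#' @param channel channel name or index.
#' @return numeric matrix (y, x).
#' @export
get_channel <- function(section, channel) {
  stopifnot(inherits(section, "section_image"))
  if (is.character(channel)) {
    i <- match(channel, section$channels)
    if (is.na(i)) stop("channel '", channel, "' not found; available: ",
                       paste(section$channels, collapse = ", "))
  } else i <- as.integer(channel)
  section$data[, , i]
}

#' Write a list of sections as multi-page TIFFs plus a manifest
#'
#' Each section becomes one multi-page TIFF (one page per channel, in channel
#' order), named `section_%04d.tif`. `manifest.json` records the ordered file
#' list, channel names, pixel size and section thickness.
#'
#' @param sections list of `section_image` objects, in cutting order.
#' @param dir output directory (created if needed).
#' @param bits bits per sample, 8 or 16.
#' @return invisibly, the manifest as a list.
#' @export
write_sections <- function(sections, dir, bits = 8L) {
  stopifnot(length(sections) >= 1L, bits %in% c(8L, 16L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  full <- if (bits == 8L) 255 else 65535
  files <- character(length(sections))
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    stopifnot(inherits(s, "section_image"))
    files[i] <- sprintf("section_%04d.tif", i)
    pages <- lapply(seq_along(s$channels), function(k)
      pmin(pmax(s$data[, , k] / full, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, files[i]), bits.per.sample = bits)
  }
  manifest <- list(files = files, channels = sections[[1L]]$channels,
                   pixel_size = sections[[1L]]$pixel_size,
                   section_thickness = sections[[1L]]$thickness,
                   n_sections = length(sections), bits = bits)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read sections written by [write_sections()]
#'
#' @param dir directory containing `manifest.json` and the section TIFFs.
#' @return list of `section_image` objects.
#' @export
read_sections <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  full <- if (manifest$bits == 8L) 255 else 65535
  lapply(seq_along(manifest$files), function(i) {
    pages <- tiff::readTIFF(file.path(dir, manifest$files[i]), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    data <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
    for (k in seq_along(pages)) data[, , k] <- round(pages[[k]] * full)
    section_image(data, manifest$channels, manifest$pixel_size,
                  manifest$section_thickness, i)
  })
}
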