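#' 2D EM image
#'
#' The unit of all processing: a real-valued 2D pixel array with a physical
#' pixel size. Pixels are stored as a matrix indexed `[x, y]` with 0-based
#' user-facing coordinates, x increasing rightward and y downward, and the
#' image centre at index `floor(N/2)` on each axis. A `normalized` flag
#' records whether the image has been scaled to zero mean / unit SD, and a
#' `provenance` list accumulates one record per transform applied.
#'
#' @param pixels Numeric matrix of densities, all finite.
#' @param pixel_size Pixel size in Angstrom per pixel, > 0.
#' @param normalized Logical; whether [normalize()] has been applied.
#' @param provenance List of provenance records (internal bookkeeping;
#'   usually left at default).
#' @return An object of class `em_image`.
#' @export
em_image <- function(pixels, pixel_size, normalized = FALSE,
                     provenance = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("image contains non-finite pixels")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0 (Angstrom/pixel)")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 normalized = isTRUE(normalized), provenance = provenance),
            class = "em_image")
}

#' @export
print.em_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("em_image %d x %d px @ %.3f A/px%s; range [%.3g, %.3g]\n",
              d[1], d[2], x$pixel_size,
              if (x$normalized) ", normalized" else "",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.em_image <- function(x, ...) x$pixels

#' @export
dim.em_image <- function(x) dim(x$pixels)

#' Display an EM image
#'
#' Shows the image in conventional orientation (y downward) on a gray scale.
#'
#' @param x An [em_image()].
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.em_image <- function(x, main = "", ...) {
  px <- x$pixels
  graphics::image(x = seq_len(nrow(px)) - 1L, y = seq_len(ncol(px)) - 1L,
                  z = px[, rev(seq_len(ncol(px)))],
                  col = grDevices::gray.colors(256, 0, 1),
                  asp = 1, xlab = "x (px)", ylab = "y (px)", main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}

add_provenance <- function(img, op, params) {
  img$provenance <- c(img$provenance, list(list(op = op, params = params)))
  img
}

#' Write an image's provenance log
#'
#' Appends the transforms applied to an image (operation name + parameters)
#' to a JSON sidecar file.
#'
#' @param image An [em_image()].
#' @param path Path of the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(image, path) {
  stopifnot(inherits(image, "em_image"))
  jsonlite::write_json(image$provenance, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
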