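#' Write images or a volume to an MRC2014 file
#'
#' Writes 32-bit float (mode 2) MRC2014, little-endian, with the pixel /
#' voxel size recorded in the cell dimensions of the header. A single
#' [em_image()] or a list of equally-sized images becomes a 2D image stack
#' (`ispg = 0`); a `density_volume` becomes a volume (`ispg = 1`).
#'
#' @param x An [em_image()], a list of them, or a `density_volume`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path) {
  if (inherits(x, "em_image")) x <- list(x)
  if (inherits(x, "density_volume")) {
    dat <- x$data; d <- dim(dat); px <- x$voxel_size; ispg <- 1L
  } else {
    stopifnot(length(x) >= 1L, all(vapply(x, inherits, logical(1), "em_image")))
    d2 <- dim(x[[1]]$pixels)
    if (!all(vapply(x, function(im) identical(dim(im$pixels), d2), logical(1))))
      stop("all images in a stack must have the same dimensions")
    px <- x[[1]]$pixel_size
    d <- c(d2, length(x))
    dat <- array(unlist(lapply(x, `[[`, "pixels"), use.names = FALSE), dim = d)
    ispg <- 0L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                      # nx ny nz
  wi(2L)                     # mode 2: float32
  wi(c(0L, 0L, 0L))          # nxstart
  wi(d)                      # mx my mz
  wf(d * px)                 # cella (Angstrom)
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc mapr maps
  wf(c(min(dat), max(dat), mean(dat)))  # dmin dmax dmean
  wi(ispg)                   # ispg: 0 image stack, 1 volume
  wi(0L)                     # nsymbt
  wi(integer(25))            # extra (words 26-50); leaves exttyp blank
  # word 28 of the extra block is NVERSION; rewrite it in place below
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(as.numeric(dat)))                    # rms
  wi(0L)                     # nlabl
  writeBin(raw(800), con)    # labels
  wf(as.numeric(dat))
  # NVERSION = 20140 at byte offset 4 * 27
  seek(con, 4 * 27, rw = "write")
  wi(20140L)
  invisible(path)
}

#' Read an MRC2014 file
#'
#' Reads mode-2 (32-bit float) MRC2014 images, stacks and volumes. The
#' pixel size is taken from the header cell dimensions (`cella / mx`).
#'
#' @param path Path to an MRC file.
#' @return For a 2D image, an [em_image()]; for an image stack, a list of
#'   `em_image` (class `em_stack`) in file order; for a volume
#'   (`ispg >= 1`), a `density_volume`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit float)")
  ri(3)                      # nxstart
  m <- ri(3)                 # mx my mz
  cella <- rf(3)
  rf(3); ri(3); rf(3)        # cellb, mapc/mapr/maps, dmin/dmax/dmean
  ispg <- ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  vals <- rf(prod(d))
  px <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  if (ispg >= 1L && d[3] > 1L)
    return(structure(list(data = array(vals, dim = d), voxel_size = px),
                     class = "density_volume"))
  if (d[3] == 1L)
    return(em_image(matrix(vals, d[1], d[2]), px))
  arr <- array(vals, dim = d)
  structure(lapply(seq_len(d[3]), function(k) em_image(arr[, , k], px)),
            class = "em_stack")
}

#' @export
print.em_stack <- function(x, ...) {
  cat(sprintf("em_stack of %d images, %d x %d px @ %.3f A/px\n",
              length(x), nrow(x[[1]]$pixels), ncol(x[[1]]$pixels),
              x[[1]]$pixel_size))
  invisible(x)
}

#' Read a 2D image from MRC, PNG or TIFF
#'
#' MRC carries its own pixel size; for PNG and TIFF a `pixel_size`
#' (Angstrom/px) must be supplied and gray values are mapped to `[0, 1]`.
#' Colour (multi-channel) PNG/TIFF images are rejected.
#'
#' @param path File path; format from extension unless `format` given.
#' @param format One of `"MRC"`, `"PNG"`, `"TIFF"` (default: by extension).
#' @param pixel_size Pixel size in Angstrom, required for PNG/TIFF.
#' @return An [em_image()], or a list of them for an MRC stack.
#' @export
read_image <- function(path, format = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mrc = "MRC", mrcs = "MRC", png = "PNG",
                     tif = "TIFF", tiff = "TIFF",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  format <- toupper(format)
  if (format == "MRC") return(read_mrc(path))
  if (is.null(pixel_size))
    stop("pixel_size (Angstrom/px) must be supplied for ", format, " input")
  arr <- switch(format,
                PNG = png::readPNG(path),
                TIFF = tiff::readTIFF(path),
                stop("unsupported format '", format, "'"))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 2L) arr <- arr[, , 1L]   # gray + alpha: drop alpha
    else stop("unsupported image mode: ", dim(arr)[3],
              "-channel colour image (grayscale required)")
  }
  # readPNG/readTIFF return [row = y, col = x] in [0, 1]; transpose to [x, y]
  em_image(t(arr), pixel_size)
}
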