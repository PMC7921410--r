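#' Mask specification
#'
#' Masks restrict which pixels enter a statistic or are retained by
#' [apply_mask()]. `"circular"` keeps a disk of `radius_px` around the
#' image centre; `"threshold"` keeps pixels above `threshold_fraction` of
#' the image peak; `"none"` keeps everything.
#'
#' @param kind One of `"none"`, `"circular"`, `"threshold"`.
#' @param radius_px Disk radius in pixels (circular masks); must not exceed
#'   half the smaller image dimension when applied.
#' @param threshold_fraction Fraction of the peak in (0, 1) (threshold
#'   masks).
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(kind = c("none", "circular", "threshold"),
                      radius_px = NULL, threshold_fraction = NULL) {
  kind <- match.arg(kind)
  if (kind == "circular") {
    if (is.null(radius_px) || !is.finite(radius_px) || radius_px <= 0)
      stop("circular mask requires radius_px > 0")
  }
  if (kind == "threshold") {
    if (is.null(threshold_fraction) || !is.finite(threshold_fraction) ||
        threshold_fraction <= 0 || threshold_fraction >= 1)
      stop("threshold mask requires 0 < threshold_fraction < 1")
  }
  structure(list(kind = kind, radius_px = radius_px,
                 threshold_fraction = threshold_fraction),
            class = "mask_spec")
}

# Logical pixel matrix selected by a mask_spec.
mask_matrix <- function(image, mask) {
  d <- dim(image$pixels)
  switch(mask$kind,
    none = matrix(TRUE, d[1], d[2]),
    circular = {
      if (mask$radius_px > min(d) / 2)
        stop("circular mask radius exceeds half the smaller image dimension")
      cx <- floor(d[1] / 2); cy <- floor(d[2] / 2)
      X <- rep(seq_len(d[1]) - 1L, times = d[2])
      Y <- rep(seq_len(d[2]) - 1L, each = d[1])
      matrix((X - cx)^2 + (Y - cy)^2 <= mask$radius_px^2, d[1], d[2])
    },
    threshold = image$pixels >= mask$threshold_fraction * max(image$pixels))
}

#' Normalize image intensities to zero mean and unit SD
#'
#' Scales a class average so that its density has mean 0 and standard
#' deviation 1.0, the standard preparation before comparing or subtracting
#' averages. The statistics are computed over the mask region (whole image
#' by default) but the affine rescaling is applied to every pixel. The
#' operation is idempotent and invariant to positive affine rescaling of
#' the input.
#'
#' @param image An [em_image()].
#' @param mask A [mask_spec()] restricting the pixels used for the mean/SD.
#' @param ... Unused.
#' @return A normalized [em_image()] (the `normalized` flag is set).
#' @export
normalize <- function(image, mask = mask_spec("none"), ...) {
  UseMethod("normalize")
}

#' @rdname normalize
#' @export
normalize.em_image <- function(image, mask = mask_spec("none"), ...) {
  stopifnot(inherits(mask, "mask_spec"))
  sel <- image$pixels[mask_matrix(image, mask)]
  if (length(sel) < 2L) stop("mask selects fewer than 2 pixels")
  s <- stats::sd(sel)
  if (s == 0) stop("degenerate image: SD over the mask region is 0")
  out <- image
  m <- mean(sel)
  # skip the arithmetic when already normalized, so the operation is
  # exactly idempotent (re-dividing would perturb the last bits)
  if (abs(m) > 1e-12 || abs(s - 1) > 1e-12)
    out$pixels <- (image$pixels - m) / s
  out$normalized <- TRUE
  add_provenance(out, "normalize", list(mask = mask$kind))
}

#' Zero pixels outside a mask
#'
#' @param image An [em_image()].
#' @param mask A [mask_spec()].
#' @return The image with pixels outside the mask set to 0; the mask is
#'   recorded in the image provenance.
#' @export
apply_mask <- function(image, mask) {
  stopifnot(inherits(image, "em_image"), inherits(mask, "mask_spec"))
  if (mask$kind == "none") return(add_provenance(image, "apply_mask",
                                                 list(mask = "none")))
  m <- mask_matrix(image, mask)
  out <- image
  out$pixels[!m] <- 0
  add_provenance(out, "apply_mask",
                 list(mask = mask$kind, radius_px = mask$radius_px,
                      threshold_fraction = mask$threshold_fraction))
}
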