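#' Alignment result
#'
#' The transform mapping a moving image onto a reference: rotation (degrees,
#' counterclockwise in pixel coordinates, about the centre pixel) applied
#' first, then a shift `(dx, dy)` in pixels. `cc` is the Pearson
#' correlation of the reference with the transformed moving image.
#' `fine_tune_delta` records any manual offsets added after the automatic
#' search.
#'
#' @param dx,dy Shift in pixels applied to the moving image.
#' @param rotation Rotation in degrees applied to the moving image.
#' @param cc Normalized cross-correlation coefficient in `[-1, 1]`.
#' @param method `"translation_only"` or `"rotation+translation"`.
#' @param fine_tune_delta Numeric length-3 `(ddx, ddy, dtheta)` of manual
#'   adjustments applied after the automatic search.
#' @return An object of class `alignment_result`.
#' @export
alignment_result <- function(dx = 0, dy = 0, rotation = 0, cc = NA_real_,
                             method = c("translation_only",
                                        "rotation+translation"),
                             fine_tune_delta = c(0, 0, 0)) {
  method <- match.arg(method)
  if (!is.na(cc) && abs(cc) > 1 + 1e-9)
    stop("cc outside [-1, 1]: ", cc)
  structure(list(shift = c(dx = dx, dy = dy), rotation = rotation, cc = cc,
                 method = method,
                 fine_tune_delta = c(ddx = fine_tune_delta[1],
                                     ddy = fine_tune_delta[2],
                                     dtheta = fine_tune_delta[3])),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment (%s): shift (%.3f, %.3f) px, rotation %.3f deg, cc = %.4f\n",
    x$method, x$shift[1], x$shift[2], x$rotation, x$cc))
  if (any(x$fine_tune_delta != 0))
    cat(sprintf("  fine-tune delta: (%.3f, %.3f) px, %.3f deg\n",
                x$fine_tune_delta[1], x$fine_tune_delta[2],
                x$fine_tune_delta[3]))
  invisible(x)
}

#' Pearson correlation of two images
#'
#' Correlation of overlapping pixels of two equally-shaped images; the
#' similarity score underlying alignment. Symmetric, in `[-1, 1]`.
#'
#' @param a,b [em_image()]s of the same shape.
#' @return Scalar correlation.
#' @export
cc_score <- function(a, b) {
  stopifnot(inherits(a, "em_image"), inherits(b, "em_image"))
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("shape mismatch: ", paste(dim(a$pixels), collapse = "x"), " vs ",
         paste(dim(b$pixels), collapse = "x"))
  stats::cor(as.vector(a$pixels), as.vector(b$pixels))
}

# Zero-padded linear cross-correlation surface of two matrices via FFT.
# Returns c(s) = sum_p A(p) * B(p - s) accessible at integer shifts
# s in (-n, n), plus the cross-spectrum for subpixel refinement.
cross_correlation_fft <- function(a, b) {
  d <- dim(a)
  M <- 2L * d
  ap <- matrix(0, M[1], M[2]); ap[seq_len(d[1]), seq_len(d[2])] <- a
  bp <- matrix(0, M[1], M[2]); bp[seq_len(d[1]), seq_len(d[2])] <- b
  Fc <- stats::fft(ap) * Conj(stats::fft(bp))
  cc <- Re(stats::fft(Fc, inverse = TRUE)) / prod(M)
  list(cc = cc, spectrum = Fc, M = M)
}

# Band-limited (Fourier-interpolated) correlation values at continuous
# shifts, evaluated by matrix-multiply DFT on the cross-spectrum.
upsampled_correlation <- function(spectrum, M, ugrid, vgrid) {
  fgrid <- function(m) {
    j <- 0:(m - 1)
    ifelse(j <= m / 2, j, j - m)
  }
  fx <- fgrid(M[1]); fy <- fgrid(M[2])
  E1 <- exp(2i * pi * outer(ugrid, fx) / M[1])        # nu x M1
  E2 <- exp(2i * pi * outer(fy, vgrid) / M[2])        # M2 x nv
  Re(E1 %*% spectrum %*% E2) / prod(M)
}

#' Translational alignment by FFT cross-correlation
#'
#' Finds the shift of the moving image that maximizes its normalized
#' cross-correlation with the reference over `|dx|, |dy| <= max_shift`,
#' using zero-padded (linear, not circular) FFT cross-correlation, with
#' optional subpixel refinement by locally upsampled correlation. The
#' integer-shift optimum is identical to an exhaustive zero-padded
#' integer-shift search.
#'
#' @param ref,moving Same-shape [em_image()]s, typically [normalize()]d.
#' @param max_shift Search radius in pixels; at most half the image size.
#' @param subpixel Upsampling factor; 1 disables subpixel refinement.
#'   The refinement error is bounded by `1 / (2 * subpixel)` px.
#' @return An [alignment_result()] with `rotation = 0`.
#' @export
#' @examples
#' vol <- build_phantom(mediator_phantom())
#' ref <- normalize(project(vol))
#' fit <- align_translation(ref, ref, max_shift = 8)
#' fit$shift  # (0, 0)
align_translation <- function(ref, moving, max_shift = 8L, subpixel = 10L) {
  stopifnot(inherits(ref, "em_image"), inherits(moving, "em_image"))
  d <- dim(ref$pixels)
  if (!identical(d, dim(moving$pixels))) stop("shape mismatch")
  if (max_shift > floor(min(d) / 2))
    stop("max_shift exceeds half the image size")
  if (subpixel < 1) stop("subpixel factor must be >= 1")
  x <- cross_correlation_fft(ref$pixels, moving$pixels)
  shifts <- (-max_shift):max_shift
  sub <- x$cc[(shifts %% x$M[1]) + 1L, (shifts %% x$M[2]) + 1L, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  best <- c(shifts[k[1]], shifts[k[2]])
  if (subpixel > 1) {
    step <- 1 / subpixel
    ug <- best[1] + seq(-1, 1, by = step)
    vg <- best[2] + seq(-1, 1, by = step)
    ug <- ug[abs(ug) <= max_shift + 1e-9]
    vg <- vg[abs(vg) <= max_shift + 1e-9]
    up <- upsampled_correlation(x$spectrum, x$M, ug, vg)
    k <- arrayInd(which.max(up), dim(up))
    best <- c(ug[k[1]], vg[k[2]])
  }
  res <- alignment_result(best[1], best[2], 0, method = "translation_only")
  res$cc <- cc_score(ref, apply_transform(moving, res))
  res
}

#' Joint rotation and translation alignment
#'
#' Exhaustive search: for each angle in `angle_grid` the moving image is
#' rotated (bilinear, about the centre pixel) and translationally aligned;
#' the global best by correlation is returned. Near-ties (within 1e-9) are
#' broken by smallest absolute rotation, then smallest shift norm, so a
#' self-alignment returns the identity. Class averages of the same complex
#' emerge approximately pre-oriented from 2D clustering, hence the default
#' grid of +-15 degrees in 1-degree steps; pass a full-circle grid for
#' unrelated views.
#'
#' @param ref,moving Same-shape [em_image()]s.
#' @param angle_grid Numeric vector of rotations to try, degrees.
#' @param max_shift Translational search radius, px.
#' @param subpixel Subpixel upsampling factor for the translation.
#' @return An [alignment_result()] with `method = "rotation+translation"`.
#' @export
align_rotation_translation <- function(ref, moving,
                                       angle_grid = seq(-15, 15, by = 1),
                                       max_shift = 8L, subpixel = 10L) {
  if (length(angle_grid) == 0L) stop("angle_grid must be nonempty")
  cand <- vector("list", length(angle_grid))
  for (i in seq_along(angle_grid)) {
    th <- angle_grid[i]
    rot <- moving
    rot$pixels <- transform_pixels(moving$pixels, 0, 0, th)
    r <- align_translation(ref, rot, max_shift = max_shift,
                           subpixel = subpixel)
    cand[[i]] <- list(theta = th, shift = r$shift, cc = r$cc)
  }
  ccs <- vapply(cand, `[[`, numeric(1), "cc")
  near <- which(ccs >= max(ccs) - 1e-9)
  ord <- order(abs(angle_grid[near]),
               vapply(cand[near], function(c) sqrt(sum(c$shift^2)), numeric(1)))
  b <- cand[[near[ord[1]]]]
  alignment_result(b$shift[1], b$shift[2], b$theta, cc = b$cc,
                   method = "rotation+translation")
}

#' Apply manual fine-tuning offsets to an alignment
#'
#' Adds interactive adjustments `(ddx, ddy, dtheta)` on top of an automatic
#' alignment, recording them in `fine_tune_delta`. If the two images are
#' supplied, the correlation is recomputed for the adjusted transform.
#'
#' @param result An [alignment_result()].
#' @param ddx,ddy Shift adjustment, px.
#' @param dtheta Rotation adjustment, degrees.
#' @param ref,moving Optional images for recomputing `cc`.
#' @return The adjusted [alignment_result()].
#' @export
fine_tune <- function(result, ddx = 0, ddy = 0, dtheta = 0,
                      ref = NULL, moving = NULL) {
  stopifnot(inherits(result, "alignment_result"))
  out <- result
  out$shift <- result$shift + c(ddx, ddy)
  out$rotation <- result$rotation + dtheta
  out$fine_tune_delta <- result$fine_tune_delta + c(ddx, ddy, dtheta)
  if (!is.null(ref) && !is.null(moving))
    out$cc <- cc_score(ref, apply_transform(moving, out))
  out
}

#' Apply an alignment transform to an image
#'
#' Rotates about the centre pixel, then shifts, with bilinear interpolation
#' and zero fill outside the frame (the same order and conventions used
#' when searching, so applying a result to the moving image reproduces the
#' configuration that was scored).
#'
#' @param image An [em_image()].
#' @param result An [alignment_result()].
#' @return The transformed [em_image()].
#' @export
apply_transform <- function(image, result) {
  stopifnot(inherits(image, "em_image"), inherits(result, "alignment_result"))
  out <- image
  if (result$rotation == 0 && all(result$shift == 0)) {
    return(add_provenance(out, "apply_transform",
                          list(dx = 0, dy = 0, rotation = 0)))
  }
  out$pixels <- transform_pixels(image$pixels, result$shift[1],
                                 result$shift[2], result$rotation)
  add_provenance(out, "apply_transform",
                 list(dx = result$shift[[1]], dy = result$shift[[2]],
                      rotation = result$rotation))
}

#' Invert an alignment transform
#'
#' Returns the transform that undoes `result` (shift back, then rotate
#' back); composing [apply_transform()] with the inverse returns the
#' original image up to interpolation error.
#'
#' @param result An [alignment_result()].
#' @return An [alignment_result()].
#' @export
invert_transform <- function(result) {
  # forward moves content q -> R(q - c) + c + t; undoing it needs rotation
  # by -theta and shift -R^-1 t
  th <- result$rotation * pi / 180
  ct <- cos(th); st <- sin(th)
  t_inv <- -c(ct * result$shift[[1]] + st * result$shift[[2]],
              -st * result$shift[[1]] + ct * result$shift[[2]])
  alignment_result(t_inv[1], t_inv[2], -result$rotation,
                   method = result$method)
}
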