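#' Gaussian blob component of a phantom
#'
#' A coarse-grained stand-in for a subunit domain: an isotropic 3D Gaussian
#' with integrated density `weight` (arbitrary units, proportional to mass)
#' and width `sigma` (Angstrom). Coordinates are in Angstrom relative to the
#' centre of the phantom box (the voxel with 0-based index `floor(N/2)` on
#' each axis).
#'
#' @param id Character label, unique within a phantom.
#' @param center Numeric length-3 vector, Angstrom, relative to box centre.
#' @param sigma Isotropic Gaussian width, Angstrom; must be positive.
#' @param weight Integrated density, arbitrary mass-proportional units;
#'   must be positive.
#' @return A list of class `gaussian_blob`.
#' @export
#' @examples
#' gaussian_blob("MBP", c(40, 10, 0), sigma = 8, weight = 40)
gaussian_blob <- function(id, center, sigma, weight) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("blob '", id, "': center must be a finite 3-vector (Angstrom)")
  if (!is.finite(sigma) || sigma <= 0)
    stop("blob '", id, "': sigma must be > 0")
  if (!is.finite(weight) || weight <= 0)
    stop("blob '", id, "': weight must be > 0")
  structure(list(id = id, center = center, sigma = sigma, weight = weight),
            class = "gaussian_blob")
}

#' Gaussian-blob phantom of a protein complex
#'
#' Container for a coarse-grained 3D model: a set of [gaussian_blob()]s in a
#' cubic box of `box_edge` voxels at `voxel_size` Angstrom per voxel. All
#' blob centres must lie inside the box.
#'
#' @param blobs List of [gaussian_blob()] objects (at least one).
#' @param box_edge Integer edge length of the cubic voxel grid, >= 16.
#' @param voxel_size Voxel size in Angstrom, > 0.
#' @return An object of class `phantom_model`.
#' @seealso [build_phantom()], [add_tag()], [delete_domain()],
#'   [mediator_phantom()]
#' @export
phantom_model <- function(blobs, box_edge, voxel_size) {
  if (inherits(blobs, "gaussian_blob")) blobs <- list(blobs)
  if (length(blobs) < 1L) stop("phantom must contain at least one blob")
  if (!all(vapply(blobs, inherits, logical(1), "gaussian_blob")))
    stop("blobs must be a list of gaussian_blob objects")
  ids <- vapply(blobs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate blob ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  box_edge <- as.integer(box_edge)
  if (is.na(box_edge) || box_edge < 16L) stop("box_edge must be an integer >= 16")
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  half <- grid_coords(box_edge, voxel_size)
  lo <- half[1L]; hi <- half[box_edge]
  for (b in blobs) {
    if (any(b$center < lo | b$center > hi))
      stop("blob '", b$id, "': center lies outside the box")
  }
  structure(list(blobs = blobs, box_edge = box_edge, voxel_size = voxel_size),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("Gaussian-blob phantom: %d blobs, box %d^3 voxels @ %.3f A/voxel\n",
              length(x$blobs), x$box_edge, x$voxel_size))
  df <- as.data.frame(t(vapply(x$blobs, function(b)
    c(b$center, b$sigma, b$weight), numeric(5))))
  names(df) <- c("x_A", "y_A", "z_A", "sigma_A", "weight")
  rownames(df) <- vapply(x$blobs, `[[`, character(1), "id")
  print(round(df, 2))
  cat(sprintf("total weight: %.4g\n", sum(df$weight)))
  invisible(x)
}

blob_ids <- function(phantom) vapply(phantom$blobs, `[[`, character(1), "id")

#' Total integrated density of a phantom
#' @param phantom A [phantom_model()].
#' @return Sum of blob weights.
#' @export
total_weight <- function(phantom) {
  sum(vapply(phantom$blobs, `[[`, numeric(1), "weight"))
}

#' Standard asymmetric multi-lobed test phantom
#'
#' A 10-blob phantom loosely shaped like a large transcription coactivator
#' complex: an elongated, hook-shaped arrangement of head, middle and tail
#' lobes with no internal symmetry (so that projections determine in-plane
#' orientation uniquely). Blob weights sum to 110 mass units, so that a
#' 40-unit fused tag emulates the mass ratio of a ~40 kDa maltose-binding
#' protein label on a peripheral domain at this coarse-grained scale. The
#' default pixel size of 3.98 Angstrom matches typical stained-specimen
#' imaging of such complexes.
#'
#' @param box_edge Cubic box edge, voxels.
#' @param voxel_size Voxel size, Angstrom.
#' @return A [phantom_model()].
#' @export
#' @examples
#' ph <- mediator_phantom()
#' total_weight(ph)  # 110
mediator_phantom <- function(box_edge = 64L, voxel_size = 3.98) {
  spec <- list(
    #        id             x    y    z  sigma weight
    list("head_jaws",     -55, -18,   0,   12,   14),
    list("head_neck",     -38,   8,   6,   10,   10),
    list("knob",          -18,  26,  -4,    9,    8),
    list("hook",            2,  40,   2,    8,    6),
    list("med14_mid",     -12,  -2,   2,   11,   12),
    list("med14_c",        22, -10,  -4,    9,    8),
    list("upper_tail",      2, -20,   6,   10,   11),
    list("lower_tail",     28, -32,   0,   12,   15),
    list("distal_tail",    52, -20,   5,   13,   18),
    list("med15_c",        40,   2,  -6,    9,    8))
  blobs <- lapply(spec, function(s)
    gaussian_blob(s[[1]], c(s[[2]], s[[3]], s[[4]]), s[[5]], s[[6]]))
  phantom_model(blobs, box_edge, voxel_size)
}

#' Attach an extra blob emulating a fused protein tag
#'
#' Models terminal tagging of a subunit (e.g. a maltose-binding protein
#' fusion) by adding one blob at a fixed offset from an existing attachment
#' blob. The input phantom is not modified.
#'
#' @param phantom A [phantom_model()].
#' @param attach_blob Id of the existing blob the tag is fused to.
#' @param offset Length-3 numeric offset from the attachment blob centre,
#'   Angstrom.
#' @param tag_weight Integrated density of the tag (40 mass units emulates
#'   MBP on the 110-unit standard phantom).
#' @param tag_sigma Tag width, Angstrom.
#' @param tag_id Id for the new blob.
#' @return A new `phantom_model` with one extra blob.
#' @export
add_tag <- function(phantom, attach_blob, offset, tag_weight = 40,
                    tag_sigma = 8, tag_id = "tag") {
  stopifnot(inherits(phantom, "phantom_model"))
  ids <- blob_ids(phantom)
  k <- match(attach_blob, ids)
  if (is.na(k)) stop("unknown attachment blob '", attach_blob, "'")
  pos <- phantom$blobs[[k]]$center + as.numeric(offset)
  tag <- gaussian_blob(tag_id, pos, tag_sigma, tag_weight)
  phantom_model(c(phantom$blobs, list(tag)), phantom$box_edge, phantom$voxel_size)
}

#' Remove blobs emulating a domain truncation
#'
#' Models a deletion mutant (a complex lacking a defined domain) by removing
#' the named blobs. Deleting every blob is disallowed.
#'
#' @param phantom A [phantom_model()].
#' @param blob_ids Character vector of ids to remove; all must exist.
#' @return A new `phantom_model` without those blobs.
#' @export
delete_domain <- function(phantom, blob_ids) {
  stopifnot(inherits(phantom, "phantom_model"))
  ids <- vapply(phantom$blobs, `[[`, character(1), "id")
  missing <- setdiff(blob_ids, ids)
  if (length(missing))
    stop("unknown blob id(s): ", paste(missing, collapse = ", "))
  keep <- phantom$blobs[!(ids %in% blob_ids)]
  if (length(keep) == 0L) stop("cannot delete all blobs: empty model disallowed")
  phantom_model(keep, phantom$box_edge, phantom$voxel_size)
}

# 0-based index i on an N-grid sits at (i - floor(N/2)) * step Angstrom.
grid_coords <- function(n, step) {
  (seq_len(n) - 1L - floor(n / 2)) * step
}

#' Rasterize a phantom onto a voxel grid
#'
#' Each blob contributes `weight * G(||x - center||; sigma)` where G is the
#' unit-integral isotropic 3D Gaussian, evaluated at voxel centres. The
#' voxel sum times `voxel_size^3` therefore equals the total blob weight up
#' to truncation at the box boundary (within 0.5% for blobs whose 3-sigma
#' support fits in the box, which is enforced).
#'
#' @param spec A [phantom_model()].
#' @return An object of class `density_volume`: list with `data` (3D array,
#'   indexed `[x, y, z]`, x fastest) and `voxel_size` (Angstrom).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_model"))
  n <- spec$box_edge; vs <- spec$voxel_size
  g <- grid_coords(n, vs)
  lo <- g[1L]; hi <- g[n]
  vol <- array(0, dim = c(n, n, n))
  for (b in spec$blobs) {
    if (any(b$center - 3 * b$sigma < lo) || any(b$center + 3 * b$sigma > hi))
      stop("blob '", b$id, "' extends beyond the box by more than 3*sigma")
    # separable: product of three unit-integral 1D Gaussians
    g1 <- lapply(1:3, function(a)
      stats::dnorm(g, mean = b$center[a], sd = b$sigma))
    vol <- vol + b$weight * (g1[[1]] %o% g1[[2]] %o% g1[[3]])
  }
  structure(list(data = vol, voxel_size = vs), class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("density volume %d x %d x %d voxels @ %.3f A/voxel, sum %.4g\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$data)))
  invisible(x)
}
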