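#' Difference map between an aligned pair of class averages
#'
#' Subtracts the aligned reference from the variant average and rescales
#' the raw difference into standard-deviation (z) units, so that the map
#' can be read as a significance heat map. The scale is by default the
#' robust SD (1.4826 * MAD) of the raw difference over a background mask
#' (pixels where both images are below 10% of their peak), making z a
#' noise-referenced unit; `scale = "whole"` uses the SD of the entire raw
#' difference instead, and the choice is recorded in the object.
#'
#' If the background mask covers less than 5% of the image, the function
#' falls back to the whole-map SD with a warning.
#'
#' @param variant The variant (tagged, or wild-type in a deletion
#'   comparison) [em_image()]; must be normalized.
#' @param ref The reference [em_image()]; must be normalized. The alignment
#'   is applied to `ref` to bring it onto `variant`.
#' @param alignment An [alignment_result()] mapping `ref` onto `variant`.
#' @param scale `"background"` (robust, default) or `"whole"`.
#' @return An object of class `difference_map`: `z` (SD units), `raw`
#'   (normalized-density units), `scale_sd`, `background_mask`,
#'   `pixel_size`, `scale_kind`.
#' @export
compute_difference <- function(variant, ref, alignment,
                               scale = c("background", "whole")) {
  stopifnot(inherits(variant, "em_image"), inherits(ref, "em_image"),
            inherits(alignment, "alignment_result"))
  scale <- match.arg(scale)
  if (!identical(dim(variant$pixels), dim(ref$pixels)))
    stop("shape mismatch between variant and reference")
  if (!variant$normalized || !ref$normalized)
    stop("both images must be normalized before differencing")
  aligned <- apply_transform(ref, alignment)
  raw <- variant$pixels - aligned$pixels
  bg <- variant$pixels < 0.1 * max(variant$pixels) &
        aligned$pixels < 0.1 * max(aligned$pixels)
  used <- scale
  s_whole <- stats::sd(raw)
  if (scale == "background") {
    if (mean(bg) < 0.05) {
      warning("degenerate background (< 5% of pixels); using whole-image SD")
      used <- "whole"
    } else {
      s_bg <- stats::mad(raw[bg])
      # a background spread at float round-off level (noiseless inputs)
      # carries no noise information; fall back to the whole-map SD
      if (s_bg < 1e-6 * s_whole) {
        warning("background spread is numerically zero; using whole-image SD")
        used <- "whole"
      }
    }
  }
  s <- if (used == "background") stats::mad(raw[bg]) else s_whole
  if (!is.finite(s) || s == 0) s <- s_whole
  if (!is.finite(s) || s == 0) s <- 1  # identically zero difference
  structure(list(z = raw / s, raw = raw, scale_sd = s, background_mask = bg,
                 pixel_size = variant$pixel_size, scale_kind = used),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf(
    "difference map %d x %d px; scale_sd = %.4g (%s); z range [%.2f, %.2f]\n",
    nrow(x$z), ncol(x$z), x$scale_sd, x$scale_kind, min(x$z), max(x$z)))
  invisible(x)
}

#' Heat-map display of a difference map
#'
#' Diverging colours over the z (SD-unit) scale; for a publication-style
#' overlay on a class average see [render_heatmap()].
#'
#' @param x A `difference_map`.
#' @param z_range Symmetric display range in SD units.
#' @param ... Passed to [graphics::image()].
#' @export
plot.difference_map <- function(x, z_range = c(-8, 8), ...) {
  z <- pmin(pmax(x$z, z_range[1]), z_range[2])
  cols <- grDevices::hcl.colors(101, "Blue-Red 2")
  graphics::image(x = seq_len(nrow(z)) - 1L, y = seq_len(ncol(z)) - 1L,
                  z = z[, rev(seq_len(ncol(z)))], zlim = z_range, col = cols,
                  asp = 1, xlab = "x (px)", ylab = "y (px)",
                  main = "difference (SD units)", useRaster = TRUE, ...)
  invisible(x)
}

# 8-connected component labelling of a logical matrix (BFS flood fill).
# Returns an integer matrix, 0 = background, components numbered in
# scanline discovery order.
label_components_8 <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nb <- c(-1L - d[1], -d[1], 1L - d[1], -1L, 1L, d[1] - 1L, d[1], d[1] + 1L)
  cur <- 0L
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    top <- 1L
    stack[1L] <- start
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      i <- ((p - 1L) %% d[1]) + 1L
      j <- ((p - 1L) %/% d[1]) + 1L
      for (k in seq_along(nb)) {
        # guard row wrap-around at matrix edges
        di <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)[k]
        dj <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)[k]
        i2 <- i + di; j2 <- j + dj
        if (i2 < 1L || i2 > d[1] || j2 < 1L || j2 > d[2]) next
        q <- p + nb[k]
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  lab
}

region_stats <- function(diff, lab, sign) {
  out <- list()
  for (k in seq_len(max(lab))) {
    pix <- which(lab == k)
    zv <- diff$z[pix]
    w <- abs(zv)
    i <- ((pix - 1L) %% nrow(diff$z))          # 0-based x
    j <- ((pix - 1L) %/% nrow(diff$z))         # 0-based y
    cx <- sum(w * i) / sum(w)
    cy <- sum(w * j) / sum(w)
    ctr <- floor(dim(diff$z) / 2)
    out[[k]] <- list(
      pixels = pix, sign = sign,
      peak_z = if (sign == "positive") max(zv) else min(zv),
      area_px = length(pix),
      centroid_px = c(x = cx, y = cy),
      centroid_ang = c(x = (cx - ctr[1]) * diff$pixel_size,
                       y = (cy - ctr[2]) * diff$pixel_size))
  }
  out
}

#' Extract significant regions from a difference map
#'
#' Thresholds the z map at `+z_threshold` and `-z_threshold` separately,
#' labels 8-connected components, drops components smaller than `min_area`
#' pixels, and returns the survivors sorted by `|peak_z|` (descending, ties
#' by area then by scanline order of the centroid). Centroids are
#' `|z|`-weighted, reported both in 0-based pixels and in Angstrom relative
#' to the image centre.
#'
#' @param diff A `difference_map` from [compute_difference()].
#' @param z_threshold Significance threshold in SD units, > 0 (default 4,
#'   calibrated so pure-noise pairs yield no calls; 3 is a typical display
#'   threshold).
#' @param min_area Minimum region area in pixels.
#' @return A list of `significant_region` objects (possibly empty), each
#'   with `pixels`, `sign`, `peak_z`, `area_px`, `centroid_px`,
#'   `centroid_ang`.
#' @export
extract_regions <- function(diff, z_threshold = 4, min_area = 4L) {
  stopifnot(inherits(diff, "difference_map"))
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  regs <- c(region_stats(diff, label_components_8(diff$z >= z_threshold),
                         "positive"),
            region_stats(diff, label_components_8(diff$z <= -z_threshold),
                         "negative"))
  regs <- Filter(function(r) r$area_px >= min_area, regs)
  if (!length(regs)) return(list())
  key <- vapply(regs, function(r)
    c(-abs(r$peak_z), -r$area_px, r$centroid_px[2], r$centroid_px[1]),
    numeric(4))
  ord <- do.call(order, as.data.frame(t(key)))
  regs <- regs[ord]
  lapply(regs, function(r) structure(r, class = "significant_region"))
}

#' @export
print.significant_region <- function(x, ...) {
  cat(sprintf(
    "%s region: peak z = %.2f, area %d px, centroid (%.2f, %.2f) px\n",
    x$sign, x$peak_z, x$area_px, x$centroid_px[1], x$centroid_px[2]))
  invisible(x)
}

#' Localize a tagged or deleted domain from a difference map
#'
#' Picks the primary region: the strongest positive region of the
#' difference. In a tag experiment the variant (labeled complex) minus the
#' reference leaves the tag as extra (positive) density; in a deletion
#' experiment the difference is taken as wild-type minus truncation, so the
#' missing domain likewise appears positive. If no positive region passes
#' the threshold, the report flags this rather than raising an error.
#'
#' @param diff A `difference_map`.
#' @param regions Regions from [extract_regions()]; computed with defaults
#'   if omitted.
#' @param truth Optional length-2 numeric, the ground-truth (x, y) position
#'   in 0-based pixels; when supplied the Euclidean localization error is
#'   reported.
#' @param case_id Identifier carried into the report.
#' @param z_threshold,min_area Used only when `regions` is missing.
#' @return An object of class `localization_report` with elements
#'   `case_id`, `regions`, `primary` (a region or `NULL`), `found`,
#'   `centroid_px`, `centroid_ang`, `error_px` (NA without truth).
#' @export
localize <- function(diff, regions = NULL, truth = NULL, case_id = "case",
                     z_threshold = 4, min_area = 4L) {
  stopifnot(inherits(diff, "difference_map"))
  if (is.null(regions))
    regions <- extract_regions(diff, z_threshold, min_area)
  pos <- Filter(function(r) r$sign == "positive", regions)
  primary <- if (length(pos)) pos[[1]] else NULL
  err <- NA_real_
  if (!is.null(primary) && !is.null(truth))
    err <- sqrt(sum((primary$centroid_px - as.numeric(truth))^2))
  structure(list(case_id = case_id, regions = regions, primary = primary,
                 found = !is.null(primary),
                 centroid_px = if (is.null(primary)) c(NA_real_, NA_real_)
                               else primary$centroid_px,
                 centroid_ang = if (is.null(primary)) c(NA_real_, NA_real_)
                                else primary$centroid_ang,
                 truth_px = if (is.null(truth)) NULL else as.numeric(truth),
                 error_px = err),
            class = "localization_report")
}

#' @export
print.localization_report <- function(x, ...) {
  cat(sprintf("localization report '%s': %d significant region(s)\n",
              x$case_id, length(x$regions)))
  if (x$found) {
    cat(sprintf("  primary: peak z = %.2f, centroid (%.2f, %.2f) px = (%.1f, %.1f) A\n",
                x$primary$peak_z, x$centroid_px[1], x$centroid_px[2],
                x$centroid_ang[1], x$centroid_ang[2]))
    if (!is.na(x$error_px))
      cat(sprintf("  error vs ground truth: %.2f px\n", x$error_px))
  } else cat("  no significant region of the expected sign\n")
  invisible(x)
}

#' Rank candidate average pairs by difference-map cleanliness
#'
#' Aligns every (variant, reference) cross pair, computes its difference
#' map, and scores the pair as `cc_after_alignment - clutter`, where
#' clutter is the fraction of pixels exceeding the z threshold outside the
#' largest significant region. The pair list is returned sorted by score
#' (descending; ties broken by ids), emulating the practice of comparing
#' multiple average pairs to find the one giving the cleanest difference
#' map.
#'
#' @param refs,variants Lists of normalized [em_image()]s (an `em_stack`
#'   works).
#' @param angle_grid,max_shift,subpixel Alignment parameters (see
#'   [align_rotation_translation()]).
#' @param z_threshold,min_area Region parameters (see [extract_regions()]).
#' @return A data frame of class `pair_score_table`: `ref_id`,
#'   `variant_id`, `cc_after_alignment`, `clutter`, `score`, plus the
#'   alignments in `attr(, "alignments")`.
#' @export
rank_pairs <- function(refs, variants, angle_grid = seq(-15, 15, by = 1),
                       max_shift = 8L, subpixel = 10L,
                       z_threshold = 4, min_area = 4L) {
  if (inherits(refs, "em_image")) refs <- list(refs)
  if (inherits(variants, "em_image")) variants <- list(variants)
  if (length(refs) < 1L || length(variants) < 1L)
    stop("need at least one reference and one variant image")
  rows <- list(); aligns <- list()
  for (i in seq_along(variants)) for (j in seq_along(refs)) {
    al <- align_rotation_translation(variants[[i]], refs[[j]],
                                     angle_grid = angle_grid,
                                     max_shift = max_shift,
                                     subpixel = subpixel)
    dm <- compute_difference(variants[[i]], refs[[j]], al)
    sig <- abs(dm$z) >= z_threshold
    regs <- extract_regions(dm, z_threshold, min_area)
    largest <- if (length(regs)) {
      areas <- vapply(regs, `[[`, integer(1), "area_px")
      regs[[which.max(areas)]]$pixels
    } else integer(0)
    clutter <- (sum(sig) - sum(sig[largest])) / length(sig)
    rows[[length(rows) + 1L]] <- data.frame(
      ref_id = j, variant_id = i, cc_after_alignment = al$cc,
      clutter = clutter, score = al$cc - clutter)
    aligns[[paste(i, j, sep = "_")]] <- al
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$score, tab$ref_id, tab$variant_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "alignments") <- aligns
  class(tab) <- c("pair_score_table", "data.frame")
  tab
}

#' Render a difference heat map over a class average
#'
#' Writes a PNG: the underlay class average in grayscale with pixels whose
#' `|z|` exceeds `z_threshold` overlaid in diverging colours (red for
#' positive, blue for negative density), clamped to `z_range`, plus a
#' colour-bar strip on the right with tick marks at whole SD units. A JSON
#' sidecar (`<path>.json`) annotates the colour scale. Output bytes are a
#' deterministic function of the inputs.
#'
#' @param diff A `difference_map`.
#' @param underlay An [em_image()] of the same shape (typically the
#'   reference class average).
#' @param path Output PNG path.
#' @param z_range Symmetric colour range in SD units; larger values clamp.
#' @param z_threshold Overlay threshold in SD units.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(diff, underlay, path, z_range = c(-8, 8),
                           z_threshold = 3) {
  stopifnot(inherits(diff, "difference_map"), inherits(underlay, "em_image"))
  if (!identical(dim(diff$z), dim(underlay$pixels)))
    stop("underlay shape does not match the difference map")
  g <- underlay$pixels
  rng <- range(g)
  g <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else g * 0
  z <- pmin(pmax(diff$z, z_range[1]), z_range[2])
  zmax <- max(abs(z_range))
  f <- pmin(abs(z) / zmax, 1)            # colour saturation
  hot <- abs(diff$z) >= z_threshold
  col_r <- ifelse(z >= 0, 1, 1 - f)
  col_g <- 1 - f
  col_b <- ifelse(z >= 0, 1 - f, 1)
  alpha <- ifelse(hot, 0.35 + 0.65 * pmin((abs(z) - z_threshold) /
                                            (zmax - z_threshold), 1), 0)
  compose <- function(chan) (1 - alpha) * g + alpha * chan
  d <- dim(g)
  bar_w <- 8L; gap <- 2L
  width <- d[1] + gap + bar_w
  rgb <- array(1, dim = c(d[2], width, 3))  # [row = y, col = x, channel]
  rgb[, seq_len(d[1]), 1] <- t(compose(col_r))
  rgb[, seq_len(d[1]), 2] <- t(compose(col_g))
  rgb[, seq_len(d[1]), 3] <- t(compose(col_b))
  # colour bar: z from z_range[2] (top) to z_range[1] (bottom)
  zbar <- seq(z_range[2], z_range[1], length.out = d[2])
  fb <- pmin(abs(zbar) / zmax, 1)
  bar <- cbind(ifelse(zbar >= 0, 1, 1 - fb), 1 - fb,
               ifelse(zbar >= 0, 1 - fb, 1))
  ticks <- unique(round(seq(z_range[1], z_range[2])))
  tick_rows <- round((z_range[2] - ticks) / (z_range[2] - z_range[1]) *
                       (d[2] - 1)) + 1
  for (ch in 1:3) {
    rgb[, d[1] + gap + seq_len(bar_w), ch] <- matrix(bar[, ch], d[2], bar_w)
    rgb[tick_rows, d[1] + gap + 1:2, ch] <- 0  # black tick marks
  }
  png::writePNG(rgb, path)
  jsonlite::write_json(
    list(color_scale = "SD units (z)", z_range = z_range,
         z_threshold = z_threshold, ticks = ticks,
         scale_sd = diff$scale_sd, scale_kind = diff$scale_kind),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
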