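#' Pipeline run configuration
#'
#' Validated settings for an end-to-end run (simulate -> normalize ->
#' rank pairs -> align -> difference -> localize -> render). Either
#' `inputs` supplies paths to existing MRC stacks (plus an optional truth
#' manifest), or the run simulates its own data from the standard phantom
#' for the requested `case`. Every resolved default is recorded in the run
#' report, and a run is reproducible bit for bit from the same
#' configuration and seed.
#'
#' @param case `"tag"`, `"deletion"` or `"control"` (simulated runs).
#' @param outdir Output directory (created if needed).
#' @param seed Master seed; per-stage seeds are derived deterministically
#'   as `(seed * 7919 + 104729 * stage) mod (2^31 - 1)`.
#' @param n_averages Class averages simulated per stack.
#' @param n_particles,snr,jitter_shift_sd,jitter_angle_sd See
#'   [sim_config()].
#' @param box_edge,voxel_size Phantom geometry (voxels / Angstrom).
#' @param angle_grid,max_shift,subpixel Alignment parameters.
#' @param z_threshold,min_area Region-calling parameters.
#' @param display_threshold Heat-map overlay threshold, SD units.
#' @param inputs Optional list with `variant`, `ref` (MRC paths) and
#'   optionally `truth` (TSV manifest path).
#' @return An object of class `run_config`.
#' @export
run_config <- function(case = c("tag", "deletion", "control"),
                       outdir = tempfile("emdiffmap_run_"), seed = 1L,
                       n_averages = 2L, n_particles = 256L, snr = 0.5,
                       jitter_shift_sd = 0.5, jitter_angle_sd = 1,
                       box_edge = 64L, voxel_size = 3.98,
                       angle_grid = seq(-12, 12, by = 1), max_shift = 8L,
                       subpixel = 10L, z_threshold = 4, min_area = 4L,
                       display_threshold = 3, inputs = NULL) {
  case <- match.arg(case)
  cfg <- list(case = case, outdir = outdir, seed = as.integer(seed),
              n_averages = as.integer(n_averages),
              n_particles = as.integer(n_particles), snr = snr,
              jitter_shift_sd = jitter_shift_sd,
              jitter_angle_sd = jitter_angle_sd,
              box_edge = as.integer(box_edge), voxel_size = voxel_size,
              angle_grid = angle_grid, max_shift = as.integer(max_shift),
              subpixel = as.integer(subpixel), z_threshold = z_threshold,
              min_area = as.integer(min_area),
              display_threshold = display_threshold, inputs = inputs)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  req <- c("case", "outdir", "seed", "n_averages", "n_particles", "snr",
           "jitter_shift_sd", "jitter_angle_sd", "box_edge", "voxel_size",
           "angle_grid", "max_shift", "subpixel", "z_threshold", "min_area",
           "display_threshold")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("run_config missing field(s): ",
                         paste(miss, collapse = ", "))
  stopifnot(cfg$case %in% c("tag", "deletion", "control"),
            is.character(cfg$outdir), length(cfg$outdir) == 1L,
            cfg$seed >= 0, cfg$n_averages >= 1L, cfg$n_particles >= 1L,
            cfg$snr > 0, cfg$jitter_shift_sd >= 0, cfg$jitter_angle_sd >= 0,
            cfg$box_edge >= 16L, cfg$voxel_size > 0,
            length(cfg$angle_grid) >= 1L, cfg$max_shift >= 1L,
            cfg$subpixel >= 1L, cfg$z_threshold > 0, cfg$min_area >= 1L,
            cfg$display_threshold > 0)
  if (!is.null(cfg$inputs)) {
    if (!all(c("variant", "ref") %in% names(cfg$inputs)))
      stop("inputs must name 'variant' and 'ref' MRC paths")
  }
  invisible(TRUE)
}

as_stack_list <- function(x) {
  if (inherits(x, "em_image")) list(x) else x
}

read_truth_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_truth_manifest <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

simulate_case_stacks <- function(cfg) {
  ph <- case_phantoms(cfg$case, cfg$box_edge, cfg$voxel_size)
  vol_ref <- build_phantom(ph$ref)
  vol_var <- build_phantom(ph$variant)
  orient <- orientation()
  sim_one <- function(phantom, vol, stage) {
    simulate_class_average(phantom, orient,
      sim_config(cfg$n_particles, cfg$snr, cfg$jitter_shift_sd,
                 cfg$jitter_angle_sd, seed = derive_seed(cfg$seed, stage)),
      volume = vol)
  }
  refs <- lapply(seq_len(cfg$n_averages),
                 function(k) sim_one(ph$ref, vol_ref, 100L + k))
  vars <- lapply(seq_len(cfg$n_averages),
                 function(k) sim_one(ph$variant, vol_var, 200L + k))
  # one global in-plane offset for the variant stack: independently
  # clustered averages carry an arbitrary in-plane pose
  off <- with_seed(derive_seed(cfg$seed, 300L),
                   c(stats::runif(2, -3, 3), stats::runif(1, -8, 8)))
  vars <- lapply(vars, function(im) {
    im$pixels <- transform_pixels(im$pixels, off[1], off[2], off[3])
    im
  })
  truth <- NULL
  if (!is.null(ph$truth_blob)) {
    k <- match(ph$truth_blob, blob_ids(ph$variant))
    p0 <- project_point(ph$variant$blobs[[k]]$center, orient,
                        cfg$box_edge, cfg$voxel_size)
    p <- transform_point(p0, off[1], off[2], off[3],
                         c(cfg$box_edge, cfg$box_edge))
    truth <- data.frame(case_id = cfg$case, true_x_px = p[1],
                        true_y_px = p[2],
                        kind = if (cfg$case == "tag") "tag" else "deletion")
  }
  list(refs = refs, variants = vars, truth = truth, offset = off,
       phantom_ref = ph$ref, phantom_variant = ph$variant)
}

#' Run the full difference-mapping pipeline
#'
#' Executes normalize -> rank pairs -> best-pair alignment -> difference
#' map -> region extraction -> localization -> heat-map rendering, writing
#' all intermediates to `cfg$outdir`: the input stacks (`refs.mrc`,
#' `variants.mrc`), the truth manifest (`truth.tsv`, simulated runs), the
#' pair-score table (`pair_scores.tsv`), the best alignment
#' (`alignment.json`), the z map (`diff_z.mrc`), the significant regions
#' (`regions.tsv`), the heat map (`heatmap.png`), a structured log
#' (`log.json`) and the run report (`report.json`). Idempotent for a fixed
#' configuration and seed.
#'
#' @param cfg A [run_config()].
#' @return An object of class `run_report` (invisibly the same content as
#'   `report.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, params) {
    log[[length(log) + 1L]] <<- list(stage = stage, params = params)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' (case ", cfg$case, "): ",
           conditionMessage(e), call. = FALSE))
  }

  dat <- stage("simulate", {
    if (is.null(cfg$inputs)) {
      d <- simulate_case_stacks(cfg)
      write_mrc(d$refs, file.path(cfg$outdir, "refs.mrc"))
      write_mrc(d$variants, file.path(cfg$outdir, "variants.mrc"))
      if (!is.null(d$truth))
        write_truth_manifest(d$truth, file.path(cfg$outdir, "truth.tsv"))
      note("simulate", list(case = cfg$case, n_averages = cfg$n_averages,
                            n_particles = cfg$n_particles, snr = cfg$snr,
                            offset = d$offset))
      d
    } else {
      refs <- as_stack_list(read_mrc(cfg$inputs$ref))
      vars <- as_stack_list(read_mrc(cfg$inputs$variant))
      truth <- if (!is.null(cfg$inputs$truth))
        read_truth_manifest(cfg$inputs$truth) else NULL
      note("load", cfg$inputs)
      list(refs = refs, variants = vars, truth = truth)
    }
  })

  refs <- stage("normalize", lapply(dat$refs, normalize))
  vars <- stage("normalize", lapply(dat$variants, normalize))
  note("normalize", list(n_ref = length(refs), n_variant = length(vars)))

  pairs <- stage("rank_pairs",
    rank_pairs(refs, vars, angle_grid = cfg$angle_grid,
               max_shift = cfg$max_shift, subpixel = cfg$subpixel,
               z_threshold = cfg$z_threshold, min_area = cfg$min_area))
  utils::write.table(as.data.frame(pairs),
                     file.path(cfg$outdir, "pair_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  best <- pairs[1L, ]
  al <- attr(pairs, "alignments")[[paste(best$variant_id, best$ref_id,
                                         sep = "_")]]
  note("align", list(variant_id = best$variant_id, ref_id = best$ref_id,
                     shift = as.numeric(al$shift), rotation = al$rotation,
                     cc = al$cc))
  jsonlite::write_json(
    list(shift = as.numeric(al$shift), rotation = al$rotation, cc = al$cc,
         method = al$method, fine_tune_delta = as.numeric(al$fine_tune_delta)),
    file.path(cfg$outdir, "alignment.json"), auto_unbox = TRUE, digits = NA)

  vimg <- vars[[best$variant_id]]
  rimg <- refs[[best$ref_id]]
  dm <- stage("difference", compute_difference(vimg, rimg, al))
  write_mrc(em_image(dm$z, dm$pixel_size),
            file.path(cfg$outdir, "diff_z.mrc"))
  note("difference", list(scale_sd = dm$scale_sd, scale_kind = dm$scale_kind))

  regs <- stage("regions", extract_regions(dm, cfg$z_threshold, cfg$min_area))
  truth_px <- NULL
  if (!is.null(dat$truth) && nrow(dat$truth) >= 1L)
    truth_px <- c(dat$truth$true_x_px[1], dat$truth$true_y_px[1])
  loc <- stage("localize",
    localize(dm, regs, truth = truth_px, case_id = cfg$case,
             z_threshold = cfg$z_threshold, min_area = cfg$min_area))
  reg_df <- if (length(regs)) do.call(rbind, lapply(regs, function(r)
    data.frame(sign = r$sign, peak_z = r$peak_z, area_px = r$area_px,
               centroid_x_px = r$centroid_px[1],
               centroid_y_px = r$centroid_px[2],
               centroid_x_ang = r$centroid_ang[1],
               centroid_y_ang = r$centroid_ang[2])))
  else data.frame(sign = character(), peak_z = numeric(),
                  area_px = integer(), centroid_x_px = numeric(),
                  centroid_y_px = numeric(), centroid_x_ang = numeric(),
                  centroid_y_ang = numeric())
  utils::write.table(reg_df, file.path(cfg$outdir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("localize", list(found = loc$found, error_px = loc$error_px))

  stage("render",
    render_heatmap(dm, apply_transform(rimg, al),
                   file.path(cfg$outdir, "heatmap.png"),
                   z_threshold = cfg$display_threshold))

  out_files <- c("refs.mrc", "variants.mrc", "pair_scores.tsv",
                 "alignment.json", "diff_z.mrc", "regions.tsv",
                 "heatmap.png")
  out_files <- out_files[file.exists(file.path(cfg$outdir, out_files))]
  hashes <- as.list(tools::md5sum(file.path(cfg$outdir, out_files)))
  names(hashes) <- out_files
  note("hash_outputs", hashes)
  jsonlite::write_json(log, file.path(cfg$outdir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- structure(list(
    package_version = as.character(utils::packageVersion("emdiffmap")),
    config = unclass(cfg)[setdiff(names(cfg), "inputs")],
    seed = cfg$seed,
    pair_scores = as.data.frame(pairs),
    alignment = list(shift = as.numeric(al$shift), rotation = al$rotation,
                     cc = al$cc),
    localization = list(case_id = loc$case_id, found = loc$found,
                        n_regions = length(loc$regions),
                        centroid_px = as.numeric(loc$centroid_px),
                        centroid_ang = as.numeric(loc$centroid_ang),
                        error_px = loc$error_px),
    files = hashes), class = "run_report")
  write_run_report(report, file.path(cfg$outdir, "report.json"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("emdiffmap run report (v%s), case '%s', seed %d\n",
              x$package_version, x$config$case, x$seed))
  cat(sprintf("  best pair cc = %.4f, rotation %.2f deg\n",
              x$alignment$cc, x$alignment$rotation))
  if (x$localization$found)
    cat(sprintf("  primary region at (%.2f, %.2f) px%s\n",
                x$localization$centroid_px[1], x$localization$centroid_px[2],
                if (is.na(x$localization$error_px)) "" else
                  sprintf(", error %.2f px", x$localization$error_px)))
  else cat("  no significant region found\n")
  invisible(x)
}

#' Write / read a run report as JSON
#'
#' The on-disk JSON form round-trips losslessly: numeric outputs are
#' written at full precision.
#'
#' @param report A `run_report`.
#' @param path JSON file path.
#' @return `write_run_report`: `path` invisibly; `read_run_report`: the
#'   `run_report`.
#' @export
write_run_report <- function(report, path) {
  # digits = I(17): 17 significant digits reproduce doubles exactly
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pair_scores <- as.data.frame(x$pair_scores)
  structure(x, class = "run_report")
}

#' Write the standard fixture bundle
#'
#' Generates the phantom spec (JSON), wild-type / tagged / deletion class
#' average stacks (MRC2014), and the ground-truth manifest (TSV with
#' columns `case_id`, `true_x_px`, `true_y_px`, `kind`) used by the test
#' suite. Deterministic for a fixed seed: the same seed yields files with
#' identical bytes.
#'
#' @param seed Master seed.
#' @param dir Output directory.
#' @param n_averages Averages per stack.
#' @param n_particles,snr Simulation settings.
#' @return Named list of written file paths, invisibly.
#' @export
make_fixtures <- function(seed, dir, n_averages = 2L, n_particles = 256L,
                          snr = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- mediator_phantom()
  tagged <- add_tag(wt, "med15_c", c(14, 10, 0), tag_weight = 40,
                    tag_sigma = 8)
  deleted <- delete_domain(wt, "med14_c")
  orient <- orientation()
  vols <- list(wt = build_phantom(wt), tagged = build_phantom(tagged),
               deleted = build_phantom(deleted))
  phs <- list(wt = wt, tagged = tagged, deleted = deleted)
  paths <- list(phantom = file.path(dir, "phantom.json"),
                truth = file.path(dir, "truth.tsv"))
  blob_df <- do.call(rbind, lapply(wt$blobs, function(b)
    data.frame(id = b$id, x = b$center[1], y = b$center[2], z = b$center[3],
               sigma = b$sigma, weight = b$weight)))
  jsonlite::write_json(list(box_edge = wt$box_edge,
                            voxel_size = wt$voxel_size, blobs = blob_df),
                       paths$phantom, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (nm in names(phs)) {
    imgs <- lapply(seq_len(n_averages), function(k)
      simulate_class_average(phs[[nm]], orient,
        sim_config(n_particles, snr,
                   seed = derive_seed(seed, match(nm, names(phs)) * 100L + k)),
        volume = vols[[nm]]))
    paths[[nm]] <- file.path(dir, paste0(nm, ".mrc"))
    write_mrc(imgs, paths[[nm]])
  }
  p_tag <- project_point(tagged$blobs[[match("tag", blob_ids(tagged))]]$center,
                         orient, wt$box_edge, wt$voxel_size)
  p_del <- project_point(wt$blobs[[match("med14_c", blob_ids(wt))]]$center,
                         orient, wt$box_edge, wt$voxel_size)
  write_truth_manifest(
    data.frame(case_id = c("tagged", "deleted"),
               true_x_px = c(p_tag[1], p_del[1]),
               true_y_px = c(p_tag[2], p_del[2]),
               kind = c("tag", "deletion")),
    paths$truth)
  invisible(paths)
}
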