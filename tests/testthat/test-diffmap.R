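# Difference maps, significant regions, localization, pair ranking and
# heat-map rendering.

test_that("difference of an image with itself is identically zero", {
  a <- normalize(std_projection())
  dm <- compute_difference(a, a, alignment_result(0, 0, 0))
  expect_identical(max(abs(dm$raw)), 0)
  expect_identical(max(abs(dm$z)), 0)
  expect_gt(dm$scale_sd, 0)
  expect_length(extract_regions(dm, z_threshold = 0.5), 0L)
})

test_that("swapping the pair negates the z map for a fixed alignment", {
  a <- normalize(simulate_class_average(std_phantom(),
                                        cfg = sim_config(32, seed = 11),
                                        volume = std_volume()))
  b <- normalize(simulate_class_average(std_phantom(),
                                        cfg = sim_config(32, seed = 12),
                                        volume = std_volume()))
  id <- alignment_result(0, 0, 0)
  z_ab <- compute_difference(a, b, id)$z
  z_ba <- compute_difference(b, a, id)$z
  expect_lt(max(abs(z_ab + z_ba)), 1e-10)
})

test_that("differencing requires normalized inputs and matching shapes", {
  raw <- std_projection()
  expect_error(compute_difference(raw, raw, alignment_result(0, 0, 0)),
               "normalized")
})

test_that("a tagged-vs-untagged noiseless pair yields one positive region at the tag", {
  ph <- std_phantom()
  tagged <- add_tag(ph, "med15_c", c(14, 10, 0), tag_weight = 40,
                    tag_sigma = 8)
  wt <- normalize(std_projection())
  tg <- normalize(project(build_phantom(tagged), orientation()))
  # noiseless inputs leave no background noise to reference z against; the
  # scale falls back to the whole-map SD (warning) and the tag dominates
  expect_warning(dm <- compute_difference(tg, wt, alignment_result(0, 0, 0)),
                 "numerically zero")
  regs <- extract_regions(dm, z_threshold = 4, min_area = 4)
  pos <- Filter(function(r) r$sign == "positive", regs)
  expect_length(pos, 1L)
  tag_ctr <- emdiffmap:::project_point(
    tagged$blobs[[length(tagged$blobs)]]$center, orientation(),
    ph$box_edge, ph$voxel_size)
  expect_lt(sqrt(sum((pos[[1]]$centroid_px - tag_ctr)^2)), 2)
})

test_that("a synthetic z bump is extracted with sub-pixel centroid accuracy", {
  n <- 64
  X <- rep(0:(n - 1), times = n); Y <- rep(0:(n - 1), each = n)
  bump <- matrix(8 * exp(-((X - 40.3)^2 + (Y - 21.7)^2) / (2 * 2.5^2)), n, n)
  dm <- fake_diffmap(bump)
  regs <- extract_regions(dm, z_threshold = 3, min_area = 4)
  expect_length(regs, 1L)
  expect_identical(regs[[1]]$sign, "positive")
  expect_equal(regs[[1]]$peak_z, 8, tolerance = 0.02)  # peak on pixel grid
  expect_lt(abs(regs[[1]]$centroid_px[1] - 40.3), 0.5)
  expect_lt(abs(regs[[1]]$centroid_px[2] - 21.7), 0.5)

  # all-zero map: no regions, and localize flags the absence
  empty <- localize(fake_diffmap(matrix(0, 16, 16)))
  expect_false(empty$found)
  expect_length(empty$regions, 0L)
})

test_that("region labelling uses 8-connectivity and respects min_area", {
  z <- matrix(0, 16, 16)
  z[4, 4] <- 5; z[5, 5] <- 5           # diagonal neighbours: one region
  z[12, 12] <- 5                       # isolated pixel
  dm <- fake_diffmap(z)
  regs <- extract_regions(dm, z_threshold = 3, min_area = 2)
  expect_length(regs, 1L)
  expect_identical(regs[[1]]$area_px, 2L)
  regs1 <- extract_regions(dm, z_threshold = 3, min_area = 1)
  expect_length(regs1, 3L - 1L)        # diagonal pair + isolated pixel
})

test_that("regions are sorted by |peak z|, then area, then scanline order", {
  z <- matrix(0, 32, 32)
  z[2:3, 2:3] <- 5                      # peak 5, area 4
  z[10:13, 10:13] <- 6                  # peak 6, area 16
  z[20:21, 20:22] <- -7                 # negative, peak |7|, area 6
  regs <- extract_regions(fake_diffmap(z), z_threshold = 4, min_area = 2)
  expect_identical(vapply(regs, `[[`, numeric(1), "peak_z"), c(-7, 6, 5))
  expect_identical(vapply(regs, `[[`, character(1), "sign"),
                   c("negative", "positive", "positive"))
})

test_that("localize reports the strongest positive region and truth error", {
  z <- matrix(0, 32, 32)
  z[10:12, 10:12] <- 6                  # 0-based pixels 9..11, centre (10, 10)
  z[20:22, 20:22] <- -9                 # stronger but negative
  rep <- localize(fake_diffmap(z), truth = c(10, 10), case_id = "t")
  expect_true(rep$found)
  expect_identical(rep$primary$sign, "positive")
  expect_equal(as.numeric(rep$centroid_px), c(10, 10))
  expect_lt(rep$error_px, 1e-10)
  # centroid also reported in Angstrom relative to the image centre
  expect_equal(as.numeric(rep$centroid_ang), (c(10, 10) - 16) * 3.98)
})

test_that("degenerate background falls back to the whole-map SD with a warning", {
  # complementary half-bright images: no pixels are dim in both, so the
  # joint background region is empty
  left <- matrix(0, 16, 16); left[1:8, ] <- 1
  noise <- emdiffmap:::with_seed(55L, matrix(stats::rnorm(512, 0, 0.01), 16))
  a <- normalize(em_image(left + noise[, 1:16], 1))
  b <- normalize(em_image(1 - left + noise[, 17:32], 1))
  expect_warning(dm <- compute_difference(a, b, alignment_result(0, 0, 0)),
                 "background")
  expect_identical(dm$scale_kind, "whole")
  expect_equal(stats::sd(dm$raw) / dm$scale_sd, 1, tolerance = 1e-10)
})

test_that("rank_pairs puts mismatched views and artifact stripes last", {
  ph <- std_phantom(); vol <- std_volume()
  mk <- function(seed) normalize(simulate_class_average(
    ph, cfg = sim_config(64, 2, 0, 0, seed = seed), volume = vol))
  refs <- list(mk(70), mk(71), mk(72))
  vars <- list(mk(80), mk(81))
  # a variant from an entirely different view
  other <- normalize(simulate_class_average(
    ph, orientation(0, 90, 0), sim_config(64, 2, 0, 0, seed = 82)))
  tab <- rank_pairs(refs, c(vars, list(other)),
                    angle_grid = seq(-6, 6, by = 2), max_shift = 6)
  expect_identical(nrow(tab), 9L)
  worst3 <- utils::tail(tab$variant_id, 3)
  expect_true(all(worst3 == 3L))

  # an injected stripe artifact raises clutter and drops the rank
  striped <- vars[[2]]
  striped$pixels[, 30:31] <- striped$pixels[, 30:31] + 3
  striped <- normalize(striped)
  tab2 <- rank_pairs(refs[1], list(vars[[1]], striped),
                     angle_grid = c(0), max_shift = 6)
  clean <- tab2[tab2$variant_id == 1L, ]
  dirty <- tab2[tab2$variant_id == 2L, ]
  expect_gt(dirty$clutter, clean$clutter)
  expect_lt(dirty$score, clean$score)
})

test_that("identical single pair scores 1 minus clutter", {
  a <- normalize(std_projection())
  tab <- rank_pairs(list(a), list(a), angle_grid = c(0), max_shift = 4)
  expect_equal(tab$cc_after_alignment, 1.0)
  expect_identical(tab$clutter, 0)
  expect_equal(tab$score, 1.0)
})

test_that("render_heatmap writes deterministic bytes and a grayscale null map", {
  a <- normalize(std_projection())
  dm0 <- compute_difference(a, a, alignment_result(0, 0, 0))
  f1 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(dm0, a, f1)
  rgb <- png::readPNG(f1)
  n <- nrow(a$pixels)
  imgpart <- rgb[, seq_len(n), ]
  expect_identical(imgpart[, , 1], imgpart[, , 2])   # no colour overlay
  expect_identical(imgpart[, , 1], imgpart[, , 3])
  expect_true(file.exists(paste0(f1, ".json")))

  z <- matrix(0, n, n); z[40:44, 10:14] <- 12        # clamps at z_range
  dm <- fake_diffmap(z)
  f2 <- withr::local_tempfile(fileext = ".png")
  f3 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(dm, a, f2)
  render_heatmap(dm, a, f3)
  expect_identical(unname(tools::md5sum(f2)), unname(tools::md5sum(f3)))
  rgb2 <- png::readPNG(f2)
  # red overlay at the bump: red channel exceeds blue there
  expect_gt(rgb2[11, 41, 1], rgb2[11, 41, 3])
})
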