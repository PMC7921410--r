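# MRC / PNG / TIFF input-output, normalization and masking.

test_that("MRC round trip is lossless at 32-bit float and keeps the pixel size", {
  img <- std_projection()
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(img, f)
  r <- read_mrc(f)
  expect_identical(dim(r$pixels), dim(img$pixels))
  # data are stored as float32: exact for float32-representable values,
  # otherwise within single precision
  expect_lt(max(abs(r$pixels - img$pixels)), 1e-6 * max(abs(img$pixels)))
  expect_equal(r$pixel_size, img$pixel_size, tolerance = 1e-6)
})

test_that("MRC stacks preserve image count and order", {
  imgs <- lapply(1:5, function(k)
    em_image(matrix(k + seq_len(64) / 64, 8, 8), 3.98))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(imgs, f)
  st <- read_image(f)
  expect_s3_class(st, "em_stack")
  expect_length(st, 5L)
  for (k in 1:5)
    expect_lt(max(abs(st[[k]]$pixels - imgs[[k]]$pixels)), 1e-6)
})

test_that("MRC volumes round trip through ispg >= 1", {
  vol <- std_volume()
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(vol, f)
  v <- read_mrc(f)
  expect_s3_class(v, "density_volume")
  expect_lt(max(abs(v$data - vol$data)), 1e-7 * max(vol$data))
  expect_equal(v$voxel_size, vol$voxel_size, tolerance = 1e-6)
})

test_that("PNG ingestion maps 8-bit gray to [0, 1] and requires a pixel size", {
  f <- withr::local_tempfile(fileext = ".png")
  grad <- matrix(seq(0, 1, length.out = 16 * 12), nrow = 12, ncol = 16)
  png::writePNG(grad, f)
  expect_error(read_image(f), "pixel_size")
  img <- read_image(f, pixel_size = 3.98)
  expect_identical(dim(img$pixels), c(16L, 12L))   # [x, y]
  expect_gte(min(img$pixels), 0)
  expect_lte(max(img$pixels), 1)
  # writePNG quantizes to 8 bits: values agree to 1/255
  expect_lt(max(abs(t(img$pixels) - grad)), 1 / 254)
})

test_that("TIFF grayscale import matches the written values", {
  f <- withr::local_tempfile(fileext = ".tif")
  grad <- matrix(seq(0, 1, length.out = 64), nrow = 8)
  tiff::writeTIFF(grad, f, bits.per.sample = 16L)
  img <- read_image(f, pixel_size = 2)
  expect_identical(dim(img$pixels), c(8L, 8L))
  expect_lt(max(abs(t(img$pixels) - grad)), 1 / 65000)
  expect_identical(img$pixel_size, 2)
})

test_that("colour images and unknown extensions are rejected by name", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(stats::runif(48), dim = c(4, 4, 3)), f)
  expect_error(read_image(f, pixel_size = 1), "colour|channel")
  expect_error(read_image("x.xyz"), "no such file")
  f2 <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(2048), f2)
  expect_error(read_mrc(f2), "mode")
})

test_that("normalize gives mean 0 and SD 1 over the mask region, idempotently", {
  img <- simulate_class_average(std_phantom(),
                                cfg = sim_config(16, seed = 4),
                                volume = std_volume())
  n1 <- normalize(img)
  expect_lt(abs(mean(n1$pixels)), 1e-10)
  expect_lt(abs(stats::sd(n1$pixels) - 1), 1e-10)
  expect_true(n1$normalized)
  n2 <- normalize(n1)
  expect_identical(n2$pixels, n1$pixels)

  # statistics over a circular mask, rescaling applied to the whole image
  m <- mask_spec("circular", radius_px = 20)
  nm <- normalize(img, m)
  sel <- nm$pixels[emdiffmap:::mask_matrix(nm, m)]
  expect_lt(abs(mean(sel)), 1e-10)
  expect_lt(abs(stats::sd(sel) - 1), 1e-10)
})

test_that("normalize is invariant to positive affine rescaling", {
  img <- std_projection()
  aff <- img
  aff$pixels <- 3.7 * img$pixels - 12
  expect_equal(normalize(aff)$pixels, normalize(img)$pixels,
               tolerance = 1e-12)
})

test_that("a constant image is rejected as degenerate", {
  flat <- em_image(matrix(5, 16, 16), 1)
  expect_error(normalize(flat), "degenerate")
})

test_that("masks validate and apply as specified", {
  expect_error(mask_spec("circular"), "radius")
  expect_error(mask_spec("threshold", threshold_fraction = 1.5), "threshold")
  img <- std_projection()

  expect_identical(apply_mask(img, mask_spec("none"))$pixels, img$pixels)

  n <- nrow(img$pixels)
  circ <- apply_mask(img, mask_spec("circular", radius_px = n / 2))
  expect_identical(circ$pixels[1, 1], 0)              # corner zeroed
  ctr <- floor(n / 2) + 1L
  expect_identical(circ$pixels[ctr, ctr], img$pixels[ctr, ctr])
  expect_error(apply_mask(img, mask_spec("circular", radius_px = n)),
               "radius")

  # threshold mask at 5% of peak on a single-blob projection: retained area
  # approximates the analytic Gaussian level set pi * 2 sigma^2 ln(20)
  vs <- 2
  ph <- phantom_model(list(gaussian_blob("b", c(0, 0, 0), 8, 1)), 64, vs)
  proj <- project(build_phantom(ph), orientation())
  thr <- apply_mask(proj, mask_spec("threshold", threshold_fraction = 0.05))
  area <- sum(thr$pixels != 0)
  expect_equal(area, pi * 2 * (8 / vs)^2 * log(20), tolerance = 0.1)
})

test_that("provenance records accumulate and serialize", {
  img <- normalize(std_projection())
  img <- apply_mask(img, mask_spec("circular", radius_px = 20))
  expect_length(img$provenance, 2L)
  f <- withr::local_tempfile(fileext = ".json")
  write_provenance(img, f)
  j <- jsonlite::read_json(f)
  expect_identical(vapply(j, `[[`, character(1), "op"),
                   c("normalize", "apply_mask"))
})
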