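# Cross-correlation scoring, FFT translational alignment vs the exhaustive
# oracle, rotation search, fine-tuning, and transform application.

test_that("cc_score has the correlation identities", {
  a <- random_fixture_image(10)
  expect_equal(cc_score(a, a), 1.0)
  neg <- a; neg$pixels <- -a$pixels
  expect_equal(cc_score(a, neg), -1.0)
  b <- random_fixture_image(11)
  expect_equal(cc_score(a, b), cc_score(b, a))
  small <- em_image(matrix(stats::rnorm(64), 8, 8), 1)
  expect_error(cc_score(a, small), "shape")
})

test_that("cc of independent noise images concentrates near zero", {
  for (s in 1:10) {
    a <- em_image(emdiffmap:::with_seed(3000 + s,
                                        matrix(stats::rnorm(128^2), 128)), 1)
    b <- em_image(emdiffmap:::with_seed(4000 + s,
                                        matrix(stats::rnorm(128^2), 128)), 1)
    expect_lt(abs(cc_score(a, b)), 0.05)
  }
})

test_that("self-alignment is the identity with cc 1", {
  ref <- random_fixture_image(20)
  r <- align_translation(ref, ref, max_shift = 8)
  expect_identical(as.numeric(r$shift), c(0, 0))
  expect_equal(r$cc, 1.0)
})

test_that("FFT argmax equals the exhaustive integer-shift oracle", {
  for (s in 1:6) {
    # zero-background raw projections: correlation is scale-free, and the
    # zero fill at the frame border is then exact
    ref <- random_fixture_image(100 + s, noise_sd = 0, normalized = FALSE)
    true_shift <- c((s %% 7) - 3, ((2 * s) %% 9) - 4)
    mov <- ref
    mov$pixels <- circ_shift(ref$pixels, true_shift[1], true_shift[2])
    r <- align_translation(ref, mov, max_shift = 8, subpixel = 1)
    oracle <- oracle_align_translation(ref$pixels, mov$pixels, 8)
    expect_equal(as.numeric(r$shift), as.numeric(oracle))
    expect_equal(as.numeric(r$shift), as.numeric(-true_shift))
    expect_gte(r$cc, 0.999)
  }
})

test_that("subpixel refinement recovers fractional shifts within 0.1 px", {
  ref <- random_fixture_image(30)
  mov <- ref
  mov$pixels <- fourier_shift(ref$pixels, 2.5, 0)
  r <- align_translation(ref, mov, max_shift = 8, subpixel = 10)
  expect_lte(abs(r$shift[[1]] + 2.5), 0.1)
  expect_lte(abs(r$shift[[2]]), 0.1)
})

test_that("alignment of (ref, moving) and (moving, ref) gives opposite shifts", {
  ref <- random_fixture_image(31)
  mov <- ref
  mov$pixels <- fourier_shift(ref$pixels, 1.7, -2.3)
  f <- align_translation(ref, mov, max_shift = 8)
  b <- align_translation(mov, ref, max_shift = 8)
  expect_equal(as.numeric(f$shift), -as.numeric(b$shift), tolerance = 0.11)
})

test_that("max_shift beyond half the image is rejected", {
  ref <- random_fixture_image(32)
  expect_error(align_translation(ref, ref, max_shift = 40), "max_shift")
  expect_error(align_rotation_translation(ref, ref, angle_grid = numeric(0)),
               "nonempty")
})

test_that("rotation search recovers a known rotation and prefers identity on ties", {
  ref <- random_fixture_image(33, noise_sd = 0)
  r0 <- align_rotation_translation(ref, ref, angle_grid = seq(-10, 10, 1),
                                   max_shift = 4)
  expect_identical(r0$rotation, 0)
  expect_identical(as.numeric(r0$shift), c(0, 0))

  mov <- ref
  mov$pixels <- emdiffmap:::transform_pixels(ref$pixels, 0, 0, 6)
  r <- align_rotation_translation(ref, mov, angle_grid = seq(-10, 10, 1),
                                  max_shift = 4)
  expect_lte(abs(r$rotation + 6), 1)
  expect_gte(r$cc, 0.99)
})

test_that("rotation is recovered within 2 degrees on noisy simulated averages", {
  ph <- std_phantom(); vol <- std_volume()
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    a <- normalize(simulate_class_average(ph, cfg = sim_config(
      256, 0.5, 0, 0, seed = 5000 + s), volume = vol))
    b <- simulate_class_average(ph, cfg = sim_config(
      256, 0.5, 0, 0, seed = 6000 + s), volume = vol)
    true_rot <- ((s * 37) %% 17) - 8
    b$pixels <- emdiffmap:::transform_pixels(b$pixels, 0, 0, true_rot)
    b <- normalize(b)
    r <- align_rotation_translation(a, b, angle_grid = seq(-12, 12, 1),
                                    max_shift = 4)
    if (abs(r$rotation + true_rot) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, round(0.9 * n_rep))
})

test_that("fine_tune composes, inverts, and recomputes the correlation", {
  ref <- random_fixture_image(34)
  mov <- ref
  mov$pixels <- shift_zero(ref$pixels, 3, -2)
  r <- align_translation(ref, mov, max_shift = 8)

  same <- fine_tune(r, 0, 0, 0, ref = ref, moving = mov)
  expect_equal(same$shift, r$shift)
  expect_equal(same$cc, r$cc)

  back <- fine_tune(fine_tune(r, 1, 0, 0), -1, 0, 0)
  expect_equal(back$shift, r$shift)
  expect_identical(as.numeric(back$fine_tune_delta), c(0, 0, 0))

  worse <- fine_tune(r, 2, 2, 0, ref = ref, moving = mov)
  expect_lt(worse$cc, r$cc)
})

test_that("apply_transform is exact for identity and invertible within tolerance", {
  img <- std_projection()
  ident <- alignment_result(0, 0, 0)
  expect_identical(apply_transform(img, ident)$pixels, img$pixels)

  # round-trip fidelity is interpolation-limited, so it is measured on a
  # smooth zero-background image (feature width well above the pixel)
  ph <- phantom_model(list(gaussian_blob("b", c(6, -10, 0), 48, 1)), 96, 4)
  img <- project(build_phantom(ph), orientation())
  tr <- alignment_result(2.3, -1.1, 5)
  round_trip <- apply_transform(apply_transform(img, tr), invert_transform(tr))
  err <- max(abs(round_trip$pixels - img$pixels))
  expect_lt(err, 0.02 * stats::sd(img$pixels))
})

test_that("a 90-degree rotation matches the axis-swap oracle", {
  n <- 32L
  L <- matrix(0, n, n)
  L[8:24, 10:12] <- 1; L[8:11, 10:22] <- 1   # L-shaped pattern
  img <- em_image(L, 1)
  rot <- apply_transform(img, alignment_result(0, 0, 90))$pixels
  ctr <- floor(n / 2)
  oracle <- matrix(0, n, n)
  for (x in 0:(n - 1)) for (y in 0:(n - 1)) {
    xs <- y; ys <- 2 * ctr - x   # inverse of a +90 deg rotation about ctr
    if (xs >= 0 && xs < n && ys >= 0 && ys < n)
      oracle[x + 1, y + 1] <- L[xs + 1, ys + 1]
  }
  expect_lt(max(abs(rot - oracle)), 1e-10)
})
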