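# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

std_phantom <- function() cached("phantom", mediator_phantom())
std_volume <- function() cached("volume", build_phantom(std_phantom()))
std_projection <- function() cached("projection",
                                    project(std_volume(), orientation()))

# Full-regime localization benchmarks, shared between property and
# acceptance tests (master seed 1 throughout).
cached_benchmark <- function(case, n_particles = 256L, n_seeds = 20L) {
  cached(sprintf("bench_%s_%d_%d", case, n_particles, n_seeds),
         benchmark_localization(case, n_seeds = n_seeds,
                                n_particles = n_particles, seed = 1L))
}

# Zero-filled integer shift of a matrix: content moves by (dx, dy).
shift_zero <- function(m, dx, dy) {
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  xd <- xs + dx; yd <- ys + dy
  okx <- xd >= 1 & xd <= d[1]; oky <- yd >= 1 & yd <= d[2]
  out[xd[okx], yd[oky]] <- m[xs[okx], ys[oky]]
  out
}

# Exhaustive integer-shift alignment oracle with the same zero padding as
# the FFT path: maximizes sum(ref * shift(moving, s)) over |s| <= max_shift.
oracle_align_translation <- function(ref, moving, max_shift) {
  best <- c(0, 0); best_v <- -Inf
  for (sx in -max_shift:max_shift) for (sy in -max_shift:max_shift) {
    v <- sum(ref * shift_zero(moving, sx, sy))
    if (v > best_v) { best_v <- v; best <- c(sx, sy) }
  }
  best
}

# Circular (wrap-around) integer shift.
circ_shift <- function(m, dx, dy) {
  d <- dim(m)
  m[((seq_len(d[1]) - 1 - dx) %% d[1]) + 1,
    ((seq_len(d[2]) - 1 - dy) %% d[2]) + 1]
}

# Subpixel circular shift via Fourier phase ramp (content moves by +dx,+dy).
fourier_shift <- function(m, dx, dy) {
  d <- dim(m)
  fx <- c(0:(d[1] %/% 2), -((d[1] - d[1] %/% 2 - 1):1)) / d[1]
  fy <- c(0:(d[2] %/% 2), -((d[2] - d[2] %/% 2 - 1):1)) / d[2]
  ph <- exp(-2i * pi * (outer(fx * dx, rep(1, d[2])) +
                        outer(rep(1, d[1]), fy * dy)))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / length(m)
}

# Smoothed random test image: projection of a random-blob phantom plus a
# little white noise, normalized. Gives structured images with a unique
# correlation peak. Blobs stay well inside the frame so image borders are
# effectively empty.
random_fixture_image <- function(seed, box_edge = 64L, n_blobs = 6L,
                                 noise_sd = 0.02, normalized = TRUE) {
  ph <- emdiffmap:::with_seed(seed, {
    blobs <- lapply(seq_len(n_blobs), function(k)
      gaussian_blob(paste0("b", k),
                    center = stats::runif(3, -45, 45),
                    sigma = stats::runif(1, 6, 10),
                    weight = stats::runif(1, 5, 20)))
    phantom_model(blobs, box_edge, 3.98)
  })
  img <- project(build_phantom(ph), orientation())
  img$pixels <- img$pixels +
    emdiffmap:::with_seed(seed + 1L,
                          matrix(stats::rnorm(length(img$pixels), 0,
                                              noise_sd * max(img$pixels)),
                                 nrow(img$pixels)))
  if (normalized) normalize(img) else img
}

# Construct a difference_map object directly from a z matrix (unit scale),
# for region-extraction tests.
fake_diffmap <- function(z, pixel_size = 3.98) {
  structure(list(z = z, raw = z, scale_sd = 1,
                 background_mask = matrix(TRUE, nrow(z), ncol(z)),
                 pixel_size = pixel_size, scale_kind = "background"),
            class = "difference_map")
}
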