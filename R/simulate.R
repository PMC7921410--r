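#' Class-average simulation settings
#'
#' Parameters for emulating a 2D class average: the mean of `n_particles`
#' copies of a noiseless projection, each given a small random in-plane
#' rotation and shift (residual misalignment left by reference-free 2D
#' clustering) plus additive white Gaussian noise at a stated per-particle
#' signal-to-noise ratio.
#'
#' SNR is defined as the variance of the noiseless projection over its
#' particle mask (pixels above 5% of the peak) divided by the noise
#' variance; a mask-based definition keeps it independent of how much empty
#' background surrounds the particle.
#'
#' @param n_particles Number of particles averaged, >= 1.
#' @param snr Per-particle signal-to-noise ratio, > 0.
#' @param jitter_shift_sd SD of the per-particle x/y shift jitter, pixels.
#' @param jitter_angle_sd SD of the per-particle rotation jitter, degrees.
#' @param seed Integer RNG seed; a fixed seed reproduces the average
#'   bit for bit.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_particles = 256L, snr = 0.5, jitter_shift_sd = 0.5,
                       jitter_angle_sd = 1, seed = 1L) {
  n_particles <- as.integer(n_particles)
  if (is.na(n_particles) || n_particles < 1L) stop("n_particles must be >= 1")
  if (!is.finite(snr) || snr <= 0) stop("snr must be > 0")
  if (jitter_shift_sd < 0 || jitter_angle_sd < 0) stop("jitter SDs must be >= 0")
  structure(list(n_particles = n_particles, snr = snr,
                 jitter_shift_sd = jitter_shift_sd,
                 jitter_angle_sd = jitter_angle_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate expr with a private RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic derivation of per-stage / per-replicate child seeds from one
# master seed (kept below 2^31 - 1).
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stage)) %% 2147483647)
}

#' Simulate a noisy 2D class average
#'
#' Projects the phantom at `orient`, then averages `cfg$n_particles` copies,
#' each transformed by rotation jitter `N(0, jitter_angle_sd)` followed by
#' shift jitter `N(0, jitter_shift_sd)` per axis (bilinear interpolation)
#' with additive white Gaussian noise scaled to the per-particle SNR (see
#' [sim_config()]). Deterministic for a fixed `cfg$seed`. The residual
#' noise SD of the average scales as `1/sqrt(n_particles)`.
#'
#' @param phantom A [phantom_model()].
#' @param orient An [orientation()].
#' @param cfg A [sim_config()].
#' @param volume Optional pre-built `density_volume` for `phantom` (saves
#'   re-rasterizing when simulating many averages of the same model).
#' @return An [em_image()] (not yet normalized).
#' @export
#' @examples
#' avg <- simulate_class_average(mediator_phantom(), orientation(),
#'                               sim_config(n_particles = 16, seed = 7))
simulate_class_average <- function(phantom, orient = orientation(),
                                   cfg = sim_config(), volume = NULL) {
  stopifnot(inherits(phantom, "phantom_model"), inherits(cfg, "sim_config"))
  if (is.null(volume)) volume <- build_phantom(phantom)
  clean <- project(volume, orient)
  px <- clean$pixels
  mask <- px > 0.05 * max(px)
  if (!any(mask)) stop("projection has no pixels above 5% of peak")
  sigma_noise <- sqrt(stats::var(px[mask]) / cfg$snr)
  n <- cfg$n_particles
  d <- dim(px)
  with_seed(cfg$seed, {
    acc <- matrix(0, d[1], d[2])
    for (i in seq_len(n)) {
      th <- if (cfg$jitter_angle_sd > 0) stats::rnorm(1, 0, cfg$jitter_angle_sd) else 0
      sh <- if (cfg$jitter_shift_sd > 0) stats::rnorm(2, 0, cfg$jitter_shift_sd) else c(0, 0)
      p <- if (th != 0 || any(sh != 0))
        transform_pixels(px, sh[1], sh[2], th) else px
      acc <- acc + p + stats::rnorm(length(p), 0, sigma_noise)
    }
    em_image(acc / n, clean$pixel_size)
  })
}
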