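# Desk-scale simulation fixtures shared across test files. Simulated runs
# are cached per test session since several tests interrogate the same run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Linear-gradient run small enough for fast scans: true shift 40 frames.
tiny_linear_cfg <- function(seed = 1L, true_shift = 40, ...) {
  sim_config(
    n_frames = 500, q = seq(0.032, 4.9, length.out = 250),
    peaks = data.frame(center = 220, width = 25, c_max = 1.75),
    gradient = gradient_program(25, 1000, "linear",
                                list(start_frame = 40, end_frame = 500,
                                     f_start = 0, f_end = 0.35)),
    true_shift = true_shift, seed = seed, ...)
}

tiny_shift_grid <- seq(-20L, 100L, by = 5L)

# Stepwise run: programmed step at frame 240, dispersion delay 2 -> true
# onset N0 = 242, decay constant 10 frames.
tiny_step_cfg <- function(seed = 1L, dispersion_Nprime = 10, ...) {
  sim_config(
    n_frames = 600, q = seq(0.032, 4.9, length.out = 250),
    peaks = data.frame(center = 290, width = 15, c_max = 0.35),
    gradient = gradient_program(25, 1000, "step",
                                data.frame(start_frame = c(0, 240),
                                           f = c(0, 0.12))),
    dispersion_N0 = 2, dispersion_Nprime = dispersion_Nprime,
    true_shift = 0, seed = seed, ...)
}

tiny_step_regions <- list(region_I = 160:219, region_II = 500:559)

# Contaminated peak: a larger second species eluting on the tail of the
# main peak, strong enough that the composition drift dominates noise.
tiny_two_species_cfg <- function(seed = 5L, ...) {
  sim_config(
    radius2_nm = 6, mass2_kda = 300,
    peaks = data.frame(center = c(830, 910), width = c(60, 35),
                       c_max = c(1.5, 0.7), species = c(1, 2)),
    seed = seed, ...)
}

# Small protein at high concentration: mid-band protein signal large
# enough that a +/-10% mis-scaled background leaves the ratio defined.
tiny_misscale_cfg <- function(seed = 1L) {
  sim_config(radius_nm = 1.5, mass_kda = 20,
             peaks = data.frame(center = 830, width = 60, c_max = 6),
             noise_level = 0, seed = seed)
}

random_curve <- function(n = 30, qmax = 5) {
  q <- sort(stats::runif(n, 0.01, qmax))
  while (any(diff(q) <= 0)) q <- sort(stats::runif(n, 0.01, qmax))
  saxs_curve(q, stats::rnorm(n, 10, 3), abs(stats::rnorm(n, 1, 0.3)))
}

expect_curves_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$q, b$q, tolerance = tol)
  expect_equal(a$I, b$I, tolerance = tol)
  expect_equal(a$sigma, b$sigma, tolerance = tol)
}
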