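#' Simulation configuration for a synthetic IEC-SAXS run
#'
#' Describes a complete sample + blank (buffer) chromatography run pair:
#' elution peaks, salt gradient, background model, dispersion of the salt
#' response at the measurement position, the clock offset between the two
#' runs, and the noise model. All defaults are chosen to emulate a BioSAXS
#' beamline acquisition at 1 Hz with a 1 ml/min flow on a 0.032-4.9 nm^-1
#' grid.
#'
#' @param n_frames frames per run.
#' @param frame_rate Hz.
#' @param flow_rate ml/min.
#' @param q momentum-transfer grid, nm^-1 (default 1000 points over
#'   0.032-4.9).
#' @param radius_nm sphere radius of the (first) species, nm; its radius of
#'   gyration is \code{sqrt(3/5) * radius_nm}.
#' @param mass_kda molar mass of the species, kDa. Intensities are on the
#'   scale where forward scattering = concentration (mg/ml) x mass (kDa).
#' @param peaks data.frame with columns \code{center, width, c_max}
#'   (frames, frames, mg/ml): Gaussian elution components. An optional
#'   \code{species} column (1 or 2) assigns a component to the second
#'   species.
#' @param radius2_nm,mass2_kda parameters of an optional second species.
#' @param gradient a [gradient_program].
#' @param b0 flat buffer background level, a.u.
#' @param a_salt background increase per mM NaCl, a.u./mM.
#' @param cap_amp,cap_exp,cap_qmax capillary term
#'   \code{cap_amp * (q^-cap_exp - cap_qmax^-cap_exp)} for \code{q <
#'   cap_qmax}, zero above (continuous at the cut).
#' @param dispersion_N0,dispersion_Nprime delay (frames) and exponential
#'   time constant (frames) of the buffer response at the measurement
#'   position.
#' @param true_shift frames by which the sample run's background clock lags
#'   the buffer run's.
#' @param noise_level scale of the counting-noise model
#'   \code{sigma(q) = noise_level * sqrt(I(q))}; 0 for a noiseless run.
#' @param poisson_noise if TRUE draw Poisson counts (with
#'   \code{1/noise_level^2} counts per intensity unit) instead of Gaussian
#'   noise.
#' @param overshoot_amp,overshoot_decay,overshoot_qmin transient additive
#'   high-q bump in the sample run after each salt step (amplitude a.u.,
#'   decay frames, applied for q >= overshoot_qmin); emulates co-eluting
#'   small ions that the exponential buffer model cannot capture.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_frames = 2400, frame_rate = 1, flow_rate = 1,
                       q = seq(0.032, 4.9, length.out = 1000),
                       radius_nm = 2.74 / sqrt(3 / 5), mass_kda = 66.5,
                       peaks = data.frame(center = 830, width = 60, c_max = 1.75),
                       radius2_nm = NULL, mass2_kda = NULL,
                       gradient = gradient_program(
                         25, 1000, "linear",
                         list(start_frame = 200, end_frame = 2400,
                              f_start = 0, f_end = 0.35)),
                       b0 = 20, a_salt = 0.01,
                       cap_amp = 2e-4, cap_exp = 3, cap_qmax = 0.2,
                       dispersion_N0 = 2, dispersion_Nprime = 17,
                       true_shift = 130, noise_level = 0.05,
                       poisson_noise = FALSE,
                       overshoot_amp = 0, overshoot_decay = 40,
                       overshoot_qmin = 2.5,
                       seed = 1L) {
  peaks <- as.data.frame(peaks)
  if (!all(c("center", "width", "c_max") %in% names(peaks)))
    stop("peaks needs columns center, width, c_max")
  if (is.null(peaks$species)) peaks$species <- 1L
  if (any(peaks$species == 2L) && (is.null(radius2_nm) || is.null(mass2_kda)))
    stop("a species-2 peak requires radius2_nm and mass2_kda")
  if (!isTRUE(frame_rate > 0) || !isTRUE(flow_rate > 0))
    stop("rates must be positive")
  if (any(peaks$center < 0 | peaks$center > n_frames))
    stop("peak centers must lie within the frame range")
  if (noise_level < 0) stop("noise_level must be >= 0")
  structure(list(
    n_frames = as.integer(n_frames), frame_rate = frame_rate,
    flow_rate = flow_rate, q = q,
    radius_nm = radius_nm, mass_kda = mass_kda, peaks = peaks,
    radius2_nm = radius2_nm, mass2_kda = mass2_kda,
    gradient = gradient, b0 = b0, a_salt = a_salt,
    cap_amp = cap_amp, cap_exp = cap_exp, cap_qmax = cap_qmax,
    dispersion_N0 = dispersion_N0, dispersion_Nprime = dispersion_Nprime,
    true_shift = true_shift, noise_level = noise_level,
    poisson_noise = poisson_noise,
    overshoot_amp = overshoot_amp, overshoot_decay = overshoot_decay,
    overshoot_qmin = overshoot_qmin,
    seed = as.integer(seed)), class = "sim_config")
}

#' Preset: BSA-like run on a linear salt gradient
#'
#' Single species (Rg 2.74 nm, 66.5 kDa) eluting as a Gaussian peak at
#' ~122 mM NaCl on a linear 25 -> 366 mM ramp, with the sample run's
#' background lagging the blank run by 130 frames.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return a \code{sim_config}.
#' @export
sim_config_linear_bsa <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

#' Preset: BSA-like run on a stepwise salt gradient
#'
#' One salt step from 25 to 142 mM programmed at frame 1287; the background
#' responds with a 2-frame delay and a 17-frame exponential time constant,
#' so the effective onset is frame 1289. The protein elutes as a sharp peak
#' on the step.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return a \code{sim_config}.
#' @export
sim_config_step_bsa <- function(seed = 1L, ...) {
  sim_config(
    n_frames = 2100,
    peaks = data.frame(center = 1345, width = 25, c_max = 0.35),
    gradient = gradient_program(25, 1000, "step",
                                data.frame(start_frame = c(0, 1287),
                                           f = c(0, 0.12))),
    true_shift = 0,
    seed = seed, ...)
}

#' Preset: hexamer-like run on a fine stepwise gradient
#'
#' Larger species (Rg 4.65 nm, 321 kDa) eluting at 142 mM on a multi-step
#' schedule, with a transient high-q overshoot after the elution step that
#' the exponential transition model cannot describe; exercises the
#' averaged-curve buffer-matching path.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return a \code{sim_config}.
#' @export
sim_config_step_hexamer <- function(seed = 1L, ...) {
  sim_config(
    n_frames = 2100,
    radius_nm = 4.65 / sqrt(3 / 5), mass_kda = 320.9,
    peaks = data.frame(center = 1345, width = 20, c_max = 3.4),
    gradient = gradient_program(25, 1000, "step",
                                data.frame(start_frame = c(0, 900, 1287, 1700),
                                           f = c(0, 0.08, 0.12, 0.16))),
    true_shift = 0, overshoot_amp = 0.8,
    seed = seed, ...)
}

#' Normalized sphere form factor
#'
#' \code{P(q) = [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2} with \code{P(0) = 1}
#' by the series limit. The radius of gyration of this curve is
#' \code{sqrt(3/5) * R}.
#'
#' @param q momentum transfer, nm^-1.
#' @param R sphere radius, nm.
#' @return P(q), dimensionless.
#' @export
sphere_form_factor <- function(q, R) {
  if (!isTRUE(R > 0)) stop("R must be positive")
  x <- q * R
  p <- numeric(length(x))
  # the closed form cancels catastrophically for small x; the series
  # 3 j1(x)/x = 1 - x^2/10 + x^4/280 - O(x^6) is exact to ~1e-13 there
  small <- abs(x) < 0.05
  xs2 <- x[small]^2
  p[small] <- (1 - xs2 / 10 + xs2^2 / 280)^2
  xs <- x[!small]
  p[!small] <- (3 * (sin(xs) - xs * cos(xs)) / xs^3)^2
  p
}

#' Elution concentration profile
#'
#' Sum of the configured Gaussian components at frame N (all species).
#'
#' @param config a [sim_config()].
#' @param N frame number(s).
#' @param species restrict to one species (1 or 2); default: all.
#' @return concentration, mg/ml.
#' @export
elution_concentration <- function(config, N, species = NULL) {
  p <- config$peaks
  if (!is.null(species)) p <- p[p$species == species, , drop = FALSE]
  c_tot <- numeric(length(N))
  for (i in seq_len(nrow(p)))
    c_tot <- c_tot + p$c_max[i] * exp(-(N - p$center[i])^2 / (2 * p$width[i]^2))
  c_tot
}

capillary_term <- function(config) {
  q <- config$q
  cap <- numeric(length(q))
  low <- q < config$cap_qmax
  cap[low] <- config$cap_amp * (q[low]^(-config$cap_exp) -
                                  config$cap_qmax^(-config$cap_exp))
  cap
}

#' Buffer background curve at a given salt concentration
#'
#' \code{I(q) = b0 + a_salt * salt + capillary(q)}: a flat, salt-dependent
#' level plus a fixed low-q capillary term confined to \code{q <
#' cap_qmax}. Deterministic (no noise).
#'
#' @param config a [sim_config()].
#' @param salt_mM NaCl concentration, mM.
#' @return a [saxs_curve] (sigma = 0).
#' @export
background_curve <- function(config, salt_mM) {
  if (salt_mM < 0) stop("salt must be >= 0")
  I <- config$b0 + config$a_salt * salt_mM + capillary_term(config)
  saxs_curve(config$q, I, rep(0, length(config$q)))
}

#' Effective salt concentration at the measurement position
#'
#' The programmed schedule convolved with the delayed exponential response
#' of the flow path: each plateau change is reached as \code{1 -
#' exp(-(N - N0_step)/Nprime)} where \code{N0_step} is the programmed step
#' frame plus the dispersion delay. Linear gradients pass through with the
#' pure delay only.
#'
#' @param config a [sim_config()].
#' @param N frame number(s).
#' @return effective NaCl concentration(s), mM.
#' @export
effective_salt <- function(config, N) {
  g <- config$gradient
  if (g$mode == "linear")
    return(salt_at(g, pmax(N - config$dispersion_N0, 0)))
  s <- g$schedule
  salt_levels <- g$cA + s$f * (g$cB - g$cA)
  out <- rep(salt_levels[1], length(N))
  if (nrow(s) > 1) {
    for (i in 2:nrow(s)) {
      N0 <- s$start_frame[i] + config$dispersion_N0
      dlevel <- salt_levels[i] - salt_levels[i - 1]
      w <- ifelse(N >= N0,
                  1 - exp(-(N - N0) / max(config$dispersion_Nprime, 1e-12)),
                  0)
      if (config$dispersion_Nprime <= 0) w <- as.numeric(N >= N0)
      out <- out + dlevel * w
    }
  }
  out
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Simulate a sample run and its blank (buffer) run
#'
#' Buffer-run frame N measures \code{background(effective_salt(N))} plus
#' noise. Sample-run frame N measures \code{c(N) * M * P(q)} for each
#' species plus \code{background(effective_salt(N - true_shift))} (the
#' sample run's background clock lags by \code{true_shift} frames) plus the
#' optional post-step overshoot and noise. Forward scattering thus equals
#' concentration x molar mass by construction.
#'
#' @param config a [sim_config()].
#' @return list with \code{sample} and \code{buffer} ([frame_series]) and
#'   \code{truth}: a record with the true shift, per-step \code{(N0,
#'   Nprime)}, the per-frame concentration and effective-salt vectors, and
#'   each species' Rg (nm), volume (nm^3) and mass (kDa).
#' @export
simulate_run <- function(config) {
  q <- config$q
  nq <- length(q)
  N <- seq_len(config$n_frames) - 1L
  cap <- capillary_term(config)

  salt_buffer <- effective_salt(config, N)
  salt_sample <- effective_salt(config, N - config$true_shift)
  bg_buffer <- outer(cap + config$b0, rep(1, length(N))) +
    outer(rep(config$a_salt, nq), salt_buffer)
  bg_sample <- outer(cap + config$b0, rep(1, length(N))) +
    outer(rep(config$a_salt, nq), salt_sample)

  protein <- outer(sphere_form_factor(q, config$radius_nm),
                   elution_concentration(config, N, species = 1L) * config$mass_kda)
  if (any(config$peaks$species == 2L))
    protein <- protein + outer(
      sphere_form_factor(q, config$radius2_nm),
      elution_concentration(config, N, species = 2L) * config$mass2_kda)

  over <- matrix(0, nq, length(N))
  if (config$overshoot_amp > 0 && config$gradient$mode == "step") {
    s <- config$gradient$schedule
    oq <- as.numeric(q >= config$overshoot_qmin)
    for (i in seq_len(nrow(s))[-1]) {
      N0 <- s$start_frame[i] + config$dispersion_N0
      dn <- pmax(N - N0, 0)
      ot <- ifelse(N >= N0,
                   config$overshoot_amp * (1 - exp(-dn / 5)) *
                     exp(-dn / config$overshoot_decay), 0)
      over <- over + outer(oq, ot)
    }
  }

  I_sample_true <- protein + bg_sample + over
  I_buffer_true <- bg_buffer

  sig_s <- config$noise_level * sqrt(pmax(I_sample_true, 0))
  sig_b <- config$noise_level * sqrt(pmax(I_buffer_true, 0))
  if (config$noise_level > 0) {
    with_seed(config$seed, {
      if (config$poisson_noise) {
        k <- 1 / config$noise_level^2  # counts per intensity unit
        I_sample <- matrix(stats::rpois(nq * length(N),
                                        pmax(I_sample_true, 0) * k) / k,
                           nq, length(N))
        I_buffer <- matrix(stats::rpois(nq * length(N),
                                        pmax(I_buffer_true, 0) * k) / k,
                           nq, length(N))
      } else {
        I_sample <- I_sample_true +
          matrix(stats::rnorm(nq * length(N)), nq, length(N)) * sig_s
        I_buffer <- I_buffer_true +
          matrix(stats::rnorm(nq * length(N)), nq, length(N)) * sig_b
      }
    })
  } else {
    I_sample <- I_sample_true
    I_buffer <- I_buffer_true
  }

  steps <- NULL
  if (config$gradient$mode == "step") {
    s <- config$gradient$schedule
    if (nrow(s) > 1)
      steps <- data.frame(
        programmed_frame = s$start_frame[-1],
        N0 = s$start_frame[-1] + config$dispersion_N0,
        Nprime = config$dispersion_Nprime,
        salt = config$gradient$cA + s$f[-1] *
          (config$gradient$cB - config$gradient$cA))
  }

  truth <- list(
    true_shift = config$true_shift,
    steps = steps,
    concentration = elution_concentration(config, N),
    salt_sample = salt_sample, salt_buffer = salt_buffer,
    rg_nm = sqrt(3 / 5) * config$radius_nm,
    volume_nm3 = 4 / 3 * pi * config$radius_nm^3,
    mass_kda = config$mass_kda,
    rg2_nm = if (is.null(config$radius2_nm)) NULL else
      sqrt(3 / 5) * config$radius2_nm,
    mass2_kda = config$mass2_kda,
    protein_I = NULL)

  list(sample = frame_series(q, I_sample, sig_s,
                             frame_rate = config$frame_rate,
                             flow_rate = config$flow_rate),
       buffer = frame_series(q, I_buffer, sig_b,
                             frame_rate = config$frame_rate,
                             flow_rate = config$flow_rate),
       truth = truth,
       config = config)
}

#' Noise-free protein component of a simulated run
#'
#' The pure in-solution scattering \code{c(N) * M * P(q)} (all species) at
#' one frame, for scoring subtraction results against ground truth.
#'
#' @param config a [sim_config()].
#' @param N frame number.
#' @return a [saxs_curve] (sigma = 0).
#' @export
true_protein_curve <- function(config, N) {
  I <- sphere_form_factor(config$q, config$radius_nm) *
    elution_concentration(config, N, species = 1L) * config$mass_kda
  if (any(config$peaks$species == 2L))
    I <- I + sphere_form_factor(config$q, config$radius2_nm) *
      elution_concentration(config, N, species = 2L) * config$mass2_kda
  saxs_curve(config$q, I, rep(0, length(config$q)))
}
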