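#' Porod volume from the scattering invariant
#'
#' Estimates the particle volume \code{Vp = 2 pi^2 I0 / Q} with \code{Q =
#' integral of q^2 (I(q) - B) dq}. The flat background B (subtraction
#' residual) is fitted over a high-q band where Porod's law \code{I = B +
#' K/q^4} holds, by linear regression of \code{q^4 I} on \code{q^4}
#' (slope = B, intercept = Porod constant K). The invariant integral uses
#' the trapezoidal rule over the measured range, a Guinier extrapolation
#' \code{I0 exp(-q^2 Rg^2 / 3)} below q_min, and the Porod tail
#' \code{K / q_max} above q_max.
#'
#' @param curve background-corrected [saxs_curve].
#' @param guinier a \code{guinier_result} supplying I0 and Rg.
#' @param highq_band [band_spec] for the Porod-law fit; default 3.5-4.9
#'   nm^-1.
#' @return object of class \code{porod_result}: \code{Vp}, \code{Vp_err}
#'   (nm^3), \code{porod_constant}, \code{background_B},
#'   \code{invariant_Q}, \code{frac_below}, \code{frac_above}
#'   (extrapolated fractions of Q).
#' @export
porod_volume <- function(curve, guinier,
                         highq_band = band_spec(3.5, min(4.9, max(curve$q)))) {
  idx <- band_indices(curve$q, highq_band)
  if (length(idx) < 10)
    stop("high-q band too narrow for the Porod-law fit")
  q4 <- curve$q[idx]^4
  y <- q4 * curve$I[idx]
  fit <- stats::lm.fit(cbind(1, q4), y)
  K <- unname(fit$coefficients[1])
  B <- unname(fit$coefficients[2])
  if (B >= mean(curve$I[idx]))
    stop("over-flattening: fitted flat background exceeds the mean intensity in the band")
  q <- curve$q
  Icorr <- curve$I - B
  integrand <- q^2 * Icorr
  core <- sum(diff(q) * (integrand[-1] + integrand[-length(q)]) / 2)
  # Guinier extrapolation 0..q_min
  qlo <- seq(0, q[1], length.out = 200)
  glo <- qlo^2 * guinier$I0 * exp(-qlo^2 * guinier$Rg^2 / 3)
  below <- sum(diff(qlo) * (glo[-1] + glo[-length(qlo)]) / 2)
  # Porod tail q_max..Inf: integral of K/q^2 = K / q_max
  above <- max(K, 0) / q[length(q)]
  Q <- core + below + above
  if (Q <= 0) stop("non-positive scattering invariant")
  Vp <- 2 * pi^2 * guinier$I0 / Q
  # first-order error from I0 only (the invariant error is dominated by it)
  Vp_err <- Vp * guinier$I0_err / guinier$I0
  structure(list(Vp = Vp, Vp_err = Vp_err,
                 porod_constant = K, background_B = B,
                 invariant_Q = Q,
                 frac_below = below / Q, frac_above = above / Q),
            class = "porod_result")
}

#' @export
print.porod_result <- function(x, ...) {
  cat(sprintf(
    "<porod: Vp = %.1f nm^3 (Q = %.4g, B = %.3g, extrapolated %.1f%% + %.1f%%)>\n",
    x$Vp, x$invariant_Q, x$background_B,
    100 * x$frac_below, 100 * x$frac_above))
  invisible(x)
}

#' Molecular mass from the Porod volume
#'
#' Empirical protein calibration: \code{M = Vp / 1.7} with Vp in nm^3 and M
#' in kDa.
#'
#' @param Vp Porod volume, nm^3 (> 0).
#' @return mass, kDa.
#' @export
mass_from_porod <- function(Vp) {
  if (!isTRUE(all(Vp > 0))) stop("Vp must be positive")
  Vp / 1.7
}
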