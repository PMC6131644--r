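#' Buffered effective diffusion coefficient
#'
#' Fast reversible binding to an immobile (or slowly diffusing) buffer slows
#' the apparent spread of an ion. When the buffer equilibrates quickly, the
#' full three-species reaction--diffusion system reduces to a single diffusion
#' equation with \deqn{\bar D = D / (1 + G), \quad G = c_B k_{on} / k_{off}.}
#'
#' @param D Free diffusion coefficient (m^2/s).
#' @param buffer A \code{\link{buffer_model}} (its \code{G} is used).
#' @return The effective diffusion coefficient (m^2/s); equals \code{D} when
#'   the buffer concentration is zero.
#' @examples
#' effective_diffusion(7e-10, buffer_model())           # unbuffered
#' effective_diffusion(2e-10, buffer_model(1, 1e8, 1e5)) # G = 1 -> D/2
#' @export
effective_diffusion <- function(D, buffer = buffer_model()) {
  D <- check_scalar(D, "D", positive = TRUE)
  stopifnot(inherits(buffer, "buffer_model"))
  D / (1 + buffer$G)
}

## Closed-form stationary concentration above baseline at radii r (vector).
## Parabolic inside the transmissive zone, logarithmic outside, matched to be
## continuously differentiable at r = R and zero at r = S.
stationary_concentration <- function(r, geom, source, transport) {
  K <- source$k / transport$D_eff
  R <- geom$R; S <- geom$S
  inner <- K / 4 * (R^2 - r^2) + R^2 * K / 2 * log(S / R)
  outer <- R^2 * K / 2 * log(S / pmax(r, .Machine$double.xmin))
  ifelse(r <= R, inner, outer)
}

#' Stationary radial concentration profile
#'
#' Solves the stationary diffusion problem in the disc: a uniform volumetric
#' source k inside r <= R, zero outside, concentration clamped to
#' \code{baseline} at the rim r = S and zero radial flux at the center. The
#' solution is parabolic in the transmissive zone and logarithmic outside,
#' \deqn{c(r) = \frac{K}{4}(R^2 - r^2) + \frac{R^2 K}{2}\ln(S/R) \; (r \le R),
#'   \qquad c(r) = \frac{R^2 K}{2}\ln(S/r) \; (R \le r \le S),}
#' with \eqn{K = k/\bar D}.
#'
#' @param geom A \code{\link{synapse_geometry}}.
#' @param source A \code{\link{source_spec}}.
#' @param transport A \code{\link{transport_params}}; its \code{D_eff} is used.
#' @param n_points Number of grid points of the uniform output grid spanning
#'   \code{[0, S]} (default 512).
#' @param baseline Far-field concentration offset (mol/m^3, default 0). The
#'   profile is the closed form plus this additive constant.
#' @return A \code{"radial_field"} object: list with \code{r} (m), \code{c}
#'   (mol/m^3) and \code{baseline}, carrying the generating parameters as
#'   attributes.
#' @export
stationary_profile <- function(geom, source, transport, n_points = 512,
                               baseline = 0) {
  stopifnot(inherits(geom, "synapse_geometry"),
            inherits(source, "source_spec"),
            inherits(transport, "transport_params"))
  n_points <- check_scalar(n_points, "n_points")
  if (n_points < 3) stop_invalid("n_points must be >= 3")
  baseline <- check_scalar(baseline, "baseline")
  r <- seq(0, geom$S, length.out = as.integer(n_points))
  cc <- stationary_concentration(r, geom, source, transport) + baseline
  radial_field(r, cc, baseline = baseline, geom = geom, source = source,
               transport = transport, analytic = TRUE)
}

#' Radial concentration field
#'
#' Container for a concentration-versus-radius snapshot (a stationary profile
#' or one saved time slice of a simulation).
#'
#' @param r Strictly increasing radii (m).
#' @param c Concentrations (mol/m^3), same length as \code{r}.
#' @param baseline Far-field offset concentration (mol/m^3).
#' @param geom,source,transport Optional generating parameters, stored as
#'   attributes.
#' @param analytic Logical; \code{TRUE} marks a closed-form stationary profile
#'   (enables exact flux-balance evaluation).
#' @return A \code{"radial_field"} object.
#' @export
radial_field <- function(r, c, baseline = 0, geom = NULL, source = NULL,
                         transport = NULL, analytic = FALSE) {
  if (any(diff(r) <= 0)) stop_invalid("r must be strictly increasing")
  if (length(r) != length(c)) stop_invalid("r and c must have equal length")
  if (any(!is.finite(c))) stop_invalid("concentrations must be finite")
  structure(list(r = as.numeric(r), c = as.numeric(c),
                 baseline = as.numeric(baseline)),
            geom = geom, source = source, transport = transport,
            analytic = isTRUE(analytic), class = "radial_field")
}

#' @export
print.radial_field <- function(x, ...) {
  cat(sprintf("Radial field: %d points on [0, %.3g um], c in [%.3g, %.3g] mol/m^3\n",
              length(x$r), max(x$r) * 1e6, min(x$c), max(x$c)))
  invisible(x)
}

#' @export
as.data.frame.radial_field <- function(x, ...) {
  data.frame(r_m = x$r, c_mol_per_m3 = x$c)
}

#' Positive zeros of the Bessel function J0
#'
#' The decay eigenmodes of radial diffusion in a disc with a clamped rim are
#' set by the positive zeros of the Bessel function of the first kind of
#' order zero. The zeros have no closed form; they are located by bracketing
#' near the large-order asymptote \eqn{(n - 1/4)\pi} and polished with a
#' high-precision root finder.
#'
#' @param n Index (or vector of indices) of the zero, n >= 1.
#' @return The n-th positive zero(s) of J0, accurate to near machine
#'   precision (first zero approximately 2.4048).
#' @examples
#' bessel_j0_root(1)     # ~ 2.404826
#' bessel_j0_root(1:3)
#' @export
bessel_j0_root <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1) || any(n != floor(n)))
    stop_invalid("n must be integer(s) >= 1")
  vapply(as.integer(n), function(k) {
    approx_root <- (k - 0.25) * pi
    lo <- approx_root - 0.6
    hi <- approx_root + 0.6
    ## widen the bracket if the asymptotic guess does not straddle the zero
    while (besselJ(lo, 0) * besselJ(hi, 0) > 0) {
      lo <- lo - 0.2
      hi <- hi + 0.2
      if (lo <= 0) stop_invalid("failed to bracket J0 zero for n = ", k)
    }
    uniroot(function(x) besselJ(x, 0), c(lo, hi), tol = 1e-14)$root
  }, numeric(1))
}

#' Slowest relaxation time constant of the cleft
#'
#' After release starts (or stops) the concentration field approaches its
#' asymptote exponentially. The slowest rate is the smallest eigenvalue of the
#' radial diffusion operator with a clamped rim,
#' \deqn{\lambda_{min} = 1/\tau_{max} = \bar D (\rho_1 / S)^2,}
#' where \eqn{\rho_1 \approx 2.4048} is the first positive zero of J0.
#'
#' @param geom A \code{\link{synapse_geometry}} (only \code{S} enters).
#' @param D_eff Effective diffusion coefficient (m^2/s), or a
#'   \code{\link{transport_params}} object.
#' @return A list of class \code{"time_constant"}: \code{tau_max} (s),
#'   \code{lambda_min} (1/s) and \code{bessel_root}.
#' @examples
#' tc <- slowest_time_constant(synapse_geometry(), 2e-10)
#' tc$tau_max   # ~ 7.8 ms for S = 3 um
#' @export
slowest_time_constant <- function(geom, D_eff) {
  stopifnot(inherits(geom, "synapse_geometry"))
  if (inherits(D_eff, "transport_params")) D_eff <- D_eff$D_eff
  D_eff <- check_scalar(D_eff, "D_eff", positive = TRUE)
  rho1 <- bessel_j0_root(1)
  lambda <- D_eff * (rho1 / geom$S)^2
  structure(list(tau_max = 1 / lambda, lambda_min = lambda,
                 bessel_root = rho1),
            class = "time_constant")
}

#' @export
print.time_constant <- function(x, ...) {
  cat(sprintf("Slowest mode: tau_max = %.4g ms (lambda_min = %.4g 1/s, J0 root %.6f)\n",
              x$tau_max * 1e3, x$lambda_min, x$bessel_root))
  invisible(x)
}

#' First-order approximate space-time concentration
#'
#' When the release rate changes on time scales longer than the slowest
#' relaxation time, the full solution is well approximated by the stationary
#' profile modulated by a single exponential:
#' \deqn{c(r,t) \approx c_{stat}(r)\,[1 - e^{-t/\tau_{max}}]} for the rise
#' after release switches on, and \eqn{c_{stat}(r)\, e^{-t/\tau_{max}}} for
#' the decay after it stops.
#'
#' @param profile A \code{"radial_field"} stationary profile.
#' @param tau Time constant (s) or a \code{"time_constant"} object.
#' @param times Vector of times (s), all >= 0.
#' @param mode \code{"rise"} or \code{"decay"}.
#' @return A data frame with columns \code{r_m}, \code{t_s},
#'   \code{c_mol_per_m3} (long format; baseline included).
#' @export
approx_time_course <- function(profile, tau, times, mode = c("rise", "decay")) {
  stopifnot(inherits(profile, "radial_field"))
  if (inherits(tau, "time_constant")) tau <- tau$tau_max
  tau <- check_scalar(tau, "tau", positive = TRUE)
  mode <- match.arg(mode)
  if (any(!is.finite(times)) || any(times < 0))
    stop_invalid("times must be finite and >= 0")
  frac <- if (mode == "rise") 1 - exp(-times / tau) else exp(-times / tau)
  excess <- profile$c - profile$baseline
  data.frame(
    r_m = rep(profile$r, times = length(times)),
    t_s = rep(times, each = length(profile$r)),
    c_mol_per_m3 = as.vector(outer(excess, frac)) + profile$baseline
  )
}

#' Global stationary flux balance residual
#'
#' In the stationary state all released material leaves through the rim:
#' the outward diffusive flux through the cylinder wall at S,
#' \eqn{-\bar D \, 2\pi S h \, (dc/dr)|_S}, must equal the total volumetric
#' release \eqn{\pi R^2 h k}. Returns the relative imbalance. For a
#' closed-form profile the rim gradient is evaluated exactly
#' (\eqn{dc/dr|_S = -R^2 K / (2S)}); for a simulated field it is evaluated
#' with the same half-cell one-sided difference the finite-volume scheme uses
#' at the rim, so the residual measures discretization error.
#'
#' @param profile A \code{"radial_field"} produced by
#'   \code{\link{stationary_profile}} or extracted from a simulation via
#'   \code{\link{final_field}}.
#' @param geom,transport,source Parameters; defaulting to the attributes
#'   stored on \code{profile}.
#' @return Dimensionless residual |flux_out - release| / release; 0 by
#'   convention when k = 0.
#' @export
stationary_flux_balance <- function(profile,
                                    geom = attr(profile, "geom"),
                                    transport = attr(profile, "transport"),
                                    source = attr(profile, "source")) {
  stopifnot(inherits(profile, "radial_field"))
  if (is.null(geom) || is.null(transport) || is.null(source))
    stop_invalid("geom, transport and source must be supplied or stored on the profile")
  k <- source$k
  if (k == 0) return(0)
  release <- pi * geom$R^2 * geom$h * k
  if (isTRUE(attr(profile, "analytic"))) {
    K <- k / transport$D_eff
    dcdr_S <- -geom$R^2 * K / (2 * geom$S)
  } else {
    ## half-cell one-sided difference at the rim, matching the FV scheme
    n <- length(profile$r)
    dr_half <- geom$S - profile$r[n]
    if (dr_half <= 0) {
      dr_half <- (profile$r[n] - profile$r[n - 1]) / 2
      dcdr_S <- (profile$baseline - profile$c[n]) / dr_half
    } else {
      dcdr_S <- (profile$baseline - profile$c[n]) / dr_half
    }
  }
  flux_out <- -transport$D_eff * 2 * pi * geom$S * geom$h * dcdr_S
  abs(flux_out - release) / release
}
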