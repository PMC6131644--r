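#' Fluorescence calibration parameters
#'
#' The fluorescence of a high-affinity zinc indicator (e.g. FluoZin-3) as a
#' function of free zinc is described by the six-parameter sigmoid
#' \deqn{F([Zn]) = \frac{a}{b + c\, e^{-d([Zn]-f)}} + t,}
#' with lower asymptote \eqn{t}, upper asymptote \eqn{a/b + t}, slope
#' parameter \eqn{d} (1/M) and center \eqn{f} (M). The parameters a, b, c are
#' only jointly identifiable through a/b and c/b, so fits may pin b = 1.
#'
#' @param a,b,c Amplitude/shape parameters (a, c > 0 for an increasing curve).
#' @param d Slope (1/M), > 0.
#' @param f Center concentration (M).
#' @param t Fluorescence offset (arbitrary units).
#' @return A \code{"calibration_params"} object.
#' @export
calibration_params <- function(a, b, c, d, f, t) {
  d <- check_scalar(d, "d", positive = TRUE)
  c <- check_scalar(c, "c", positive = TRUE)
  structure(list(a = check_scalar(a, "a"), b = check_scalar(b, "b"), c = c,
                 d = d, f = check_scalar(f, "f"), t = check_scalar(t, "t")),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf("Calibration: a=%.4g b=%.4g c=%.4g d=%.4g f=%.4g t=%.4g (upper asymptote %.4g)\n",
              x$a, x$b, x$c, x$d, x$f, x$t, x$a / x$b + x$t))
  invisible(x)
}

#' Default demonstration calibration parameters
#'
#' A parameter set producing a monotone sigmoid over the 0-250 nM range with
#' the 250 nM point already in the upper asymptotic region, as observed for
#' FluoZin-3 dilution series. Used by the synthetic-series generator.
#'
#' @return A \code{\link{calibration_params}} object.
#' @export
default_calibration_params <- function() {
  calibration_params(a = 1000, b = 1, c = 4, d = 2e7, f = 5e-8, t = 50)
}

#' Forward calibration: fluorescence from free zinc
#'
#' @param params A \code{\link{calibration_params}}.
#' @param zn Free zinc concentration(s) (M).
#' @return Fluorescence intensity (arbitrary units); strictly increasing in
#'   zn for a > 0, c > 0, d > 0.
#' @export
forward_fluorescence <- function(params, zn) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(!is.finite(zn))) stop_invalid("zn must be finite")
  denom <- params$b + params$c * exp(-params$d * (zn - params$f))
  if (any(denom <= 0))
    stop_invalid("calibration denominator b + c*exp(-d([Zn]-f)) is <= 0 in the requested range")
  params$a / denom + params$t
}

#' Inverse calibration: free zinc from fluorescence
#'
#' Algebraic inverse of \code{\link{forward_fluorescence}}:
#' \deqn{[Zn] = f - \frac{1}{d} \ln\!\left(\frac{a/(F-t) - b}{c}\right).}
#' Only intensities strictly between the asymptotes \eqn{t} and
#' \eqn{a/b + t} are invertible; readings at or beyond an asymptote (e.g. a
#' saturated high-concentration well) raise an error naming the bound.
#'
#' @param params A \code{\link{calibration_params}}.
#' @param F Fluorescence intensity(ies).
#' @return Free zinc concentration(s) (M).
#' @export
invert_fluorescence <- function(params, F) {
  stopifnot(inherits(params, "calibration_params"))
  if (any(!is.finite(F))) stop_invalid("F must be finite")
  upper <- params$a / params$b + params$t
  if (any(F <= params$t))
    stop_invalid("intensity at or below the lower asymptote t = ", params$t,
                 "; cannot invert")
  if (any(F >= upper))
    stop_invalid("intensity at or above the upper asymptote a/b + t = ",
                 signif(upper, 6), " (saturated reading); cannot invert")
  params$f - log((params$a / (F - params$t) - params$b) / params$c) / params$d
}

#' Calibration dilution series
#'
#' @param zn Non-negative, sorted free-zinc concentrations (M), length >= 6
#'   (one point per free parameter).
#' @param fluorescence Measured intensities, same length.
#' @param condition Label for the measurement condition (calcium level, UV
#'   exposure, ...); calibrations are condition-specific.
#' @return A data frame of class \code{"calibration_series"} with columns
#'   \code{zn_molar}, \code{fluorescence}, \code{condition}.
#' @export
calibration_series <- function(zn, fluorescence, condition = "control") {
  if (length(zn) != length(fluorescence))
    stop_invalid("zn and fluorescence must have equal length")
  if (length(zn) < 6)
    stop_invalid("a calibration series needs >= 6 points (6 free parameters)")
  if (any(zn < 0) || is.unsorted(zn))
    stop_invalid("zn must be non-negative and sorted")
  structure(data.frame(zn_molar = as.numeric(zn),
                       fluorescence = as.numeric(fluorescence),
                       condition = condition),
            class = c("calibration_series", "data.frame"))
}

#' Default zinc dilution ladder
#'
#' A plate-style dilution series from 0 through 50 pM up to 250 nM
#' (approximately half-log steps), mirroring indicator calibration practice.
#'
#' @return Concentrations in M.
#' @export
fluozin_ladder <- function() {
  c(0, 50e-12, 150e-12, 500e-12, 1.5e-9, 5e-9, 15e-9, 50e-9, 150e-9, 250e-9)
}

#' Synthesize a calibration series
#'
#' Forward model plus seeded Gaussian intensity noise; emulates a
#' plate-reader dilution series for testing the fitting procedure.
#'
#' @param params Generating \code{\link{calibration_params}}.
#' @param zn_grid Concentrations (M); default \code{\link{fluozin_ladder}()}.
#' @param noise_sd Intensity noise standard deviation (>= 0).
#' @param seed Integer seed (RNG state restored).
#' @param condition Condition label.
#' @return A \code{\link{calibration_series}}.
#' @export
synthesize_calibration_series <- function(params, zn_grid = fluozin_ladder(),
                                          noise_sd = 0, seed = NULL,
                                          condition = "synthetic") {
  noise_sd <- check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  F <- forward_fluorescence(params, zn_grid)
  if (noise_sd > 0)
    F <- F + with_local_seed(seed, rnorm(length(zn_grid), 0, noise_sd))
  calibration_series(zn_grid, F, condition)
}

## Sum of squared residuals of the calibration curve for a parameter vector
## theta = (a, c, d, f, t) with b pinned, or (a, b, c, d, f, t).
calib_ssr <- function(theta, zn, F, pin_b) {
  p <- if (pin_b) list(a = theta[1], b = 1, c = theta[2], d = theta[3],
                       f = theta[4], t = theta[5])
       else list(a = theta[1], b = theta[2], c = theta[3], d = theta[4],
                 f = theta[5], t = theta[6])
  denom <- p$b + p$c * exp(-p$d * (zn - p$f))
  if (any(denom <= 0) || any(!is.finite(denom))) return(Inf)
  pred <- p$a / denom + p$t
  s <- sum((pred - F)^2)
  if (!is.finite(s)) Inf else s
}

## Compact seeded differential evolution (rand/1/bin) within box bounds.
de_minimize <- function(fn, lower, upper, np = 60L, maxiter = 300L,
                        F_w = 0.8, CR = 0.9) {
  d <- length(lower)
  pop <- matrix(runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  cost <- apply(pop, 1L, fn)
  for (gen in seq_len(maxiter)) {
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3L)
      mutant <- pop[idx[1], ] + F_w * (pop[idx[2], ] - pop[idx[3], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      tc <- fn(trial)
      if (tc <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}

#' Fit the calibration curve to a dilution series
#'
#' Seeded population-based global least-squares fit of the six-parameter
#' calibration sigmoid (differential-evolution search within box bounds,
#' best of \code{restarts} runs), followed by a Levenberg-Marquardt polish.
#' Because a, b, c are only jointly identifiable, b is pinned to 1 by
#' default; the fitted curve (not the raw parameters) is the meaningful
#' output, and per-condition series must be fitted separately.
#'
#' @param series A \code{\link{calibration_series}}.
#' @param bounds Optional named list with elements \code{lower} and
#'   \code{upper} (length 5 in the order a, c, d, f, t when b is pinned);
#'   defaults are derived from the data scale.
#' @param seed Integer seed driving the stochastic search (RNG restored).
#' @param restarts Number of independent search runs (best kept).
#' @param pin_b Pin b = 1 (default TRUE).
#' @param np,maxiter Population size and generations per search run.
#' @return A \code{"calibration_fit"}: \code{params}
#'   (\code{\link{calibration_params}}), \code{rss}, \code{rms_rel}
#'   (RMS residual / data range), \code{converged}, \code{seed},
#'   \code{series}.
#' @export
fit_calibration <- function(series, bounds = NULL, seed = 1L, restarts = 3L,
                            pin_b = TRUE, np = 60L, maxiter = 250L) {
  if (!inherits(series, "calibration_series")) {
    if (is.data.frame(series) && all(c("zn_molar", "fluorescence") %in% names(series)))
      series <- calibration_series(series$zn_molar, series$fluorescence,
                                   if ("condition" %in% names(series))
                                     series$condition[1] else "unknown")
    else stop_invalid("series must be a calibration_series")
  }
  zn <- series$zn_molar
  F <- series$fluorescence
  rngF <- max(F) - min(F)
  if (rngF <= 0) stop_invalid("fluorescence values are constant; nothing to fit")
  span <- max(zn) - min(zn)
  if (is.null(bounds)) {
    bounds <- list(lower = c(a = 1e-3 * rngF, c = 1e-3, d = 0.05 / span,
                             f = min(zn) - span, t = min(F) - 2 * rngF),
                   upper = c(a = 1e3 * rngF, c = 1e3, d = 50 / span,
                             f = max(zn) + span, t = min(F) + 0.5 * rngF))
  }
  lower <- bounds$lower; upper <- bounds$upper
  if (length(lower) != 5L || length(upper) != 5L || any(upper <= lower))
    stop_invalid("bounds must give finite lower < upper for (a, c, d, f, t)")

  ## Search in a normalized space: log10 for the positive scale parameters
  ## (a, c, d span many decades), linear for f (units of the zn span) and t
  ## (units of the intensity range). Equalizes step sizes for the global
  ## search and conditions the least-squares Jacobian.
  to_par <- function(u) c(10^u[1], 10^u[2], 10^u[3], u[4] * span,
                          u[5] * rngF + min(F))
  u_lower <- c(log10(lower[1:3]), (lower[4] - 0) / span, (lower[5] - min(F)) / rngF)
  u_upper <- c(log10(upper[1:3]), (upper[4] - 0) / span, (upper[5] - min(F)) / rngF)

  fn <- function(u) calib_ssr(to_par(u), zn, F, pin_b = TRUE)
  resid_fn <- function(u) {
    theta <- to_par(u)
    denom <- 1 + theta[2] * exp(-theta[3] * (zn - theta[4]))
    if (any(denom <= 0) || any(!is.finite(denom)))
      return(rep(1e3 * rngF, length(zn)))
    r <- theta[1] / denom + theta[5] - F
    if (any(!is.finite(r))) rep(1e3 * rngF, length(zn)) else r
  }
  polish <- function(u) {
    pol <- tryCatch(
      minpack.lm::nls.lm(par = u, fn = resid_fn, lower = u_lower,
                         upper = u_upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(pol)) list(par = u, value = fn(u))
    else list(par = coef(pol), value = sum(pol$fvec^2))
  }
  best <- with_local_seed(seed, {
    runs <- lapply(seq_len(restarts), function(i) {
      de <- de_minimize(fn, u_lower, u_upper, np = np, maxiter = maxiter)
      pol <- polish(de$par)
      if (pol$value <= de$value) pol else de
    })
    runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  })
  par <- to_par(best$par)
  rss <- calib_ssr(par, zn, F, pin_b = TRUE)

  params <- calibration_params(a = par[1], b = 1, c = par[2], d = par[3],
                               f = par[4], t = par[5])
  rms_rel <- sqrt(rss / length(zn)) / rngF
  converged <- is.finite(rss) && rms_rel < 0.05
  if (!converged)
    warning("calibration fit did not converge after ", restarts,
            " restarts (relative RMS residual ", signif(rms_rel, 3), ")")
  structure(list(params = params, rss = rss, rms_rel = rms_rel,
                 converged = converged, seed = seed, series = series,
                 bounds = bounds),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (%s): RSS = %.4g, relative RMS = %.3g, converged: %s\n",
              x$series$condition[1], x$rss, x$rms_rel, x$converged))
  print(x$params)
  invisible(x)
}

#' Free zinc and released fraction from a sample measurement
#'
#' Inverts a sample well's fluorescence through a condition-matched fitted
#' calibration and expresses the free zinc as a fraction of the total zinc
#' loaded on the (caged) chelator. A reading of ~30 pM free zinc against
#' 1 uM loaded chelator corresponds to a released fraction of 0.003%.
#'
#' @param sample_F Sample fluorescence intensity (within the calibrated
#'   range).
#' @param params A \code{\link{calibration_params}} (or a
#'   \code{"calibration_fit"}).
#' @param total_chelator_zn Total zinc loaded on the chelator (M), > 0.
#' @return A list: \code{free_zn} (M), \code{released_fraction}
#'   (dimensionless) and \code{released_percent}.
#' @examples
#' p <- default_calibration_params()
#' F30 <- forward_fluorescence(p, 30e-12)
#' free_zinc_from_measurement(F30, p, 1e-6)$released_percent  # 0.003
#' @export
free_zinc_from_measurement <- function(sample_F, params, total_chelator_zn) {
  if (inherits(params, "calibration_fit")) params <- params$params
  total <- check_scalar(total_chelator_zn, "total_chelator_zn", positive = TRUE)
  free <- invert_fluorescence(params, sample_F)
  frac <- free / total
  list(free_zn = free, released_fraction = frac,
       released_percent = 100 * frac)
}

#' Read / write a calibration series CSV
#'
#' Delimited text with columns \code{zn_molar}, \code{fluorescence},
#' \code{condition}.
#'
#' @param path File path.
#' @return \code{read_calibration_series}: a \code{\link{calibration_series}}.
#' @export
read_calibration_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("zn_molar", "fluorescence")
  if (!all(need %in% names(df)))
    stop_invalid("calibration CSV needs columns zn_molar, fluorescence")
  calibration_series(df$zn_molar, df$fluorescence,
                     if ("condition" %in% names(df)) df$condition[1] else "unknown")
}

#' @rdname read_calibration_series
#' @param series A \code{\link{calibration_series}}.
#' @export
write_calibration_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
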