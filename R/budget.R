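#' Synaptic vesicle specification
#'
#' @param diameter Vesicle diameter (m); glutamatergic vesicles are ~30-40 nm.
#' @param luminal_concentration Free-zinc concentration inside the vesicle
#'   (mol/L); vesicular zinc reaches 1 mM or more.
#' @return An object of class \code{"vesicle_spec"}.
#' @export
vesicle_spec <- function(diameter = 40e-9, luminal_concentration = 1.25e-3) {
  structure(list(
    diameter = check_scalar(diameter, "diameter", positive = TRUE),
    luminal_concentration = check_scalar(luminal_concentration,
                                         "luminal_concentration",
                                         positive = TRUE)
  ), class = "vesicle_spec")
}

#' Ions per vesicle
#'
#' Number of ions in a spherical vesicle of diameter d at luminal
#' concentration C: \eqn{N = (\pi/6) d^3 \cdot C \cdot N_A} (C in mol/L,
#' volume converted to litres). A 40 nm vesicle at 1-1.5 mM holds roughly
#' 25-30 ions; at 5 mM, on the order of 100.
#'
#' @param vesicle A \code{\link{vesicle_spec}}.
#' @return Ion count (fractional; round only for display).
#' @examples
#' ions_per_vesicle(vesicle_spec(40e-9, 1.25e-3))  # ~ 25
#' @export
ions_per_vesicle <- function(vesicle) {
  stopifnot(inherits(vesicle, "vesicle_spec"))
  vol_L <- pi / 6 * vesicle$diameter^3 * 1000  # m^3 -> L
  vol_L * vesicle$luminal_concentration * .N_A
}

#' Ion budget of a stimulation train
#'
#' Converts a stimulation protocol (frequency, duration, per-event release
#' probability) and a per-vesicle ion content into the total number of ions
#' released during the train and the mean release rate. In
#' \code{"expected"} mode the deterministic expectation
#' \eqn{f \cdot T \cdot p \cdot N_{ves}} is returned; in \code{"stochastic"}
#' mode each event fires as an independent Bernoulli(p) draw from a seeded
#' generator.
#'
#' @param frequency Events per second (Hz).
#' @param duration Train duration (s).
#' @param release_probability Per-event fusion probability in [0, 1].
#' @param ions_per_event Ions released per fusion event.
#' @param mode \code{"expected"} or \code{"stochastic"}.
#' @param seed Integer seed for stochastic mode (RNG state is restored).
#' @return An object of class \code{"train_budget"}: \code{n_events},
#'   \code{expected_fusions}, \code{ions_total}, \code{mean_rate} (ions/s).
#' @examples
#' # 1 s of 100 Hz stimulation, p = 0.5, ~28 ions per vesicle -> 1400 ions
#' train_ion_budget(100, 1, 0.5, 28)
#' @export
train_ion_budget <- function(frequency, duration, release_probability,
                             ions_per_event,
                             mode = c("expected", "stochastic"),
                             seed = NULL) {
  frequency <- check_scalar(frequency, "frequency", positive = TRUE)
  duration <- check_scalar(duration, "duration", positive = TRUE)
  p <- check_scalar(release_probability, "release_probability", nonneg = TRUE)
  if (p > 1) stop_invalid("release_probability must be in [0, 1]")
  ions_per_event <- check_scalar(ions_per_event, "ions_per_event", nonneg = TRUE)
  mode <- match.arg(mode)
  n_events <- as.integer(round(frequency * duration))
  fusions <- if (mode == "expected") n_events * p
             else with_local_seed(seed, rbinom(1L, n_events, p))
  ions_total <- fusions * ions_per_event
  structure(list(n_events = n_events, expected_fusions = n_events * p,
                 fusions = fusions, ions_total = ions_total,
                 mean_rate = ions_total / duration, mode = mode, seed = seed),
            class = "train_budget")
}

#' @export
print.train_budget <- function(x, ...) {
  cat(sprintf("Train budget (%s): %d events, %.1f fusions, %.0f ions (%.0f ions/s)\n",
              x$mode, x$n_events, x$fusions, x$ions_total, x$mean_rate))
  invisible(x)
}

#' Volumetric source rate from an ion release rate
#'
#' Converts a mean ion release rate (ions/s) into the uniform volumetric
#' source rate k (mol/(m^3 s)) over the transmissive-zone cleft volume
#' \eqn{\pi R^2 h}: \eqn{k = (\dot N / N_A) / (\pi R^2 h)}.
#'
#' @param mean_ion_rate Mean release rate (ions/s).
#' @param geom A \code{\link{synapse_geometry}}.
#' @return A \code{\link{source_spec}} with the derived k.
#' @export
source_rate_from_budget <- function(mean_ion_rate, geom) {
  mean_ion_rate <- check_scalar(mean_ion_rate, "mean_ion_rate", nonneg = TRUE)
  stopifnot(inherits(geom, "synapse_geometry"))
  source_spec((mean_ion_rate / .N_A) / (pi * geom$R^2 * geom$h))
}

#' Ion release rate from a volumetric source rate
#'
#' Exact inverse of \code{\link{source_rate_from_budget}}.
#'
#' @param source A \code{\link{source_spec}}.
#' @param geom A \code{\link{synapse_geometry}}.
#' @return Mean ion release rate (ions/s).
#' @export
ion_rate_from_source <- function(source, geom) {
  stopifnot(inherits(source, "source_spec"),
            inherits(geom, "synapse_geometry"))
  source$k * pi * geom$R^2 * geom$h * .N_A
}
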