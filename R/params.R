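#' Synapse geometry
#'
#' The synaptic cleft is modelled as a thin disc of height \code{h}. Vesicular
#' release occurs inside the central transmissive (active) zone of radius
#' \code{R}; at the outer rim \code{S} the concentration is clamped to the
#' far-field baseline (extracellular matrix / glial sink).
#'
#' @param R Transmissive-zone radius in m (must satisfy 0 < R < S).
#' @param S Outer synapse radius in m.
#' @param h Cleft height in m.
#' @return An object of class \code{"synapse_geometry"}.
#' @examples
#' synapse_geometry(R = 300e-9, S = 3e-6, h = 40e-9)
#' @export
synapse_geometry <- function(R = 300e-9, S = 3e-6, h = 40e-9) {
  R <- check_scalar(R, "R", positive = TRUE)
  S <- check_scalar(S, "S", positive = TRUE)
  h <- check_scalar(h, "h", positive = TRUE)
  if (R >= S) stop_invalid("transmissive-zone radius R must be < outer radius S")
  structure(list(R = R, S = S, h = h), class = "synapse_geometry")
}

#' Immobile-buffer model for effective diffusion
#'
#' Fast reversible binding to a slow/immobile buffer reduces the apparent
#' diffusion coefficient by the factor 1 + G with G = c_B * k_on / k_off.
#'
#' @param c_B Buffer concentration (mol/m^3). \code{c_B = 0} disables buffering.
#' @param k_on On-rate (1/(M s)).
#' @param k_off Off-rate (1/s). Must be > 0 whenever \code{c_B > 0}.
#' @return An object of class \code{"buffer_model"} with the derived binding
#'   ratio \code{G} (dimensionless). Note c_B in mol/m^3 equals mM, so G uses
#'   c_B/1000 to convert to M before multiplying by k_on (per-M units).
#' @export
buffer_model <- function(c_B = 0, k_on = 0, k_off = 1) {
  c_B <- check_scalar(c_B, "c_B", nonneg = TRUE)
  k_on <- check_scalar(k_on, "k_on", nonneg = TRUE)
  k_off <- check_scalar(k_off, "k_off", nonneg = TRUE)
  if (c_B > 0 && k_off <= 0)
    stop_invalid("k_off must be > 0 when the buffer concentration is > 0")
  G <- if (c_B > 0) (c_B / 1000) * k_on / k_off else 0
  structure(list(c_B = c_B, k_on = k_on, k_off = k_off, G = G),
            class = "buffer_model")
}

#' Transport parameters
#'
#' Bundles the free diffusion coefficient with a buffer model and the derived
#' buffered effective coefficient \code{D_eff = D / (1 + G)}.
#'
#' @param D Free diffusion coefficient (m^2/s). Free Zn2+ in water is about
#'   7e-10 m^2/s; in the cleft a 3-10 fold reduction is expected.
#' @param buffer A \code{\link{buffer_model}}.
#' @return An object of class \code{"transport_params"}.
#' @export
transport_params <- function(D = 2e-10, buffer = buffer_model()) {
  D <- check_scalar(D, "D", positive = TRUE)
  stopifnot(inherits(buffer, "buffer_model"))
  structure(list(D = D, buffer = buffer,
                 D_eff = effective_diffusion(D, buffer)),
            class = "transport_params")
}

#' Volumetric source specification
#'
#' The release of ions from fusing vesicles (or channels) inside the
#' transmissive zone is represented as a uniform volumetric rate k
#' (mol/(m^3 s)) for r <= R, zero outside.
#'
#' @param k Volumetric release rate inside the transmissive zone
#'   (mol/(m^3 s)). The helper \code{\link{source_rate_from_budget}} converts
#'   an ion release rate into k.
#' @return An object of class \code{"source_spec"}.
#' @export
source_spec <- function(k) {
  k <- check_scalar(k, "k", nonneg = TRUE)
  structure(list(k = k), class = "source_spec")
}

#' @export
print.synapse_geometry <- function(x, ...) {
  cat(sprintf("Synapse geometry: R = %.3g um, S = %.3g um, h = %.3g nm\n",
              x$R * 1e6, x$S * 1e6, x$h * 1e9))
  invisible(x)
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("Transport: D = %.3g m^2/s, G = %.3g, D_eff = %.3g m^2/s\n",
              x$D, x$buffer$G, x$D_eff))
  invisible(x)
}
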