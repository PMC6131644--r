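#' Read and validate a run configuration
#'
#' YAML (or JSON) configuration with sections \code{geometry} (R_m, S_m,
#' h_m), \code{transport} (D_m2_per_s, optional buffer: c_B_mol_per_m3,
#' k_on_per_M_s, k_off_per_s), \code{source} (k_mol_per_m3_s or
#' mean_ion_rate_per_s), and optional \code{schedule}, \code{uptake},
#' \code{solver}, \code{seed}. Unknown keys are rejected so typos fail
#' loudly; the effective configuration is echoed into every run's metadata.
#'
#' @param path Path to a YAML config file.
#' @return A validated list of class \code{"run_config"} with constructed
#'   parameter objects (\code{geom}, \code{transport}, \code{source},
#'   \code{schedule}, \code{uptake}, \code{solver}, \code{seed}).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("geometry", "transport", "source", "schedule", "uptake",
             "solver", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_invalid("unknown config sections: ", paste(extra, collapse = ", "))
  if (is.null(raw$geometry) || is.null(raw$transport) || is.null(raw$source))
    stop_invalid("config needs geometry, transport and source sections")

  g <- raw$geometry
  geom <- synapse_geometry(R = g$R_m, S = g$S_m, h = g$h_m)

  tr <- raw$transport
  buf <- if (is.null(tr$buffer)) buffer_model()
         else buffer_model(tr$buffer$c_B_mol_per_m3, tr$buffer$k_on_per_M_s,
                           tr$buffer$k_off_per_s)
  D_list <- tr$D_m2_per_s
  if (is.null(D_list) || !length(D_list))
    stop_invalid("transport$D_m2_per_s must list at least one diffusion coefficient")
  transport <- transport_params(D_list[[1]], buf)

  so <- raw$source
  source <- if (!is.null(so$k_mol_per_m3_s)) source_spec(so$k_mol_per_m3_s)
            else if (!is.null(so$mean_ion_rate_per_s))
              source_rate_from_budget(so$mean_ion_rate_per_s, geom)
            else stop_invalid("source needs k_mol_per_m3_s or mean_ion_rate_per_s")

  sc <- raw$schedule
  schedule <- if (is.null(sc)) constant_release()
              else pulse_schedule(
                frequency = sc$frequency_hz %||% 100,
                pulse_duration = sc$pulse_duration_s %||% 5e-3,
                train_duration = sc$train_duration_s %||% 1,
                release_probability = sc$release_probability %||% 1,
                mode = sc$mode %||% "expected",
                seed = sc$seed %||% raw$seed)

  up <- raw$uptake
  uptake <- if (is.null(up) || !isTRUE(up$enabled)) no_uptake()
            else uptake_model(J_max = up$J_max_mol_per_m2_s %||% 3e-6,
                              K_m = up$K_m_mol_per_m3 %||% 1)

  sol <- raw$solver %||% list()
  structure(list(geom = geom, transport = transport, D_list = unlist(D_list),
                 source = source, schedule = schedule, uptake = uptake,
                 solver = list(n_cells = sol$n_cells %||% 300,
                               dt = sol$dt_s %||% "auto",
                               t_end = sol$t_end_s),
                 seed = raw$seed, raw = raw),
            class = "run_config")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## echo config + extras as JSON metadata next to an output file
write_metadata <- function(path, config, extra = list()) {
  meta <- c(list(config = config$raw), extra,
            list(package = "zincleft",
                 version = as.character(utils::packageVersion("zincleft"))))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stationary profiles for a set of diffusion coefficients
#'
#' Evaluates the closed-form stationary profile for each diffusion
#' coefficient in the configuration (default trio 7e-10, 2e-10, 7e-11
#' m^2/s: free aqueous diffusion and 3.5- and 10-fold cleft-hindered
#' values) and writes a tidy CSV plus a JSON summary (tau_max and c_max per
#' coefficient).
#'
#' @param config A \code{"run_config"} (or path to one).
#' @param out_dir Output directory (created if missing); \code{NULL} skips
#'   writing.
#' @param n_points Radial grid resolution.
#' @return Invisibly, a list with the tidy data frame (\code{profiles}:
#'   r_m, D_m2_per_s, c_mol_per_m3) and the summary data frame.
#' @export
run_stationary <- function(config, out_dir = NULL, n_points = 512) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  Ds <- config$D_list
  if (!length(Ds)) stop_invalid("no diffusion coefficients configured")
  rows <- lapply(Ds, function(D) {
    tp <- transport_params(D, config$transport$buffer)
    prof <- stationary_profile(config$geom, config$source, tp, n_points)
    cbind(as.data.frame(prof), D_m2_per_s = D)
  })
  profiles <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(Ds, function(D) {
    tp <- transport_params(D, config$transport$buffer)
    tc <- slowest_time_constant(config$geom, tp$D_eff)
    data.frame(D_m2_per_s = D, D_eff_m2_per_s = tp$D_eff,
               tau_max_s = tc$tau_max,
               c_max_mol_per_m3 = stationary_concentration(
                 0, config$geom, config$source, tp))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(profiles, file.path(out_dir, "stationary_profiles.csv"),
              row.names = FALSE)
    write_metadata(file.path(out_dir, "stationary_summary.json"), config,
                   list(summary = summary))
  }
  invisible(list(profiles = profiles, summary = summary))
}

#' Scaling of time constant and peak concentration with synapse radius
#'
#' Sweeps the outer radius S and the diffusion coefficient D and tabulates
#' the slowest time constant (quadratic in S, inverse-linear in D) and the
#' central stationary concentration (logarithmic in S, inverse-linear in D)
#' at fixed transmissive-zone radius and source rate.
#'
#' @param config A \code{"run_config"} (or path).
#' @param S_values Outer radii to sweep (m); default 1-6 um.
#' @param out_dir Optional output directory for the CSV.
#' @return Invisibly, a data frame (S_m, D_m2_per_s, tau_max_s,
#'   c_max_mol_per_m3).
#' @export
run_scaling <- function(config, S_values = seq(1e-6, 6e-6, by = 0.5e-6),
                        out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  grid <- expand.grid(S_m = S_values, D_m2_per_s = config$D_list)
  rows <- mapply(function(S, D) {
    geom <- synapse_geometry(config$geom$R, S, config$geom$h)
    tp <- transport_params(D, config$transport$buffer)
    c(tau_max_s = slowest_time_constant(geom, tp$D_eff)$tau_max,
      c_max_mol_per_m3 = stationary_concentration(0, geom, config$source, tp))
  }, grid$S_m, grid$D_m2_per_s)
  out <- cbind(grid, t(rows))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(out_dir, "scaling.csv"), row.names = FALSE)
  }
  invisible(out)
}

#' Pulsed-release simulation versus the analytic approximation
#'
#' Runs the finite-volume simulation with pulsed release, with and without
#' membrane uptake, and tabulates probe time series against the
#' single-exponential analytic rise. Defaults follow the published
#' comparison setting: S = 3 um, R = 500 nm, D = 2e-10 m^2/s, 100 Hz pulses
#' of 5 ms, uptake rate scale 3e-6 mol/(m^2 s), probes at 100 nm and 1 um.
#'
#' @param config Optional \code{"run_config"} (or path); \code{NULL} uses
#'   the defaults above with a demonstration source rate of 200
#'   mol/(m^3 s) (the per-event release rate is not independently
#'   measurable, so the absolute scale is a user choice).
#' @param probes Probe radii (m).
#' @param n_cells Radial resolution.
#' @param t_end Simulated time (s).
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in the metadata and driving any stochastic
#'   release.
#' @return Invisibly, a list: \code{traces} (long data frame: t_s, r_m,
#'   c_mol_per_m3, uptake, source), the two simulations, and the analytic
#'   profile and time constant.
#' @export
run_pulse_comparison <- function(config = NULL, probes = c(100e-9, 1e-6),
                                 n_cells = 150, t_end = 0.1, out_dir = NULL,
                                 seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config)) {
    geom <- synapse_geometry(R = 500e-9, S = 3e-6, h = 40e-9)
    transport <- transport_params(2e-10)
    source <- source_spec(200)
    schedule <- pulse_schedule(frequency = 100, pulse_duration = 5e-3,
                               train_duration = t_end, seed = seed)
    uptake <- uptake_model(J_max = 3e-6)
  } else {
    geom <- config$geom; transport <- config$transport
    source <- config$source; schedule <- config$schedule
    uptake <- if (config$uptake$enabled) config$uptake else uptake_model()
    seed <- seed %||% config$seed
  }
  tc <- slowest_time_constant(geom, transport$D_eff)
  prof <- stationary_profile(geom, source, transport)
  sims <- list(
    off = simulate_cleft(geom, transport, source, schedule,
                         uptake = no_uptake(), n_cells = n_cells,
                         t_end = t_end),
    on = simulate_cleft(geom, transport, source, schedule,
                        uptake = uptake, n_cells = n_cells, t_end = t_end))
  traces <- do.call(rbind, lapply(names(sims), function(nm) {
    do.call(rbind, lapply(probes, function(r) {
      pr <- probe(sims[[nm]], r)
      cs <- stationary_concentration(r, geom, source, transport)
      rbind(
        data.frame(t_s = pr$t_s, r_m = r, c_mol_per_m3 = pr$c_mol_per_m3,
                   uptake = nm, source = "finite-volume"),
        data.frame(t_s = pr$t_s, r_m = r,
                   c_mol_per_m3 = cs * (1 - exp(-pr$t_s / tc$tau_max)),
                   uptake = nm, source = "analytic"))
    }))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(traces, file.path(out_dir, "pulse_comparison.csv"),
              row.names = FALSE)
    meta <- list(seed = seed, tau_max_s = tc$tau_max, n_cells = n_cells,
                 dt_s = sims$off$dt, t_end_s = t_end,
                 package = "zincleft",
                 version = as.character(utils::packageVersion("zincleft")))
    jsonlite::write_json(meta, file.path(out_dir, "pulse_comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(traces = traces, sims = sims, profile = prof,
                 time_constant = tc))
}

#' Convert a tidy SI table to reporting units
#'
#' Human-facing unit convention: radii in um, times in ms, concentrations in
#' uM (1 mol/m^3 = 1000 uM).
#'
#' @param df A data frame with any of the columns \code{r_m}, \code{t_s},
#'   \code{c_mol_per_m3}, \code{S_m}, \code{tau_max_s},
#'   \code{c_max_mol_per_m3}.
#' @return The data frame with converted, renamed columns.
#' @export
as_report_units <- function(df) {
  conv <- c(r_m = 1e6, S_m = 1e6, t_s = 1e3, tau_max_s = 1e3,
            c_mol_per_m3 = 1e3, c_max_mol_per_m3 = 1e3)
  newname <- c(r_m = "r_um", S_m = "S_um", t_s = "t_ms", tau_max_s = "tau_max_ms",
               c_mol_per_m3 = "c_uM", c_max_mol_per_m3 = "c_max_uM")
  for (nm in intersect(names(df), names(conv))) {
    df[[nm]] <- df[[nm]] * conv[[nm]]
    names(df)[names(df) == nm] <- newname[[nm]]
  }
  df
}
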