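#' Finite-volume grid for the disc-shaped cleft
#'
#' Uniform cell-centered grid in radius: faces at 0, dr, ..., S; cell centers
#' midway between faces. Cell volumes are cylindrical shells
#' \eqn{\pi(r_{i+1/2}^2 - r_{i-1/2}^2) h}; membrane areas cover the pre- and
#' postsynaptic faces of each shell.
#'
#' @param geom A \code{\link{synapse_geometry}}.
#' @param n_cells Number of cells (>= 8).
#' @param membrane_sides Number of membranes carrying uptake transporters
#'   (2 = both pre- and postsynaptic, the default).
#' @return A \code{"fv_grid"}: faces, centers, dr, cell_volumes,
#'   membrane_area, geometry.
#' @export
build_grid <- function(geom, n_cells, membrane_sides = 2) {
  stopifnot(inherits(geom, "synapse_geometry"))
  n_cells <- check_scalar(n_cells, "n_cells")
  if (n_cells < 8) stop_invalid("n_cells must be >= 8")
  n_cells <- as.integer(n_cells)
  faces <- seq(0, geom$S, length.out = n_cells + 1L)
  centers <- (faces[-1] + faces[-(n_cells + 1L)]) / 2
  ring <- pi * (faces[-1]^2 - faces[-(n_cells + 1L)]^2)  # annulus area
  structure(list(n_cells = n_cells, faces = faces, centers = centers,
                 dr = geom$S / n_cells,
                 cell_volumes = ring * geom$h,
                 membrane_area = membrane_sides * ring,
                 geom = geom),
            class = "fv_grid")
}

#' Pulsed vesicular release schedule
#'
#' Action potentials arrive at \code{frequency}; each triggers release for
#' \code{pulse_duration} with per-event probability \code{release_probability},
#' until \code{train_duration}. In \code{"expected"} mode every event fires
#' with amplitude p (deterministic mean-field release); in
#' \code{"stochastic"} mode each event is an independent seeded Bernoulli(p)
#' draw. \code{constant_release()} is the un-pulsed limit used by the
#' analytic model.
#'
#' @param frequency Events per second (Hz); LTP-inducing bursts are ~100 Hz.
#' @param pulse_duration Release duration per event (s); must not exceed the
#'   inter-event period.
#' @param train_duration Total stimulation time (s).
#' @param release_probability Per-event fusion probability in [0, 1].
#' @param mode \code{"expected"} or \code{"stochastic"}.
#' @param seed Integer seed for stochastic mode.
#' @return A \code{"pulse_schedule"} object.
#' @export
pulse_schedule <- function(frequency = 100, pulse_duration = 5e-3,
                           train_duration = 1, release_probability = 1,
                           mode = c("expected", "stochastic"), seed = NULL) {
  frequency <- check_scalar(frequency, "frequency", positive = TRUE)
  pulse_duration <- check_scalar(pulse_duration, "pulse_duration", positive = TRUE)
  train_duration <- check_scalar(train_duration, "train_duration", positive = TRUE)
  p <- check_scalar(release_probability, "release_probability", nonneg = TRUE)
  if (p > 1) stop_invalid("release_probability must be in [0, 1]")
  if (pulse_duration > 1 / frequency + 1e-15)
    stop_invalid("pulse_duration must not exceed the period 1/frequency")
  mode <- match.arg(mode)
  structure(list(frequency = frequency, pulse_duration = pulse_duration,
                 train_duration = train_duration, release_probability = p,
                 mode = mode, seed = seed, constant = FALSE),
            class = "pulse_schedule")
}

#' @rdname pulse_schedule
#' @export
constant_release <- function(train_duration = Inf, release_probability = 1) {
  p <- check_scalar(release_probability, "release_probability", nonneg = TRUE)
  if (p > 1) stop_invalid("release_probability must be in [0, 1]")
  structure(list(frequency = 0, pulse_duration = Inf,
                 train_duration = train_duration, release_probability = p,
                 mode = "expected", seed = NULL, constant = TRUE),
            class = "pulse_schedule")
}

## Per-event firing amplitudes for a schedule (length = number of events).
## Expected mode: constant p. Stochastic mode: seeded Bernoulli(p) draws.
schedule_fire <- function(schedule, t_end) {
  if (schedule$constant) return(schedule$release_probability)
  n_events <- max(1L, as.integer(ceiling(
    min(schedule$train_duration, t_end) * schedule$frequency)))
  if (schedule$mode == "expected") {
    rep(schedule$release_probability, n_events)
  } else {
    with_local_seed(schedule$seed,
                    as.numeric(rbinom(n_events, 1L, schedule$release_probability)))
  }
}

## Instantaneous in-pulse rate so the train-averaged release (at p = 1)
## equals the configured mean rate k.
schedule_k_inst <- function(schedule, k) {
  if (schedule$constant) k
  else k / (schedule$pulse_duration * schedule$frequency)
}

#' Per-cell volumetric source rates at a given time
#'
#' Evaluates the pulsed release field on a grid at time t: cells whose center
#' lies inside the transmissive zone receive the in-pulse instantaneous rate
#' while a pulse is active, zero otherwise.
#'
#' @param schedule A \code{\link{pulse_schedule}}.
#' @param source A \code{\link{source_spec}} (train-mean rate k at p = 1).
#' @param grid A \code{\link{build_grid}} grid.
#' @param t Time (s), >= 0.
#' @param fire Optional precomputed per-event amplitudes (from a simulation's
#'   metadata) so stochastic schedules are reproducible.
#' @return Numeric vector of volumetric rates (mol/(m^3 s)) per cell.
#' @export
source_vector <- function(schedule, source, grid, t, fire = NULL) {
  stopifnot(inherits(schedule, "pulse_schedule"),
            inherits(source, "source_spec"), inherits(grid, "fv_grid"))
  t <- check_scalar(t, "t", nonneg = TRUE)
  if (is.null(fire)) fire <- schedule_fire(schedule, t + 1 / max(schedule$frequency, 1))
  amp <- 0
  if (t < schedule$train_duration) {
    if (schedule$constant) {
      amp <- fire[1]
    } else {
      ev <- floor(t * schedule$frequency)
      if (ev < length(fire) && (t - ev / schedule$frequency) < schedule$pulse_duration)
        amp <- fire[ev + 1]
    }
  }
  k_inst <- schedule_k_inst(schedule, source$k)
  ifelse(grid$centers <= grid$geom$R, k_inst * amp, 0)
}

#' Saturable transmembrane uptake model
#'
#' Concentration-dependent removal of ions through the pre- and postsynaptic
#' membranes (e.g. by ATPases/transporters), saturating at the areal flux
#' \code{J_max} with half-saturation \code{K_m}; linear (rate
#' \code{J_max/K_m} per unit concentration) for c << K_m.
#'
#' @param J_max Maximal areal flux (mol/(m^2 s)); physiological scale
#'   3e-6 mol/(m^2 s).
#' @param K_m Half-saturation concentration (mol/m^3; default 1, i.e. 1 mM).
#' @param enabled Logical flag.
#' @return An \code{"uptake_model"} object.
#' @export
uptake_model <- function(J_max = 3e-6, K_m = 1, enabled = TRUE) {
  structure(list(J_max = check_scalar(J_max, "J_max", nonneg = TRUE),
                 K_m = check_scalar(K_m, "K_m", positive = TRUE),
                 enabled = isTRUE(enabled)),
            class = "uptake_model")
}

#' @rdname uptake_model
#' @export
no_uptake <- function() uptake_model(0, 1, enabled = FALSE)

#' Per-cell volumetric uptake sink
#'
#' @param c Per-cell concentrations (mol/m^3), all >= 0.
#' @param uptake An \code{\link{uptake_model}}.
#' @param grid A \code{\link{build_grid}} grid.
#' @return Volumetric sink rates (mol/(m^3 s)) per cell:
#'   \eqn{(A_i/V_i) J_{max} c_i/(K_m + c_i)}; zero when disabled.
#' @export
uptake_rate <- function(c, uptake, grid) {
  stopifnot(inherits(uptake, "uptake_model"), inherits(grid, "fv_grid"))
  if (any(!is.finite(c)) || any(c < 0))
    stop_invalid("uptake_rate requires finite non-negative concentrations")
  if (!uptake$enabled) return(numeric(length(c)))
  grid$membrane_area / grid$cell_volumes * uptake$J_max * c / (uptake$K_m + c)
}

#' Time-dependent finite-volume simulation of the cleft
#'
#' Integrates the radial diffusion equation with pulsed vesicular release and
#' optional saturable membrane uptake, using a conservative second-order
#' central flux discretization and explicit forward-Euler stepping at a
#' CFL-limited time step (safety factor 0.25 by default). The inner boundary
#' is reflecting; the outer boundary clamps the face value at S to
#' \code{baseline} (set \code{outer = "reflecting"} for closed-system mass
#' conservation checks).
#'
#' @param geom A \code{\link{synapse_geometry}}.
#' @param transport A \code{\link{transport_params}}.
#' @param source A \code{\link{source_spec}} (train-mean rate at p = 1).
#' @param schedule A \code{\link{pulse_schedule}} or
#'   \code{\link{constant_release}()}.
#' @param uptake An \code{\link{uptake_model}} (default off).
#' @param n_cells Number of radial cells.
#' @param t_end End time (s).
#' @param dt Time step (s) or \code{"auto"} for 0.25 dr^2 / D_eff.
#' @param save_every Save the field every this many steps (default chosen for
#'   ~400 snapshots).
#' @param init Initial field: a single value, a per-cell vector, or a
#'   \code{"radial_field"} interpolated onto the cell centers.
#' @param baseline Outer clamped concentration (mol/m^3).
#' @param outer \code{"dirichlet"} (default) or \code{"reflecting"}.
#' @param membrane_sides Membranes carrying uptake (default 2).
#' @return A \code{"cleft_simulation"}: saved \code{times}, \code{fields}
#'   matrix (snapshots x cells), \code{final} field, released and uptaken
#'   moles, the grid, and all run metadata (dt, seed, fire amplitudes).
#' @export
simulate_cleft <- function(geom, transport, source, schedule = constant_release(),
                           uptake = no_uptake(), n_cells = 300,
                           t_end, dt = "auto", save_every = NULL,
                           init = 0, baseline = 0,
                           outer = c("dirichlet", "reflecting"),
                           membrane_sides = 2) {
  stopifnot(inherits(geom, "synapse_geometry"),
            inherits(transport, "transport_params"),
            inherits(source, "source_spec"),
            inherits(schedule, "pulse_schedule"),
            inherits(uptake, "uptake_model"))
  t_end <- check_scalar(t_end, "t_end", positive = TRUE)
  outer <- match.arg(outer)
  grid <- build_grid(geom, n_cells, membrane_sides)

  D <- transport$D_eff
  dt_cfl <- 0.25 * grid$dr^2 / D
  if (identical(dt, "auto")) dt <- dt_cfl
  dt <- check_scalar(dt, "dt", positive = TRUE)
  n_steps <- as.integer(ceiling(t_end / dt))
  dt <- t_end / n_steps
  if (is.null(save_every)) save_every <- max(1L, n_steps %/% 400L)
  save_every <- as.integer(save_every)

  c0 <- if (inherits(init, "radial_field")) {
    approx(init$r, init$c, xout = grid$centers, rule = 2)$y
  } else if (length(init) == 1L) {
    rep(as.numeric(init), grid$n_cells)
  } else if (length(init) == grid$n_cells) {
    as.numeric(init)
  } else stop_invalid("init must be scalar, per-cell vector, or radial_field")

  fire <- schedule_fire(schedule, t_end)
  k_inst <- schedule_k_inst(schedule, source$k)

  res <- fv_run_cpp(c0, D, geom$h, baseline, geom$S, grid$dr,
                    grid$faces, grid$cell_volumes, grid$membrane_area,
                    grid$centers <= geom$R, k_inst,
                    if (schedule$constant) -1 else schedule$frequency,
                    schedule$pulse_duration, schedule$train_duration,
                    as.numeric(fire),
                    uptake$J_max, uptake$K_m, uptake$enabled,
                    outer == "reflecting",
                    dt, n_steps, save_every)

  structure(list(times = res$times, fields = res$fields, final = res$final,
                 released_mol = res$released_mol, uptaken_mol = res$uptaken_mol,
                 grid = grid, geom = geom, transport = transport,
                 source = source, schedule = schedule, uptake = uptake,
                 baseline = baseline, outer = outer, dt = dt,
                 n_steps = n_steps, seed = schedule$seed, fire = fire),
            class = "cleft_simulation")
}

#' @export
print.cleft_simulation <- function(x, ...) {
  cat(sprintf(paste0("Cleft simulation: %d cells, dt = %.3g s, %d steps, ",
                     "%d snapshots\n  released %.3g mol, uptaken %.3g mol\n"),
              x$grid$n_cells, x$dt, x$n_steps, length(x$times),
              x$released_mol, x$uptaken_mol))
  invisible(x)
}

#' Extract a saved snapshot as a radial field
#'
#' @param result A \code{"cleft_simulation"}.
#' @param index Snapshot index (default: last).
#' @return A \code{"radial_field"} at the cell centers.
#' @export
final_field <- function(result, index = length(result$times)) {
  stopifnot(inherits(result, "cleft_simulation"))
  cc <- if (index == length(result$times)) result$final
        else result$fields[index, ]
  radial_field(result$grid$centers, cc, baseline = result$baseline,
               geom = result$geom, source = result$source,
               transport = result$transport, analytic = FALSE)
}

#' Concentration time series at a probe radius
#'
#' Linear interpolation between adjacent cell centers at each saved time; the
#' rim value at S is the clamped baseline (Dirichlet runs) or the outermost
#' cell (reflecting runs), and inside the innermost center the field is flat
#' (reflecting symmetry).
#'
#' @param result A \code{"cleft_simulation"}.
#' @param r Probe radius (m), 0 <= r <= S.
#' @return Data frame with \code{t_s} and \code{c_mol_per_m3}.
#' @export
probe <- function(result, r) {
  stopifnot(inherits(result, "cleft_simulation"))
  r <- check_scalar(r, "r", nonneg = TRUE)
  S <- result$geom$S
  if (r > S) stop_invalid("probe radius must lie in [0, S]")
  centers <- result$grid$centers
  n <- length(centers)
  xs <- c(0, centers, S)
  series <- apply(result$fields, 1L, function(cc) {
    rim <- if (result$outer == "dirichlet") result$baseline else cc[n]
    approx(xs, c(cc[1], cc, rim), xout = r)$y
  })
  data.frame(t_s = result$times, c_mol_per_m3 = series)
}

#' Compare a simulation against the analytic approximation
#'
#' Measures how far the finite-volume solution is from the closed-form
#' stationary profile (final snapshot vs the profile at the cell centers,
#' relative L-infinity and L2 norms scaled by the profile maximum) and, when
#' a time constant is supplied, from the single-exponential approximate time
#' course at each probe radius.
#'
#' @param result A \code{"cleft_simulation"}.
#' @param analytic_profile A \code{"radial_field"} from
#'   \code{\link{stationary_profile}} on the same geometry.
#' @param tau Optional time constant (s) or \code{"time_constant"} for the
#'   rise-course comparison.
#' @param probes Probe radii (m) for per-probe deviations
#'   (default 100 nm and 1 um).
#' @return A list: \code{linf_rel}, \code{l2_rel}, and a data frame
#'   \code{probe_dev} with the maximal relative deviation from the
#'   approximate rise course per probe (NA without \code{tau}).
#' @export
compare_to_analytic <- function(result, analytic_profile, tau = NULL,
                                probes = c(100e-9, 1e-6)) {
  stopifnot(inherits(result, "cleft_simulation"),
            inherits(analytic_profile, "radial_field"))
  ageom <- attr(analytic_profile, "geom")
  if (!is.null(ageom) &&
      (abs(ageom$S - result$geom$S) > 1e-15 || abs(ageom$R - result$geom$R) > 1e-15))
    stop_invalid("analytic profile and simulation use different geometries")
  geom <- result$geom
  src <- attr(analytic_profile, "source")
  trn <- attr(analytic_profile, "transport")
  cstat <- stationary_concentration(result$grid$centers, geom, src, trn) +
    analytic_profile$baseline
  scale <- max(abs(cstat - analytic_profile$baseline))
  diffs <- result$final - cstat
  if (inherits(tau, "time_constant")) tau <- tau$tau_max
  probe_dev <- data.frame(r_m = probes, max_rel_dev = NA_real_)
  if (!is.null(tau)) {
    for (i in seq_along(probes)) {
      pr <- probe(result, probes[i])
      cs <- stationary_concentration(probes[i], geom, src, trn)
      appr <- cs * (1 - exp(-pr$t_s / tau)) + analytic_profile$baseline
      probe_dev$max_rel_dev[i] <- max(abs(pr$c_mol_per_m3 - appr)) / max(cs, .Machine$double.eps)
    }
  }
  list(linf_rel = max(abs(diffs)) / scale,
       l2_rel = sqrt(mean(diffs^2)) / scale,
       probe_dev = probe_dev)
}
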