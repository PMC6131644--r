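---
title: "Methods: zinc dynamics in a disc-shaped synaptic cleft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zinc dynamics in a disc-shaped synaptic cleft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincleft)
```

## The physical model

The synaptic cleft is idealised as a thin disc of height $h$ and outer
radius $S$, bounded above and below by membranes. Vesicular release injects
Zn^2+^ uniformly within a central *transmissive zone* of radius $R \ll S$
at a volumetric rate $k$ (mol m^-3^ s^-1^). Because $h \ll R$, vertical
equilibration is effectively instantaneous and the concentration field
$c(r, t)$ is treated as a function of the cylindrical radius alone:

$$ \frac{\partial c}{\partial t}
   = \bar D \, \frac{1}{r} \frac{\partial}{\partial r}
     \left( r \frac{\partial c}{\partial r} \right)
   + k \, \mathbf{1}_{\{r \le R\}} - u(c), $$

with a symmetry condition at $r = 0$ and the rim clamped to the ambient
(extracellular) concentration at $r = S$ — the surrounding neuropil acts as
an effectively infinite sink. $u(c)$ is an optional saturable membrane
uptake term described below.

### Buffered effective diffusion

Fast-equilibrating immobile or slowly mobile buffers retard transport. For
a buffer at total concentration $c_B$ with on/off rates $k_{on}$, $k_{off}$
the rapid-buffering approximation yields an effective coefficient

$$ \bar D = \frac{D}{1 + G}, \qquad
   G = \frac{c_B \, k_{on}}{k_{off}}, $$

implemented by `buffer_model()` and `effective_diffusion()`. The package
works internally in SI units, so $c_B$ in mol m^-3^ is converted to molar
before multiplying by $k_{on}$ (per M per s).

### Stationary profile (closed form)

With constant release the steady state of the equation above (without
uptake) is, writing $K = k / \bar D$:

$$ c(r) = \begin{cases}
  \dfrac{K}{4}(R^2 - r^2) + \dfrac{R^2 K}{2} \ln\dfrac{S}{R}, & r \le R,\\[2ex]
  \dfrac{R^2 K}{2} \ln \dfrac{S}{r}, & R \le r \le S.
\end{cases} $$

`stationary_profile()` evaluates this; `stationary_flux_balance()` verifies
that the rim efflux $-2\pi S h \bar D \, c'(S)$ balances the injected flux
$\pi R^2 h k$ (exactly, for the closed form). Note two structural
consequences the tests exploit: the centre-to-zone-edge ratio is
$1 + 1/(2 \ln(S/R))$ independent of $k$, and the peak concentration is
*affine in* $\ln S$ at fixed $R$, $k$, $\bar D$.

### Relaxation time constant

The homogeneous decay modes in a clamped disc are Bessel modes
$J_0(\rho_n r / S) e^{-\lambda_n t}$ with
$\lambda_n = \bar D (\rho_n / S)^2$, where $\rho_n$ are the positive zeros
of $J_0$ ($\rho_1 = 2.404826\ldots$, located by bracketing and `uniroot()`
in `bessel_j0_root()`). The slowest time constant

$$ \tau_{\max} = \frac{1}{\lambda_1} = \frac{(S/\rho_1)^2}{\bar D} $$

(`slowest_time_constant()`) controls both filling and clearance.
`approx_time_course()` builds the single-exponential approximation
$c(r, t) \approx c_\infty(r) \, (1 - e^{-t/\tau_{\max}})$ (rise) and
$c_\infty(r) e^{-t/\tau_{\max}}$ (decay).

```{r time-constants}
geom <- synapse_geometry(R = 300e-9, S = 3e-6, h = 40e-9)
sapply(c(7e-10, 2e-10, 7e-11),
       function(D) slowest_time_constant(geom, D)$tau_max)
```

Even for tenfold-hindered diffusion ($\bar D = 7 \times 10^{-11}$
m^2^ s^-1^) the time constant is ~22 ms, so the cleft is cleared well
within a second.

## Release budget

A vesicle of diameter $d$ with luminal concentration $C$ carries
$N = \frac{\pi}{6} d^3 \, C \, N_A$ ions (`ions_per_vesicle()`); 40 nm at
1.25 mM gives ~25 ions. A stimulus train at frequency $f$ for duration $T$
with per-event release probability $p$ delivers $f T p N$ ions in
expectation (`train_ion_budget()`; a seeded Bernoulli mode draws individual
fusion events). `source_rate_from_budget()` converts a mean ion rate into
the volumetric source rate $k = (\text{rate}/N_A)/(\pi R^2 h)$ used by the
solvers.

```{r budget}
ions <- ions_per_vesicle(vesicle_spec(40e-9, 1.25e-3))
train_ion_budget(100, 1, 0.5, 28)$ions_total   # ~1400 ions per second
```

## Finite-volume simulator

`simulate_cleft()` integrates the full time-dependent problem on
concentric annular cells with explicit Euler stepping. Numerical choices:

* **Conservative fluxes.** Face conductances
  $\bar D \cdot 2\pi r_{face} h / \Delta r$ guarantee discrete mass
  conservation; with a reflecting rim the cleft content matches the
  integrated release to round-off (tested at $10^{-8}$ relative, achieved
  at ~$10^{-13}$).
* **Dirichlet rim via a half-cell ghost.** The clamped boundary uses a
  conductance over $\Delta r / 2$ to the rim value, keeping second-order
  accuracy of the boundary flux.
* **CFL safety factor 0.25.** The stable explicit step for this operator is
  $\Delta t \le \Delta r^2 / (4 \bar D)$ near the axis; `dt = "auto"` uses
  $0.25 \, \Delta r^2 / \bar D$, which also preserves positivity.
* **Grid/staircase alignment.** The source indicator is piecewise-constant
  per cell, so resolutions whose faces land on $r = R$ avoid a staircase
  bias: for $R = 500$ nm, $S = 3$ µm the aligned counts are 150, 300, 600
  cells. Tests and the acceptance script use these sizes (128 or 64 cells
  for cheap conservation/smoke checks where alignment is irrelevant).
* **Performance.** The inner loop is compiled (Rcpp with raw buffers); a
  600-cell, ~2.5-million-step steady-state run takes a few seconds.

Pulsed release (`pulse_schedule()`) models action potentials at
`frequency` with `pulse_duration` of release per event; the in-pulse rate
is boosted by the inverse duty cycle so the cycle-averaged rate equals $k$.
In `"expected"` mode every event fires with amplitude $p$; in
`"stochastic"` mode each event is a seeded Bernoulli($p$) draw. Pulsed
trains time-average to the constant-release steady state, and the
simulated field matches the closed form within 1% at 600 cells (measured
max relative error $9 \times 10^{-6}$).

### Membrane uptake

`uptake_model()` adds a Michaelis–Menten sink on both membrane faces:
volumetric rate $(A_i/V_i) \, J_{\max} \, c / (K_m + c)$ with $A_i/V_i =
2/h$. Defaults: $J_{\max} = 3 \times 10^{-6}$ mol m^-2^ s^-1^ and $K_m = 1$
mol m^-3^ (1 mM). The $K_m$ default is deliberately of the order of the
concentrations actually reached in the cleft (hundreds of µM): a
micromolar-scale $K_m$ would drive the transporters to saturation and make
uptake negligible relative to lateral diffusion, whereas the millimolar
choice yields steady levels *moderately lower* than the diffusion-only
solution (measured factors ~0.5–0.7 at the probe radii) without changing
the order of magnitude — the qualitative regime the model is meant to
illustrate. Users studying a specific transporter should set $K_m$ (and
$J_{\max}$) from its measured kinetics.

### The demonstration source rate

The per-release volumetric rate is not independently measurable, so runner
defaults use $k = 200$ mol m^-3^ s^-1^, which puts the diffusion-only peak
near 290 µM — "some hundreds of micromolar", the scale usually quoted for
cleft zinc transients. All closed-form results are linear in $k$, so any
other choice simply rescales the profiles.

```{r simulate}
tp <- transport_params(2e-10)
sim <- simulate_cleft(synapse_geometry(500e-9, 3e-6, 40e-9), tp,
                      source_spec(200),
                      pulse_schedule(100, 5e-3, train_duration = 0.05),
                      n_cells = 150, t_end = 0.05)
tail(probe(sim, 100e-9), 3)
```

## Indicator calibration

Low-affinity fluorescent indicators are calibrated against a dilution
series of buffered free-zinc standards. The forward model is a shifted
logistic in concentration,

$$ F([\mathrm{Zn}]) = \frac{a}{b + c \, e^{-d([\mathrm{Zn}] - f)}} + t, $$

with `forward_fluorescence()` / `invert_fluorescence()` as exact mutual
inverses within the open range $(t + a/(b+c'),\ t + a/b)$. Because $a$ and
$b$ are jointly unidentifiable (only $a/b$ matters), fits pin $b = 1$.

`fit_calibration()` runs a seeded differential-evolution global search
followed by a Levenberg–Marquardt polish, with each parameter searched in
a normalised space: $\log_{10}$ for the scale-like $a$, $c$, $d$; $f$
scaled by the concentration span; $t$ by the fluorescence range. This
matters — the raw parameters span ~15 orders of magnitude and direct
optimisation stalls, while the normalised search recovers noiseless ladders
to machine precision (~$10^{-15}$ curve error). Each fit takes a few
seconds (population 60, ≤250 generations, 3 restarts).

The default dilution ladder (`fluozin_ladder()`: blank plus 50 pM–250 nM,
roughly half-decade spacing) concentrates points through the rising limb of
the default curve while anchoring both plateaus. The synthetic-series
generator (`synthesize_calibration_series()`) adds i.i.d. Gaussian noise to
the forward model. That is a deliberate simplification: real plate-reader
series show intensity-dependent (multiplicative) noise, photobleaching
drift, and pipetting error in the *x*-values, none of which are modelled.
The generator is meant for validating the fitting machinery, not for
simulating instrument behaviour.

`free_zinc_from_measurement()` inverts a sample intensity and reports the
released fraction of a known chelated-zinc pool:

```{r calibration}
p <- default_calibration_params()
F_sample <- forward_fluorescence(p, 30e-12)          # a 30 pM free signal
free_zinc_from_measurement(F_sample, p, 1e-6)$released_percent
```

A 30 pM free signal against a 1 µM total pool corresponds to 0.003%
released — illustrating how little of the chelated pool a detectable
signal requires.

## Verification summary

The test suite checks the implementation against independent oracles:

* $J_0$ zeros against a power-series evaluation of $J_0$;
* the closed-form profile against a direct sparse tridiagonal solve of the
  discrete Poisson problem (3000 cells, agreement $< 10^{-5}$);
* $\lambda_1$ against inverse power iteration on the discrete operator;
* the simulator against the closed form (steady state, decay rate, mass
  conservation, flux balance, maximum principle, pulsed time-averages);
* the calibration fit against the generating parameters.

`scripts/acceptance.R` recomputes the headline quantities from scratch and
writes them as JSON.

## Limitations

* The cleft is radially symmetric and vertically homogeneous; discrete
  release sites, cleft-height variation and tortuosity are not resolved.
* Buffering uses the rapid-equilibrium approximation; explicit
  buffer-binding kinetics (and buffer transport) are not simulated.
* Uptake kinetics are phenomenological; no specific transporter is
  parameterised.
* The Dirichlet rim treats the surrounding neuropil as a perfect sink;
  crowded extracellular space would slow clearance.
* The calibration noise model is additive Gaussian only.
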