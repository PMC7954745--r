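---
title: "Model-based monitoring and control of fed-batch dilution refolding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based monitoring and control of fed-batch dilution refolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refoldcontrol)
```

## The process and its model

Recombinant proteins overexpressed in bacteria frequently accumulate as
inclusion bodies. After solubilization in a chaotrope, the protein is
refolded by dilution into refolding buffer, where productive first-order
folding competes with an off-pathway aggregation reaction of order
`n_agg` (typically 2; order 1 is appropriate at low protein
concentrations):

$$
\frac{dc_{SL}}{dt} = -(k_r c_{SL} + k_a c_{SL}^{\,n}), \qquad
\frac{dc_{NL}}{dt} = k_r c_{SL}, \qquad
\frac{dc_{AL}}{dt} = k_a c_{SL}^{\,n}.
$$

Because aggregation is of higher order than folding, the yield improves
when the instantaneous solubilized-protein concentration is kept low. That
is what fed-batch dilution does: the solubilizate is fed from a finite
reservoir (volume $V_R$, composition $c_{SR}$, $c_{DR}$) at rate $F_R$,
adding volume, protein and denaturant balances:

$$
\frac{dV_L}{dt} = F_R, \qquad
\frac{dc_{DL}}{dt} = \frac{F_R}{V_L}(c_{DR} - c_{DL}), \qquad
\frac{dc_{XL}}{dt} = (\text{reaction}) + \frac{F_R}{V_L}(c_{XR} - c_{XL}),
$$

with $c_{XR} = c_{SR}$ for the solubilized species and zero for native and
aggregated protein (the reservoir holds only solubilized material). Both
rate constants may depend on the denaturant concentration through the power
law $k_i = a_i (1 + c_{DL})^{b_i}$, $i \in \{r, a\}$; `c_DL` enters as its
numeric value in mol/L (i.e. relative to a 1 mol/L reference), which keeps
the base dimensionless. Denaturant is carried in mol/L on both sides of the
feed for internal consistency.

No published numeric rate constants are shipped: the literature this model
family comes from defers the values to protein-specific fits. The package
defaults (`k_r` = 1/h, `k_a` = 1 L/g/h in constant mode; `a_r` = 2,
`b_r` = −1, `a_a` = 8, `b_a` = −3 in denaturant-dependent mode) are
documented synthetic fixtures on the scale reported for lysozyme-class
refolding, chosen once for the test scenarios. The negative exponents
encode that denaturant slows both reactions, aggregation more strongly.

## Simulation and numerics

`simulate_refolding()` integrates the balances with `deSolve::lsoda`
(relative tolerance 1e-8, absolute 1e-10 by default). Because the feed
policy is piecewise constant, the cumulative fed volume is piecewise linear
and the reservoir-depletion time is located *exactly* by arithmetic; the
integration is restarted there and continues in batch mode to `t_end`
(the yield keeps developing after depletion). Tiny negative integrator
undershoots are clamped to zero in the reported table only, never in the
integrator state; inside the right-hand side the solubilized concentration
is clamped at zero in the rate terms so an undershoot cannot create
spurious aggregate mass.

The batch model with second-order aggregation has a closed-form solution
(a Bernoulli equation), shipped as `analytic_batch_solution()` and used as
an independent oracle in the tests; for the unit scenario
($c_0 = k_r = k_a = 1$) the asymptotic yield is $\ln 2 \approx 0.693$.

```{r batch}
tr <- simulate_refolding(vessel_state(V_L = 1, c_SL = 1),
                         reservoir_spec(0, 0, 0), constant_feed(0),
                         kinetic_parameters(k_r = 1, k_a = 1), t_end = 40)
tail(tr$c_NL_g_L, 1)   # ~ log(2)
```

## KPIs and the yield / productivity tradeoff

The two soft sensors are the refolding yield $c_{NL}/c_{PL}$ and the
space-time-yield $c_{NL}/t$. The total protein concentration $c_{PL}$ is
computed from the cumulative mass balance
$(M_0 + c_{SR} V_{fed})/V_L$, which reduces to the familiar
$F_R\,t\,c_{SR}/V_L$ for constant feed and no initial protein, and remains
valid for pulsed feeds and after depletion. The yield denominator is the
instantaneous $c_{PL}(t)$ by default; evaluating against the final or
maximal total protein concentration is exposed as an option
(`kpi_series(denominator = )`) since a plant-side soft sensor may only know
the planned final load. The "mean STY over the fed-batch phase" is defined
here as the trapezoidal time-average of the instantaneous STY over
$[0, t_{dep}]$ with STY(0) = 0 — the averaging rule itself is a package
choice. The maximal yield is taken over the entire trajectory because it
keeps rising during the batch continuation.

`pareto_sweep()` re-simulates one scenario under a set of constant feed
rates (mL/min user-facing, converted to L/h internally) and records the
max-yield / mean-STY pair per rate. Log spacing is the default because the
high-yield end of the frontier lives at very low rates. The sweep refines
the output grid inside the fed-batch window (300 points) on top of the
overall grid: at 10 mL/min the reservoir empties in 50 minutes, and the
mean-STY trapezoid is meaningless if that window holds only a couple of
grid points — an earlier coarse-grid version produced a spurious
non-monotone frontier precisely for this reason.

## PAT measurement emulation

No external dataset exists for this framework; all test inputs come from
the seeded emulator. `generate_measurements()` samples each configured
sensor on its own clock, adds Gaussian noise with standard deviation
`abs + rel * truth`, stamps records with an availability time
(sample time + feedback delay) and censors values below the limit of
quantification at the LOQ (flagged, never fabricated). The presets follow
the published characteristics of refolding PAT methods: chromatographic
species quantification with an LOQ of 0.01 g/L and minutes-scale feedback,
seconds-scale FTIR and DLS channels. The noise magnitudes themselves are
synthetic defaults — the methods are characterized only qualitatively in
the literature — and the emulator does not model drift, fouling or
spectral structure, so passing tests say nothing about real-sensor
artifacts beyond noise, delay and censoring.

## Parameter estimation and model qualification

`fit_parameters()` minimizes the weighted residual sum of squares over
uncensored records with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`), weights defaulting to inverse sensor variance
(overridable per quantity). Censored records are excluded by default.
Qualification reports $R^2$, NRMSE (range-normalized by default; mean and
sd normalizations available) per quantity and pooled, and the Gaussian
concentrated-likelihood criteria
$AIC = n\ln(WRSS/n) + 2p$, $BIC = n\ln(WRSS/n) + p\ln n$.
A per-parameter identifiability probe perturbs each estimate by 1% and
flags parameters whose objective stays flat — observing only total protein,
for instance, identifies neither rate constant, because the total obeys the
mass balance whatever the kinetics. The published model-quality expectation
of a state error below 10–15% is operationalized as the NRMSE of the
refitted model's state trajectories against noise-free truth; under the
test conditions (5% relative noise, 50 observation times, 3 species) the
fitted models stay well inside that band.

## State observation

`observer_step()` implements unscented (default) and extended Kalman
filtering over the five-dimensional vessel state. The UKF needs no
Jacobians of the kinetics; the EKF uses central finite differences. The
filter core is generic and verified against the closed-form scalar Kalman
recursion — on linear systems the sigma points transform linearly and the
update is algebraically exact. A particle filter is out of scope.

Delayed records are assimilated at their availability time by evaluating
the measurement function through deterministic back-propagation of the
state to the sample time under the logged feed history; between updates the
dynamics are deterministic, so this is the exact state-to-measurement map
and avoids storing and re-filtering explicit history. Posterior mean
concentrations are clipped at zero (covariance untouched); covariances are
re-symmetrized and jittered if an update leaves them marginally indefinite.
Seconds-scale sensors oversample the slow dynamics heavily, so the replay
loop by default assimilates only the latest available record per channel
per step. No observer tuning for refolding exists in the literature; the
defaults here (update step 0.1 h, diagonal process noise 1e-6) are the
package's own.

## Model predictive control

`mpc_step()` minimizes the quadratic KPI-tracking cost
$J = \sum_k w_Y (Y_{ref} - \hat Y_k)^2 + w_{STY}(STY_{ref} -
\widehat{STY}_k)^2$ over piecewise-constant feed sequences subject to pump
bounds, a slew limit $|F_k - F_{k-1}| \le \Delta F_{max}$ (against pump
alternation between slack and high speeds), the vessel volume limit and
reservoir non-negativity. The quadratic-tracking form is this package's
concretization — the framework literature specifies only weighted KPIs,
references and constraints. Both KPIs are tracked as running targets
(STY in global process time); a terminal-only yield target can be emulated
by weighting the final step through a short horizon. Predictions roll the
controller's internal model out from the observer mean (certainty
equivalence). The solver enumerates slew-feasible sequences on a coarse
grid and polishes the best with L-BFGS-B under exact post-hoc constraint
verification, so its cost never exceeds the grid optimum; the exhaustive
grid search is exported (`mpc_grid_search()`) and doubles as the test
oracle. Default control step 0.1 h and horizon 10 are configurable.

`run_closed_loop()` wires the pieces together: plant simulation (optionally
with perturbed parameters for plant–model mismatch), measurement release at
availability times, observer update, re-optimization, first-move
application, exact feed cut at reservoir depletion. All noise is pre-drawn
per sensor schedule from the mandatory seed, so runs are byte-reproducible.

## Problem sizes used in the shipped experiments

The regression experiments use a 1 L vessel / 0.5 L reservoir scenario
(depletion at 5 h), 10–20 h horizons for fitting and observation, 20-seed
replications for the stochastic checks, a 20-rate sweep to 600 h for the
frontier, and a 3 h closed-loop run at 0.5 h control steps with horizon 6.
These sizes resolve every phase of the process while keeping the whole
suite comfortably fast on a single core.

## Known limitations

- Single well-mixed compartment: no spatial inhomogeneity, temperature,
  pH or redox dynamics; oxidizing-agent and cofactor feeds, misfolded-state
  reactions and continuous refolding are out of scope (extension hooks:
  the rate-law mode enum and the reservoir spec).
- The closed form used as the simulator oracle exists only for `n_agg = 2`.
- Joint state-and-parameter estimation is not implemented; parameters are
  fitted offline, states observed online.
- Certainty-equivalence MPC: the optimizer ignores state uncertainty.
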