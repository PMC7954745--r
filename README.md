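# refoldcontrol

Model-based monitoring and control of inclusion-body dilution refolding
operated in fed-batch mode.

Recombinant proteins expressed as inclusion bodies are solubilized in
chaotrope and refolded by dilution. Productive folding is first order in the
solubilized protein while off-pathway aggregation is of higher order
(typically second), so yield is bought by keeping the instantaneous
solubilized concentration low — classically by feeding the solubilizate
slowly from a reservoir instead of diluting it at once. That buys yield at
the cost of productivity (space-time-yield), and steering the tradeoff in
real time requires a process model, state estimation from the few available
PAT signals, and feed-rate optimization. This package implements that whole
loop for process-development scientists and control engineers:

- **Kinetics**: off-pathway model
  `dc_SL/dt = -(k_r c_SL + k_a c_SL^n)`, `dc_NL/dt = k_r c_SL`,
  `dc_AL/dt = k_a c_SL^n`, with optional denaturant-dependent rate
  constants `k_i = a_i (1 + c_DL)^{b_i}` and fed-batch volume / denaturant /
  species balances.
- **Simulation** (`simulate_refolding`): stiff-capable integration with
  exact reservoir-depletion detection and batch continuation; closed-form
  batch oracle (`analytic_batch_solution`).
- **KPIs** (`kpi_series`, `pareto_sweep`): refolding yield `c_NL/c_PL`,
  space-time-yield `c_NL/t`, and the yield-vs-productivity Pareto frontier
  over feed rates.
- **PAT emulation** (`generate_measurements`): seeded sensor streams with
  sampling period, feedback delay, Gaussian noise and LOQ censoring,
  presets modeled on FTIR / RP-HPLC / DLS characteristics.
- **Estimation** (`fit_parameters`): bounded weighted least squares with
  R², NRMSE, AIC/BIC and identifiability flags.
- **Observation** (`run_observer`): unscented / extended Kalman filtering
  of the full vessel state from delayed, noisy, partial measurements.
- **Control** (`mpc_step`, `run_closed_loop`): receding-horizon MPC of the
  feed rate under pump bounds, slew limits and volume constraints, with an
  exhaustive grid oracle.

## Worked example

```r
library(refoldcontrol)

cfg <- load_scenario(scenario_fixture("fedbatch_baseline"))
tr  <- simulate_refolding(cfg$initial, cfg$reservoir, cfg$feed, cfg$params,
                          t_end = cfg$t_end, dt = cfg$dt)
tr
#> Refolding trajectory: 401 points, t in [0, 20] h; depletion at t = 5 h
#>    t_h V_L_L   c_SL_g_L    c_NL_g_L     c_AL_g_L c_DL_mol_L   c_PL_g_L ...
#> 1 0.00 1.000 0.00000000 0.000000000 0.000000e+00  0.5000000 0.00000000
#> 2 0.05 1.005 0.04848868 0.001222812 3.975294e-05  0.5273632 0.04975124

kp <- kpi_series(tr)
attr(kp, "max_yield")          # 0.695
attr(kp, "mean_sty_fedbatch")  # 0.347 g/L/h
```

The fixture feeds 0.5 L of 10 g/L solubilizate at 0.1 L/h into 1 L of
buffer: the reservoir empties at exactly 5 h, refolding continues in batch
mode, and about 69% of the 3.33 g/L total protein ends up native — the rest
is lost to second-order aggregation.

Fitting the two rate constants back from emulated noisy sensors:

```r
m   <- generate_measurements(tr, cfg$sensors, seed = 42)
fit <- fit_parameters(m, cfg$initial, cfg$reservoir, cfg$feed, cfg$params,
                      free = list(k_r = c(0.4, 1e-3, 20),
                                  k_a = c(0.4, 1e-3, 20)))
fit
#> Kinetic parameter fit (7621 obs, 2 parameters)
#>   k_r  = 0.994426
#>   k_a  = 0.991614
#>   WRSS = 7814.92 | AIC = 195.5 | BIC = 209.4 | converged: TRUE
#>   R2:     c_AL=0.8899  c_NL=0.9933  c_SL=0.9975  pooled=0.9602
#>   NRMSE:  c_AL=0.0712  c_NL=0.0207  c_SL=0.0193  pooled=0.0371
```

Both constants (truth 1.0) are recovered within 1%, and the per-species
NRMSE sits far inside the 10–15% state-error band expected of a
control-grade model.

A command-line wrapper with `simulate`, `sweep`, `emulate`, `fit`,
`observe` and `control` subcommands is installed under
`inst/scripts/refoldctl.R`:

```sh
Rscript inst/scripts/refoldctl.R control \
  --config inst/extdata/fedbatch_baseline.yaml --out-dir out --seed 4
```

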