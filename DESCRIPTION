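Package: refoldcontrol
Title: Model-Based Monitoring and Control of Fed-Batch Dilution Refolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, monitoring and control toolkit for inclusion-body
    dilution refolding operated in fed-batch mode. Implements the off-pathway
    refolding kinetics with denaturant-dependent rate constants, a fed-batch
    ODE simulator with reservoir-depletion phase switching, soft sensors for
    the refolding yield and space-time-yield, a seeded emulator of process
    analytical technology (PAT) measurements (sampling period, feedback delay,
    noise, limit of quantification), weighted least-squares kinetic parameter
    estimation with R2/NRMSE/AIC/BIC model qualification, unscented and
    extended Kalman state observers, and receding-horizon model predictive
    control of the feed rate with yield versus space-time-yield tradeoff
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
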