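test_that("validation metrics match hand-computed values", {
  vm <- validation_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(vm$r2, 1)
  expect_equal(vm$nrmse, 0)
  # constant prediction at the observation mean has r2 = 0
  vm0 <- validation_metrics(rep(1, 3), c(0, 1, 2))
  expect_equal(vm0$r2, 0)
  # three-point hand computation
  vm3 <- validation_metrics(c(0, 1, 4), c(0, 1, 2))
  expect_equal(vm3$r2, -1)
  expect_equal(vm3$nrmse, sqrt(4 / 3) / 2)
  expect_error(validation_metrics(c(1, 2), c(3, 3)), "identical")
  # alternative normalizations
  expect_equal(validation_metrics(c(0, 1, 4), c(0, 1, 2), "mean")$nrmse,
               sqrt(4 / 3) / 1)
})

test_that("information criteria penalize parameters correctly", {
  ic2 <- information_criteria(50, 30, 2)
  ic4 <- information_criteria(50, 30, 4)
  expect_equal(ic4$aic - ic2$aic, 4)
  ic <- information_criteria(100, 100, 2)
  expect_equal(ic$aic, 4)
  expect_equal(ic$bic, 2 * log(100))
  # BIC penalty exceeds AIC penalty for n > e^2
  expect_gt(ic$bic - ic$aic, 0)
  expect_warning(ic0 <- information_criteria(0, 10, 1), "degenerate")
  expect_equal(ic0$aic, -Inf)
  expect_error(information_criteria(1, 2, 2))
})

test_that("noise-free data at the true initial guess is a zero-residual fixed point", {
  sc <- baseline_scenario(t_end = 10)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 10, dt = 0.05)
  m <- generate_measurements(tr, species_sensors(0.5, rel = 0), seed = 1)
  fit <- fit_parameters(m, sc$initial, sc$res, sc$feed, sc$params,
                        free = list(k_r = c(1, 1e-3, 20),
                                    k_a = c(1, 1e-3, 20)),
                        sigma = c(c_SL = 1, c_NL = 1, c_AL = 1))
  expect_lt(fit$wrss, 1e-10)
  expect_equal(unname(fit$estimates), c(1, 1), tolerance = 1e-5)
  expect_true(fit$converged)
})

test_that("both rate constants are recovered from 5% noisy data", {
  sc <- baseline_scenario(t_end = 10)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 10, dt = 0.05)
  m <- generate_measurements(tr, species_sensors(10 / 50, rel = 0.05),
                             seed = 12)
  fit <- fit_parameters(m, sc$initial, sc$res, sc$feed, sc$params,
                        free = list(k_r = c(0.4, 1e-3, 20),
                                    k_a = c(0.4, 1e-3, 20)))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["k_r"]] - 1), 0.1)
  expect_lt(abs(fit$estimates[["k_a"]] - 1), 0.1)
  expect_true(all(fit$identifiable))
  expect_lt(fit$nrmse[["pooled"]], 0.15)
})

test_that("recovery error shrinks as measurement noise vanishes", {
  sc <- baseline_scenario(t_end = 10)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 10, dt = 0.05)
  noise_levels <- c(0.10, 0.05, 0.01, 0)
  med_err <- vapply(noise_levels, function(nl) {
    errs <- vapply(1:3, function(s) {
      m <- generate_measurements(tr, species_sensors(0.5, rel = nl),
                                 seed = 100 + s)
      fit <- fit_parameters(m, sc$initial, sc$res, sc$feed, sc$params,
                            free = list(k_r = c(0.4, 1e-3, 20),
                                        k_a = c(0.4, 1e-3, 20)))
      max(abs(fit$estimates - 1))
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 1e-8))
})

test_that("total-protein-only observation is flagged non-identifiable", {
  # c_PL obeys the mass balance regardless of the kinetics, so the WRSS
  # surface is flat in both rate constants
  sc <- baseline_scenario(t_end = 10)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 10, dt = 0.05)
  s <- sensor_spec("c_PL", sampling_period = 0.5, noise_sd_rel = 0.02)
  m <- generate_measurements(tr, s, seed = 3)
  fit <- fit_parameters(m, sc$initial, sc$res, sc$feed, sc$params,
                        free = list(k_r = c(0.5, 1e-3, 20),
                                    k_a = c(0.5, 1e-3, 20)))
  expect_false(any(fit$identifiable))
})

test_that("information criteria select the true aggregation order", {
  sc <- baseline_scenario(t_end = 10)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 10, dt = 0.05)
  prefer2 <- vapply(1:3, function(s) {
    m <- generate_measurements(tr, species_sensors(0.5, rel = 0.05),
                               seed = 200 + s)
    f2 <- fit_parameters(m, sc$initial, sc$res, sc$feed,
                         kinetic_parameters(n_agg = 2),
                         free = list(k_r = c(0.4, 1e-3, 20),
                                     k_a = c(0.4, 1e-3, 20)))
    f1 <- fit_parameters(m, sc$initial, sc$res, sc$feed,
                         kinetic_parameters(n_agg = 1),
                         free = list(k_r = c(0.4, 1e-3, 20),
                                     k_a = c(0.4, 1e-3, 20)))
    f2$aic < f1$aic && f2$bic < f1$bic
  }, logical(1))
  expect_true(all(prefer2))
})

test_that("fit inputs are validated and reports are written", {
  sc <- baseline_scenario(t_end = 5)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 5, dt = 0.1)
  m <- generate_measurements(tr, species_sensors(1), seed = 2)
  expect_error(fit_parameters(m, sc$initial, sc$res, sc$feed, sc$params,
                              free = list(k_r = c(0.5, 1, 2))),
               "bounds containing")
  expect_error(fit_parameters(m, sc$initial, sc$res, sc$feed, sc$params,
                              free = list(bogus = c(1, 0, 2))),
               "unknown free parameter")
  fit <- fit_parameters(m, sc$initial, sc$res, sc$feed, sc$params,
                        free = list(k_r = c(0.8, 1e-3, 20),
                                    k_a = c(0.8, 1e-3, 20)))
  path <- tempfile(fileext = ".txt")
  write_fit_report(fit, path)
  lines <- readLines(path)
  expect_true(any(grepl("^k_r:", lines)))
  expect_true(file.exists(sub("\\.txt$", "_residuals.csv", path)))
})
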