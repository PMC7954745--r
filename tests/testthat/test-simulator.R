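test_that("batch simulation matches the closed-form Bernoulli solution", {
  set.seed(31)
  for (i in 1:20) {
    c0 <- runif(1, 0.2, 5)
    k_r <- runif(1, 0.2, 3)
    k_a <- runif(1, 0, 3)
    p <- kinetic_parameters(k_r = k_r, k_a = k_a)
    tr <- simulate_refolding(vessel_state(V_L = 1, c_SL = c0),
                             reservoir_spec(0, 0, 0), constant_feed(0),
                             p, t_end = 5, dt = 0.25)
    an <- analytic_batch_solution(c0, k_r, k_a, tr$t_h)
    dev <- max(abs(tr$c_SL_g_L - an$c_SL), abs(tr$c_NL_g_L - an$c_NL),
               abs(tr$c_AL_g_L - an$c_AL)) / c0
    expect_lt(dev, 1e-6)
  }
})

test_that("analytic batch solution has the exact limits", {
  s0 <- analytic_batch_solution(2, 1, 1, 0)
  expect_equal(unname(unlist(s0[c("c_SL", "c_NL", "c_AL")])), c(2, 0, 0))
  # aggregation-free limit is pure first-order decay
  s <- analytic_batch_solution(1, 0.7, 0, c(1, 2))
  expect_equal(s$c_SL, exp(-0.7 * c(1, 2)))
  # asymptotic yield of the unit scenario is ln 2
  s_inf <- analytic_batch_solution(1, 1, 1, 200)
  expect_equal(s_inf$c_NL, log(2), tolerance = 1e-10)
  expect_equal(s_inf$c_SL + s_inf$c_NL + s_inf$c_AL, 1)
  expect_error(analytic_batch_solution(1, 1, 1, 1, n_agg = 1), "n_agg = 2")
  expect_error(analytic_batch_solution(1, 0, 1, 1), "positive")
})

test_that("aggregation-free refolding approaches complete yield", {
  p <- kinetic_parameters(k_r = 1, k_a = 0)
  tr <- simulate_refolding(vessel_state(V_L = 1, c_SL = 1),
                           reservoir_spec(0, 0, 0), constant_feed(0),
                           p, t_end = 20)
  expect_equal(tr$c_NL_g_L, 1 * (1 - exp(-tr$t_h)), tolerance = 1e-6)
  expect_gt(tr$c_NL_g_L[nrow(tr)], 1 - 1e-6)
})

test_that("reservoir depletion switches the phase exactly", {
  sc <- baseline_scenario()
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = sc$t_end, dt = 0.05)
  expect_equal(attr(tr, "t_dep"), 5.0, tolerance = 1e-9)
  expect_true(all(tr$phase[tr$t_h < 5 - 1e-9] == "fed_batch"))
  expect_true(all(tr$phase[tr$t_h >= 5] == "batch"))
  # volume frozen and feed terms dead after depletion
  post <- tr$V_L_L[tr$t_h >= 5]
  expect_equal(post, rep(1.5, length(post)), tolerance = 1e-9)
  # state continuous across the switch: straddle t_dep at 1e-6 h
  tr_fine <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                                t_end = 6, times = c(5 - 1e-6, 5, 5 + 1e-6))
  near <- abs(tr_fine$t_h - 5) <= 2e-6
  fine <- as.matrix(as.data.frame(tr_fine)[near, 2:7])
  expect_equal(sum(near), 3)
  expect_lt(max(abs(diff(fine))), 1e-5)
})

test_that("conservation laws hold along randomized fed-batch trajectories", {
  set.seed(41)
  for (i in 1:8) {
    V0 <- runif(1, 0.5, 2)
    ini <- vessel_state(V_L = V0, c_SL = runif(1, 0, 1),
                        c_DL = runif(1, 0, 1))
    res <- reservoir_spec(runif(1, 5, 20), runif(1, 4, 8), runif(1, 0.2, 1))
    F_R <- runif(1, 0.05, 0.3)
    p <- kinetic_parameters(mode = sample(c("constant",
                                            "denaturant_dependent"), 1),
                            k_r = runif(1, 0.3, 2), k_a = runif(1, 0, 2))
    tr <- simulate_refolding(ini, res, constant_feed(F_R), p, t_end = 15,
                             dt = 0.1)
    v_fed <- attr(tr, "v_fed")
    M0 <- attr(tr, "M0")
    total_mass <- tr$V_L_L * (tr$c_SL_g_L + tr$c_NL_g_L + tr$c_AL_g_L)
    scale_p <- max(total_mass, M0 + res$c_SR * res$V_R)
    expect_lt(max(abs(total_mass - M0 - res$c_SR * v_fed)) / scale_p, 1e-6)
    den_mass <- tr$V_L_L * tr$c_DL_mol_L
    scale_d <- max(den_mass)
    expect_lt(max(abs(den_mass - V0 * ini$c_DL - res$c_DR * v_fed)) /
                scale_d, 1e-6)
    # c_PL cross-check against the summed species balances
    expect_lt(max(abs(tr$c_PL_g_L -
                        (tr$c_SL_g_L + tr$c_NL_g_L + tr$c_AL_g_L))) /
                max(tr$c_PL_g_L), 1e-6)
    expect_true(all(as.matrix(tr[, 2:7]) > -1e-9))
  }
})

test_that("denaturant dilutes monotonically when fed below the vessel level", {
  ini <- vessel_state(V_L = 1, c_DL = 4)
  res <- reservoir_spec(10, 1, 0.5)  # c_DR < c_DL(0)
  p <- kinetic_parameters(k_r = 1, k_a = 1)
  tr <- simulate_refolding(ini, res, constant_feed(0.1), p, t_end = 6)
  expect_true(all(diff(tr$c_DL_mol_L) <= 1e-12))
})

test_that("halving the output grid step leaves reported states unchanged", {
  sc <- baseline_scenario(t_end = 10)
  tr1 <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                            t_end = 10, dt = 0.1)
  tr2 <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                            t_end = 10, dt = 0.05)
  common <- tr2$t_h %in% tr1$t_h
  for (col in c("c_SL_g_L", "c_NL_g_L", "c_AL_g_L", "c_DL_mol_L"))
    expect_equal(tr2[[col]][common], tr1[[col]], tolerance = 1e-7)
})

test_that("pulsed feeds and infeasible configurations are handled", {
  sc <- baseline_scenario()
  feed <- pulsed_feed(c(0, 2, 4), 1, 0.2)  # 0.6 L total demand > 0.5 L V_R
  tr <- simulate_refolding(sc$initial, sc$res, feed, sc$params, t_end = 8)
  expect_equal(attr(tr, "t_dep"), 4.5, tolerance = 1e-9)  # depletes mid-pulse
  expect_equal(max(attr(tr, "v_fed")), 0.5, tolerance = 1e-9)
  expect_error(simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                                  t_end = 10, V_max = 1.2),
               "V_max")
  expect_error(simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                                  t_end = 0), "t_end")
})

test_that("trajectory CSV round-trips with the fixed schema", {
  sc <- baseline_scenario(t_end = 2)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 2, dt = 0.5)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(names(back),
               c("t_h", "V_L_L", "c_SL_g_L", "c_NL_g_L", "c_AL_g_L",
                 "c_DL_mol_L", "c_PL_g_L", "k_r", "k_a", "phase"))
  expect_equal(back$c_NL_g_L, tr$c_NL_g_L, tolerance = 1e-12)
  bad <- back[, -3]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_trajectory_csv(path2), "c_SL_g_L")
})
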