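test_that("filter core reproduces the closed-form scalar Kalman recursion", {
  # scalar linear system x' = 0.9 x, y = x + noise
  a <- 0.9; Q <- 0.04; R <- 0.25
  f <- function(x) a * x
  h <- function(x) x
  set.seed(7)
  x_true <- 1
  for (filt in c("ukf", "ekf")) {
    x <- 0; P <- 1
    xk <- 0; Pk <- 1  # hand-rolled linear Kalman reference
    for (step in 1:30) {
      x_true <- a * x_true + rnorm(1, 0, sqrt(Q))
      y <- x_true + rnorm(1, 0, sqrt(R))
      if (filt == "ukf") {
        pr <- ukf_predict(x, P, f, matrix(Q, 1, 1))
        up <- ukf_update(pr$x, pr$P, h, matrix(R, 1, 1), y)
      } else {
        pr <- ekf_predict(x, P, f, matrix(Q, 1, 1))
        up <- ekf_update(pr$x, pr$P, h, matrix(R, 1, 1), y)
      }
      Pk_pred <- a^2 * Pk + Q
      K_ref <- Pk_pred / (Pk_pred + R)
      xk <- a * xk + K_ref * (y - a * xk)
      Pk <- (1 - K_ref) * Pk_pred
      tol <- if (filt == "ukf") 1e-10 else 1e-8
      expect_lt(abs(as.numeric(up$K) - K_ref), tol)
      expect_lt(abs(up$x - xk), 10 * tol)
      expect_lt(abs(as.numeric(up$P) - Pk), tol)
      x <- up$x; P <- as.numeric(up$P)
    }
  }
})

test_that("noiseless exact-init observer tracks the true state", {
  sc <- baseline_scenario(t_end = 8)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 8, dt = 0.05)
  sensors <- species_sensors(0.25, rel = 0, abs = 0)
  m <- generate_measurements(tr, sensors, seed = 1)
  cfg <- observer_config("ukf", x0 = sc$initial, P0 = 1e-8,
                         process_noise = 0, dt = 0.1)
  est <- run_observer(tr, m, cfg, sc$params, sc$res, sc$feed)
  for (col in c("c_SL_g_L", "c_NL_g_L", "c_AL_g_L", "c_DL_mol_L", "V_L_L")) {
    truth <- traj_at(tr, col, est$t_h)
    expect_lt(max(abs(est[[col]] - truth)), 1e-5)
  }
})

test_that("a step without measurements is pure prediction with covariance growth", {
  sc <- baseline_scenario()
  # small prior, non-trivial process noise: the injected noise dominates
  # the (contractive) kinetics so the prediction-only trace must grow
  cfg <- observer_config("ukf", x0 = sc$initial, P0 = 1e-8,
                         process_noise = 1e-4, dt = 0.5)
  est0 <- init_estimate(cfg, t = 0)
  est1 <- observer_step(est0, 0.1, NULL, cfg, sc$params, sc$res)
  # mean follows the deterministic model prediction
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 0.5, dt = 0.25)
  expect_equal(est1$mean[["c_SL"]], tr$c_SL_g_L[nrow(tr)], tolerance = 1e-5)
  expect_equal(est1$mean[["V_L"]], 1.05, tolerance = 1e-8)
  expect_gt(sum(diag(est1$P)), sum(diag(est0$P)))
  # covariance stays numerically PSD
  expect_gt(min(eigen(est1$P, symmetric = TRUE)$values), -1e-10)
})

test_that("filtering beats raw measurements and reconstructs unmeasured states", {
  sc <- baseline_scenario(t_end = 6)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 6, dt = 0.05)
  sensors <- list(sensor_spec("c_SL", 0.25, noise_sd_rel = 0.05,
                              noise_sd_abs = 0.02),
                  sensor_spec("c_NL", 0.25, noise_sd_rel = 0.05,
                              noise_sd_abs = 0.02))
  cfg <- observer_config("ukf", x0 = sc$initial, P0 = 1e-4,
                         process_noise = 1e-6, dt = 0.25)
  for (s in 1:3) {
    m <- generate_measurements(tr, sensors, seed = 300 + s)
    est <- run_observer(tr, m, cfg, sc$params, sc$res, sc$feed)
    for (q in c("c_SL", "c_NL")) {
      col <- paste0(q, "_g_L")
      truth <- traj_at(tr, col, est$t_h)
      raw <- stats::approx(m$t_sample_h[m$quantity == q],
                           m$value_g_L[m$quantity == q],
                           xout = est$t_h, rule = 2)$y
      rmse_f <- sqrt(mean((est[[col]] - truth)^2))
      rmse_r <- sqrt(mean((raw - truth)^2))
      expect_lt(rmse_f, rmse_r)
    }
    # aggregate is never measured yet finitely reconstructed
    truth_A <- traj_at(tr, "c_AL_g_L", est$t_h)
    expect_lt(sqrt(mean((est$c_AL_g_L - truth_A)^2)), 0.1)
  }
})

test_that("delayed chromatographic records are assimilated consistently", {
  sc <- baseline_scenario(t_end = 6)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 6, dt = 0.05)
  sensors <- list(sensor_preset("hplc_species", "c_SL"),
                  sensor_preset("hplc_species", "c_NL"))
  m <- generate_measurements(tr, sensors, seed = 17)
  expect_true(all(m$t_available_h - m$t_sample_h == 0.25))
  cfg <- observer_config("ukf", x0 = sc$initial, P0 = 1e-4,
                         process_noise = 1e-6, dt = 0.25)
  est <- run_observer(tr, m, cfg, sc$params, sc$res, sc$feed)
  truth <- traj_at(tr, "c_NL_g_L", est$t_h)
  expect_lt(sqrt(mean((est$c_NL_g_L - truth)^2)), 0.1)
})

test_that("innovations are statistically consistent under matched noise", {
  sc <- baseline_scenario(t_end = 8)
  tr <- simulate_refolding(sc$initial, sc$res, sc$feed, sc$params,
                           t_end = 8, dt = 0.05)
  sensors <- list(sensor_spec("c_SL", 0.2, noise_sd_abs = 0.05),
                  sensor_spec("c_NL", 0.2, noise_sd_abs = 0.05))
  m <- generate_measurements(tr, sensors, seed = 23)
  cfg <- observer_config("ukf", x0 = sc$initial, P0 = 1e-4,
                         process_noise = 1e-7, dt = 0.2)
  sched <- refoldcontrol:::.feed_schedule(sc$feed, sc$res, 0, 8)
  est <- init_estimate(cfg, t = 0)
  nis <- numeric(0)
  while (est$t < 8 - 1e-9) {
    t1 <- est$t + 0.2
    Fr <- refoldcontrol:::.schedule_rate(sched, est$t, t1)
    due <- m[m$t_available_h > est$t + 1e-12 & m$t_available_h <= t1 + 1e-12, ]
    est <- observer_step(est, Fr, due, cfg, sc$params, sc$res)
    if (!is.null(est$innovations))
      nis <- c(nis, est$innovations$innovation^2 / est$innovations$S)
  }
  band <- stats::qchisq(c(0.025, 0.975), df = 1)
  frac <- mean(nis >= band[1] & nis <= band[2])
  expect_gte(frac, 0.8)
})

test_that("observer configuration validates covariances", {
  expect_error(observer_config("ukf", x0 = rep(1, 5),
                               P0 = matrix(c(1, 2, 0, 0, 0,
                                             0, 1, 0, 0, 0,
                                             0, 0, 1, 0, 0,
                                             0, 0, 0, 1, 0,
                                             0, 0, 0, 0, 1), 5, 5)),
               "symmetric")
  expect_error(observer_config("ukf", x0 = rep(1, 5), P0 = 1, dt = 0),
               "positive")
  expect_error(observer_config("ukf", x0 = rep(1, 5), P0 = 1,
                               process_noise = -1), "non-negative")
})
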