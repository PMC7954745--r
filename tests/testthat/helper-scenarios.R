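# Shared fixture scenario: 1 L refolding buffer at 0.5 mol/L residual
# denaturant, 0.5 L reservoir of 10 g/L solubilizate in 6 mol/L denaturant,
# constant 0.1 L/h feed (depletion at exactly 5 h), constant-mode kinetics.
baseline_scenario <- function(t_end = 20, F_R = 0.1, c_SR = 10,
                              k_r = 1, k_a = 1) {
  list(initial = vessel_state(V_L = 1, c_DL = 0.5),
       res = reservoir_spec(c_SR = c_SR, c_DR = 6, V_R = 0.5),
       feed = constant_feed(F_R),
       params = kinetic_parameters(k_r = k_r, k_a = k_a),
       t_end = t_end)
}

# Three equal-rate species sensors with shared period and relative noise.
species_sensors <- function(period, rel = 0.05, abs = 0) {
  lapply(c("c_SL", "c_NL", "c_AL"), sensor_spec,
         sampling_period = period, noise_sd_rel = rel, noise_sd_abs = abs)
}

# Interpolate trajectory column at given times.
traj_at <- function(traj, column, t) {
  stats::approx(traj$t_h, traj[[column]], xout = t, rule = 2)$y
}

# Pooled NRMSE of a fitted model trajectory against noise-free truth,
# averaged over the three protein species.
state_nrmse <- function(traj_model, traj_truth) {
  mean(vapply(c("c_SL_g_L", "c_NL_g_L", "c_AL_g_L"), function(col) {
    y_hat <- traj_at(traj_model, col, traj_truth$t_h)
    validation_metrics(y_hat, traj_truth[[col]])$nrmse
  }, numeric(1)))
}

# Independent brute-force oracle: enumerate all slew-feasible sequences on
# the level grid with expand.grid and cost them through the full ODE
# simulator (not the controller's rollout).
oracle_mpc <- function(state, obj, params, res, F_prev, n_levels = 5) {
  levels <- seq(obj$F_min, obj$F_max, length.out = n_levels)
  grid <- do.call(expand.grid, rep(list(levels), obj$horizon))
  best <- list(cost = Inf, F_seq = NULL)
  for (i in seq_len(nrow(grid))) {
    Fs <- as.numeric(grid[i, ])
    slew <- diff(c(if (is.null(F_prev)) Fs[1] else F_prev, Fs))
    if (any(abs(slew) > obj$dF_max + 1e-12)) next
    feed <- feed_policy(state$t + (seq_along(Fs) - 1) * obj$dt_c,
                        state$t + seq_along(Fs) * obj$dt_c, Fs)
    tr <- simulate_refolding(state, res, feed, params,
                             t_end = state$t + obj$horizon * obj$dt_c,
                             times = state$t + seq_len(obj$horizon) * obj$dt_c)
    if (max(tr$V_L_L) > obj$V_max + 1e-9) next
    idx <- match(round(state$t + seq_len(obj$horizon) * obj$dt_c, 9),
                 round(tr$t_h, 9))
    Y <- ifelse(tr$c_PL_g_L[idx] > 0,
                tr$c_NL_g_L[idx] / tr$c_PL_g_L[idx], 0)
    STY <- ifelse(tr$t_h[idx] > 0, tr$c_NL_g_L[idx] / tr$t_h[idx], 0)
    cost <- sum(obj$w_Y * (obj$Y_ref - Y)^2 +
                  obj$w_STY * (obj$STY_ref - STY)^2)
    if (cost < best$cost) best <- list(cost = cost, F_seq = Fs)
  }
  best
}

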