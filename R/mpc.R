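## Receding-horizon model predictive control of the feed rate. The cost is
## quadratic tracking of the two KPIs (yield, space-time-yield) over the
## prediction horizon, subject to pump bounds, a slew (rate-of-change)
## limit, the vessel volume limit, and reservoir non-negativity. A
## slew-feasible exhaustive grid search doubles as the shipped optimizer
## seed and as the independent test oracle; a bounded quasi-Newton
## refinement polishes the grid optimum.

#' Control objective for the refolding MPC
#'
#' @param w_Y,w_STY Non-negative weights on the yield and space-time-yield
#'   tracking errors; at least one must be positive. The weighting encodes
#'   the process strategy: expensive upstream material favors yield,
#'   a refolding bottleneck favors productivity.
#' @param Y_ref Yield reference (fraction).
#' @param STY_ref Space-time-yield reference \[g/L/h\].
#' @param F_min,F_max Feed-rate bounds \[L/h\].
#' @param dF_max Maximum feed-rate change per control step \[L/h\]
#'   (prevents alternation between slack and high pump speeds).
#' @param V_max Vessel volume limit \[L\] (`Inf` to disable).
#' @param horizon Number of control steps in the prediction horizon, >= 1.
#' @param dt_c Control step \[h\].
#' @return Object of class `control_objective`.
#' @export
control_objective <- function(w_Y = 1, w_STY = 0, Y_ref = 1, STY_ref = 0,
                              F_min = 0, F_max, dF_max = Inf, V_max = Inf,
                              horizon = 10L, dt_c = 0.1) {
  if (w_Y < 0 || w_STY < 0 || w_Y + w_STY <= 0)
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  if (F_min > F_max) stop("F_min must not exceed F_max", call. = FALSE)
  if (dF_max < 0) stop("dF_max must be non-negative", call. = FALSE)
  if (horizon < 1) stop("horizon must be at least 1", call. = FALSE)
  if (dt_c <= 0) stop("control step must be positive", call. = FALSE)
  structure(list(w_Y = w_Y, w_STY = w_STY, Y_ref = Y_ref,
                 STY_ref = STY_ref, F_min = F_min, F_max = F_max,
                 dF_max = dF_max, V_max = V_max,
                 horizon = as.integer(horizon), dt_c = dt_c),
            class = "control_objective")
}

# Roll the 6-state (vessel + cumulative fed volume) forward over the
# horizon under a candidate feed sequence, capping each step exactly at
# reservoir depletion. Returns per-step KPI values and the final volume,
# or NULL if the volume limit is violated.
.mpc_rollout <- function(y6, t_now, F_seq, obj, params, res) {
  H <- length(F_seq)
  Y <- STY <- numeric(H)
  for (k in seq_len(H)) {
    t0 <- t_now + (k - 1) * obj$dt_c
    t1 <- t_now + k * obj$dt_c
    Fk <- F_seq[k]
    remaining <- res$V_R - y6[[6L]]
    if (remaining <= 1e-12) Fk <- 0
    if (Fk > 0 && Fk * obj$dt_c > remaining) {
      t_split <- t0 + remaining / Fk
      y6 <- .rk4_propagate(y6, t0, t_split, params, Fk, res)
      y6 <- .rk4_propagate(y6, t_split, t1, params, 0, res)
    } else {
      y6 <- .rk4_propagate(y6, t0, t1, params, Fk, res)
    }
    if (y6[[1L]] > obj$V_max + 1e-9) return(NULL)
    cP <- max(y6[[3L]], 0) + max(y6[[4L]], 0) + max(y6[[5L]], 0)
    Y[k] <- if (cP > 0) max(y6[[4L]], 0) / cP else 0
    STY[k] <- if (t1 > 0) max(y6[[4L]], 0) / t1 else 0
  }
  list(Y = Y, STY = STY, V_end = y6[[1L]])
}

.mpc_cost_of <- function(y6, t_now, F_seq, obj, params, res) {
  ro <- .mpc_rollout(y6, t_now, F_seq, obj, params, res)
  if (is.null(ro)) return(Inf)
  sum(obj$w_Y * (obj$Y_ref - ro$Y)^2 + obj$w_STY * (obj$STY_ref - ro$STY)^2)
}

#' Exhaustive grid-search solution of the MPC subproblem
#'
#' Enumerates every feed sequence on an `n_levels`-point grid between
#' `F_min` and `F_max` that satisfies the slew limit (including against the
#' previously applied rate), discards sequences violating the volume limit,
#' and returns the cheapest. Exponential in the horizon — intended as the
#' optimizer seed and as an independent oracle at small horizons.
#'
#' @inheritParams mpc_step
#' @param n_levels Number of grid levels per step.
#' @return List `(F_seq, cost)`; error if no admissible sequence exists.
#' @export
mpc_grid_search <- function(state, obj, params, res, v_fed = 0,
                            F_prev = NULL, n_levels = 5L) {
  y6 <- .mpc_initial_y6(state, v_fed)
  t_now <- .mpc_time(state)
  levels <- if (obj$F_max > obj$F_min)
    seq(obj$F_min, obj$F_max, length.out = n_levels) else obj$F_min
  best <- list(F_seq = NULL, cost = Inf)
  seqs <- list(numeric(0))
  for (k in seq_len(obj$horizon)) {
    nxt <- list()
    for (s in seqs) {
      ref <- if (k == 1) F_prev else s[k - 1]
      for (f in levels) {
        if (!is.null(ref) && abs(f - ref) > obj$dF_max + 1e-12) next
        nxt[[length(nxt) + 1L]] <- c(s, f)
      }
    }
    seqs <- nxt
    if (!length(seqs))
      stop("MPC infeasible: slew limit dF_max admits no grid sequence",
           call. = FALSE)
  }
  for (s in seqs) {
    cost <- .mpc_cost_of(y6, t_now, s, obj, params, res)
    if (cost < best$cost) best <- list(F_seq = s, cost = cost)
  }
  if (!is.finite(best$cost))
    stop("MPC infeasible: volume limit V_max violated by every admissible ",
         "feed sequence", call. = FALSE)
  best
}

.mpc_initial_y6 <- function(state, v_fed) {
  if (inherits(state, "state_estimate")) {
    m <- state$mean
    c(m[["V_L"]], m[["c_DL"]], m[["c_SL"]], m[["c_NL"]], m[["c_AL"]], v_fed)
  } else if (inherits(state, "vessel_state")) {
    c(state$V_L, state$c_DL, state$c_SL, state$c_NL, state$c_AL, v_fed)
  } else stop("state must be a state_estimate or vessel_state", call. = FALSE)
}

.mpc_time <- function(state) {
  if (inherits(state, "state_estimate")) state$t else state$t
}

#' One receding-horizon MPC step
#'
#' Minimizes the quadratic KPI-tracking cost
#' \deqn{J = \sum_{k=1}^{H} w_Y (Y_{ref} - \hat Y_k)^2 +
#'           w_{STY} (STY_{ref} - \widehat{STY}_k)^2}
#' over piecewise-constant feed sequences subject to the pump bounds, the
#' slew limit, the vessel volume limit and reservoir non-negativity. KPI
#' predictions roll the controller's internal model out from the current
#' state estimate (certainty equivalence); the STY uses global process
#' time. The solver seeds a bounded quasi-Newton refinement (slew and
#' volume violations penalized, then verified exactly) with the best
#' slew-feasible grid sequence, so its cost never exceeds the grid
#' optimum. Per the receding-horizon convention only the first move is
#' applied.
#'
#' @param state Current [vessel_state()] or `state_estimate` (observer
#'   mean).
#' @param obj A [control_objective()].
#' @param params Controller-side [kinetic_parameters()].
#' @param res A [reservoir_spec()].
#' @param v_fed Cumulative fed volume so far \[L\] (tracks reservoir
#'   depletion).
#' @param F_prev Previously applied feed rate \[L/h\]; the slew limit is
#'   enforced against it for the first move (`NULL` to leave the first move
#'   unconstrained).
#' @param n_levels Grid levels for the seeding search.
#' @param refine Run the continuous refinement (default `TRUE`).
#' @return List `(F_seq, F_apply, cost)`.
#' @export
mpc_step <- function(state, obj, params, res, v_fed = 0, F_prev = NULL,
                     n_levels = 5L, refine = TRUE) {
  y6 <- .mpc_initial_y6(state, v_fed)
  t_now <- .mpc_time(state)
  if (!is.null(obj$V_max) && is.finite(obj$V_max) &&
      y6[[1L]] + max(obj$F_min, 0) * obj$dt_c * obj$horizon >
        obj$V_max + 1e-9) {
    chk <- .mpc_rollout(y6, t_now, rep(obj$F_min, obj$horizon), obj, params,
                        res)
    if (is.null(chk))
      stop("MPC infeasible: F_min forces V_L beyond V_max within the horizon",
           call. = FALSE)
  }
  seed_sol <- mpc_grid_search(state, obj, params, res, v_fed, F_prev,
                              n_levels)
  best <- seed_sol
  if (refine && obj$F_max > obj$F_min) {
    pen_cost <- function(Fs) {
      slew <- diff(c(if (is.null(F_prev)) Fs[1] else F_prev, Fs))
      viol <- pmax(abs(slew) - obj$dF_max, 0)
      ro <- .mpc_rollout(y6, t_now, Fs, obj, params, res)
      vol_pen <- if (is.null(ro)) 1e8 else 0
      base <- if (is.null(ro)) 1e8 else
        sum(obj$w_Y * (obj$Y_ref - ro$Y)^2 +
              obj$w_STY * (obj$STY_ref - ro$STY)^2)
      base + 1e6 * sum(viol^2) + vol_pen
    }
    opt <- tryCatch(
      stats::optim(seed_sol$F_seq, pen_cost, method = "L-BFGS-B",
                   lower = rep(obj$F_min, obj$horizon),
                   upper = rep(obj$F_max, obj$horizon),
                   control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      Fs <- pmin(pmax(opt$par, obj$F_min), obj$F_max)
      slew_ok <- all(abs(diff(c(if (is.null(F_prev)) Fs[1] else F_prev,
                                Fs))) <= obj$dF_max + 1e-9)
      cost <- .mpc_cost_of(y6, t_now, Fs, obj, params, res)
      if (slew_ok && is.finite(cost) && cost < best$cost)
        best <- list(F_seq = Fs, cost = cost)
    }
  }
  list(F_seq = best$F_seq, F_apply = best$F_seq[1], cost = best$cost)
}

#' Run the full monitoring-and-control loop
#'
#' Closed-loop simulation of the proposed control architecture: at every
#' control step the PAT emulator releases the measurements that have become
#' available, the observer assimilates them, the MPC re-optimizes the feed
#' sequence from the state estimate, and the first move is applied to the
#' plant (simulated with its own — possibly perturbed — parameters).
#' Feeding ceases at reservoir depletion. Fully reproducible for a fixed
#' seed.
#'
#' @param initial Plant initial [vessel_state()].
#' @param res [reservoir_spec()].
#' @param plant_params True plant [kinetic_parameters()].
#' @param model_params Controller/observer model parameters (defaults to
#'   the plant's: no plant–model mismatch).
#' @param sensors List of [sensor_spec()]s (empty list runs the observer as
#'   a pure predictor).
#' @param obs_cfg [observer_config()]; its update step is forced to the
#'   control step.
#' @param obj [control_objective()].
#' @param t_end Final time \[h\].
#' @param seed RNG seed for the measurement noise (mandatory).
#' @param n_levels Grid levels for [mpc_step()].
#' @return A `closed_loop_result` list: `plant` (true trajectory at control
#'   grid, with KPI columns), `estimates` (observer means), `controls`
#'   (applied feed and predicted cost per step), `t_dep`, `seed`.
#' @export
run_closed_loop <- function(initial, res, plant_params,
                            model_params = plant_params, sensors, obs_cfg,
                            obj, t_end, seed, n_levels = 5L) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for the closed loop", call. = FALSE)
  if (inherits(sensors, "sensor_spec")) sensors <- list(sensors)
  t0 <- initial$t
  steps <- seq(t0, t_end, by = obj$dt_c)
  if (steps[length(steps)] < t_end) steps <- c(steps, t_end)

  # pre-draw the measurement noise on each sensor's own clock (determinism)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  schedules <- lapply(sensors, function(s) {
    ts <- seq(t0, t_end, by = s$sampling_period)
    data.frame(t_sample_h = ts, t_available_h = ts + s$feedback_delay,
               quantity = s$quantity, noise = stats::rnorm(length(ts)),
               sensor = s$name, taken = FALSE, truth = NA_real_,
               consumed = NA)
  })

  y6 <- c(initial$V_L, initial$c_DL, initial$c_SL, initial$c_NL,
          initial$c_AL, 0)
  obs_cfg$dt <- obj$dt_c
  est <- init_estimate(obs_cfg, t = t0)
  plant_rows <- list(); est_rows <- list(.estimate_row(est))
  ctrl_rows <- list()
  F_prev <- NULL
  t_dep <- NA_real_
  meas_buffer <- NULL

  plant_row <- function(t, y6) {
    cP <- sum(pmax(y6[3:5], 0))
    data.frame(t_h = t, V_L_L = y6[1], c_DL_mol_L = max(y6[2], 0),
               c_SL_g_L = max(y6[3], 0), c_NL_g_L = max(y6[4], 0),
               c_AL_g_L = max(y6[5], 0), c_PL_g_L = cP, v_fed_L = y6[6],
               yield = if (cP > 0) max(y6[4], 0) / cP else NA_real_,
               sty_g_L_h = if (t > 0) max(y6[4], 0) / t else 0)
  }
  plant_rows[[1]] <- plant_row(t0, y6)

  for (k in seq_len(length(steps) - 1L)) {
    tk <- steps[k]; tk1 <- steps[k + 1]
    # --- control decision from the current estimate
    sol <- mpc_step(est, obj, model_params, res, v_fed = y6[[6L]],
                    F_prev = F_prev, n_levels = n_levels)
    Fk <- sol$F_apply
    remaining <- res$V_R - y6[[6L]]
    if (remaining <= 1e-12) Fk <- 0
    # --- apply to the plant (split exactly at depletion)
    if (Fk > 0 && Fk * (tk1 - tk) >= remaining - 1e-15) {
      t_split <- tk + remaining / Fk
      if (is.na(t_dep)) t_dep <- t_split
      sub <- .sample_plant(y6, tk, t_split, plant_params, Fk, res,
                           schedules)
      y6 <- sub$y6; schedules <- sub$schedules
      sub <- .sample_plant(y6, t_split, tk1, plant_params, 0, res,
                           schedules)
      y6 <- sub$y6; schedules <- sub$schedules
    } else {
      sub <- .sample_plant(y6, tk, tk1, plant_params, Fk, res, schedules)
      y6 <- sub$y6; schedules <- sub$schedules
    }
    # --- release measurements that became available in this step
    due <- .due_measurements(schedules, sensors, tk, tk1)
    schedules <- due$schedules
    cfg_step <- obs_cfg; cfg_step$dt <- tk1 - tk
    est <- observer_step(est, Fk, .thin_measurements(due$records), cfg_step,
                         model_params, res)
    F_prev <- Fk
    plant_rows[[k + 1L]] <- plant_row(tk1, y6)
    est_rows[[k + 1L]] <- .estimate_row(est)
    ctrl_rows[[k]] <- data.frame(t_h = tk, F_applied_L_h = Fk,
                                 predicted_cost = sol$cost)
  }
  plant <- do.call(rbind, plant_rows)
  structure(list(plant = plant,
                 estimates = do.call(rbind, est_rows),
                 controls = do.call(rbind, ctrl_rows),
                 t_dep = t_dep, seed = as.integer(seed), objective = obj),
            class = "closed_loop_result")
}

# Propagate the plant over [t0, t1] under constant feed, filling in the
# truth (and measured value) for every sensor sample falling in the window.
.sample_plant <- function(y6, t0, t1, params, F_R, res, schedules) {
  for (j in seq_along(schedules)) {
    sc <- schedules[[j]]
    hit <- which(!sc$taken & sc$t_sample_h > t0 + 1e-12 &
                   sc$t_sample_h <= t1 + 1e-12)
    for (i in hit) {
      y6 <- .rk4_propagate(y6, t0, sc$t_sample_h[i], params, F_R, res)
      t0 <- sc$t_sample_h[i]
      truth <- switch(as.character(sc$quantity[i]),
                      c_SL = max(y6[3], 0), c_NL = max(y6[4], 0),
                      c_AL = max(y6[5], 0), c_DL = max(y6[2], 0),
                      c_PL = sum(pmax(y6[3:5], 0)))
      schedules[[j]]$truth[i] <- truth
      schedules[[j]]$taken[i] <- TRUE
    }
  }
  y6 <- .rk4_propagate(y6, t0, t1, params, F_R, res)
  list(y6 = y6, schedules = schedules)
}

# Turn sampled schedule rows whose availability time falls in (t0, t1]
# into measurement_set records (noise applied, LOQ censoring).
.due_measurements <- function(schedules, sensors, t0, t1) {
  recs <- NULL
  for (j in seq_along(schedules)) {
    sc <- schedules[[j]]; s <- sensors[[j]]
    hit <- which(sc$taken & !is.na(sc$truth) &
                   sc$t_available_h > t0 + 1e-12 &
                   sc$t_available_h <= t1 + 1e-12 &
                   is.na(sc$consumed))
    if (!length(hit)) next
    truth <- sc$truth[hit]
    sd <- s$noise_sd_abs + s$noise_sd_rel * truth
    value <- truth + sc$noise[hit] * sd
    censored <- truth < s$loq | value < s$loq
    value[censored] <- s$loq
    recs <- rbind(recs, data.frame(t_sample_h = sc$t_sample_h[hit],
                                   t_available_h = sc$t_available_h[hit],
                                   quantity = s$quantity, value_g_L = value,
                                   censored = censored, sensor = s$name))
    schedules[[j]]$consumed[hit] <- TRUE
  }
  if (!is.null(recs)) {
    recs <- recs[order(recs$t_available_h), , drop = FALSE]
    attr(recs, "sensors") <- sensors
    class(recs) <- c("measurement_set", "data.frame")
  }
  list(records = recs, schedules = schedules)
}

#' Realized closed-loop tracking cost
#'
#' Evaluates the same weighted quadratic KPI-tracking cost the MPC
#' minimizes, on the *realized* plant trajectory of a closed-loop run
#' (summed over control steps after the start).
#' @param result A `closed_loop_result`.
#' @param obj A [control_objective()] (defaults to the run's own).
#' @return Scalar realized cost.
#' @export
closed_loop_cost <- function(result, obj = result$objective) {
  p <- result$plant[-1, , drop = FALSE]
  y <- ifelse(is.na(p$yield), 0, p$yield)
  sum(obj$w_Y * (obj$Y_ref - y)^2 + obj$w_STY * (obj$STY_ref - p$sty_g_L_h)^2)
}

#' Write closed-loop results as CSV files
#'
#' Three files: `<prefix>_plant.csv`, `<prefix>_estimates.csv`,
#' `<prefix>_controls.csv`.
#' @param result A `closed_loop_result`.
#' @param prefix Path prefix.
#' @export
write_closed_loop_csv <- function(result, prefix) {
  utils::write.csv(result$plant, paste0(prefix, "_plant.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$estimates, paste0(prefix, "_estimates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$controls, paste0(prefix, "_controls.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
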