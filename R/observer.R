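## Nonlinear Bayesian state observation ("digital twin"): unscented and
## extended Kalman filtering of the vessel state (V_L, c_DL, c_SL, c_NL,
## c_AL) from delayed, noisy, partial PAT measurements. The filter core is
## generic (arbitrary propagation and measurement functions) so it can be
## verified against the closed-form scalar Kalman recursion.

.num_jacobian <- function(fn, x, fx = fn(x)) {
  n <- length(x); m <- length(fx)
  J <- matrix(0, m, n)
  for (i in seq_len(n)) {
    h <- max(1e-5, 1e-5 * abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

.psd_sqrt <- function(M) {
  # Cholesky with symmetric-eigen fallback for marginally PSD matrices
  M <- (M + t(M)) / 2
  ch <- tryCatch(t(chol(M)), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M)) %*% t(e$vectors)
}

.symmetrize_psd <- function(P, jitter = 1e-12) {
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    warning("covariance lost positive semidefiniteness; jitter applied")
    P <- P + diag(-min(ev) + jitter, nrow(P))
  }
  P
}

# Unscented transform sigma points (alpha = 1, beta = 2, kappa = 0):
# 2n+1 points, center weight 0 for the mean, 1/(2n) for the others.
.sigma_points <- function(x, P) {
  n <- length(x)
  S <- .psd_sqrt(n * P)
  pts <- cbind(x, x + S, x - S)
  wm <- c(0, rep(1 / (2 * n), 2 * n))
  wc <- c(2, rep(1 / (2 * n), 2 * n))
  list(pts = pts, wm = wm, wc = wc)
}

#' Low-level Kalman filter steps
#'
#' Generic unscented (`ukf_*`) and extended (`ekf_*`, finite-difference
#' Jacobians) prediction and update steps over arbitrary propagation
#' functions `f(x)` and measurement functions `h(x)`. On a linear system
#' both reduce exactly to the classical Kalman recursion (the UKF sigma
#' points transform linearly), which is how the implementation is verified.
#'
#' @param x State mean (numeric vector).
#' @param P State covariance (square matrix).
#' @param f Propagation function, `x -> x_next`.
#' @param h Measurement function, `x -> y_hat` (vector-valued allowed).
#' @param Q Process-noise covariance added after propagation.
#' @param R Measurement-noise covariance.
#' @param y Observed measurement vector.
#' @return For predictions, list `(x, P)`; for updates, list
#'   `(x, P, innovation, S, K)` with innovation covariance `S` and gain `K`.
#' @export
ukf_predict <- function(x, P, f, Q) {
  sp <- .sigma_points(x, P)
  prop <- apply(sp$pts, 2, f)
  if (is.null(dim(prop))) prop <- matrix(prop, nrow = 1)
  xn <- drop(prop %*% sp$wm)
  dev <- prop - xn
  Pn <- dev %*% diag(sp$wc, length(sp$wc)) %*% t(dev) + Q
  list(x = xn, P = .symmetrize_psd(Pn))
}

#' @rdname ukf_predict
#' @export
ukf_update <- function(x, P, h, R, y) {
  sp <- .sigma_points(x, P)
  Y <- apply(sp$pts, 2, h)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  yhat <- drop(Y %*% sp$wm)
  dy <- Y - yhat
  dx <- sp$pts - x
  W <- diag(sp$wc, length(sp$wc))
  S <- dy %*% W %*% t(dy) + R
  K <- dx %*% W %*% t(dy) %*% solve(S)
  innov <- y - yhat
  list(x = drop(x + K %*% innov),
       P = .symmetrize_psd(P - K %*% S %*% t(K)),
       innovation = innov, S = S, K = K)
}

#' @rdname ukf_predict
#' @export
ekf_predict <- function(x, P, f, Q) {
  Fm <- .num_jacobian(f, x)
  list(x = f(x), P = .symmetrize_psd(Fm %*% P %*% t(Fm) + Q))
}

#' @rdname ukf_predict
#' @export
ekf_update <- function(x, P, h, R, y) {
  H <- .num_jacobian(h, x)
  S <- H %*% P %*% t(H) + R
  K <- P %*% t(H) %*% solve(S)
  innov <- y - h(x)
  list(x = drop(x + K %*% innov),
       P = .symmetrize_psd((diag(length(x)) - K %*% H) %*% P),
       innovation = innov, S = S, K = K)
}

.state_names <- c("V_L", "c_DL", "c_SL", "c_NL", "c_AL")

#' Observer configuration
#'
#' @param filter `"ukf"` (default; no kinetics Jacobians needed) or `"ekf"`
#'   (finite-difference Jacobians).
#' @param x0 Initial state estimate: a [vessel_state()] or named numeric
#'   vector over `(V_L, c_DL, c_SL, c_NL, c_AL)`.
#' @param P0 Initial covariance: diagonal vector (length 5) or full matrix.
#' @param process_noise Continuous-time process-noise intensities per state
#'   (diagonal, length 5 or scalar); the per-step covariance added is
#'   `diag(process_noise) * dt`.
#' @param dt Observer update step \[h\], > 0.
#' @return Object of class `observer_config`.
#' @export
observer_config <- function(filter = c("ukf", "ekf"), x0, P0,
                            process_noise = 1e-6, dt = 0.1) {
  filter <- match.arg(filter)
  if (inherits(x0, "vessel_state"))
    x0 <- c(V_L = x0$V_L, c_DL = x0$c_DL, c_SL = x0$c_SL,
            c_NL = x0$c_NL, c_AL = x0$c_AL)
  stopifnot(length(x0) == 5)
  x0 <- stats::setNames(as.numeric(x0), .state_names)
  if (is.null(dim(P0))) {
    P0 <- diag(rep_len(as.numeric(P0), 5), 5)
  }
  if (max(abs(P0 - t(P0))) > 1e-12)
    stop("P0 must be symmetric", call. = FALSE)
  if (min(eigen(P0, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("P0 must be positive semidefinite", call. = FALSE)
  if (dt <= 0) stop("update step must be positive", call. = FALSE)
  q <- rep_len(as.numeric(process_noise), 5)
  if (any(q < 0)) stop("process noise must be non-negative", call. = FALSE)
  structure(list(filter = filter, x0 = x0, P0 = P0, q = q, dt = dt),
            class = "observer_config")
}

#' Initial state estimate from an observer configuration
#' @param cfg An [observer_config()].
#' @param t Start time \[h\].
#' @return A `state_estimate` with fields `t`, `mean`, `P`, `innovations`,
#'   `feed_log`.
#' @export
init_estimate <- function(cfg, t = 0) {
  structure(list(t = t, mean = cfg$x0, P = cfg$P0,
                 innovations = NULL,
                 feed_log = data.frame(t0 = numeric(), t1 = numeric(),
                                       F_R = numeric())),
            class = "state_estimate")
}

# Deterministic propagation of the 5-state vessel vector over [t0, t1]
# under the logged piecewise-constant feed (backward integration allowed,
# used to evaluate delayed measurements at their sample time).
.propagate_state <- function(x, t0, t1, feed_log, params, res,
                             n_sub = NULL) {
  if (abs(t1 - t0) < 1e-12) return(x)
  if (is.null(n_sub)) n_sub <- max(1L, ceiling(abs(t1 - t0) / 0.025))
  y <- c(x, 0)
  if (t1 > t0) {
    segs <- feed_log[feed_log$t1 > t0 + 1e-12 & feed_log$t0 < t1 - 1e-12, ,
                     drop = FALSE]
    if (!nrow(segs)) segs <- data.frame(t0 = t0, t1 = t1, F_R = 0)
  } else {
    segs <- feed_log[feed_log$t1 > t1 + 1e-12 & feed_log$t0 < t0 - 1e-12, ,
                     drop = FALSE]
    if (!nrow(segs)) segs <- data.frame(t0 = t1, t1 = t0, F_R = 0)
    segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  }
  for (i in seq_len(nrow(segs))) {
    a <- max(min(segs$t0[i], segs$t1[i]), min(t0, t1))
    b <- min(max(segs$t0[i], segs$t1[i]), max(t0, t1))
    if (b <= a) next
    ns <- max(1L, ceiling(n_sub * (b - a) / abs(t1 - t0)))
    if (t1 > t0) y <- .rk4_propagate(y, a, b, params, segs$F_R[i], res, ns)
    else y <- .rk4_propagate(y, b, a, params, segs$F_R[i], res, ns)
  }
  stats::setNames(y[1:5], .state_names)
}

#' One observer step: model prediction plus measurement update
#'
#' Predicts the state distribution over one update step by propagating the
#' fed-batch balances under the applied feed rate, then assimilates every
#' measurement record that has become available during the step. Delayed
#' records (availability time after sample time) are handled by evaluating
#' the measurement function through deterministic back-propagation of the
#' state to the sample time under the logged feed history — exact for the
#' deterministic dynamics between updates. Censored records are skipped.
#' With no new measurements the step is pure prediction and the covariance
#' trace cannot decrease.
#'
#' @param est A `state_estimate` (see [init_estimate()]).
#' @param F_R Feed rate applied over the step \[L/h\].
#' @param new_meas `measurement_set` rows with availability time in
#'   `(est$t, est$t + cfg$dt]`. Records sampled earlier are back-propagated
#'   as described above.
#' @param cfg An [observer_config()].
#' @param params Controller-side [kinetic_parameters()].
#' @param res A [reservoir_spec()].
#' @return Updated `state_estimate` at `est$t + cfg$dt`. The posterior mean
#'   concentrations are clipped at zero (covariance untouched).
#' @export
observer_step <- function(est, F_R, new_meas, cfg, params, res) {
  stopifnot(inherits(est, "state_estimate"), inherits(cfg, "observer_config"))
  t0 <- est$t; t1 <- t0 + cfg$dt
  feed_log <- rbind(est$feed_log,
                    data.frame(t0 = t0, t1 = t1, F_R = F_R))
  f <- function(x) .propagate_state(x, t0, t1, feed_log, params, res)
  Q <- diag(cfg$q * cfg$dt, 5)
  pred <- if (cfg$filter == "ukf") ukf_predict(est$mean, est$P, f, Q)
          else ekf_predict(est$mean, est$P, f, Q)
  x <- pred$x; P <- pred$P
  innovs <- NULL
  if (!is.null(new_meas) && nrow(new_meas)) {
    new_meas <- new_meas[!new_meas$censored, , drop = FALSE]
    if (nrow(new_meas)) {
      sig <- .measurement_sigma(new_meas)
      for (i in seq_len(nrow(new_meas))) {
        q_i <- new_meas$quantity[i]
        ts_i <- new_meas$t_sample_h[i]
        h <- function(xx) {
          xs <- if (abs(ts_i - t1) < 1e-12) xx
                else .propagate_state(xx, t1, ts_i, feed_log, params, res)
          switch(q_i,
                 c_SL = xs[["c_SL"]], c_NL = xs[["c_NL"]],
                 c_AL = xs[["c_AL"]], c_DL = xs[["c_DL"]],
                 c_PL = xs[["c_SL"]] + xs[["c_NL"]] + xs[["c_AL"]])
        }
        R <- matrix(max(sig[i]^2, 1e-12), 1, 1)
        upd <- if (cfg$filter == "ukf")
          ukf_update(x, P, h, R, new_meas$value_g_L[i])
        else ekf_update(x, P, h, R, new_meas$value_g_L[i])
        x <- upd$x; P <- upd$P
        innovs <- rbind(innovs,
                        data.frame(t_sample_h = ts_i, quantity = q_i,
                                   innovation = as.numeric(upd$innovation),
                                   S = as.numeric(upd$S)))
      }
    }
  }
  x[2:5] <- pmax(x[2:5], 0)  # concentrations cannot be negative
  names(x) <- .state_names
  structure(list(t = t1, mean = x, P = P, innovations = innovs,
                 feed_log = feed_log),
            class = "state_estimate")
}

#' Replay a full observation run over a simulated process
#'
#' Runs [observer_step()] on a fixed update grid over the span of a plant
#' trajectory, feeding it the measurement records as they become available
#' (availability time, not sample time). The applied feed is the effective
#' feed of the plant scenario (policy capped at reservoir depletion).
#'
#' @param traj Plant `refold_trajectory` (defines the time span and the
#'   true effective feed).
#' @param meas `measurement_set` generated from the plant.
#' @param cfg [observer_config()].
#' @param params Controller-side model parameters.
#' @param res [reservoir_spec()].
#' @param feed The plant [feed_policy()].
#' @param thin If `TRUE` (default), assimilate only the most recent
#'   available record per sensor channel in each update step. Seconds-scale
#'   sensors oversample the slow refolding dynamics heavily; the latest
#'   sample carries almost all of the step's information at a fraction of
#'   the cost.
#' @return An `observer_trajectory`: data.frame with the estimate mean and
#'   per-state posterior standard deviations on the update grid.
#' @export
run_observer <- function(traj, meas, cfg, params, res, feed, thin = TRUE) {
  t0 <- traj$t_h[1]; t_end <- traj$t_h[nrow(traj)]
  sched <- .feed_schedule(feed, res, t0, t_end)
  est <- init_estimate(cfg, t = t0)
  out <- list(.estimate_row(est))
  while (est$t < t_end - 1e-9) {
    t1 <- min(est$t + cfg$dt, t_end)
    Fr <- .schedule_rate(sched, est$t, t1)
    due <- meas[meas$t_available_h > est$t + 1e-12 &
                  meas$t_available_h <= t1 + 1e-12, , drop = FALSE]
    if (thin) due <- .thin_measurements(due)
    cfg_step <- cfg; cfg_step$dt <- t1 - est$t
    est <- observer_step(est, Fr, due, cfg_step, params, res)
    out[[length(out) + 1L]] <- .estimate_row(est)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  structure(df, class = c("observer_trajectory", "data.frame"))
}

# Keep the most recent uncensored record per (sensor, quantity) channel.
.thin_measurements <- function(due) {
  if (is.null(due) || !nrow(due)) return(due)
  keep <- unlist(lapply(split(seq_len(nrow(due)),
                              paste(due$sensor, due$quantity)),
                        function(idx) {
    unc <- idx[!due$censored[idx]]
    if (length(unc)) unc[which.max(due$t_sample_h[unc])]
    else idx[which.max(due$t_sample_h[idx])]
  }))
  due[sort(keep), , drop = FALSE]
}

# Mean effective feed rate of a schedule over [t0, t1] (piecewise constant;
# averages exactly if a breakpoint falls inside the step).
.schedule_rate <- function(sched, t0, t1) {
  iv <- sched$intervals
  tot <- 0
  for (i in seq_len(nrow(iv))) {
    a <- max(iv$t0[i], t0); b <- min(iv$t1[i], t1)
    if (b > a) tot <- tot + iv$F_R[i] * (b - a)
  }
  tot / (t1 - t0)
}

.estimate_row <- function(est) {
  sds <- sqrt(pmax(diag(est$P), 0))
  data.frame(t_h = est$t,
             V_L_L = est$mean[["V_L"]], c_DL_mol_L = est$mean[["c_DL"]],
             c_SL_g_L = est$mean[["c_SL"]], c_NL_g_L = est$mean[["c_NL"]],
             c_AL_g_L = est$mean[["c_AL"]],
             sd_V_L = sds[1], sd_c_DL = sds[2], sd_c_SL = sds[3],
             sd_c_NL = sds[4], sd_c_AL = sds[5])
}

#' Write an estimated trajectory as CSV
#' @param est_traj An `observer_trajectory` from [run_observer()].
#' @param path File path.
#' @export
write_estimates_csv <- function(est_traj, path) {
  utils::write.csv(as.data.frame(est_traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
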