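## Fed-batch / batch trajectory simulation.
##
## The feed policy is piecewise constant, so the cumulative fed volume is
## piecewise linear and the reservoir-depletion time is located exactly by
## arithmetic (no numeric root finding). Integration restarts at every feed
## breakpoint and at depletion, which keeps the phase switch sharp.

# Raw ODE right-hand side used by deSolve and by the fixed-step integrator.
# y = (V_L, c_DL, c_SL, c_NL, c_AL, V_fed). Rate terms evaluate the
# solubilized concentration clamped at zero so an integrator undershoot
# cannot generate spurious aggregation mass.
.vessel_rhs <- function(y, params, F_R, res) {
  V <- y[[1L]]
  if (V <= 0) stop("singular state: vessel volume reached zero", call. = FALSE)
  D <- y[[2L]]; S <- y[[3L]]; N <- y[[4L]]; A <- y[[5L]]
  if (params$mode == "constant") {
    kr <- params$k_r; ka <- params$k_a
  } else {
    base <- 1 + max(D, 0)
    kr <- params$a_r * base^params$b_r
    ka <- params$a_a * base^params$b_a
  }
  Sp <- max(S, 0)
  r_fold <- kr * Sp
  r_agg <- ka * Sp^params$n_agg
  dil <- F_R / V
  c(F_R,
    dil * (res$c_DR - D),
    -(r_fold + r_agg) + dil * (res$c_SR - S),
    r_fold - dil * N,
    r_agg - dil * A,
    F_R)
}

.desolve_rhs <- function(t, y, parms) {
  list(.vessel_rhs(y, parms$params, parms$F_R, parms$res))
}

# Classical RK4 with fixed substeps; used where many short deterministic
# predictions are needed (observer sigma points, MPC horizon rollouts).
.rk4_propagate <- function(y, t0, t1, params, F_R, res, n_sub = 8L) {
  h <- (t1 - t0) / n_sub
  if (h == 0) return(y)
  for (i in seq_len(n_sub)) {
    k1 <- .vessel_rhs(y, params, F_R, res)
    k2 <- .vessel_rhs(y + h / 2 * k1, params, F_R, res)
    k3 <- .vessel_rhs(y + h / 2 * k2, params, F_R, res)
    k4 <- .vessel_rhs(y + h * k3, params, F_R, res)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Effective feed schedule: policy segments clipped to [t0, t_end], feed
# forced to zero after cumulative volume reaches V_R. Returns the interval
# table (constant F_R each) and the exact depletion time (NA if the
# reservoir never empties before t_end).
.feed_schedule <- function(feed, res, t0, t_end) {
  seg <- feed$segments
  seg <- seg[seg$t_end > t0 & seg$t_start < t_end, , drop = FALSE]
  brk <- sort(unique(c(t0, t_end,
                       pmax(pmin(c(seg$t_start, seg$t_end), t_end), t0))))
  iv <- data.frame(t0 = brk[-length(brk)], t1 = brk[-1])
  iv$F_R <- feed_rate_at(feed, iv$t0)
  t_dep <- NA_real_
  if (res$V_R <= 0) {
    t_dep <- t0
    iv$F_R <- 0
  } else {
    cum <- 0
    for (i in seq_len(nrow(iv))) {
      dv <- iv$F_R[i] * (iv$t1[i] - iv$t0[i])
      if (cum + dv >= res$V_R - 1e-15 && iv$F_R[i] > 0) {
        t_dep <- iv$t0[i] + (res$V_R - cum) / iv$F_R[i]
        if (t_dep < iv$t1[i] - 1e-12) {
          # split the interval at depletion; later intervals get zero feed
          tail_iv <- data.frame(t0 = t_dep, t1 = iv$t1[i], F_R = 0)
          iv <- rbind(iv[seq_len(i), , drop = FALSE], tail_iv,
                      if (i < nrow(iv)) iv[(i + 1):nrow(iv), , drop = FALSE])
          iv$t1[i] <- t_dep
        }
        if (i < nrow(iv)) iv$F_R[(i + 1):nrow(iv)] <- 0
        break
      }
      cum <- cum + dv
    }
  }
  iv <- iv[iv$t1 > iv$t0 + 1e-15, , drop = FALSE]
  list(intervals = iv, t_dep = t_dep)
}

#' Simulate a fed-batch dilution refolding process
#'
#' Integrates the fed-batch species/volume/denaturant balances through the
#' feeding phase, switches to batch mode exactly when the reservoir is
#' depleted, and continues to `t_end` (the yield keeps developing during the
#' batch continuation). Uses `deSolve::lsoda` restarted at every feed
#' breakpoint and at the depletion time, which is located exactly from the
#' piecewise-linear cumulative fed volume.
#'
#' @param initial A [vessel_state()] at the start of the process.
#' @param res A [reservoir_spec()]. `V_R = 0` gives a pure batch process.
#' @param feed A [feed_policy()].
#' @param params A [kinetic_parameters()].
#' @param t_end Final process time \[h\].
#' @param dt Output grid step \[h\]; ignored if `times` is given. Default
#'   `(t_end - initial$t)/400`.
#' @param times Optional explicit output time grid \[h\].
#' @param rtol,atol Integrator relative/absolute tolerances (defaults 1e-8
#'   and 1e-10).
#' @param V_max Optional declared vessel volume limit \[L\]; a configuration
#'   in which the full reservoir cannot fit (`V_L(0) + V_R > V_max`) is
#'   rejected.
#' @return A `refold_trajectory`: a data.frame with columns
#'   `t_h, V_L_L, c_SL_g_L, c_NL_g_L, c_AL_g_L, c_DL_mol_L, c_PL_g_L,
#'   k_r, k_a, phase` and attributes `t_dep` (depletion time, `NA` if the
#'   reservoir never empties), `v_fed` (cumulative fed volume series) and
#'   `M0` (initial protein mass). Tiny negative integrator undershoots are
#'   clamped to zero in the reported table only.
#' @examples
#' tr <- simulate_refolding(vessel_state(V_L = 1, c_DL = 0.5),
#'                          reservoir_spec(c_SR = 10, c_DR = 6, V_R = 0.5),
#'                          constant_feed(0.1),
#'                          kinetic_parameters(k_r = 1, k_a = 1),
#'                          t_end = 20)
#' attr(tr, "t_dep")  # 5 h
#' @export
simulate_refolding <- function(initial, res, feed, params, t_end,
                               dt = NULL, times = NULL,
                               rtol = 1e-8, atol = 1e-10, V_max = NULL) {
  stopifnot(inherits(initial, "vessel_state"),
            inherits(res, "reservoir_spec"),
            inherits(feed, "feed_policy"),
            inherits(params, "kinetic_parameters"))
  t0 <- initial$t
  if (t_end <= t0) stop("t_end must exceed the initial time", call. = FALSE)
  if (!is.null(V_max) && initial$V_L + res$V_R > V_max + 1e-12)
    stop("infeasible configuration: V_L(0) + V_R exceeds V_max",
         call. = FALSE)

  sched <- .feed_schedule(feed, res, t0, t_end)
  if (is.null(times)) {
    if (is.null(dt)) dt <- (t_end - t0) / 400
    times <- seq(t0, t_end, by = dt)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  } else {
    times <- sort(as.numeric(times))
    if (times[1] < t0 - 1e-12 || times[length(times)] > t_end + 1e-12)
      stop("output times must lie in [initial$t, t_end]", call. = FALSE)
  }
  grid <- sort(c(times, sched$intervals$t0, sched$intervals$t1))
  grid <- grid[c(TRUE, diff(grid) > 1e-12)]

  y <- c(V_L = initial$V_L, c_DL = initial$c_DL, c_SL = initial$c_SL,
         c_NL = initial$c_NL, c_AL = initial$c_AL, V_fed = 0)
  out_t <- grid[1]
  out_y <- matrix(y, nrow = 1, dimnames = list(NULL, names(y)))
  for (i in seq_len(nrow(sched$intervals))) {
    iv <- sched$intervals[i, ]
    seg_t <- grid[grid >= iv$t0 - 1e-12 & grid <= iv$t1 + 1e-12]
    seg_t <- unique(c(iv$t0, seg_t, iv$t1))
    seg_t <- sort(seg_t[seg_t >= iv$t0 & seg_t <= iv$t1])
    sol <- deSolve::lsoda(y, seg_t, .desolve_rhs,
                          parms = list(params = params, F_R = iv$F_R,
                                       res = res),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure in [", iv$t0, ", ", iv$t1, "] h; last time ",
           max(sol[, 1]), call. = FALSE)
    y <- sol[nrow(sol), -1]
    keep <- sol[, 1] > out_t[length(out_t)] + 1e-12
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
  }

  t_dep <- sched$t_dep
  conc <- pmax(out_y[, c("c_SL", "c_NL", "c_AL", "c_DL")], 0)
  v_fed <- pmin(pmax(out_y[, "V_fed"], 0), res$V_R)
  M0 <- initial$V_L * (initial$c_SL + initial$c_NL + initial$c_AL)
  k <- rate_constants(params, conc[, "c_DL"])
  phase <- if (is.na(t_dep)) rep("fed_batch", length(out_t)) else
    ifelse(out_t < t_dep - 1e-12, "fed_batch", "batch")
  traj <- data.frame(t_h = out_t,
                     V_L_L = out_y[, "V_L"],
                     c_SL_g_L = conc[, "c_SL"],
                     c_NL_g_L = conc[, "c_NL"],
                     c_AL_g_L = conc[, "c_AL"],
                     c_DL_mol_L = conc[, "c_DL"],
                     c_PL_g_L = total_protein(v_fed, res, out_y[, "V_L"], M0),
                     k_r = k$k_r, k_a = k$k_a,
                     phase = phase,
                     row.names = NULL)
  structure(traj, t_dep = t_dep, v_fed = unname(v_fed), M0 = M0,
            class = c("refold_trajectory", "data.frame"))
}

#' Closed-form batch solution for second-order aggregation
#'
#' Exact solution of the batch balances with first-order refolding and
#' second-order aggregation (a Bernoulli equation in the solubilized
#' concentration):
#' \deqn{c_{SL}(t) = \frac{k_r c_0 e^{-k_r t}}{k_r + k_a c_0 (1 - e^{-k_r t})},
#'       \qquad
#'       c_{NL}(t) = \frac{k_r}{k_a}
#'         \ln\!\Big(1 + \frac{k_a c_0}{k_r}(1 - e^{-k_r t})\Big),}
#' with `c_AL = c0 - c_SL - c_NL` (exact mass closure). As `t` grows the
#' yield approaches `(k_r/(k_a c0)) ln(1 + k_a c0 / k_r)`. Used as an
#' independent oracle for the numerical simulator.
#'
#' @param c0 Initial solubilized protein concentration \[g/L\].
#' @param k_r Refolding rate constant \[1/h\], > 0.
#' @param k_a Aggregation rate coefficient \[L/g/h\], >= 0.
#' @param t Time(s) \[h\].
#' @param n_agg Must be 2 (the closed form is implemented for the default
#'   aggregation order only).
#' @return Data frame with columns `t`, `c_SL`, `c_NL`, `c_AL`.
#' @export
analytic_batch_solution <- function(c0, k_r, k_a, t, n_agg = 2L) {
  if (n_agg != 2L)
    stop("closed form implemented for n_agg = 2 only", call. = FALSE)
  if (k_r <= 0) stop("k_r must be positive", call. = FALSE)
  E <- exp(-k_r * t)
  if (k_a == 0) {
    c_SL <- c0 * E
    c_NL <- c0 * (1 - E)
  } else {
    g <- k_a * c0 * (1 - E) / k_r
    c_SL <- c0 * E / (1 + g)
    c_NL <- (k_r / k_a) * log1p(g)
  }
  data.frame(t = t, c_SL = c_SL, c_NL = c_NL, c_AL = c0 - c_SL - c_NL)
}

#' @export
print.refold_trajectory <- function(x, ...) {
  td <- attr(x, "t_dep")
  cat("Refolding trajectory: ", nrow(x), " points, t in [",
      signif(x$t_h[1], 4), ", ", signif(x$t_h[nrow(x)], 4), "] h; ",
      if (is.na(td)) "reservoir never depleted"
      else paste0("depletion at t = ", signif(td, 6), " h"), "\n", sep = "")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("... (", nrow(x) - 4, " more rows)\n", sep = "")
  invisible(x)
}

.trajectory_columns <- c("t_h", "V_L_L", "c_SL_g_L", "c_NL_g_L", "c_AL_g_L",
                         "c_DL_mol_L", "c_PL_g_L", "k_r", "k_a", "phase")

#' Write / read a trajectory as CSV
#'
#' Fixed column order `t_h, V_L_L, c_SL_g_L, c_NL_g_L, c_AL_g_L, c_DL_mol_L,
#' c_PL_g_L, k_r, k_a, phase`; units are embedded in the column names.
#' @param traj A `refold_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, .trajectory_columns],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trajectory_columns, names(df))
  if (length(missing_cols))
    stop("trajectory CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df[, .trajectory_columns]
}

# Linear interpolation of a trajectory column at arbitrary times.
.traj_interp <- function(traj, column, t) {
  stats::approx(traj$t_h, traj[[column]], xout = t, rule = 2)$y
}
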