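## Key performance indicators: refolding yield and space-time-yield,
## evaluated as soft sensors on simulated or estimated trajectories.

#' Refolding yield
#'
#' Quotient of native protein concentration over total protein concentration
#' in the vessel, a dimensionless fraction in \[0, 1\] for any consistent
#' trajectory.
#'
#' @param c_NL Native protein concentration(s) \[g/L\].
#' @param c_PL Total protein concentration(s) \[g/L\].
#' @return Yield fraction(s). A zero total protein concentration (empty
#'   vessel before the first feed) is an error for scalar input; the series
#'   builder [kpi_series()] reports `NA` there instead.
#' @export
refolding_yield <- function(c_NL, c_PL) {
  if (any(c_NL < 0) || any(c_PL < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (length(c_PL) == 1L && c_PL == 0)
    stop("yield undefined: total protein concentration is zero",
         call. = FALSE)
  ifelse(c_PL > 0, c_NL / c_PL, NA_real_)
}

#' Space-time-yield
#'
#' Native protein produced per vessel volume and per process time,
#' `c_NL / t` \[g/L/h\]. At `t = 0` the value is 0 by convention: starting
#' from an empty vessel the native concentration grows quadratically in
#' time, so the ratio has limit zero.
#'
#' @param c_NL Native protein concentration(s) \[g/L\].
#' @param t Process time(s) \[h\], >= 0.
#' @return Space-time-yield(s) \[g/L/h\].
#' @export
space_time_yield <- function(c_NL, t) {
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  ifelse(t > 0, c_NL / t, 0)
}

#' KPI series along a trajectory
#'
#' Evaluates both soft sensors at every grid point and summarizes them with
#' the maximum yield over the whole trajectory (the yield keeps rising in the
#' batch continuation after depletion) and the mean space-time-yield over the
#' fed-batch phase (trapezoidal time average of the instantaneous STY over
#' `[t0, t_dep]`).
#'
#' @param traj A `refold_trajectory` from [simulate_refolding()].
#' @param denominator Yield denominator: `"instantaneous"` (default) uses
#'   `c_PL(t)` at each point; `"final"` and `"max"` evaluate every point
#'   against the final / maximal total protein concentration.
#' @return A `kpi_series`: data.frame with columns `t_h`, `yield`,
#'   `sty_g_L_h`, and attributes `max_yield`, `mean_sty_fedbatch`
#'   (`NA` when there is no fed-batch phase), `t_dep`.
#' @export
kpi_series <- function(traj,
                       denominator = c("instantaneous", "final", "max")) {
  stopifnot(inherits(traj, "refold_trajectory"))
  denominator <- match.arg(denominator)
  c_PL <- switch(denominator,
                 instantaneous = traj$c_PL_g_L,
                 final = rep(traj$c_PL_g_L[nrow(traj)], nrow(traj)),
                 max = rep(max(traj$c_PL_g_L), nrow(traj)))
  yield <- ifelse(c_PL > 0, traj$c_NL_g_L / c_PL, NA_real_)
  sty <- space_time_yield(traj$c_NL_g_L, traj$t_h)
  t_dep <- attr(traj, "t_dep")
  t0 <- traj$t_h[1]
  mean_sty <- NA_real_
  fb_end <- if (is.na(t_dep)) traj$t_h[nrow(traj)] else t_dep
  if (fb_end > t0 + 1e-12) {
    sel <- traj$t_h <= fb_end + 1e-12
    mean_sty <- .trapz(traj$t_h[sel], sty[sel]) / (traj$t_h[max(which(sel))] - t0)
  }
  structure(data.frame(t_h = traj$t_h, yield = yield, sty_g_L_h = sty),
            max_yield = max(yield, na.rm = TRUE),
            mean_sty_fedbatch = mean_sty,
            t_dep = t_dep,
            class = c("kpi_series", "data.frame"))
}

#' Feed-rate Pareto sweep of yield versus space-time-yield
#'
#' Re-simulates one scenario under a set of constant feed rates (otherwise
#' equal conditions: same initial state, reservoir, kinetics and `t_end`)
#' and records, per rate, the maximal yield over the full trajectory and the
#' mean space-time-yield over the fed-batch phase. Slow feeding buys yield at
#' the cost of productivity; the sweep traces that tradeoff frontier.
#'
#' @param initial A [vessel_state()].
#' @param res A [reservoir_spec()].
#' @param params A [kinetic_parameters()].
#' @param feed_rates Constant feed rates to sweep \[mL/min\] (the pump-facing
#'   unit; converted internally to L/h).
#' @param t_end Common final time \[h\]; must allow the slowest feed to
#'   deplete the reservoir for a full-frontier comparison.
#' @param dt Overall output step \[h\] (default `t_end/200`); the fed-batch
#'   window is additionally resolved with 300 points so the mean STY is
#'   well integrated even when depletion is fast.
#' @param ... Further arguments passed to [simulate_refolding()].
#' @return A `pareto_result`: data.frame with columns `feed_rate_mL_min`,
#'   `max_yield`, `mean_sty_g_L_h`, `t_dep_h`, `error` (NA unless that
#'   member simulation failed; failures never abort the sweep), ordered by
#'   feed rate.
#' @examples
#' \donttest{
#' ps <- pareto_sweep(vessel_state(V_L = 1, c_DL = 0.5),
#'                    reservoir_spec(c_SR = 10, c_DR = 6, V_R = 0.5),
#'                    kinetic_parameters(k_r = 1, k_a = 1),
#'                    feed_rates = c(0.5, 2, 8), t_end = 40)
#' }
#' @export
pareto_sweep <- function(initial, res, params, feed_rates, t_end,
                         dt = NULL, ...) {
  stopifnot(length(feed_rates) >= 1)
  feed_rates <- sort(as.numeric(feed_rates))
  out <- data.frame(feed_rate_mL_min = feed_rates,
                    max_yield = NA_real_, mean_sty_g_L_h = NA_real_,
                    t_dep_h = NA_real_, error = NA_character_)
  for (i in seq_along(feed_rates)) {
    F_L_h <- mL_min_to_L_h(feed_rates[i])
    # resolve the fed-batch window explicitly: the mean-STY trapezoid over
    # [0, t_dep] needs a fine grid even when t_dep << t_end
    times <- seq(initial$t, t_end, length.out = if (is.null(dt)) 201
                 else max(2, ceiling((t_end - initial$t) / dt) + 1))
    if (F_L_h > 0 && res$V_R > 0) {
      t_dep_i <- initial$t + res$V_R / F_L_h
      if (t_dep_i < t_end)
        times <- sort(unique(c(times, seq(initial$t, t_dep_i,
                                          length.out = 301))))
    }
    res_i <- tryCatch({
      tr <- simulate_refolding(initial, res, constant_feed(F_L_h), params,
                               t_end = t_end, times = times, ...)
      kp <- kpi_series(tr)
      list(my = attr(kp, "max_yield"), ms = attr(kp, "mean_sty_fedbatch"),
           td = attr(tr, "t_dep"))
    }, error = function(e) e)
    if (inherits(res_i, "error")) {
      out$error[i] <- conditionMessage(res_i)
    } else {
      out$max_yield[i] <- res_i$my
      out$mean_sty_g_L_h[i] <- res_i$ms
      out$t_dep_h[i] <- res_i$td
    }
  }
  structure(out, class = c("pareto_result", "data.frame"))
}

#' Log- or linearly spaced feed-rate grids
#'
#' Helper to build the swept rates, e.g. 20 rates between 0.015 and
#' 10 mL/min. Log spacing (default) resolves the low-rate, high-yield end of
#' the frontier.
#' @param from,to Range \[mL/min\].
#' @param n Number of rates.
#' @param spacing `"log"` or `"linear"`.
#' @return Numeric vector of feed rates \[mL/min\].
#' @export
feed_rate_grid <- function(from = 0.015, to = 10, n = 20,
                           spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  stopifnot(from > 0 || spacing == "linear", to > from, n >= 1)
  if (n == 1) return(from)
  if (spacing == "log") exp(seq(log(from), log(to), length.out = n))
  else seq(from, to, length.out = n)
}

#' Write a Pareto sweep result as CSV
#'
#' Columns `feed_rate_mL_min, max_yield, mean_sty_g_L_h`, ordered by feed
#' rate.
#' @param pareto A `pareto_result`.
#' @param path Output file path.
#' @export
write_pareto_csv <- function(pareto, path) {
  utils::write.csv(as.data.frame(pareto)[, c("feed_rate_mL_min", "max_yield",
                                             "mean_sty_g_L_h")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
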