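#' Kinetic parameters of the off-pathway refolding model
#'
#' Bundles the rate-law parameters of the competing first-order refolding and
#' n-th order aggregation reactions that consume solubilized protein. Two
#' modes are supported: `"constant"` rate constants, and
#' `"denaturant_dependent"` constants of the form
#' \deqn{k_i = a_i (1 + c_{DL})^{b_i}, \quad i \in \{r, a\},}
#' where `c_DL` is the numeric value of the vessel denaturant concentration in
#' mol/L (i.e. relative to a 1 mol/L reference, so the base of the power is
#' dimensionless).
#'
#' The refolding literature reports second-order aggregation
#' (`n_agg = 2`, the default) with first-order aggregation appropriate at low
#' protein concentrations (`n_agg = 1`). No published numeric values are
#' shipped: the package defaults are documented synthetic fixtures.
#'
#' @param mode `"constant"` or `"denaturant_dependent"`.
#' @param k_r Refolding rate constant \[1/h\] (constant mode).
#' @param k_a Aggregation rate coefficient \[L^(n-1) g^(1-n) / h\]
#'   (constant mode).
#' @param a_r,a_a Pre-factors of the denaturant power law (same units as
#'   `k_r`, `k_a`).
#' @param b_r,b_a Dimensionless exponents of the denaturant power law.
#'   Negative exponents make increasing denaturant slow the reaction down.
#' @param n_agg Aggregation reaction order, integer >= 1. Default 2.
#' @return Object of class `kinetic_parameters`.
#' @examples
#' kinetic_parameters(k_r = 1, k_a = 1)
#' kinetic_parameters(mode = "denaturant_dependent",
#'                    a_r = 2, b_r = -1, a_a = 8, b_a = -3)
#' @export
kinetic_parameters <- function(mode = c("constant", "denaturant_dependent"),
                               k_r = 1, k_a = 1,
                               a_r = 2, b_r = -1, a_a = 8, b_a = -3,
                               n_agg = 2L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n_agg), length(n_agg) == 1L, n_agg >= 1,
            n_agg == round(n_agg))
  if (mode == "constant") {
    if (k_r < 0 || k_a < 0)
      stop("rate constants k_r, k_a must be non-negative", call. = FALSE)
  } else {
    if (a_r < 0 || a_a < 0)
      stop("pre-factors a_r, a_a must be non-negative", call. = FALSE)
  }
  structure(list(mode = mode,
                 k_r = as.numeric(k_r), k_a = as.numeric(k_a),
                 a_r = as.numeric(a_r), b_r = as.numeric(b_r),
                 a_a = as.numeric(a_a), b_a = as.numeric(b_a),
                 n_agg = as.integer(n_agg)),
            class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Refolding kinetics (", x$mode, " mode, aggregation order ",
      x$n_agg, ")\n", sep = "")
  if (x$mode == "constant") {
    cat(sprintf("  k_r = %g 1/h, k_a = %g (L/g)^%d/h\n",
                x$k_r, x$k_a, x$n_agg - 1L))
  } else {
    cat(sprintf("  k_r = %g*(1+c_DL)^%g, k_a = %g*(1+c_DL)^%g\n",
                x$a_r, x$b_r, x$a_a, x$b_a))
  }
  invisible(x)
}

#' Instantaneous refolding-vessel state
#'
#' @param t Process time \[h\].
#' @param V_L Liquid volume in the refolding vessel \[L\].
#' @param c_SL Solubilized (denatured) protein concentration \[g/L\].
#' @param c_NL Native protein concentration \[g/L\].
#' @param c_AL Aggregated protein concentration \[g/L\].
#' @param c_DL Denaturant concentration \[mol/L\].
#' @return Object of class `vessel_state` (a named numeric list).
#' @examples
#' vessel_state(V_L = 1, c_DL = 0.5)
#' @export
vessel_state <- function(t = 0, V_L, c_SL = 0, c_NL = 0, c_AL = 0, c_DL = 0) {
  vals <- c(t = t, V_L = V_L, c_SL = c_SL, c_NL = c_NL,
            c_AL = c_AL, c_DL = c_DL)
  if (any(!is.finite(vals)))
    stop("vessel state must be finite", call. = FALSE)
  if (V_L <= 0)
    stop("vessel volume V_L must be positive", call. = FALSE)
  if (t < 0 || c_SL < 0 || c_NL < 0 || c_AL < 0 || c_DL < 0)
    stop("time and concentrations must be non-negative", call. = FALSE)
  structure(as.list(vals), class = "vessel_state")
}

#' Feed reservoir specification
#'
#' The finite reservoir holds protein in the solubilized form only, dissolved
#' in denaturant; it contributes no native or aggregated protein inflow. Once
#' the cumulative fed volume reaches `V_R` the reservoir is depleted and the
#' effective feed rate drops to zero (batch continuation).
#'
#' @param c_SR Solubilized protein concentration in the reservoir \[g/L\].
#' @param c_DR Denaturant concentration in the reservoir \[mol/L\].
#' @param V_R Initial reservoir volume \[L\].
#' @return Object of class `reservoir_spec`.
#' @export
reservoir_spec <- function(c_SR, c_DR, V_R) {
  if (c_SR < 0 || c_DR < 0 || V_R < 0)
    stop("reservoir fields must be non-negative", call. = FALSE)
  structure(list(c_SR = as.numeric(c_SR), c_DR = as.numeric(c_DR),
                 V_R = as.numeric(V_R)),
            class = "reservoir_spec")
}

#' Piecewise-constant feed-rate policy
#'
#' Solubilizate can be added drop-wise, pulsed, or as a constant fed-batch
#' stream; all are represented as ordered, non-overlapping segments of
#' constant feed rate. Outside every segment the feed rate is zero, and the
#' simulator forces it to zero once the reservoir is depleted regardless of
#' the policy.
#'
#' @param t_start,t_end Segment boundaries \[h\]; vectors of equal length.
#' @param F_R Feed rate per segment \[L/h\], non-negative.
#' @return Object of class `feed_policy` holding a `data.frame` of segments.
#' @seealso [constant_feed()], [pulsed_feed()]
#' @export
feed_policy <- function(t_start, t_end, F_R) {
  stopifnot(length(t_start) == length(t_end),
            length(t_start) == length(F_R))
  seg <- data.frame(t_start = as.numeric(t_start),
                    t_end = as.numeric(t_end),
                    F_R = as.numeric(F_R))
  seg <- seg[order(seg$t_start), , drop = FALSE]
  if (any(seg$F_R < 0))
    stop("feed rates must be non-negative", call. = FALSE)
  if (any(seg$t_end <= seg$t_start))
    stop("each feed segment needs t_end > t_start", call. = FALSE)
  if (nrow(seg) > 1 &&
      any(seg$t_start[-1] < seg$t_end[-nrow(seg)] - 1e-12))
    stop("feed segments must not overlap", call. = FALSE)
  structure(list(segments = seg), class = "feed_policy")
}

#' @rdname feed_policy
#' @param t_start Feed start \[h\].
#' @param t_end Feed stop \[h\]; may be `Inf` (feed until reservoir depletion).
#' @export
constant_feed <- function(F_R, t_start = 0, t_end = Inf) {
  feed_policy(t_start, t_end, F_R)
}

#' @rdname feed_policy
#' @param pulse_times Start times of the pulses \[h\].
#' @param pulse_duration Duration of each pulse \[h\].
#' @param pulse_rate Feed rate during each pulse \[L/h\].
#' @export
pulsed_feed <- function(pulse_times, pulse_duration, pulse_rate) {
  feed_policy(pulse_times, pulse_times + pulse_duration,
              rep_len(pulse_rate, length(pulse_times)))
}

#' Evaluate the feed policy at given times (before depletion capping)
#' @param feed A `feed_policy`.
#' @param t Times \[h\].
#' @return Feed rate(s) \[L/h\].
#' @export
feed_rate_at <- function(feed, t) {
  stopifnot(inherits(feed, "feed_policy"))
  seg <- feed$segments
  out <- numeric(length(t))
  for (i in seq_len(nrow(seg))) {
    hit <- t >= seg$t_start[i] & t < seg$t_end[i]
    out[hit] <- seg$F_R[i]
  }
  out
}

#' Denaturant-dependent rate constants
#'
#' In `"constant"` mode returns `(k_r, k_a)` unchanged; in
#' `"denaturant_dependent"` mode evaluates the power law
#' `k_i = a_i * (1 + c_DL)^b_i`. Vectorized over `c_DL`.
#'
#' @param params A [kinetic_parameters()] object.
#' @param c_DL Vessel denaturant concentration(s) \[mol/L\], >= 0.
#' @return List with numeric components `k_r` and `k_a` (same length as
#'   `c_DL`).
#' @examples
#' p <- kinetic_parameters(mode = "denaturant_dependent", a_r = 8, b_r = -3)
#' rate_constants(p, 1)$k_r  # 8 * 2^-3 = 1
#' @export
rate_constants <- function(params, c_DL) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(c_DL < 0))
    stop("denaturant concentration must be non-negative", call. = FALSE)
  if (params$mode == "constant") {
    list(k_r = rep_len(params$k_r, length(c_DL)),
         k_a = rep_len(params$k_a, length(c_DL)))
  } else {
    list(k_r = params$a_r * (1 + c_DL)^params$b_r,
         k_a = params$a_a * (1 + c_DL)^params$b_a)
  }
}

#' Batch reaction right-hand side
#'
#' Species balances of the closed (no-feed) dilution refolding system:
#' first-order productive refolding competing with n-th order off-pathway
#' aggregation,
#' \deqn{dc_{SL}/dt = -(k_r c_{SL} + k_a c_{SL}^{n}),\quad
#'       dc_{NL}/dt = k_r c_{SL},\quad dc_{AL}/dt = k_a c_{SL}^{n}.}
#' The three derivatives sum to zero: a closed batch conserves protein mass.
#'
#' @param state A [vessel_state()].
#' @param params A [kinetic_parameters()]; rate constants are evaluated at
#'   the state's denaturant concentration.
#' @return Named numeric vector `c(dc_SL, dc_NL, dc_AL)` \[g/L/h\].
#' @export
batch_derivatives <- function(state, params) {
  stopifnot(inherits(state, "vessel_state"))
  k <- rate_constants(params, state$c_DL)
  r_fold <- k$k_r * state$c_SL
  r_agg <- k$k_a * state$c_SL^params$n_agg
  c(dc_SL = -(r_fold + r_agg), dc_NL = r_fold, dc_AL = r_agg)
}

#' Fed-batch reaction right-hand side
#'
#' Extends the batch balances with the feed and dilution terms of fed-batch
#' operation: the vessel volume grows at the feed rate, and every vessel
#' concentration is diluted at specific rate `F_R / V_L` while solubilized
#' protein and denaturant flow in at reservoir composition.
#'
#' @param state A [vessel_state()].
#' @param params A [kinetic_parameters()].
#' @param F_R Instantaneous feed rate \[L/h\], >= 0.
#' @param res A [reservoir_spec()].
#' @return Named numeric vector
#'   `c(dV_L, dc_DL, dc_SL, dc_NL, dc_AL)`.
#' @export
fedbatch_derivatives <- function(state, params, F_R, res) {
  stopifnot(inherits(state, "vessel_state"), inherits(res, "reservoir_spec"))
  if (F_R < 0) stop("feed rate must be non-negative", call. = FALSE)
  if (state$V_L <= 0)
    stop("singular state: vessel volume must be positive", call. = FALSE)
  d <- batch_derivatives(state, params)
  dil <- F_R / state$V_L
  c(dV_L = F_R,
    dc_DL = dil * (res$c_DR - state$c_DL),
    dc_SL = d[["dc_SL"]] + dil * (res$c_SR - state$c_SL),
    dc_NL = d[["dc_NL"]] - dil * state$c_NL,
    dc_AL = d[["dc_AL"]] - dil * state$c_AL)
}

#' Total protein concentration soft sensor
#'
#' Cumulative-mass-balance generalization of the total protein concentration:
#' \deqn{c_{PL}(t) = (M_0 + c_{SR} V_{fed}(t)) / V_L(t),}
#' where `M_0` is the protein mass present at time zero and `V_fed` the
#' cumulative fed volume (capped at the reservoir volume). For a constant
#' feed rate, zero initial protein, and no depletion this reduces to the
#' textbook form `c_PL = F_R * t * c_SR / V_L`.
#'
#' @param v_fed Cumulative fed volume series \[L\], non-decreasing, capped at
#'   `res$V_R`.
#' @param res A [reservoir_spec()].
#' @param V_L Vessel volume series \[L\], same length as `v_fed`.
#' @param initial_protein_mass Protein mass present at t = 0 \[g\].
#' @return Total protein concentration series \[g/L\].
#' @export
total_protein <- function(v_fed, res, V_L, initial_protein_mass = 0) {
  stopifnot(inherits(res, "reservoir_spec"),
            length(v_fed) == length(V_L))
  if (any(V_L <= 0))
    stop("singular state: vessel volume must be positive", call. = FALSE)
  if (any(diff(v_fed) < -1e-12))
    stop("cumulative fed volume must be non-decreasing", call. = FALSE)
  if (any(v_fed > res$V_R + 1e-9))
    stop("cumulative fed volume exceeds reservoir volume", call. = FALSE)
  (initial_protein_mass + res$c_SR * v_fed) / V_L
}
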