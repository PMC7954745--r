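## Scenario configuration: one YAML dialect, strict validation (unknown keys
## are rejected by name), canonical dump for reproducible round-trips.
## Units are embedded in key names throughout.

.known_keys <- list(
  top = c("vessel", "reservoir", "kinetics", "feed", "sensors", "observer",
          "objective", "simulation"),
  vessel = c("t_h", "V_L_L", "c_SL_g_L", "c_NL_g_L", "c_AL_g_L",
             "c_DL_mol_L"),
  reservoir = c("c_SR_g_L", "c_DR_mol_L", "V_R_L"),
  kinetics = c("mode", "k_r", "k_a", "a_r", "b_r", "a_a", "b_a", "n_agg"),
  feed = c("type", "F_R_L_h", "t_start_h", "t_end_h", "segments",
           "pulse_times_h", "pulse_duration_h", "pulse_rate_L_h"),
  feed_segment = c("t_start_h", "t_end_h", "F_R_L_h"),
  sensor = c("preset", "quantity", "sampling_period_h", "feedback_delay_h",
             "noise_sd_abs_g_L", "noise_sd_rel", "loq_g_L", "name"),
  observer = c("filter", "process_noise", "P0_diag", "dt_h"),
  objective = c("w_Y", "w_STY", "Y_ref", "STY_ref", "F_min_L_h",
                "F_max_L_h", "dF_max_L_h", "V_max_L", "horizon", "dt_c_h"),
  simulation = c("t_end_h", "dt_h", "seed"))

.check_keys <- function(x, section, where) {
  unknown <- setdiff(names(x), .known_keys[[section]])
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ",
         paste(paste0(where, ".", unknown), collapse = ", "), call. = FALSE)
}

.build_feed <- function(fd) {
  type <- fd$type %||% if (!is.null(fd$segments)) "segments" else "constant"
  switch(type,
         constant = constant_feed(fd$F_R_L_h,
                                  t_start = fd$t_start_h %||% 0,
                                  t_end = fd$t_end_h %||% Inf),
         pulsed = pulsed_feed(unlist(fd$pulse_times_h), fd$pulse_duration_h,
                              fd$pulse_rate_L_h),
         segments = {
           for (s in fd$segments) .check_keys(s, "feed_segment",
                                              "feed.segments[]")
           feed_policy(vapply(fd$segments, `[[`, 0, "t_start_h"),
                       vapply(fd$segments, `[[`, 0, "t_end_h"),
                       vapply(fd$segments, `[[`, 0, "F_R_L_h"))
         },
         stop("unknown feed type: ", type, call. = FALSE))
}

.build_sensor <- function(sn) {
  if (!is.null(sn$preset)) {
    sensor_preset(sn$preset, quantity = sn$quantity)
  } else {
    sensor_spec(sn$quantity, sn$sampling_period_h,
                feedback_delay = sn$feedback_delay_h %||% 0,
                noise_sd_abs = sn$noise_sd_abs_g_L %||% 0,
                noise_sd_rel = sn$noise_sd_rel %||% 0,
                loq = sn$loq_g_L %||% 0,
                name = sn$name %||% sn$quantity)
  }
}

#' Load and validate a scenario configuration
#'
#' Reads the YAML scenario dialect, rejects unknown keys by name, rebuilds
#' every domain object (which re-runs all type invariants), and returns a
#' `scenario_config`. `vessel`, `reservoir`, `kinetics`, `feed` and
#' `simulation` are mandatory sections; `sensors`, `observer` and
#' `objective` are optional. Round-trips through [dump_scenario()] are
#' idempotent.
#'
#' @param path YAML file path.
#' @return A `scenario_config` list with components `initial`, `reservoir`,
#'   `params`, `feed`, `sensors` (possibly empty list), `observer`
#'   (config or `NULL`), `objective` (or `NULL`), `t_end`, `dt`, `seed`
#'   (or `NULL`), and `raw` (the parsed YAML).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  .check_keys(raw, "top", basename(path))
  for (sec in c("vessel", "reservoir", "kinetics", "feed", "simulation"))
    if (is.null(raw[[sec]]))
      stop("missing mandatory section '", sec, "' in ", path, call. = FALSE)
  .check_keys(raw$vessel, "vessel", "vessel")
  .check_keys(raw$reservoir, "reservoir", "reservoir")
  .check_keys(raw$kinetics, "kinetics", "kinetics")
  .check_keys(raw$feed, "feed", "feed")
  .check_keys(raw$simulation, "simulation", "simulation")
  if (!is.null(raw$observer)) .check_keys(raw$observer, "observer", "observer")
  if (!is.null(raw$objective)) .check_keys(raw$objective, "objective",
                                           "objective")
  v <- raw$vessel
  initial <- vessel_state(t = v$t_h %||% 0, V_L = v$V_L_L,
                          c_SL = v$c_SL_g_L %||% 0,
                          c_NL = v$c_NL_g_L %||% 0,
                          c_AL = v$c_AL_g_L %||% 0,
                          c_DL = v$c_DL_mol_L %||% 0)
  r <- raw$reservoir
  res <- reservoir_spec(r$c_SR_g_L, r$c_DR_mol_L, r$V_R_L)
  k <- raw$kinetics
  params <- do.call(kinetic_parameters,
                    c(list(mode = k$mode %||% "constant"),
                      k[setdiff(names(k), "mode")]))
  feed <- .build_feed(raw$feed)
  sensors <- lapply(raw$sensors %||% list(), function(sn) {
    .check_keys(sn, "sensor", "sensors[]")
    .build_sensor(sn)
  })
  obs <- NULL
  if (!is.null(raw$observer)) {
    o <- raw$observer
    obs <- observer_config(filter = o$filter %||% "ukf",
                           x0 = initial,
                           P0 = unlist(o$P0_diag %||% 1e-4),
                           process_noise = unlist(o$process_noise %||% 1e-6),
                           dt = o$dt_h %||% 0.1)
  }
  obj <- NULL
  if (!is.null(raw$objective)) {
    b <- raw$objective
    if (!is.null(b$F_min_L_h) && !is.null(b$F_max_L_h) &&
        b$F_min_L_h > b$F_max_L_h)
      stop("schema error: objective.F_min_L_h exceeds objective.F_max_L_h",
           call. = FALSE)
    obj <- control_objective(w_Y = b$w_Y %||% 1, w_STY = b$w_STY %||% 0,
                             Y_ref = b$Y_ref %||% 1,
                             STY_ref = b$STY_ref %||% 0,
                             F_min = b$F_min_L_h %||% 0,
                             F_max = b$F_max_L_h,
                             dF_max = b$dF_max_L_h %||% Inf,
                             V_max = b$V_max_L %||% Inf,
                             horizon = b$horizon %||% 10L,
                             dt_c = b$dt_c_h %||% 0.1)
  }
  structure(list(initial = initial, reservoir = res, params = params,
                 feed = feed, sensors = sensors, observer = obs,
                 objective = obj,
                 t_end = raw$simulation$t_end_h,
                 dt = raw$simulation$dt_h %||% NULL,
                 seed = raw$simulation$seed %||% NULL,
                 raw = raw),
            class = "scenario_config")
}

#' Dump a scenario configuration to canonical YAML
#'
#' Writes the canonical form (fixed section and key order, units in key
#' names) so that load–dump–load round-trips are idempotent.
#' @param cfg A `scenario_config` from [load_scenario()].
#' @param path Output path; `NULL` returns the YAML string.
#' @export
dump_scenario <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  ini <- cfg$initial; res <- cfg$reservoir; p <- cfg$params
  canon <- list(
    vessel = list(t_h = ini$t, V_L_L = ini$V_L, c_SL_g_L = ini$c_SL,
                  c_NL_g_L = ini$c_NL, c_AL_g_L = ini$c_AL,
                  c_DL_mol_L = ini$c_DL),
    reservoir = list(c_SR_g_L = res$c_SR, c_DR_mol_L = res$c_DR,
                     V_R_L = res$V_R),
    kinetics = if (p$mode == "constant")
      list(mode = p$mode, k_r = p$k_r, k_a = p$k_a, n_agg = p$n_agg)
    else list(mode = p$mode, a_r = p$a_r, b_r = p$b_r, a_a = p$a_a,
              b_a = p$b_a, n_agg = p$n_agg),
    feed = list(type = "segments",
                segments = lapply(seq_len(nrow(cfg$feed$segments)),
                                  function(i) {
                                    s <- cfg$feed$segments[i, ]
                                    list(t_start_h = s$t_start,
                                         t_end_h = s$t_end,
                                         F_R_L_h = s$F_R)
                                  })),
    simulation = c(list(t_end_h = cfg$t_end),
                   if (!is.null(cfg$dt)) list(dt_h = cfg$dt),
                   if (!is.null(cfg$seed)) list(seed = cfg$seed)))
  if (length(cfg$sensors))
    canon$sensors <- lapply(cfg$sensors, function(s)
      list(quantity = s$quantity, sampling_period_h = s$sampling_period,
           feedback_delay_h = s$feedback_delay,
           noise_sd_abs_g_L = s$noise_sd_abs,
           noise_sd_rel = s$noise_sd_rel, loq_g_L = s$loq, name = s$name))
  if (!is.null(cfg$observer))
    canon$observer <- list(filter = cfg$observer$filter,
                           process_noise = cfg$observer$q,
                           P0_diag = diag(cfg$observer$P0),
                           dt_h = cfg$observer$dt)
  if (!is.null(cfg$objective)) {
    b <- cfg$objective
    canon$objective <- list(w_Y = b$w_Y, w_STY = b$w_STY, Y_ref = b$Y_ref,
                            STY_ref = b$STY_ref, F_min_L_h = b$F_min,
                            F_max_L_h = b$F_max,
                            dF_max_L_h = if (is.finite(b$dF_max)) b$dF_max
                                         else .Machine$double.xmax,
                            V_max_L = if (is.finite(b$V_max)) b$V_max
                                      else .Machine$double.xmax,
                            horizon = b$horizon, dt_c_h = b$dt_c)
  }
  txt <- yaml::as.yaml(canon, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Path to a shipped fixture scenario
#'
#' `fedbatch_baseline` is the package's reference fed-batch-then-batch scenario:
#' 1 L of refolding buffer at 0.5 mol/L residual denaturant, a 0.5 L
#' reservoir of 10 g/L solubilizate in 6 mol/L denaturant, fed at 0.1 L/h
#' (depletion at exactly 5 h), then batch continuation to 20 h with
#' constant-mode kinetics k_r = 1/h, k_a = 1 L/g/h.
#' @param name Fixture name (currently `"fedbatch_baseline"`).
#' @return File path inside the installed package.
#' @export
scenario_fixture <- function(name = "fedbatch_baseline") {
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "refoldcontrol")
  if (path == "") stop("no fixture named ", name, call. = FALSE)
  path
}
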