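## PAT (process analytical technology) measurement emulation: turns a
## noise-free simulated trajectory into the sparse, delayed, noisy, and
## LOQ-censored data streams a real sensor suite would deliver.

#' Sensor specification
#'
#' Describes one measurement channel: which vessel quantity it observes, how
#' often it samples, how long the analysis takes before the value becomes
#' available to the monitoring layer (feedback delay), its Gaussian noise
#' level (absolute and/or relative standard deviation), and its limit of
#' quantification (LOQ).
#'
#' @param quantity One of `"c_SL"`, `"c_NL"`, `"c_AL"`, `"c_DL"`, `"c_PL"`.
#' @param sampling_period Time between samples \[h\], > 0.
#' @param feedback_delay Analysis delay before the value is available \[h\].
#' @param noise_sd_abs Absolute noise standard deviation \[g/L\].
#' @param noise_sd_rel Relative noise standard deviation \[fraction of
#'   truth\]. The total sd is `noise_sd_abs + noise_sd_rel * truth`.
#' @param loq Limit of quantification \[g/L\]; true values below it are
#'   reported as censored at the LOQ, never as fabricated numbers.
#' @param name Optional channel label (defaults to the quantity).
#' @return Object of class `sensor_spec`.
#' @seealso [sensor_preset()] for named presets of common refolding PAT
#'   methods.
#' @export
sensor_spec <- function(quantity, sampling_period, feedback_delay = 0,
                        noise_sd_abs = 0, noise_sd_rel = 0, loq = 0,
                        name = quantity) {
  quantity <- match.arg(quantity, c("c_SL", "c_NL", "c_AL", "c_DL", "c_PL"))
  if (sampling_period <= 0) stop("sampling_period must be > 0", call. = FALSE)
  if (feedback_delay < 0 || noise_sd_abs < 0 || noise_sd_rel < 0 || loq < 0)
    stop("delay, noise and LOQ must be non-negative", call. = FALSE)
  structure(list(quantity = quantity,
                 sampling_period = as.numeric(sampling_period),
                 feedback_delay = as.numeric(feedback_delay),
                 noise_sd_abs = as.numeric(noise_sd_abs),
                 noise_sd_rel = as.numeric(noise_sd_rel),
                 loq = as.numeric(loq), name = name),
            class = "sensor_spec")
}

#' Named sensor presets
#'
#' Presets modeled on the PAT methods commonly combined for refolding
#' monitoring. The concentration floors follow the published method limits
#' (RP-HPLC LOQ below 10 ug/mL, i.e. 0.01 g/L; FTIR usable from about
#' 0.01 g/L); the sampling periods reflect the reported feedback-time
#' classes (seconds-scale for FTIR/DLS, tens of minutes for HPLC). The noise
#' magnitudes themselves are synthetic defaults — the methods are described
#' only qualitatively in the literature this emulator draws on.
#'
#' * `ftir_native` — fast inline spectroscopy of the native species:
#'   10 s sampling (0.003 h), no delay, 2% relative + 0.01 g/L absolute sd.
#' * `hplc_species` — chromatographic species quantification (one spec per
#'   call, pick the quantity): 0.5 h sampling, 0.25 h feedback delay,
#'   LOQ 0.01 g/L, 3% relative sd.
#' * `dls_aggregate` — fast but semi-quantitative aggregate monitoring:
#'   0.02 h sampling, no delay, 10% relative sd.
#'
#' @param preset Preset name.
#' @param quantity Observed quantity; defaults to the preset's natural
#'   target.
#' @return A [sensor_spec()].
#' @export
sensor_preset <- function(preset = c("ftir_native", "hplc_species",
                                     "dls_aggregate"),
                          quantity = NULL) {
  preset <- match.arg(preset)
  switch(preset,
    ftir_native = sensor_spec(quantity %||% "c_NL",
                              sampling_period = 0.003, feedback_delay = 0,
                              noise_sd_abs = 0.01, noise_sd_rel = 0.02,
                              loq = 0.01, name = "ftir_native"),
    hplc_species = sensor_spec(quantity %||% "c_SL",
                               sampling_period = 0.5, feedback_delay = 0.25,
                               noise_sd_abs = 0, noise_sd_rel = 0.03,
                               loq = 0.01, name = "hplc_species"),
    dls_aggregate = sensor_spec(quantity %||% "c_AL",
                                sampling_period = 0.02, feedback_delay = 0,
                                noise_sd_abs = 0.005, noise_sd_rel = 0.10,
                                loq = 0, name = "dls_aggregate"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emulate PAT measurements from a ground-truth trajectory
#'
#' Samples each sensor channel on its own clock over the trajectory span,
#' adds seeded Gaussian noise with standard deviation
#' `noise_sd_abs + noise_sd_rel * truth`, stamps each record with its
#' availability time (`sample time + feedback delay`), and censors records
#' whose true or measured value falls below the channel LOQ (censored
#' records carry the LOQ itself, flagged, never a fabricated value).
#' Identical seeds give byte-identical output.
#'
#' @param traj A `refold_trajectory` covering all sample times.
#' @param sensors A list of [sensor_spec()] objects (a single spec is
#'   accepted).
#' @param seed Integer RNG seed (mandatory: measurement emulation is the
#'   stochastic boundary of every downstream pipeline).
#' @return A `measurement_set`: data.frame with columns `t_sample_h`,
#'   `t_available_h`, `quantity`, `value_g_L`, `censored`, `sensor`, sorted
#'   by availability time.
#' @export
generate_measurements <- function(traj, sensors, seed) {
  stopifnot(inherits(traj, "refold_trajectory"))
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for measurement emulation", call. = FALSE)
  if (inherits(sensors, "sensor_spec")) sensors <- list(sensors)
  stopifnot(all(vapply(sensors, inherits, TRUE, "sensor_spec")))
  t0 <- traj$t_h[1]; t1 <- traj$t_h[nrow(traj)]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  recs <- lapply(sensors, function(s) {
    ts <- seq(t0, t1, by = s$sampling_period)
    col <- if (s$quantity == "c_DL") "c_DL_mol_L" else
      paste0(s$quantity, "_g_L")
    truth <- .traj_interp(traj, col, ts)
    sd <- s$noise_sd_abs + s$noise_sd_rel * truth
    value <- truth + stats::rnorm(length(ts), 0, sd)
    censored <- truth < s$loq | value < s$loq
    value[censored] <- s$loq
    data.frame(t_sample_h = ts, t_available_h = ts + s$feedback_delay,
               quantity = s$quantity, value_g_L = value,
               censored = censored, sensor = s$name)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$t_available_h, out$t_sample_h, out$quantity), ]
  rownames(out) <- NULL
  structure(out, sensors = sensors, seed = as.integer(seed),
            class = c("measurement_set", "data.frame"))
}

.measurement_columns <- c("t_sample_h", "t_available_h", "quantity",
                          "value_g_L", "censored", "sensor")

#' Write / read a measurement set as CSV
#'
#' Fixed column order `t_sample_h, t_available_h, quantity, value_g_L,
#' censored, sensor`.
#' @param meas A `measurement_set`.
#' @param path File path.
#' @export
write_measurements_csv <- function(meas, path) {
  utils::write.csv(as.data.frame(meas)[, .measurement_columns],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.measurement_columns, names(df))
  if (length(missing_cols))
    stop("measurement CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$censored <- as.logical(df$censored)
  structure(df[, .measurement_columns],
            class = c("measurement_set", "data.frame"))
}
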