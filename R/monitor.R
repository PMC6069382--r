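# Threshold-driven monitoring and control loop.
#
# Each sampling tick compares the temperature / humidity / light reading
# against the recommended storage values within accuracy-derived bands.
# Only the temperature test selects the decay rate (recommended band ->
# k_ref, otherwise the Arrhenius rate at the reading); humidity and light
# violations raise intervention flags but do not alter the kinetics,
# since the shelf-life model is temperature-driven.

#' Monitoring-loop configuration
#'
#' @param ts Sampling interval (s); default 300 s (one reading per
#'   5 minutes).
#' @param T_ref,H_ref,L_ref Recommended storage temperature (deg C),
#'   relative humidity (%) and illuminance (lux).
#' @param T_th,H_th,L_th Tolerance half-widths around the references,
#'   conventionally set to the sensor accuracies (2 deg C, 3.5 %RH, 20%
#'   of the light reference).
#' @param C_th Firmness-decrease displacement trigger (N/s between
#'   consecutive measurements); see [c_th_preset()].
#' @return An object of class `monitor_config`.
#' @export
monitor_config <- function(ts = 300, T_ref = 20, H_ref = 55.73,
                           L_ref = 100, T_th = 2, H_th = 3.5,
                           L_th = 0.2 * L_ref, C_th = c_th_preset("24C")) {
  if (!is.finite(ts) || ts <= 0) stop("ts must be a positive interval (s)")
  if (any(c(T_th, H_th, L_th, C_th) < 0)) stop("thresholds must be >= 0")
  structure(list(ts = ts, T_ref = T_ref, H_ref = H_ref, L_ref = L_ref,
                 T_th = T_th, H_th = H_th, L_th = L_th, C_th = C_th),
            class = "monitor_config")
}

#' Preset firmness-decrease displacement triggers
#'
#' Two reprogrammable trigger constants ship by default, expressed as a
#' firmness decrease per second between consecutive measurements over a
#' 10-minute window: 2.68e-5 N/s (24 deg C setting) and 3.184e-5 N/s
#' (26 deg C setting). They are stored verbatim as configuration
#' constants, not derived from the kinetic parameters.
#'
#' @param which `"24C"` or `"26C"`.
#' @return Trigger threshold (N/s).
#' @export
c_th_preset <- function(which = c("24C", "26C")) {
  which <- match.arg(which)
  switch(which, "24C" = 2.68e-5, "26C" = 3.184e-5)
}

#' Flag set raised at one monitoring tick
#'
#' @param temp,hum,light,battery,working Logical flags.
#' @param t Timestamp (day).
#' @return An object of class `flag_set`.
#' @export
flag_set <- function(temp = FALSE, hum = FALSE, light = FALSE,
                     battery = FALSE, working = FALSE, t = NA_real_) {
  structure(list(temp_flag = temp, hum_flag = hum, light_flag = light,
                 battery_flag = battery, working_flag = working, t = t),
            class = "flag_set")
}

#' Initialize a pallet's quality state
#'
#' Sets the quality factor to its initial value `c0`, derives the decay
#' rate at the reference temperature, and computes the initial shelf life
#' (about 7.1 days for the tomato-firmness preset).
#'
#' @param params A [kinetic_params()] object.
#' @param config A [monitor_config()].
#' @return A [quality_state()] at `t = 0`.
#' @export
init_pallet <- function(params, config = monitor_config()) {
  stopifnot(inherits(params, "kinetic_params"))
  SL0 <- shelf_life(params$c0, params, params$k_ref)
  sb <- shelf_life_bounds(params$c0, params, params$T_ref_C, config$T_th)
  quality_state(t = 0, c = params$c0, k_current = params$k_ref, SL = SL0,
                SL_lo = sb[["SL_lo"]], SL_hi = sb[["SL_hi"]])
}

#' One tick of the monitoring loop
#'
#' Compares a (T, H, L) reading against the recommended bands. Inside all
#' bands the reference rate `k_ref` is used; if the temperature band is
#' violated the rate is re-derived from the Arrhenius law at the reading.
#' Every violated band raises its intervention flag. The quality factor
#' then decays over one sampling interval and the shelf life (with its
#' sensor-accuracy bounds) is recomputed.
#'
#' @param state A [quality_state()] with `SL > 0`.
#' @param reading Named vector or list with `T`, `H`, `L`.
#' @param config A [monitor_config()].
#' @param params A [kinetic_params()] object.
#' @param form Decay form passed to [decay_step()].
#' @return A list `(state, flags)`.
#' @export
monitor_step <- function(state, reading, config, params,
                         form = "exponential") {
  stopifnot(inherits(state, "quality_state"))
  if (!is.finite(state$SL) || state$SL <= 0)
    stop("monitoring loop has terminated: SL is exhausted")
  Tv <- reading[["T"]]; Hv <- reading[["H"]]; Lv <- reading[["L"]]
  temp_bad <- abs(Tv - config$T_ref) > config$T_th
  hum_bad <- !is.null(Hv) && is.finite(Hv) &&
    abs(Hv - config$H_ref) > config$H_th
  light_bad <- !is.null(Lv) && is.finite(Lv) &&
    abs(Lv - config$L_ref) > config$L_th
  k <- if (temp_bad) arrhenius_rate(params, Tv) else params$k_ref
  dt <- config$ts / 86400
  c_new <- decay_step(state$c, k, dt, form = form, c_eq = params$c_eq)
  SL <- shelf_life(c_new, params, k)
  sb <- shelf_life_bounds(c_new, params, Tv, config$T_th)
  new_state <- quality_state(t = state$t + dt, c = c_new, k_current = k,
                             SL = SL, SL_lo = min(sb[["SL_lo"]], SL),
                             SL_hi = max(sb[["SL_hi"]], SL))
  list(state = new_state,
       flags = flag_set(temp = temp_bad, hum = isTRUE(hum_bad),
                        light = isTRUE(light_bad), t = new_state$t))
}

#' Run the monitoring loop over a reading series
#'
#' Iterates [monitor_step()] at the sampling interval until the shelf
#' life is exhausted or the series ends. A missing reading (any `NA`) at
#' a tick carries the last reading forward and raises the working flag.
#'
#' @param state Initial [quality_state()] (from [init_pallet()]).
#' @param readings data.frame with columns `T`, `H`, `L`, one row per
#'   tick.
#' @param config A [monitor_config()].
#' @param params A [kinetic_params()] object.
#' @param form Decay form passed to [decay_step()].
#' @return A list with `trajectory` (data.frame: t, c, k, SL, SL_lo,
#'   SL_hi), `flags` (data.frame of raised flags per tick), and
#'   `expired_at` (day of expiry, `NA` if the series ended first).
#' @export
run_monitor <- function(state, readings, config, params,
                        form = "exponential") {
  if (nrow(readings) == 0) stop("empty reading series")
  if (!is.finite(state$SL) || state$SL <= 0)
    return(list(trajectory = data.frame(), flags = data.frame(),
                state = state, expired_at = state$t))
  n <- nrow(readings)
  traj <- data.frame(t = numeric(n), c = numeric(n), k = numeric(n),
                     SL = numeric(n), SL_lo = numeric(n), SL_hi = numeric(n))
  flags <- data.frame(t = numeric(n), temp = logical(n), hum = logical(n),
                      light = logical(n), working = logical(n))
  last <- NULL
  expired_at <- NA_real_
  used <- 0L
  for (i in seq_len(n)) {
    r <- readings[i, , drop = FALSE]
    carried <- anyNA(r[c("T", "H", "L")])
    if (carried) {
      if (is.null(last)) stop("first reading is missing")
      r <- last
    } else last <- r
    step <- monitor_step(state, as.list(r), config, params, form = form)
    state <- step$state
    used <- i
    traj[i, ] <- c(state$t, state$c, state$k_current, state$SL,
                   state$SL_lo, state$SL_hi)
    flags[i, ] <- list(state$t, step$flags$temp_flag, step$flags$hum_flag,
                       step$flags$light_flag, carried)
    if (state$SL <= 0) { expired_at <- state$t; break }
  }
  list(trajectory = traj[seq_len(used), , drop = FALSE],
       flags = flags[seq_len(used), , drop = FALSE],
       state = state, expired_at = expired_at)
}
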