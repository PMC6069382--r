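# Seeded synthetic environment: replaces the physical storage room and
# its sensor hardware. The latent temperature model is a daily sinusoid
# plus a window-side overheating ramp (9:00-16:00, relaxing afterwards)
# plus AR(1) jitter; relative humidity co-varies inversely with
# temperature. Reported values add bounded measurement noise matching
# the sensor accuracies (+/-2 degC, +/-3.5 %RH).

#' Synthetic room profile specification
#'
#' Parameter defaults emulate a non-refrigerated storage room: mean
#' temperature 21.3 deg C (sd 1.2), a window-side overheating of
#' 2.8 +/- 0.8 deg C building from 9:00 to 16:00 and relaxing back at
#' about 0.1 deg C/h, relative humidity 55.73 +/- 3 % coupled inversely
#' to temperature at about -2.5 % per +3 deg C, and sensor accuracies of
#' +/-2 deg C and +/-3.5 %RH.
#'
#' @param duration_h Simulated span (h); default 251 (10 days and 11 h).
#' @param dt_s Sampling interval (s); default 300.
#' @param base_mean,base_sd Room mean temperature and the sd of its
#'   random fluctuation (deg C).
#' @param diurnal_amp Amplitude of the shared daily sinusoid (deg C).
#' @param window_sensor_ids Node IDs adjacent to the window (carry the
#'   overheating ramp).
#' @param overheat_mean,overheat_sd Daily peak of the window ramp (deg C).
#' @param overheat_start,overheat_end Ramp hours of day.
#' @param relax_rate Post-peak relaxation (deg C per h).
#' @param rh_mean,rh_sd Relative-humidity level (%) and jitter sd.
#' @param rh_coupling RH change per deg C of temperature excursion
#'   (% / deg C); default -2.5/3.
#' @param T_noise,RH_noise Measurement-noise bounds (deg C, %RH).
#' @param lux_day,lux_night Day/night illuminance plateaus (lux, 1-1000).
#' @param battery_drain Battery discharge (%/day).
#' @param dropout_prob Per-tick probability of a working-flag drop.
#' @return An object of class `env_profile_spec`.
#' @export
env_profile_spec <- function(duration_h = 251, dt_s = 300,
                             base_mean = 21.3, base_sd = 1.2,
                             diurnal_amp = 1.0,
                             window_sensor_ids = c("S1", "S2"),
                             overheat_mean = 2.8, overheat_sd = 0.8,
                             overheat_start = 9, overheat_end = 16,
                             relax_rate = 0.1,
                             rh_mean = 55.73, rh_sd = 3,
                             rh_coupling = -2.5 / 3,
                             T_noise = 2, RH_noise = 3.5,
                             lux_day = 500, lux_night = 1,
                             battery_drain = 0.5, dropout_prob = 0) {
  if (dt_s <= 0) stop("dt_s must be positive")
  if (any(c(base_sd, overheat_sd, rh_sd, T_noise, RH_noise) < 0))
    stop("spreads and noise bounds must be >= 0")
  if (lux_day < 1 || lux_day > 1000 || lux_night < 1 || lux_night > 1000)
    stop("lux plateaus must lie within the sensor range 1-1000")
  structure(as.list(environment()), class = "env_profile_spec")
}

#' Generate synthetic sensor logs for a room
#'
#' Produces a deterministic (given `seed`) per-sensor time series of
#' temperature, relative humidity, illuminance, battery level and
#' working flag. Window-adjacent sensors carry the 9:00-16:00
#' overheating ramp with post-peak relaxation; RH co-varies inversely
#' with temperature; reported values differ from the latent truth by at
#' most the configured sensor accuracy (uniform bounded noise); battery
#' decreases monotonically.
#'
#' @param spec An [env_profile_spec()].
#' @param sensors Sensor data.frame (see [sensor_table()]).
#' @param seed RNG seed.
#' @return A data.frame with columns `tick`, `time_h`, `node_id`, `T_C`,
#'   `RH_pct`, `lux`, `battery_pct`, `working`, plus the latent truths
#'   `latent_T`, `latent_RH` for simulator introspection.
#' @export
generate_room <- function(spec, sensors, seed = 1) {
  stopifnot(inherits(spec, "env_profile_spec"))
  if (length(spec$window_sensor_ids) &&
      !all(spec$window_sensor_ids %in% sensors$node_id))
    stop("unknown sensor id in window_sensor_ids")
  set.seed(seed)
  nt <- max(1L, floor(spec$duration_h * 3600 / spec$dt_s))
  th <- (seq_len(nt) - 1) * spec$dt_s / 3600       # hours since start (8:00)
  hod <- (8 + th) %% 24                            # hour of day
  # shared room trajectory: sinusoid peaking mid-afternoon + AR(1)
  diurnal <- spec$diurnal_amp * sin(2 * pi * (hod - 9) / 24)
  phi <- 0.95
  innov_sd <- spec$base_sd * sqrt(1 - phi^2)
  room_ar <- as.numeric(stats::filter(stats::rnorm(nt, 0, innov_sd), phi,
                                      method = "recursive"))
  room_T <- spec$base_mean + diurnal + room_ar

  # window ramp offset shared by window sensors: rises linearly to the
  # day's peak between the ramp hours, relaxes at relax_rate otherwise
  ndays <- ceiling(spec$duration_h / 24) + 1
  peaks <- pmax(0, stats::rnorm(ndays, spec$overheat_mean, spec$overheat_sd))
  offset <- numeric(nt)
  cur <- 0
  ramp_len <- spec$overheat_end - spec$overheat_start
  dth <- spec$dt_s / 3600
  for (i in seq_len(nt)) {
    d <- floor((8 + th[i]) / 24) + 1
    h <- hod[i]
    if (h >= spec$overheat_start && h < spec$overheat_end) {
      peak <- peaks[d]
      cur <- max(cur, peak * (h - spec$overheat_start) / ramp_len)
      cur <- min(cur, peak)
    } else {
      cur <- max(0, cur - spec$relax_rate * dth)
    }
    offset[i] <- cur
  }

  lux_lat <- ifelse(hod >= 7 & hod < 19, spec$lux_day, spec$lux_night)
  out <- vector("list", nrow(sensors))
  for (s in seq_len(nrow(sensors))) {
    id <- sensors$node_id[s]
    is_window <- id %in% spec$window_sensor_ids
    jitter <- as.numeric(stats::filter(stats::rnorm(nt, 0, innov_sd / 2),
                                       phi, method = "recursive"))
    lat_T <- room_T + jitter + if (is_window) offset else 0
    lat_RH <- spec$rh_mean + spec$rh_coupling * (lat_T - spec$base_mean) +
      as.numeric(stats::filter(stats::rnorm(nt, 0, spec$rh_sd *
                                              sqrt(1 - phi^2)),
                               phi, method = "recursive"))
    T_acc <- sensors$T_acc[s]; RH_acc <- sensors$RH_acc[s]
    rep_T <- lat_T + stats::runif(nt, -T_acc, T_acc)
    rep_RH <- pmin(95, pmax(0, lat_RH + stats::runif(nt, -RH_acc, RH_acc)))
    rep_lux <- pmin(1000, pmax(1, lux_lat * (1 + stats::runif(nt, -0.2, 0.2))))
    batt <- pmax(0, sensors$battery[s] - spec$battery_drain * th / 24)
    working <- rep(1L, nt)
    if (spec$dropout_prob > 0)
      working[stats::runif(nt) < spec$dropout_prob] <- 0L
    working[sensors$working[s] == 0] <- 0L
    out[[s]] <- data.frame(tick = seq_len(nt), time_h = th, node_id = id,
                           T_C = rep_T, RH_pct = rep_RH, lux = rep_lux,
                           battery_pct = batt, working = working,
                           latent_T = lat_T, latent_RH = lat_RH,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate an observed firmness decay series
#'
#' Integrates the first-order decay along a temperature series with a
#' piecewise-constant rate per sampling interval, then adds seeded
#' multiplicative observation noise. At constant 20/30/40 deg C this
#' reproduces the characteristic firmness decay curves of stored tomato.
#'
#' @param params A [kinetic_params()] object.
#' @param T_C Temperature series (deg C), one value per interval.
#' @param dt_s Sampling interval (s).
#' @param noise_sd Multiplicative noise sd (fraction; 0.02 = 2%).
#' @param seed RNG seed.
#' @param form Decay form passed to [decay_step()].
#' @return data.frame with `t_day`, `c_true`, `c_obs` (the initial state
#'   is row one).
#' @export
generate_firmness_series <- function(params, T_C, dt_s = 300,
                                     noise_sd = 0, seed = 1,
                                     form = "exponential") {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(T_C) == 0) stop("empty temperature series")
  set.seed(seed)
  n <- length(T_C)
  dt <- dt_s / 86400
  c_true <- numeric(n + 1)
  c_true[1] <- params$c0
  for (i in seq_len(n)) {
    k <- arrhenius_rate(params, T_C[i])
    c_true[i + 1] <- decay_step(c_true[i], k, dt, form = form,
                                c_eq = params$c_eq)
  }
  noise <- if (noise_sd > 0) stats::rnorm(n + 1, 0, noise_sd) else 0
  data.frame(t_day = (0:n) * dt, c_true = c_true,
             c_obs = pmax(c_true * (1 + noise), 1e-9))
}

#' Reference warehouse scenario fixture
#'
#' The reusable proof-of-concept scenario: a 6.3 m x 6.7 m room on a
#' 5 x 5 lattice, eight wall sensors at the printed coordinates (two per
#' wall, sensors S1/S2 on the window side), and four tomato pallets at
#' their printed initial positions.
#'
#' @param params Kinetic parameters for the pallets.
#' @return A list with `spec` ([lattice_spec()]), `sensors` (mapped to
#'   cells) and `registry` ([pallet_registry()]).
#' @export
#' @examples
#' sc <- reference_scenario()
#' sc$registry
reference_scenario <- function(params = tomato_firmness_params()) {
  spec <- lattice_spec(5, 5, 6.3, 6.7)
  sensors <- sensor_table(
    node_id = paste0("S", 1:8),
    x = c(1.26, 3.78, 0, 0, 1.26, 3.78, 6.3, 6.3),
    y = c(0, 0, 1.34, 4.02, 6.7, 6.7, 1.34, 4.02))
  sensors <- map_sensors_to_cells(spec, sensors)
  pallet_xy <- data.frame(id = as.character(1:4),
                          x = c(1.26, 2.52, 1.26, 3.78),
                          y = c(0, 2.68, 5.36, 0))
  prow <- cell_index(pallet_xy$y, spec$cell_dy, spec$M1)
  pcol <- cell_index(pallet_xy$x, spec$cell_dx, spec$M2)
  registry <- pallet_registry(pallet_xy$id, prow, pcol,
                              c = rep(params$c0, 4), params = params,
                              spec = spec)
  list(spec = spec, sensors = sensors, registry = registry)
}
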