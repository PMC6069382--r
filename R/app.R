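# Configuration, file I/O and the end-to-end pipeline tying the modules
# together: synthetic logs -> per-tick field reconstruction -> monitoring
# -> displacement trigger -> QCL optimization -> transporter commands.

#' Default configuration
#'
#' All built-in constants in one nested list: the tomato-firmness
#' kinetic preset, sensor accuracies, the 300 s sampling interval, the
#' 5 x 5 lattice over the 6.3 m x 6.7 m reference room, the displacement
#' trigger presets and the Isd characterization grid (1-2.5 m, step
#' 0.25 m, 16 events per distance).
#'
#' @return A nested named list; serialize with [yaml::write_yaml()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    room = list(M1 = 5L, M2 = 5L, l1 = 6.3, l2 = 6.7),
    kinetics = list(k_ref_per_day = 0.2, T_ref_C = 20,
                    Ea_kJ_per_mol = 64.8, c0_N = 12.4, c_eq_N = 3,
                    product_label = "tomato firmness"),
    monitor = list(ts_s = 300, T_ref_C = 20, H_ref_pct = 55.73,
                   L_ref_lux = 100, T_th_C = 2, H_th_pct = 3.5,
                   L_th_lux = 20, C_th_preset = "24C",
                   retrigger_cooldown_s = 7200),
    profile = list(duration_h = 251, dt_s = 300, base_mean = 21.3,
                   base_sd = 1.2, diurnal_amp = 1.0,
                   window_sensor_ids = c("S1", "S2")),
    isd = list(values = seq(1, 2.5, by = 0.25), reps = 16L)
  )
}

#' Read a configuration file
#'
#' Loads a YAML configuration and validates it against the keys of
#' [default_config()]; unknown keys abort with a message naming the
#' offending key. Missing keys fall back to the defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return The merged configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (section in names(user)) {
    if (!section %in% names(cfg))
      stop(sprintf("unknown configuration section '%s'", section))
    if (!is.list(user[[section]])) { cfg[[section]] <- user[[section]]; next }
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop(sprintf("unknown configuration key '%s.%s'", section, key))
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

config_params <- function(cfg) {
  k <- cfg$kinetics
  kinetic_params(k$k_ref_per_day, k$T_ref_C, k$Ea_kJ_per_mol, k$c0_N,
                 k$c_eq_N, product_label = k$product_label)
}

config_monitor <- function(cfg) {
  m <- cfg$monitor
  monitor_config(ts = m$ts_s, T_ref = m$T_ref_C, H_ref = m$H_ref_pct,
                 L_ref = m$L_ref_lux, T_th = m$T_th_C, H_th = m$H_th_pct,
                 L_th = m$L_th_lux, C_th = c_th_preset(m$C_th_preset))
}

config_profile <- function(cfg) {
  p <- cfg$profile
  env_profile_spec(duration_h = p$duration_h, dt_s = p$dt_s,
                   base_mean = p$base_mean, base_sd = p$base_sd,
                   diurnal_amp = p$diurnal_amp,
                   window_sensor_ids = p$window_sensor_ids)
}

#' Write synthetic sensor logs to disk
#'
#' Generates the reference-scenario logs and writes one tab-delimited
#' file per sensor (columns: `timestamp_iso`, `node_id`, `T_C`,
#' `RH_pct`, `lux`, `battery_pct`, `working`) plus a `manifest.json`
#' recording the seed and the scenario.
#'
#' @param config Path to a YAML config, or a config list, or `NULL` for
#'   defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the config seed when non-`NULL`.
#' @return Invisibly, the paths written.
#' @export
cli_simulate <- function(config = NULL, out_dir = "logs", seed = NULL) {
  cfg <- if (is.list(config)) config else read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  sc <- reference_scenario(config_params(cfg))
  logs <- generate_room(config_profile(cfg), sc$sensors, seed = cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.POSIXct("2020-01-01 08:00:00", tz = "UTC")
  paths <- character(0)
  for (id in unique(logs$node_id)) {
    li <- logs[logs$node_id == id, , drop = FALSE]
    out <- data.frame(
      timestamp_iso = format(t0 + li$time_h * 3600, "%Y-%m-%dT%H:%M:%SZ"),
      node_id = li$node_id, T_C = round(li$T_C, 3),
      RH_pct = round(li$RH_pct, 3), lux = round(li$lux, 1),
      battery_pct = round(li$battery_pct, 2), working = li$working)
    p <- file.path(out_dir, paste0(id, ".tsv"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = cfg$seed, n_sensors = nrow(sc$sensors),
                            room = cfg$room, files = basename(paths)),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest))
}

#' Read sensor logs written by [cli_simulate()]
#'
#' @param dir Directory holding `*.tsv` sensor logs.
#' @return A combined data.frame with a `tick` column per node.
#' @export
read_sensor_logs <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) stop("no .tsv sensor logs found in ", dir)
  logs <- do.call(rbind, lapply(files, function(f)
    utils::read.table(f, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)))
  logs$tick <- ave(seq_len(nrow(logs)), logs$node_id, FUN = seq_along)
  logs
}

#' Reconstruct a lattice field from one tick of sensor readings
#'
#' Places each sensor's reading in its lattice cell (averaging when two
#' sensors share a cell) and fills the remaining cells with
#' [interpolate_field()].
#'
#' @param spec A [lattice_spec()].
#' @param sensors Sensor data.frame with `row`/`col` columns (see
#'   [map_sensors_to_cells()]).
#' @param readings data.frame with `node_id` and the value column for
#'   this tick.
#' @param quantity Field label.
#' @param value_col Column of `readings` holding the values.
#' @return A fully populated [scalar_field()].
#' @export
tick_field <- function(spec, sensors, readings, quantity = "temperature_C",
                       value_col = "T_C") {
  v <- matrix(NA_real_, spec$M1, spec$M2)
  meas <- matrix(FALSE, spec$M1, spec$M2)
  for (i in seq_len(nrow(readings))) {
    s <- sensors[sensors$node_id == readings$node_id[i], ]
    if (nrow(s) == 0) next
    val <- readings[[value_col]][i]
    if (meas[s$row, s$col]) val <- mean(c(v[s$row, s$col], val))
    v[s$row, s$col] <- val
    meas[s$row, s$col] <- TRUE
  }
  interpolate_field(scalar_field(v, meas, quantity))
}

#' Run the full warehouse pipeline over a log series
#'
#' For every sampling tick: excludes unhealthy sensors, reconstructs the
#' temperature and humidity fields by contiguous-element averaging,
#' advances each pallet's quality and shelf life with the monitoring
#' loop (the pallet senses its own cell), and tests the firmness-drop
#' displacement trigger. When a pallet's firmness decrease meets the
#' trigger, the QCL optimizer runs on the frozen field, the resulting
#' moves are executed (with a collision-free path and a transporter
#' command string per unit step), and a cooldown suppresses immediate
#' re-triggering.
#'
#' @param logs Combined sensor logs (see [read_sensor_logs()] or
#'   [generate_room()]).
#' @param scenario A scenario list as from [reference_scenario()].
#' @param cfg Configuration list (see [default_config()]).
#' @return A `run_report` list: `trajectories` (per pallet), `flag_log`,
#'   `warnings`, `move_plans` (each with tick, plan, paths, commands),
#'   `overall_SL_initial`, `overall_SL_final`, `total_iterations`.
#' @export
run_warehouse <- function(logs, scenario, cfg = default_config()) {
  params <- config_params(cfg)
  mcfg <- config_monitor(cfg)
  spec <- scenario$spec
  registry <- scenario$registry
  np <- nrow(registry$pallets)
  states <- lapply(seq_len(np), function(p) init_pallet(params, mcfg))
  ticks <- sort(unique(logs$tick))
  c_hist <- lapply(seq_len(np), function(p) registry$pallets$c[p])
  traj <- vector("list", np)
  flag_log <- list()
  warn_log <- character(0)
  move_plans <- list()
  cooldown_until <- -Inf
  overall_initial <- NA_real_
  dt_day <- mcfg$ts / 86400

  for (tk in ticks) {
    rd <- logs[logs$tick == tk, , drop = FALSE]
    hs <- scenario$sensors
    mm <- match(hs$node_id, rd$node_id)
    hs$battery <- rd$battery_pct[mm]
    hs$working <- rd$working[mm]
    health <- exclude_unhealthy(hs[!is.na(mm), , drop = FALSE])
    if (length(health$warnings))
      warn_log <- c(warn_log, sprintf("tick %d: %s", tk, health$warnings))
    rd_ok <- rd[rd$node_id %in% health$active$node_id, , drop = FALSE]
    if (nrow(rd_ok) == 0) {
      warn_log <- c(warn_log, sprintf("tick %d: no healthy sensors", tk))
      next
    }
    Tfield <- tick_field(spec, scenario$sensors, rd_ok)
    Hfield <- tick_field(spec, scenario$sensors, rd_ok, "RH_pct", "RH_pct")
    Lmean <- mean(rd_ok$lux)

    triggered <- FALSE
    for (p in seq_len(np)) {
      if (states[[p]]$SL <= 0) next
      cell <- c(registry$pallets$row[p], registry$pallets$col[p])
      reading <- list(T = Tfield$values[cell[1], cell[2]],
                      H = Hfield$values[cell[1], cell[2]], L = Lmean)
      st <- monitor_step(states[[p]], reading, mcfg, params)
      states[[p]] <- st$state
      registry$pallets$c[p] <- st$state$c
      c_hist[[p]] <- c(c_hist[[p]], st$state$c)
      traj[[p]][[length(traj[[p]]) + 1L]] <-
        data.frame(tick = tk, t_day = st$state$t, c = st$state$c,
                   SL = st$state$SL, SL_lo = st$state$SL_lo,
                   SL_hi = st$state$SL_hi)
      fl <- st$flags
      if (fl$temp_flag || fl$hum_flag || fl$light_flag)
        flag_log[[length(flag_log) + 1L]] <-
          data.frame(tick = tk, pallet = registry$pallets$id[p],
                     temp = fl$temp_flag, hum = fl$hum_flag,
                     light = fl$light_flag)
      if (length(c_hist[[p]]) >= 2 &&
          displacement_trigger(c_hist[[p]], mcfg$C_th, mcfg$ts))
        triggered <- TRUE
    }
    if (is.na(overall_initial)) {
      cube0 <- build_cubes(Tfield, registry, ts = mcfg$ts)
      overall_initial <- sum(vapply(seq_len(np), function(p)
        cube0$SL[registry$pallets$row[p], registry$pallets$col[p], p],
        numeric(1)))
    }
    if (triggered && tk * mcfg$ts >= cooldown_until) {
      cube <- build_cubes(Tfield, registry, ts = mcfg$ts)
      plan <- qcl_optimize(registry, cube)
      exec <- execute_moves(registry, plan)
      registry <- exec$registry
      move_plans[[length(move_plans) + 1L]] <-
        list(tick = tk, plan = plan, paths = exec$paths,
             commands = exec$commands)
      cooldown_until <- tk * mcfg$ts + cfg$monitor$retrigger_cooldown_s
    }
  }

  final_SL <- vapply(states, function(s) max(s$SL, 0), numeric(1))
  structure(list(
    trajectories = lapply(traj, function(x)
      if (length(x)) do.call(rbind, x) else data.frame()),
    flag_log = if (length(flag_log)) do.call(rbind, flag_log)
               else data.frame(),
    warnings = warn_log,
    move_plans = move_plans,
    overall_SL_initial = overall_initial,
    overall_SL_final = sum(final_SL),
    total_iterations = sum(vapply(move_plans, function(m)
      m$plan$total_iterations, numeric(1))),
    pallet_ids = registry$pallets$id,
    final_cells = registry$pallets[, c("id", "row", "col")]),
    class = "run_report")
}

# Execute a move plan: plan a collision-free path for each move in order
# and emit one 12-byte transporter command per unit step.
execute_moves <- function(registry, plan) {
  em <- encumbrance_matrix(registry)
  paths <- list()
  commands <- list()
  for (m in seq_len(nrow(plan$moves))) {
    mv <- plan$moves[m, ]
    from <- c(mv$from_row, mv$from_col)
    to <- c(mv$to_row, mv$to_col)
    em[from[1], from[2]] <- FALSE     # the moving pallet leaves its cell
    pp <- plan_path(from, to, em)
    em[to[1], to[2]] <- TRUE
    idx <- which(registry$pallets$id == mv$id)
    registry$pallets$row[idx] <- to[1]
    registry$pallets$col[idx] <- to[2]
    cmds <- lapply(seq_len(max(nrow(pp) - 1, 0)), function(h)
      encode_command(transport_command(1, idx,
                                       c(pp[h, "col"], pp[h, "row"]),
                                       c(pp[h + 1, "col"], pp[h + 1, "row"]))))
    paths[[mv$id]] <- pp
    commands[[mv$id]] <- cmds
  }
  list(registry = registry, paths = paths, commands = commands)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Warehouse run: %d pallet(s), %d optimization(s), %d QCL iterations\n",
              length(x$pallet_ids), length(x$move_plans),
              x$total_iterations))
  cat(sprintf("Overall shelf life: %.3f -> %.3f day\n",
              x$overall_SL_initial, x$overall_SL_final))
  invisible(x)
}

#' Serialize a run report to JSON with stable key order
#'
#' @param report A `run_report` from [run_warehouse()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  out <- list(
    pallet_ids = report$pallet_ids,
    overall_SL_initial = report$overall_SL_initial,
    overall_SL_final = report$overall_SL_final,
    total_iterations = report$total_iterations,
    n_optimizations = length(report$move_plans),
    subroutine_iterations = lapply(report$move_plans, function(m)
      m$plan$subroutine_iterations),
    moves = lapply(report$move_plans, function(m) m$plan$moves),
    final_cells = report$final_cells,
    warnings = report$warnings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the optimization pipeline from logs on disk
#'
#' @param log_dir Directory of sensor logs from [cli_simulate()].
#' @param config Path to a YAML config, config list, or `NULL`.
#' @param out Optional path for the JSON report.
#' @return The `run_report`, invisibly when `out` is given.
#' @export
cli_optimize <- function(log_dir, config = NULL, out = NULL) {
  cfg <- if (is.list(config)) config else read_config(config)
  logs <- read_sensor_logs(log_dir)
  sc <- reference_scenario(config_params(cfg))
  report <- run_warehouse(logs, sc, cfg)
  if (!is.null(out)) { write_report(report, out); return(invisible(report)) }
  report
}

#' Run the Isd error characterization and write the table
#'
#' @param config Path to a YAML config, config list, or `NULL`.
#' @param out Output TSV path, or `NULL` to return the table only.
#' @param seed Overrides the config seed when non-`NULL`.
#' @return The error table data.frame.
#' @export
cli_characterize_isd <- function(config = NULL, out = NULL, seed = NULL) {
  cfg <- if (is.list(config)) config else read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  tab <- characterize_isd(cfg$isd$values, reps = cfg$isd$reps,
                          seed = cfg$seed,
                          spec = lattice_spec(cfg$room$M1, cfg$room$M2,
                                              cfg$room$l1, cfg$room$l2))
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
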