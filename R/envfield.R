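# Storage-room lattice, sparse-sensor field reconstruction and the
# inter-sensor-distance (Isd) error characterization.
#
# Lattice convention: row i spans the y axis, column j the x axis, both
# 1-based as in standard matrix notation. A sensor at metric position
# (x, y) lands in cell (floor(y/cell_dy)+1, floor(x/cell_dx)+1), clamped
# so sensors on the far walls fall in the last row/column.

#' Lattice specification for a storage room
#'
#' Divides a rectangular room of `l1 x l2` metres into an `M1 x M2` grid
#' of cells. Rows run along the y axis (length `l2`), columns along the x
#' axis (length `l1`).
#'
#' @param M1,M2 Lattice dimensions (cells), each >= 2.
#' @param l1,l2 Room side lengths (m), each > 0.
#' @return An object of class `lattice_spec` with cell sizes `cell_dx =
#'   l1/M2` and `cell_dy = l2/M1` (columns count across x).
#' @export
#' @examples
#' lattice_spec(5, 5, 6.3, 6.7)
lattice_spec <- function(M1, M2, l1, l2) {
  stopifnot(is.numeric(M1), is.numeric(M2), is.numeric(l1), is.numeric(l2))
  if (M1 < 2 || M2 < 2 || M1 != round(M1) || M2 != round(M2))
    stop("M1 and M2 must be integers >= 2")
  if (l1 <= 0 || l2 <= 0) stop("room side lengths must be positive")
  structure(list(M1 = as.integer(M1), M2 = as.integer(M2),
                 l1 = l1, l2 = l2,
                 cell_dx = l1 / M2, cell_dy = l2 / M1),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("Lattice %d x %d over a %.2f m x %.2f m room (cells %.2f x %.2f m)\n",
              x$M1, x$M2, x$l1, x$l2, x$cell_dx, x$cell_dy))
  invisible(x)
}

#' Build a wall-sensor table
#'
#' @param node_id Sensor identifiers.
#' @param x,y Metric positions (m) within the room.
#' @param T_acc,RH_acc Sensor accuracies (deg C, %RH).
#' @param battery Battery level (%).
#' @param working Working flag (1 = healthy, 0 = faulty).
#' @return A data.frame with one row per sensor.
#' @export
sensor_table <- function(node_id, x, y, T_acc = 2, RH_acc = 3.5,
                         battery = 100, working = 1L) {
  data.frame(node_id = node_id, x = x, y = y, T_acc = T_acc,
             RH_acc = RH_acc, battery = battery, working = working,
             stringsAsFactors = FALSE)
}

#' Assign lattice cells to sensors
#'
#' Maps each sensor's metric position to its lattice cell with floor
#' division, clamped so sensors mounted on the far walls (`x = l1` or
#' `y = l2`) land in the last cell.
#'
#' @param spec A [lattice_spec()].
#' @param sensors A sensor data.frame (see [sensor_table()]).
#' @return `sensors` with integer columns `row` and `col` added (1-based).
#' @export
#' @examples
#' sp <- lattice_spec(5, 5, 6.3, 6.7)
#' map_sensors_to_cells(sp, sensor_table("S1", 1.26, 0))  # cell (1, 2)
map_sensors_to_cells <- function(spec, sensors) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (any(sensors$x < 0 | sensors$x > spec$l1 |
          sensors$y < 0 | sensors$y > spec$l2))
    stop("sensor position outside the room")
  sensors$row <- cell_index(sensors$y, spec$cell_dy, spec$M1)
  sensors$col <- cell_index(sensors$x, spec$cell_dx, spec$M2)
  sensors
}

# Floor division with a tolerance so positions lying exactly on a grid
# line (up to fp rounding) fall into the upper cell, and far-wall
# positions clamp into the last cell.
cell_index <- function(pos, d, M) {
  as.integer(pmin(floor(pos / d + 1e-9) + 1L, M))
}

#' Scalar field on the lattice
#'
#' An `M1 x M2` matrix of an environmental quantity together with a mask
#' marking which cells hold direct sensor measurements; the remaining
#' cells are filled by [interpolate_field()].
#'
#' @param values Numeric matrix; unmeasured cells may be `NA`.
#' @param measured Logical matrix of the same shape; `TRUE` where a
#'   sensor measured the cell. Defaults to `!is.na(values)`.
#' @param quantity Label, e.g. `"temperature_C"` or `"RH_pct"`.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(values, measured = !is.na(values),
                         quantity = "temperature_C") {
  stopifnot(is.matrix(values), is.logical(measured),
            all(dim(values) == dim(measured)))
  if (any(measured & !is.finite(values)))
    stop("measured cells must carry finite values")
  structure(list(values = values, measured = measured, quantity = quantity),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("Scalar field (%s), %d x %d, %d measured cell(s)\n",
              x$quantity, nrow(x$values), ncol(x$values), sum(x$measured)))
  print(round(x$values, 2))
  invisible(x)
}

#' Fill unmeasured lattice cells by contiguous-element averaging
#'
#' Reconstructs the full field from sparse measurements: measured cells
#' are held fixed and every unmeasured cell is repeatedly replaced by the
#' mean of its available 4-neighbours (boundary cells average their
#' existing neighbours) in a deterministic row-major sweep, until the
#' largest per-sweep change falls below `tol`. This is a discrete Laplace
#' fill, so derived values obey the maximum principle: they stay within
#' the range of the measured values.
#'
#' @param field A [scalar_field()] with at least one measured cell.
#' @param tol Convergence tolerance on the max per-sweep change (same
#'   unit as the field; default 0.01).
#' @param max_sweeps Sweep cap (default 10000).
#' @return The field with all cells populated.
#' @export
interpolate_field <- function(field, tol = 0.01, max_sweeps = 10000L) {
  stopifnot(inherits(field, "scalar_field"))
  v <- field$values
  meas <- field$measured
  if (!any(meas)) stop("interpolation requires at least one measured cell")
  nr <- nrow(v); nc <- ncol(v)
  # seed unmeasured cells with the measured mean so the sweep starts finite
  v[!meas] <- mean(v[meas])
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        if (meas[i, j]) next
        nb <- c(if (i > 1) v[i - 1, j], if (i < nr) v[i + 1, j],
                if (j > 1) v[i, j - 1], if (j < nc) v[i, j + 1])
        new <- mean(nb)
        delta <- max(delta, abs(new - v[i, j]))
        v[i, j] <- new
      }
    }
    if (delta < tol) break
  }
  scalar_field(v, field$measured, field$quantity)
}

#' Elementwise absolute error between two fields
#'
#' @param truth,derived Two [scalar_field()]s on the same lattice.
#' @return A numeric matrix of absolute differences.
#' @export
field_error <- function(truth, derived) {
  stopifnot(inherits(truth, "scalar_field"), inherits(derived, "scalar_field"))
  if (!all(dim(truth$values) == dim(derived$values)))
    stop("fields must share the same lattice")
  abs(truth$values - derived$values)
}

#' Empirical rule for the number of wall sensors
#'
#' `Ns = round((l1 + l2) / isd_star)`, where `isd_star` is the largest
#' inter-sensor distance whose reconstruction error stays below the
#' sensor accuracy (determined by [characterize_isd()]).
#'
#' @param l1,l2 Room side lengths (m).
#' @param isd_star Admissible inter-sensor distance (m), > 0.
#' @return Integer sensor count.
#' @export
#' @examples
#' required_sensor_count(6.3, 6.7, 2.5)  # 5
required_sensor_count <- function(l1, l2, isd_star) {
  if (!is.numeric(isd_star) || !is.finite(isd_star) || isd_star <= 0)
    stop("isd_star must be a positive distance (m)")
  as.integer(floor((l1 + l2) / isd_star + 0.5))
}

#' Drop unhealthy sensors and record intervention warnings
#'
#' A node with battery strictly below 5% or a working flag of 0 is
#' excluded from measurement; each exclusion produces a warning record
#' asking for intervention.
#'
#' @param sensors Sensor data.frame with `battery` and `working` columns.
#' @return A list with `active` (healthy rows), `excluded` and `warnings`
#'   (character vector, one entry per exclusion).
#' @export
exclude_unhealthy <- function(sensors) {
  bad <- sensors$battery < 5 | sensors$working == 0
  warnings <- character(0)
  if (any(bad)) {
    reasons <- ifelse(sensors$battery[bad] < 5,
                      sprintf("battery %.1f%% < 5%%", sensors$battery[bad]),
                      "working flag 0")
    warnings <- sprintf("node %s excluded (%s): asking for intervention",
                        sensors$node_id[bad], reasons)
  }
  list(active = sensors[!bad, , drop = FALSE],
       excluded = sensors[bad, , drop = FALSE],
       warnings = warnings)
}

# Smooth synthetic truth field used by the Isd characterization: a plane
# plus one sinusoidal bump, coefficients drawn per replicate.
synthetic_truth_field <- function(spec, base = 21.3, grad_amp = 2,
                                  noise_sd = 0, quantity = "temperature_C") {
  xc <- (seq_len(spec$M2) - 0.5) * spec$cell_dx
  yc <- (seq_len(spec$M1) - 0.5) * spec$cell_dy
  gx <- stats::runif(1, -1, 1) * grad_amp / spec$l1
  gy <- stats::runif(1, -1, 1) * grad_amp / spec$l2
  amp <- stats::runif(1, 0, grad_amp / 2)
  phx <- stats::runif(1, 0, 2 * pi); phy <- stats::runif(1, 0, 2 * pi)
  v <- outer(yc, xc, function(y, x) {
    base + gx * x + gy * y +
      amp * sin(pi * x / spec$l1 + phx) * sin(pi * y / spec$l2 + phy)
  })
  if (noise_sd > 0) v <- v + matrix(stats::rnorm(length(v), 0, noise_sd),
                                    nrow = nrow(v))
  scalar_field(v, matrix(TRUE, spec$M1, spec$M2), quantity)
}

# Wall sensor positions spaced isd metres along the room perimeter,
# starting at the origin corner and walking counter-clockwise.
perimeter_sensors <- function(spec, isd) {
  per <- 2 * (spec$l1 + spec$l2)
  s <- seq(0, per - 1e-9, by = isd)
  pos <- t(vapply(s, function(d) {
    if (d < spec$l1) c(d, 0)
    else if (d < spec$l1 + spec$l2) c(spec$l1, d - spec$l1)
    else if (d < 2 * spec$l1 + spec$l2) c(2 * spec$l1 + spec$l2 - d, spec$l2)
    else c(0, per - d)
  }, numeric(2)))
  # guard against fp overshoot at the corners
  pos[, 1] <- pmin(pmax(pos[, 1], 0), spec$l1)
  pos[, 2] <- pmin(pmax(pos[, 2], 0), spec$l2)
  sensor_table(sprintf("P%02d", seq_len(nrow(pos))), pos[, 1], pos[, 2])
}

#' Characterize reconstruction error versus inter-sensor distance
#'
#' Re-creates the Isd error experiment on synthetic rooms: for each
#' candidate spacing, Setup 1 senses every lattice cell (ground truth)
#' while Setup 2 senses only wall positions spaced `isd` metres apart and
#' derives the rest by [interpolate_field()]; the elementwise absolute
#' error is aggregated over seeded replicates. An `isd` of 0 means full
#' coverage and yields zero error. Temperature and relative-humidity
#' fields are characterized jointly (RH derived from the temperature
#' field through the configured inverse coupling).
#'
#' @param isd_values Inter-sensor distances (m) to evaluate.
#' @param reps Monitoring events per distance (>= 2 for a spread).
#' @param seed RNG seed.
#' @param spec Room lattice, default the 5 x 5 grid over 6.3 x 6.7 m.
#' @param grad_amp Spatial contrast of the synthetic truth fields (deg C).
#' @param noise_sd Measurement noise added to sensed cells (deg C);
#'   0 gives the noiseless trend.
#' @param rh_base,rh_coupling RH level (%) and coupling (% per deg C)
#'   used to derive the companion RH field.
#' @return A data.frame with one row per `isd`: mean/sd of the
#'   temperature and RH errors and the Setup-2 sensor count.
#' @export
characterize_isd <- function(isd_values, reps = 16, seed = 1,
                             spec = lattice_spec(5, 5, 6.3, 6.7),
                             grad_amp = 2, noise_sd = 0,
                             rh_base = 55.73, rh_coupling = -2.5 / 3) {
  if (length(isd_values) == 0) stop("isd_values must be non-empty")
  if (reps < 2) stop("need reps >= 2 for a statistical spread")
  set.seed(seed)
  rows <- lapply(isd_values, function(isd) {
    errT <- errH <- numeric(0)
    ns <- NA_integer_
    for (r in seq_len(reps)) {
      truth <- synthetic_truth_field(spec, grad_amp = grad_amp)
      rh_truth <- scalar_field(rh_base + rh_coupling * (truth$values - 21.3),
                               matrix(TRUE, spec$M1, spec$M2), "RH_pct")
      if (isd <= 0) {
        meas <- matrix(TRUE, spec$M1, spec$M2)
        ns <- spec$M1 * spec$M2
      } else {
        sens <- map_sensors_to_cells(spec, perimeter_sensors(spec, isd))
        ns <- nrow(sens)
        meas <- matrix(FALSE, spec$M1, spec$M2)
        meas[cbind(sens$row, sens$col)] <- TRUE
      }
      noisy <- function(tr) {
        v <- tr$values
        if (noise_sd > 0)
          v[meas] <- v[meas] + stats::rnorm(sum(meas), 0, noise_sd)
        v[!meas] <- NA
        interpolate_field(scalar_field(v, meas, tr$quantity))
      }
      errT <- c(errT, field_error(truth, noisy(truth)))
      errH <- c(errH, field_error(rh_truth, noisy(rh_truth)))
    }
    data.frame(isd = isd, n_sensors = ns,
               mean_err_T = mean(errT), sd_err_T = stats::sd(errT),
               mean_err_RH = mean(errH), sd_err_RH = stats::sd(errH))
  })
  do.call(rbind, rows)
}
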