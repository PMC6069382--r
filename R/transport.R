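# Displacement layer: transporter command codec, unit-step path planning
# around the encumbrance matrix, and the drive-logic state machine.
#
# Command strings are 12 bytes with fixed separators:
#   [89, add_btT, add_btP, 89, 90, x1, y1, 90, 91, x2, y2, 91]
# add_btT addresses the transporter, add_btP the pallet; (x1, y1) is the
# current cell and (x2, y2) the next cell, which must differ by a single
# unit step along one axis.

SEP_ADDR <- 89L
SEP_INIT <- 90L
SEP_FINAL <- 91L

#' Transporter displacement command
#'
#' @param add_btT Transporter address (0-255).
#' @param add_btP Pallet address (0-255).
#' @param init_coord,final_coord Integer pairs `(x, y)` of lattice
#'   coordinates (each 0-255).
#' @return An object of class `transport_command`.
#' @export
transport_command <- function(add_btT, add_btP, init_coord, final_coord) {
  fields <- c(add_btT, add_btP, init_coord, final_coord)
  if (length(init_coord) != 2 || length(final_coord) != 2)
    stop("coordinates must be (x, y) pairs")
  if (any(!is.finite(fields)) || any(fields != round(fields)) ||
      any(fields < 0 | fields > 255))
    stop("all command fields must be integers in 0-255")
  structure(list(add_btT = as.integer(add_btT),
                 add_btP = as.integer(add_btP),
                 init_coord = as.integer(init_coord),
                 final_coord = as.integer(final_coord)),
            class = "transport_command")
}

#' Encode a transport command to its 12-byte string
#'
#' @param cmd A [transport_command()].
#' @return Integer vector of 12 byte values.
#' @export
#' @examples
#' b <- encode_command(transport_command(1, 2, c(2, 2), c(2, 3)))
#' decode_command(b, 5, 5)$command
encode_command <- function(cmd) {
  stopifnot(inherits(cmd, "transport_command"))
  as.integer(c(SEP_ADDR, cmd$add_btT, cmd$add_btP, SEP_ADDR,
               SEP_INIT, cmd$init_coord, SEP_INIT,
               SEP_FINAL, cmd$final_coord, SEP_FINAL))
}

#' Decode and validate a 12-byte transport command
#'
#' Verifies length and the three separator pairs, extracts the fields,
#' and checks the coordinates against the lattice bounds. Malformed or
#' out-of-range strings yield a structured rejection (the transporter
#' waits for the next communication); a mismatched transporter address
#' yields an addressed-elsewhere result with no motion.
#'
#' @param bytes Integer vector of byte values.
#' @param max1,max2 Maximum x and y coordinate indexes.
#' @param expected_address Optional transporter address to check
#'   `add_btT` against.
#' @return A list with `status` (`"ok"`, `"bad_length"`,
#'   `"bad_separator"`, `"out_of_range"`, `"addressed_elsewhere"`) and,
#'   when `status == "ok"`, the decoded `command`.
#' @export
decode_command <- function(bytes, max1, max2, expected_address = NULL) {
  if (length(bytes) != 12)
    return(list(status = "bad_length", command = NULL))
  b <- as.integer(bytes)
  if (b[1] != SEP_ADDR || b[4] != SEP_ADDR ||
      b[5] != SEP_INIT || b[8] != SEP_INIT ||
      b[9] != SEP_FINAL || b[12] != SEP_FINAL)
    return(list(status = "bad_separator", command = NULL))
  coords <- b[c(6, 7, 10, 11)]
  if (any(coords < 0) || b[6] > max1 || b[10] > max1 ||
      b[7] > max2 || b[11] > max2)
    return(list(status = "out_of_range", command = NULL))
  if (!is.null(expected_address) && b[2] != expected_address)
    return(list(status = "addressed_elsewhere", command = NULL))
  list(status = "ok",
       command = transport_command(b[2], b[3], b[6:7], b[10:11]))
}

#' Shortest collision-free unit-step path on the lattice
#'
#' Breadth-first search over 4-neighbours avoiding cells flagged in the
#' encumbrance matrix. The start cell is treated as free (the moving
#' pallet occupies it); the goal must be free. Neighbour expansion is
#' deterministic: x-axis moves before y-axis moves, increasing index
#' before decreasing, so tie-breaks are reproducible.
#'
#' @param start,goal Cells as `(row, col)` integer pairs.
#' @param em Logical encumbrance matrix (`TRUE` = occupied).
#' @return A `path_plan`: integer matrix of waypoints, one row per cell
#'   from start to goal.
#' @export
plan_path <- function(start, goal, em) {
  stopifnot(is.matrix(em), is.logical(em))
  nr <- nrow(em); nc <- ncol(em)
  inb <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc
  if (!inb(start) || !inb(goal)) stop("start/goal outside the lattice")
  if (em[goal[1], goal[2]]) stop("goal cell is occupied")
  free <- !em
  free[start[1], start[2]] <- TRUE
  idx <- function(p) (p[2] - 1L) * nr + p[1]
  prev <- rep(NA_integer_, nr * nc)
  seen <- rep(FALSE, nr * nc)
  queue <- list(as.integer(start))
  seen[idx(start)] <- TRUE
  head <- 1L
  found <- identical(as.integer(start), as.integer(goal))
  while (!found && head <= length(queue)) {
    cur <- queue[[head]]; head <- head + 1L
    # x-axis (column) moves first, increasing index before decreasing
    for (d in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
      nxt <- cur + d
      if (!inb(nxt) || !free[nxt[1], nxt[2]] || seen[idx(nxt)]) next
      seen[idx(nxt)] <- TRUE
      prev[idx(nxt)] <- idx(cur)
      queue[[length(queue) + 1L]] <- nxt
      if (nxt[1] == goal[1] && nxt[2] == goal[2]) { found <- TRUE; break }
    }
  }
  if (!found) stop("no collision-free path exists")
  # reconstruct
  cells <- list(as.integer(goal))
  at <- idx(goal)
  while (!is.na(prev[at])) {
    at <- prev[at]
    cells[[length(cells) + 1L]] <- c((at - 1L) %% nr + 1L,
                                     (at - 1L) %/% nr + 1L)
  }
  wp <- do.call(rbind, rev(cells))
  colnames(wp) <- c("row", "col")
  structure(wp, class = c("path_plan", class(wp)))
}

HEADINGS <- c("+x", "-x", "+y", "-y")
# clockwise cycle used to decide steering direction
CLOCKWISE <- c("+y" = "+x", "+x" = "-y", "-y" = "-x", "-x" = "+y")

#' Transporter drive state
#'
#' The behavioral model of the transporter: a compass heading on the
#' lattice (x along columns, y along rows), the axis-memory bit Z (0 when
#' the last travel was along x, 1 along y), the servo's central wheel
#' angle `cp` and steering offset `rs`.
#'
#' @param heading One of `"+x"`, `"-x"`, `"+y"`, `"-y"`.
#' @param cp Central angular wheel position (deg).
#' @param rs Steering rotation angle (deg) added/subtracted from `cp`.
#' @return An object of class `drive_state`.
#' @export
drive_state <- function(heading = "+x", cp = 90, rs = 45) {
  heading <- match.arg(heading, HEADINGS)
  structure(list(heading = heading, Z = as.integer(heading %in% c("+y", "-y")),
                 cp = cp, rs = rs),
            class = "drive_state")
}

step_direction <- function(dX, dY) {
  if (dX == 1) "+x" else if (dX == -1) "-x"
  else if (dY == 1) "+y" else "-y"
}

#' Execute one unit grid step of the transporter
#'
#' Given the current drive state and a unit step `(dX, dY)` (x along
#' columns, y along rows), emits the wheel angle and the DC-motor input
#' pair and updates heading and the axis bit Z. Motor semantics: equal
#' inputs keep the position, `(0, 1)` drives ahead, `(1, 0)` backward. A
#' step along the heading drives ahead with the wheel centred; the
#' opposite step drives backward without turning; a perpendicular step
#' steers (wheel at `cp + rs` for a clockwise turn, `cp - rs`
#' counter-clockwise) and re-orients the heading. Steps with
#' `|dX| + |dY| > 1` violate the step-by-step path constraint and are
#' rejected.
#'
#' @param state A [drive_state()].
#' @param dX,dY Unit step components, each in -1/0/1.
#' @return A list with the updated `state` and `outputs` (wheel_angle,
#'   IN1, IN2, moved direction or `"none"`).
#' @export
drive_step <- function(state, dX, dY) {
  stopifnot(inherits(state, "drive_state"))
  if (!dX %in% -1:1 || !dY %in% -1:1) stop("dX, dY must be in -1/0/1")
  if (abs(dX) + abs(dY) > 1)
    stop("invalid step: unit moves change exactly one axis")
  if (dX == 0 && dY == 0)
    return(list(state = state,
                outputs = list(wheel_angle = state$cp, IN1 = 0L, IN2 = 0L,
                               moved = "none")))
  dir <- step_direction(dX, dY)
  wheel <- state$cp
  in1 <- 0L; in2 <- 1L                      # default: go ahead
  heading <- state$heading
  if (dir == heading) {
    # straight ahead, wheel centred
  } else if (dir == CLOCKWISE[[heading]]) {
    wheel <- state$cp + state$rs
    heading <- dir
  } else if (heading == CLOCKWISE[[dir]]) {
    wheel <- state$cp - state$rs
    heading <- dir
  } else {
    # opposite direction: reverse without turning
    in1 <- 1L; in2 <- 0L
  }
  new_state <- drive_state(heading, state$cp, state$rs)
  new_state$Z <- as.integer(dir %in% c("+y", "-y"))
  list(state = new_state,
       outputs = list(wheel_angle = wheel, IN1 = in1, IN2 = in2,
                      moved = dir))
}

#' Replay a path plan through the drive state machine
#'
#' Applies [drive_step()] hop by hop and tracks the resulting position,
#' verifying that the actuation lands on each waypoint.
#'
#' @param plan A [plan_path()] result.
#' @param heading Initial heading.
#' @param cp,rs Wheel geometry passed to [drive_state()].
#' @return A data.frame with one row per hop: from/to cells, wheel
#'   angle, motor inputs, heading after the hop and whether the hop
#'   steered.
#' @export
simulate_route <- function(plan, heading = "+x", cp = 90, rs = 45) {
  stopifnot(inherits(plan, "path_plan"))
  st <- drive_state(heading, cp, rs)
  n <- nrow(plan) - 1L
  out <- data.frame(from_row = integer(n), from_col = integer(n),
                    to_row = integer(n), to_col = integer(n),
                    wheel_angle = numeric(n), IN1 = integer(n),
                    IN2 = integer(n), heading = character(n),
                    steered = logical(n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  pos <- plan[1, ]
  for (h in seq_len(n)) {
    nxt <- plan[h + 1, ]
    dX <- nxt[["col"]] - pos[["col"]]
    dY <- nxt[["row"]] - pos[["row"]]
    step <- drive_step(st, dX, dY)
    st <- step$state
    # derive the new position from the actuation, not from the plan, so
    # the replay genuinely verifies that the drive logic tracks the path
    delta <- switch(step$outputs$moved,
                    "+x" = c(0L, 1L), "-x" = c(0L, -1L),
                    "+y" = c(1L, 0L), "-y" = c(-1L, 0L), c(0L, 0L))
    pos <- c(row = pos[["row"]] + delta[1], col = pos[["col"]] + delta[2])
    if (pos[["row"]] != nxt[["row"]] || pos[["col"]] != nxt[["col"]])
      stop("drive logic diverged from the planned waypoint")
    out[h, ] <- list(plan[h, "row"], plan[h, "col"], nxt[["row"]],
                     nxt[["col"]], step$outputs$wheel_angle,
                     step$outputs$IN1, step$outputs$IN2, st$heading,
                     step$outputs$wheel_angle != cp)
  }
  out
}
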