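# Quality-controlled logistics (QCL): FEFO pallet placement on the
# storage-room lattice.
#
# The optimizer works on a shelf-life cube SL[i, j, p] — the shelf life
# pallet p would have if it sat in cell (i, j) under the current
# temperature field. One selection subroutine evaluates all cyclic left
# shifts of the active pallet-ID vector with a greedy first-come
# placement per order; the order with the highest summed shelf life
# identifies the "best pallet" (its first ID), which is displaced and
# excluded. Iteration accounting: one iteration per greedy placement and
# one per order sum, so a subroutine over n active pallets costs
# n * (n + 1) iterations; the final lone pallet costs a single placement
# iteration. A full run over Np pallets therefore executes
# sum_{n=2..Np} n(n+1) + 1 iterations (39 for Np = 4).

#' Pallet registry on a lattice
#'
#' @param id Pallet identifiers (distinct).
#' @param row,col Current lattice cells (1-based, distinct).
#' @param c Current quality factors (N).
#' @param params A single [kinetic_params()] shared by all pallets, or a
#'   list of one per pallet.
#' @param spec A [lattice_spec()]; enforces the capacity rule
#'   `Np < M1*M2 - 3`.
#' @return An object of class `pallet_registry`.
#' @export
pallet_registry <- function(id, row, col, c, params, spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  n <- length(id)
  if (length(row) != n || length(col) != n || length(c) != n)
    stop("id, row, col, c must have equal length")
  if (anyDuplicated(id)) stop("pallet IDs must be distinct")
  if (anyDuplicated(paste(row, col))) stop("pallet cells must be distinct")
  if (any(row < 1 | row > spec$M1 | col < 1 | col > spec$M2))
    stop("pallet cell outside the lattice")
  if (n >= spec$M1 * spec$M2 - 3)
    stop("too many pallets: Np must be < M1*M2 - 3")
  if (inherits(params, "kinetic_params")) params <- rep(list(params), n)
  if (length(params) != n) stop("one kinetic_params per pallet required")
  structure(list(pallets = data.frame(id = id, row = as.integer(row),
                                      col = as.integer(col), c = c,
                                      stringsAsFactors = FALSE),
                 params = params, spec = spec),
            class = "pallet_registry")
}

#' @export
print.pallet_registry <- function(x, ...) {
  cat(sprintf("Pallet registry: %d pallet(s) on a %d x %d lattice\n",
              nrow(x$pallets), x$spec$M1, x$spec$M2))
  print(x$pallets)
  invisible(x)
}

#' Encumbrance matrix of pallet-occupied cells
#'
#' @param registry A [pallet_registry()].
#' @return Logical `M1 x M2` matrix, `TRUE` where a pallet sits.
#' @export
encumbrance_matrix <- function(registry) {
  stopifnot(inherits(registry, "pallet_registry"))
  em <- matrix(FALSE, registry$spec$M1, registry$spec$M2)
  em[cbind(registry$pallets$row, registry$pallets$col)] <- TRUE
  em
}

#' Quality and shelf-life cubes over the lattice
#'
#' For every pallet p and cell (i, j), derives the decay rate from the
#' cell temperature, the hypothetical quality after one sampling
#' interval, and the shelf life the pallet would have in that cell:
#' `SL[i,j,p] = shelf_life(c_p, params_p, k(T_amb[i,j]))`.
#'
#' @param field A fully populated temperature [scalar_field()].
#' @param registry A [pallet_registry()].
#' @param ts Sampling interval (s) used for the hypothetical one-step
#'   quality cube.
#' @return A list with 3-D arrays `C` and `SL` (`M1 x M2 x Np`) and the
#'   pallet IDs along the third dimension.
#' @export
build_cubes <- function(field, registry, ts = 300) {
  stopifnot(inherits(field, "scalar_field"),
            inherits(registry, "pallet_registry"))
  if (anyNA(field$values) || any(!is.finite(field$values)))
    stop("field must be fully populated before building cubes")
  M1 <- registry$spec$M1; M2 <- registry$spec$M2
  np <- nrow(registry$pallets)
  C <- SL <- array(0, dim = c(M1, M2, max(np, 1)))
  if (np == 0) return(list(C = array(0, c(M1, M2, 0)),
                           SL = array(0, c(M1, M2, 0)), ids = character(0)))
  for (p in seq_len(np)) {
    pars <- registry$params[[p]]
    cp <- registry$pallets$c[p]
    k <- arrhenius_rate(pars, field$values)      # vectorized over cells
    C[, , p] <- cp * exp(-k * ts / 86400)
    SL[, , p] <- vapply(seq_along(k), function(ix)
      shelf_life(cp, pars, k[ix]), numeric(1))
  }
  list(C = C, SL = SL, ids = registry$pallets$id)
}

#' Displacement trigger on consecutive quality measurements
#'
#' Fires when the firmness decrease between the last two consecutive
#' measurements, expressed per second, meets or exceeds the configured
#' threshold.
#'
#' @param c_history Numeric vector of consecutive quality measurements
#'   (N), length >= 2; the last two entries are compared.
#' @param threshold Trigger (N/s), e.g. [c_th_preset()].
#' @param interval_s Time between consecutive measurements (s).
#' @return `TRUE` if displacement operations should start.
#' @export
displacement_trigger <- function(c_history, threshold, interval_s = 600) {
  if (length(c_history) < 2) stop("need at least two consecutive measurements")
  if (!is.finite(interval_s) || interval_s <= 0)
    stop("interval_s must be positive")
  m <- length(c_history)
  drop_per_s <- (c_history[m - 1] - c_history[m]) / interval_s
  drop_per_s >= threshold
}

# Row-major argmax over allowed cells: smallest row, then column, wins ties.
argmax_cell <- function(layer, allowed) {
  vals <- layer
  vals[!allowed] <- -Inf
  best <- max(vals)
  if (!is.finite(best)) stop("no free cell available for placement")
  hits <- which(vals == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  hits[1, ]
}

#' Greedy placement of one cyclic pallet order
#'
#' Walks the IDs in the given order; each pallet takes the free cell
#' maximizing its shelf-life layer (its own current cell counts as free),
#' which is then excluded for the rest of the order. The summed shelf
#' life of the assignment, SLs, scores the order. Iterations: one per
#' placement plus one for the sum.
#'
#' @param order Character/ID vector, a permutation of the active IDs.
#' @param cube Output of [build_cubes()].
#' @param occupied Logical matrix of cells occupied by pallets (the
#'   encumbrance matrix); a pallet's own cell is treated as free for
#'   itself.
#' @param own_cells Two-column matrix of current (row, col) per active
#'   ID, with rownames the IDs.
#' @return List with `assignment` (data.frame id/row/col/SL), `SLs` and
#'   `iterations` (= n + 1).
#' @export
evaluate_order <- function(order, cube, occupied, own_cells) {
  n <- length(order)
  if (!setequal(order, rownames(own_cells)) || n != nrow(own_cells))
    stop("order must be a permutation of the active pallet IDs")
  free <- !occupied
  free[own_cells] <- TRUE                  # own cells count as free
  if (sum(free) < n) stop("fewer free cells than pallets in the order")
  assigned <- matrix(FALSE, nrow(occupied), ncol(occupied))
  out <- data.frame(id = order, row = integer(n), col = integer(n),
                    SL = numeric(n), stringsAsFactors = FALSE)
  iterations <- 0L
  for (m in seq_len(n)) {
    id <- order[m]
    p <- match(id, cube$ids)
    allowed <- (!occupied) & (!assigned)
    oc <- own_cells[id, ]
    if (!assigned[oc[1], oc[2]]) allowed[oc[1], oc[2]] <- TRUE
    cell <- argmax_cell(cube$SL[, , p], allowed)
    assigned[cell[1], cell[2]] <- TRUE
    out$row[m] <- cell[1]; out$col[m] <- cell[2]
    out$SL[m] <- cube$SL[cell[1], cell[2], p]
    iterations <- iterations + 1L
  }
  SLs <- sum(out$SL)
  iterations <- iterations + 1L    # the order-sum step
  list(assignment = out, SLs = SLs, iterations = iterations)
}

#' Select the best pallet to displace
#'
#' Evaluates all n cyclic left shifts of the active ID vector with
#' [evaluate_order()] and picks the order with the highest summed shelf
#' life (earliest shift wins ties). The best pallet is the first ID of
#' the winning order and its target the cell that order assigned to it.
#' Costs n placements + 1 sum per order: n(n+1) iterations in total
#' (20 for n = 4, 12 for n = 3).
#'
#' @param active_ids Active pallet IDs (>= 2).
#' @param cube Output of [build_cubes()].
#' @param occupied Encumbrance matrix.
#' @param own_cells (row, col) matrix as in [evaluate_order()].
#' @return List with `best_id`, `target` (row, col), `order` (winning
#'   order), `SLs_all` (per shift), `iterations` (= n(n+1)).
#' @export
select_best <- function(active_ids, cube, occupied, own_cells) {
  n <- length(active_ids)
  if (n < 2) stop("select_best requires >= 2 active pallets")
  iterations <- 0L
  evals <- vector("list", n)
  for (s in seq_len(n)) {
    ord <- active_ids[((s - 1 + seq_len(n) - 1) %% n) + 1]
    evals[[s]] <- evaluate_order(ord, cube, occupied, own_cells)
    iterations <- iterations + evals[[s]]$iterations
  }
  SLs_all <- vapply(evals, `[[`, numeric(1), "SLs")
  win <- which.max(SLs_all)           # earliest shift on ties
  winner <- evals[[win]]
  list(best_id = winner$assignment$id[1],
       target = c(winner$assignment$row[1], winner$assignment$col[1]),
       order = winner$assignment$id, SLs_all = SLs_all,
       assignment = winner$assignment, iterations = iterations)
}

#' Run the full QCL displacement optimization
#'
#' Repeats [select_best()] on the shrinking active set, executing one
#' displacement per subroutine and excluding the moved pallet, until a
#' single pallet remains; that pallet is placed at the shelf-life argmax
#' of the remaining free cells (one final iteration). Temperatures and
#' quality factors are frozen for the duration of one run; re-triggering
#' happens on the next monitoring tick.
#'
#' @param registry A [pallet_registry()].
#' @param cube Output of [build_cubes()] for the registry.
#' @return A `move_plan`: data.frame `moves` (id, from/to cells, SL
#'   before/after), `subroutine_iterations`, `total_iterations`,
#'   `overall_SL_before`, `overall_SL_after`.
#' @export
qcl_optimize <- function(registry, cube) {
  stopifnot(inherits(registry, "pallet_registry"))
  pl <- registry$pallets
  np <- nrow(pl)
  if (np == 0) stop("registry holds no pallets")
  occupied <- encumbrance_matrix(registry)
  own <- cbind(pl$row, pl$col)
  rownames(own) <- pl$id
  layer_of <- function(id) match(id, cube$ids)
  sl_at <- function(id, cell) cube$SL[cell[1], cell[2], layer_of(id)]
  before <- sum(vapply(pl$id, function(id) sl_at(id, own[id, ]), numeric(1)))

  active <- pl$id
  moves <- data.frame(id = character(0), from_row = integer(0),
                      from_col = integer(0), to_row = integer(0),
                      to_col = integer(0), SL_from = numeric(0),
                      SL_to = numeric(0), stringsAsFactors = FALSE)
  sub_iters <- integer(0)
  while (length(active) > 1) {
    sel <- select_best(active, cube, occupied,
                       own[active, , drop = FALSE])
    sub_iters <- c(sub_iters, sel$iterations)
    from <- own[sel$best_id, ]
    to <- sel$target
    moves[nrow(moves) + 1, ] <- list(sel$best_id, from[1], from[2],
                                     to[1], to[2],
                                     sl_at(sel$best_id, from),
                                     sl_at(sel$best_id, to))
    occupied[from[1], from[2]] <- FALSE
    occupied[to[1], to[2]] <- TRUE
    own[sel$best_id, ] <- to
    active <- setdiff(active, sel$best_id)
  }
  # final lone pallet: one placement iteration, no order sum
  id <- active[1]
  from <- own[id, ]
  allowed <- !occupied
  allowed[from[1], from[2]] <- TRUE
  to <- argmax_cell(cube$SL[, , layer_of(id)], allowed)
  moves[nrow(moves) + 1, ] <- list(id, from[1], from[2], to[1], to[2],
                                   sl_at(id, from), sl_at(id, to))
  occupied[from[1], from[2]] <- FALSE
  occupied[to[1], to[2]] <- TRUE
  own[id, ] <- to
  sub_iters <- c(sub_iters, 1L)

  after <- sum(vapply(pl$id, function(id) sl_at(id, own[id, ]), numeric(1)))
  structure(list(moves = moves, subroutine_iterations = sub_iters,
                 total_iterations = sum(sub_iters),
                 overall_SL_before = before, overall_SL_after = after,
                 final_cells = own),
            class = "move_plan")
}

#' @export
print.move_plan <- function(x, ...) {
  cat(sprintf("QCL move plan: %d move(s), %d iterations (subroutines: %s)\n",
              nrow(x$moves), x$total_iterations,
              paste(x$subroutine_iterations, collapse = " + ")))
  cat(sprintf("Overall shelf life: %.3f -> %.3f day\n",
              x$overall_SL_before, x$overall_SL_after))
  print(x$moves)
  invisible(x)
}

#' Closed-form QCL iteration count
#'
#' `sum_{n=2..Np} n(n+1) + 1` — the number of recursive iterations a full
#' optimization over `Np` pallets executes under the placement + sum
#' accounting (39 for `Np = 4`).
#'
#' @param np Number of pallets, >= 1.
#' @return Integer iteration count (1 when `np = 1`).
#' @export
qcl_iteration_count <- function(np) {
  stopifnot(np >= 1)
  if (np == 1) return(1L)
  as.integer(sum(vapply(2:np, function(n) n * (n + 1), numeric(1))) + 1L)
}
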