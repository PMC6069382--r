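# Shared fixtures and independent oracles used across the suite.

tomato <- tomato_firmness_params()

# Direct evaluation of the Arrhenius ratio form, independent of the
# package's arrhenius_rate (kept deliberately verbose).
oracle_arrhenius <- function(k_ref, T_ref_C, Ea_kJ, T_C) {
  R <- 8.314
  k_ref * exp(-(Ea_kJ * 1000 / R) * (1 / (T_C + 273.15) -
                                       1 / (T_ref_C + 273.15)))
}

# Exact solve of the harmonic (contiguous-average) system: unmeasured
# cells satisfy v = mean(available neighbours); measured cells are
# boundary data. Linear solve, independent of the iterative sweep.
oracle_harmonic_fill <- function(values, measured) {
  nr <- nrow(values); nc <- ncol(values)
  unk <- which(!measured)
  if (length(unk) == 0) return(values)
  A <- matrix(0, length(unk), length(unk))
  b <- numeric(length(unk))
  pos <- function(i, j) (j - 1) * nr + i
  for (u in seq_along(unk)) {
    i <- (unk[u] - 1) %% nr + 1
    j <- (unk[u] - 1) %/% nr + 1
    nbs <- list()
    if (i > 1) nbs <- c(nbs, list(c(i - 1, j)))
    if (i < nr) nbs <- c(nbs, list(c(i + 1, j)))
    if (j > 1) nbs <- c(nbs, list(c(i, j - 1)))
    if (j < nc) nbs <- c(nbs, list(c(i, j + 1)))
    A[u, u] <- length(nbs)
    for (nb in nbs) {
      q <- pos(nb[1], nb[2])
      if (measured[nb[1], nb[2]]) b[u] <- b[u] + values[q]
      else A[u, match(q, unk)] <- A[u, match(q, unk)] - 1
    }
  }
  out <- values
  out[unk] <- solve(A, b)
  out
}

# Independent greedy replay of one cyclic order over a shelf-life cube:
# plain loops, flattened row-major scan for the argmax.
oracle_greedy_replay <- function(order, sl, ids, occupied, own) {
  taken <- matrix(FALSE, nrow(occupied), ncol(occupied))
  total <- 0
  cells <- list()
  for (id in order) {
    p <- match(id, ids)
    best <- -Inf; best_cell <- NULL
    for (i in seq_len(nrow(occupied))) {
      for (j in seq_len(ncol(occupied))) {
        own_cell <- own[id, 1] == i && own[id, 2] == j
        if ((occupied[i, j] && !own_cell) || taken[i, j]) next
        if (sl[i, j, p] > best) { best <- sl[i, j, p]; best_cell <- c(i, j) }
      }
    }
    taken[best_cell[1], best_cell[2]] <- TRUE
    cells[[id]] <- best_cell
    total <- total + best
  }
  list(SLs = total, cells = cells)
}

# Random QCL problem on an M x M lattice: registry at distinct cells and
# a positive random shelf-life cube.
random_qcl_problem <- function(M, np, seed) {
  set.seed(seed)
  spec <- lattice_spec(M, M, M * 1.26, M * 1.34)
  cells <- sample(M * M, np)
  reg <- pallet_registry(as.character(seq_len(np)),
                         row = (cells - 1) %% M + 1,
                         col = (cells - 1) %/% M + 1,
                         c = rep(12.4, np), params = tomato, spec = spec)
  sl <- array(runif(M * M * np, 1, 10), dim = c(M, M, np))
  list(registry = reg, cube = list(C = sl, SL = sl,
                                   ids = reg$pallets$id))
}

# Exhaustive shortest-path length on a small lattice by breadth-less
# brute force: iterative relaxation of distance matrix (Bellman-Ford
# style), independent of the planner's BFS.
oracle_shortest_len <- function(start, goal, em) {
  nr <- nrow(em); nc <- ncol(em)
  free <- !em
  free[start[1], start[2]] <- TRUE
  dist <- matrix(Inf, nr, nc)
  dist[start[1], start[2]] <- 0
  for (iter in seq_len(nr * nc)) {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!free[i, j]) next
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- i + d[1]; nj <- j + d[2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc || !free[ni, nj]) next
        if (dist[ni, nj] + 1 < dist[i, j]) {
          dist[i, j] <- dist[ni, nj] + 1; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist[goal[1], goal[2]]
}
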