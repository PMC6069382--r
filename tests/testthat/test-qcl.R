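# QCL optimizer: cubes, trigger, cyclic-greedy subroutines, iteration
# accounting and the FEFO move schedule.

test_that("registry construction enforces capacity and distinctness", {
  sp <- lattice_spec(5, 5, 6.3, 6.7)
  expect_error(pallet_registry(c("1", "1"), c(1, 2), c(1, 2), c(12, 12),
                               tomato, sp), "distinct")
  expect_error(pallet_registry(c("1", "2"), c(1, 1), c(1, 1), c(12, 12),
                               tomato, sp), "distinct")
  expect_error(pallet_registry(as.character(1:22), rep(1:5, 5)[1:22],
                               rep(1:5, each = 5)[1:22], rep(12, 22),
                               tomato, sp), "Np")
  reg <- reference_scenario()$registry
  em <- encumbrance_matrix(reg)
  expect_equal(sum(em), 4)
  expect_true(all(em[cbind(reg$pallets$row, reg$pallets$col)]))
})

test_that("cubes hold the hypothetical shelf life per pallet per cell", {
  sc <- reference_scenario()
  # uniform field: every layer constant
  fu <- scalar_field(matrix(21.3, 5, 5), matrix(TRUE, 5, 5))
  cu <- build_cubes(fu, sc$registry)
  for (p in 1:4) expect_equal(max(cu$SL[, , p]) - min(cu$SL[, , p]), 0)
  expect_equal(cu$SL[1, 1, 1],
               shelf_life(12.4, tomato, arrhenius_rate(tomato, 21.3)))
  # one cold cell is the argmax of every layer
  v <- matrix(25, 5, 5); v[4, 2] <- 15
  cc <- build_cubes(scalar_field(v, matrix(TRUE, 5, 5)), sc$registry)
  for (p in 1:4)
    expect_equal(which.max(cc$SL[, , p]), (2 - 1) * 5 + 4)
  # quality cube decays over one interval, more in warm cells
  expect_true(all(cc$C[, , 1] < 12.4))
  expect_gt(cc$C[4, 2, 1], cc$C[1, 1, 1])
  expect_error(build_cubes(scalar_field(matrix(NA_real_, 5, 5),
                                        matrix(FALSE, 5, 5)), sc$registry),
               "at least one measured|populated")
})

test_that("the displacement trigger compares per-second firmness drops", {
  expect_false(displacement_trigger(c(12.4, 12.4), c_th_preset("24C"), 600))
  # decay simulated at 30 degC over 10 min exceeds the 26 degC preset
  k30 <- arrhenius_rate(tomato, 30)
  c_after <- decay_step(12.4, k30, 600 / 86400)
  expect_true(displacement_trigger(c(12.4, c_after),
                                   c_th_preset("26C"), 600))
  # the two shipped presets carry their configured values
  expect_equal(c_th_preset("24C"), 2.68e-5)
  expect_equal(c_th_preset("26C"), 3.184e-5)
  expect_error(displacement_trigger(12.4, 1e-5), "two consecutive")
})

test_that("greedy order evaluation matches the independent replay oracle", {
  for (seed in 1:10) {
    prob <- random_qcl_problem(4, 4, seed)
    reg <- prob$registry
    occ <- encumbrance_matrix(reg)
    own <- cbind(reg$pallets$row, reg$pallets$col)
    rownames(own) <- reg$pallets$id
    ord <- sample(reg$pallets$id)
    got <- evaluate_order(ord, prob$cube, occ, own)
    want <- oracle_greedy_replay(ord, prob$cube$SL, prob$cube$ids, occ, own)
    expect_equal(got$SLs, want$SLs, tolerance = 1e-12)
    expect_equal(got$iterations, length(ord) + 1L)
    # assignments distinct and inside the lattice
    expect_equal(anyDuplicated(paste(got$assignment$row,
                                     got$assignment$col)), 0L)
    expect_true(all(got$assignment$row %in% 1:4 &
                      got$assignment$col %in% 1:4))
  }
  # identical layers: SLs independent of the order
  sl <- array(rep(matrix(1:9, 3, 3), 2), dim = c(3, 3, 2))
  occ <- matrix(FALSE, 3, 3); occ[1, 1] <- occ[2, 2] <- TRUE
  own <- rbind(A = c(1, 1), B = c(2, 2))
  cube <- list(SL = sl, ids = c("A", "B"))
  e1 <- evaluate_order(c("A", "B"), cube, occ, own)
  e2 <- evaluate_order(c("B", "A"), cube, occ, own)
  expect_equal(e1$SLs, e2$SLs)
})

test_that("select_best scans all cyclic shifts with the printed iteration cost", {
  for (np in 2:4) {
    prob <- random_qcl_problem(5, np, np + 100)
    reg <- prob$registry
    occ <- encumbrance_matrix(reg)
    own <- cbind(reg$pallets$row, reg$pallets$col)
    rownames(own) <- reg$pallets$id
    sel <- select_best(reg$pallets$id, prob$cube, occ, own)
    expect_equal(sel$iterations, np * (np + 1))   # 20 @ n=4, 12 @ n=3
    # winning SLs equals the best over an explicit shift enumeration
    shifts <- lapply(seq_len(np) - 1, function(s)
      reg$pallets$id[((s + seq_len(np) - 1) %% np) + 1])
    oracle <- vapply(shifts, function(o)
      oracle_greedy_replay(o, prob$cube$SL, prob$cube$ids, occ, own)$SLs,
      numeric(1))
    expect_equal(max(sel$SLs_all), max(oracle), tolerance = 1e-12)
    expect_equal(sel$best_id, sel$order[1])
  }
  # all-equal cube: first cyclic order wins by tie-break
  sl <- array(1, dim = c(3, 3, 2))
  occ <- matrix(FALSE, 3, 3); occ[1, 1] <- occ[3, 3] <- TRUE
  own <- rbind(A = c(1, 1), B = c(3, 3))
  sel <- select_best(c("A", "B"), list(SL = sl, ids = c("A", "B")),
                     occ, own)
  expect_equal(sel$order, c("A", "B"))
  expect_error(select_best("A", list(SL = sl, ids = "A"), occ,
                           own["A", , drop = FALSE]), ">= 2")
})

test_that("full optimization reproduces the recursive iteration accounting", {
  for (np in 2:6) {
    prob <- random_qcl_problem(5, np, np)
    plan <- qcl_optimize(prob$registry, prob$cube)
    expect_equal(plan$total_iterations, qcl_iteration_count(np))
    subs <- plan$subroutine_iterations
    expect_equal(subs, c(vapply(np:2, function(n) n * (n + 1L), integer(1)),
                         1L))
  }
  # the reference 4-pallet scenario: 20 + 12 + 6 + 1 = 39
  sc <- reference_scenario()
  f <- scalar_field(matrix(seq(19, 24, length.out = 25), 5, 5),
                    matrix(TRUE, 5, 5))
  plan <- qcl_optimize(sc$registry, build_cubes(f, sc$registry))
  expect_equal(plan$subroutine_iterations[1:2], c(20L, 12L))
  expect_equal(plan$total_iterations, 39L)
})

test_that("optimization never decreases the overall shelf life", {
  for (seed in 1:25) {
    np <- sample(2:6, 1)
    prob <- random_qcl_problem(5, np, seed * 7)
    plan <- qcl_optimize(prob$registry, prob$cube)
    expect_gte(plan$overall_SL_after, plan$overall_SL_before - 1e-9)
    # final cells distinct and within the lattice
    fc <- plan$final_cells
    expect_equal(anyDuplicated(paste(fc[, 1], fc[, 2])), 0L)
    expect_true(all(fc >= 1 & fc <= 5))
  }
})

test_that("single-pallet optimization places at the global argmax", {
  prob <- random_qcl_problem(4, 1, 5)
  plan <- qcl_optimize(prob$registry, prob$cube)
  expect_equal(plan$total_iterations, 1L)
  best <- which(prob$cube$SL[, , 1] == max(prob$cube$SL[, , 1]),
                arr.ind = TRUE)[1, ]
  expect_equal(unname(plan$final_cells[1, ]), unname(best))
})
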