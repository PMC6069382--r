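# Command codec, path planning and the transporter drive logic.

test_that("the 12-byte codec round-trips over the valid domain", {
  set.seed(11)
  for (i in 1:200) {
    cmd <- transport_command(sample(0:255, 1), sample(0:255, 1),
                             sample(0:255, 2, replace = TRUE),
                             sample(0:255, 2, replace = TRUE))
    b <- encode_command(cmd)
    expect_length(b, 12)
    expect_equal(b[c(1, 4)], c(89L, 89L))
    expect_equal(b[c(5, 8)], c(90L, 90L))
    expect_equal(b[c(9, 12)], c(91L, 91L))
    got <- decode_command(b, 255, 255)
    expect_equal(got$status, "ok")
    expect_equal(got$command, cmd)
  }
  expect_error(transport_command(256, 0, c(0, 0), c(0, 0)), "0-255")
})

test_that("malformed or out-of-range strings yield distinct rejections", {
  b <- encode_command(transport_command(7, 3, c(2, 2), c(2, 3)))
  expect_equal(decode_command(b[-1], 5, 5)$status, "bad_length")
  bad <- b; bad[5] <- 99L
  expect_equal(decode_command(bad, 5, 5)$status, "bad_separator")
  # coordinate beyond the lattice bound
  far <- encode_command(transport_command(7, 3, c(6, 2), c(2, 3)))
  expect_equal(decode_command(far, 5, 5)$status, "out_of_range")
  # mismatched transporter address: no motion, addressed elsewhere
  expect_equal(decode_command(b, 5, 5, expected_address = 9)$status,
               "addressed_elsewhere")
  expect_equal(decode_command(b, 5, 5, expected_address = 7)$status, "ok")
})

test_that("path plans are unit-step, collision-free and shortest", {
  em <- matrix(FALSE, 5, 5)
  # degenerate: start equals goal
  p0 <- plan_path(c(1, 1), c(1, 1), em)
  expect_equal(nrow(p0), 1)
  # empty room: Manhattan lower bound met
  p1 <- plan_path(c(1, 1), c(3, 1), em)
  expect_equal(nrow(p1), 3)
  # wall of obstacles forcing a detour
  em2 <- matrix(FALSE, 5, 5)
  em2[2, 1:4] <- TRUE
  p2 <- plan_path(c(1, 1), c(3, 1), em2)
  expect_equal(nrow(p2) - 1, oracle_shortest_len(c(1, 1), c(3, 1), em2))
  expect_true(all(!em2[p2[-1, , drop = FALSE]]))
  # blocked goal and unreachable goal
  em3 <- matrix(FALSE, 3, 3); em3[2, ] <- TRUE
  expect_error(plan_path(c(1, 1), c(3, 3), em3), "no collision-free")
  em3[3, 3] <- TRUE
  expect_error(plan_path(c(1, 1), c(3, 3), em3), "occupied")
})

test_that("planned length equals the exhaustive shortest path on small rooms", {
  # every obstacle set of size <= 2 on a 4x4 room, corner to corner
  cells <- setdiff(1:16, c(1, 16))
  sets <- c(list(integer(0)), as.list(cells),
            combn(cells, 2, simplify = FALSE))
  for (s in sets) {
    em <- matrix(FALSE, 4, 4)
    em[s] <- TRUE
    want <- oracle_shortest_len(c(1, 1), c(4, 4), em)
    if (!is.finite(want)) {
      expect_error(plan_path(c(1, 1), c(4, 4), em))
    } else {
      p <- plan_path(c(1, 1), c(4, 4), em)
      expect_equal(nrow(p) - 1, want)
      hops <- abs(diff(p[, 1])) + abs(diff(p[, 2]))
      expect_true(all(hops == 1))
    }
  }
  # seeded random denser instances
  set.seed(23)
  for (i in 1:50) {
    em <- matrix(FALSE, 5, 5)
    em[sample(setdiff(1:25, c(1, 25)), 4)] <- TRUE
    want <- oracle_shortest_len(c(1, 1), c(5, 5), em)
    if (is.finite(want))
      expect_equal(nrow(plan_path(c(1, 1), c(5, 5), em)) - 1, want)
  }
})

test_that("drive steps follow the motor truth table", {
  st <- drive_state("+x", cp = 90, rs = 45)
  # zero step: keep position, wheel centred
  keep <- drive_step(st, 0, 0)
  expect_equal(keep$outputs$IN1, keep$outputs$IN2)
  expect_equal(keep$outputs$wheel_angle, 90)
  # ahead along the heading: 01, wheel centred
  ahead <- drive_step(st, 1, 0)
  expect_equal(c(ahead$outputs$IN1, ahead$outputs$IN2), c(0L, 1L))
  expect_equal(ahead$outputs$wheel_angle, 90)
  expect_equal(ahead$state$Z, 0L)
  # opposite: backward 10, no steering, heading kept
  back <- drive_step(st, -1, 0)
  expect_equal(c(back$outputs$IN1, back$outputs$IN2), c(1L, 0L))
  expect_equal(back$state$heading, "+x")
  # perpendicular: steering off-centre, heading re-oriented, axis bit set
  turn <- drive_step(st, 0, 1)
  expect_true(turn$outputs$wheel_angle != 90)
  expect_equal(turn$state$heading, "+y")
  expect_equal(turn$state$Z, 1L)
  # step-by-step constraint: diagonal and long steps rejected
  expect_error(drive_step(st, 1, 1), "one axis")
  expect_error(drive_step(st, 2, 0), "-1/0/1")
})

test_that("route replay is position-exact and counts turns correctly", {
  # L-shaped path: exactly one steering event
  em <- matrix(FALSE, 5, 5)
  plan <- plan_path(c(1, 1), c(3, 3), em)
  route <- simulate_route(plan, heading = if (plan[2, 2] != 1) "+x" else "+y")
  expect_equal(sum(route$steered), 1)
  expect_equal(unname(route[nrow(route), c("to_row", "to_col")]),
               data.frame(3L, 3L), ignore_attr = TRUE)
  # 100 seeded random plans all land on the goal
  set.seed(31)
  for (i in 1:100) {
    em <- matrix(FALSE, 5, 5)
    em[sample(setdiff(1:25, c(1, 25)), 3)] <- TRUE
    got <- tryCatch(plan_path(c(1, 1), c(5, 5), em), error = function(e) NULL)
    if (is.null(got)) next
    rt <- simulate_route(got, heading = sample(c("+x", "-x", "+y", "-y"), 1))
    expect_equal(c(rt$to_row[nrow(rt)], rt$to_col[nrow(rt)]), c(5, 5))
  }
})

test_that("the printed pallet-3 route replays to its final cell", {
  # metric waypoints (1.26, 5.36) -> (0, 5.36) -> (0, 2.68) on the 6x6
  # node grid (index = round(position / cell size)), expanded to unit
  # steps; x -> column index, y -> row index (0-based nodes + 1)
  node <- function(x, y) c(round(y / 1.34) + 1, round(x / 1.26) + 1)
  wps <- rbind(node(1.26, 5.36), node(0, 5.36), node(0, 2.68))
  # expand to unit steps
  path <- wps[1, , drop = FALSE]
  for (r in 2:nrow(wps)) {
    to <- wps[r, ]
    repeat {
      cur <- path[nrow(path), ]
      if (all(cur == to)) break
      ax <- which(cur != to)[1]
      cur[ax] <- cur[ax] + sign(to[ax] - cur[ax])
      path <- rbind(path, cur)
    }
  }
  colnames(path) <- c("row", "col")
  class(path) <- c("path_plan", class(path))
  hops <- abs(diff(path[, 1])) + abs(diff(path[, 2]))
  expect_true(all(hops == 1))
  rt <- simulate_route(path, heading = "-x")
  expect_equal(c(rt$to_row[nrow(rt)], rt$to_col[nrow(rt)]),
               unname(node(0, 2.68)))
})
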