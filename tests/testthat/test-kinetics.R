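# Arrhenius rate law, first-order decay and shelf-life prediction.

test_that("arrhenius_rate reproduces the ratio form of the rate law", {
  # identity at the reference temperature
  expect_equal(arrhenius_rate(tomato, 20), 0.2, tolerance = 1e-12)
  # frozen values from the independent direct evaluation:
  # oracle_arrhenius(0.2, 20, 64.8, 30) = 0.4807530, (., 40) = 1.0926659
  expect_equal(arrhenius_rate(tomato, 30), 0.4807530, tolerance = 1e-6)
  expect_equal(arrhenius_rate(tomato, 40), 1.0926659, tolerance = 1e-6)
  expect_equal(arrhenius_rate(tomato, c(25, 35)),
               oracle_arrhenius(0.2, 20, 64.8, c(25, 35)),
               tolerance = 1e-12)
  # strictly increasing in temperature
  Ts <- seq(-5, 45, by = 0.5)
  expect_true(all(diff(arrhenius_rate(tomato, Ts)) > 0))
  expect_error(arrhenius_rate(tomato, -300), "absolute zero")
  expect_error(arrhenius_rate(tomato, NaN), "finite")
})

test_that("rate_bounds brackets the nominal rate per the SL-/SL+ convention", {
  b0 <- rate_bounds(tomato, 20, 0)
  expect_equal(unname(b0), c(0.2, 0.2))
  b <- rate_bounds(tomato, 20, 2)
  expect_equal(b[["k_minus"]], arrhenius_rate(tomato, 22))
  expect_equal(b[["k_plus"]], arrhenius_rate(tomato, 18))
  k30 <- arrhenius_rate(tomato, 30)
  b30 <- rate_bounds(tomato, 30, 2)
  expect_true(b30[["k_plus"]] < k30 && k30 < b30[["k_minus"]])
  expect_error(rate_bounds(tomato, 20, -1), "non-negative")
})

test_that("decay_step follows the closed forms and composes over time", {
  expect_equal(decay_step(12.4, 0.7, 0), 12.4)
  expect_equal(decay_step(12.4, 0.2, 1), 12.4 * exp(-0.2), tolerance = 1e-12)
  # equilibrium form approaches c_eq, never below
  expect_equal(decay_step(12.4, 0.2, 1e6, form = "equilibrium", c_eq = 3), 3)
  # composition: dt then dt2 equals dt + dt2 at constant k, both forms
  for (form in c("exponential", "equilibrium")) {
    one <- decay_step(decay_step(12.4, 0.3, 0.7, form, c_eq = 3),
                      0.3, 1.6, form, c_eq = 3)
    two <- decay_step(12.4, 0.3, 2.3, form, c_eq = 3)
    expect_equal(one, two, tolerance = 1e-12)
  }
  expect_error(decay_step(12.4, 0.2, -1), "non-negative")
  st <- quality_state(t = 0, c = 12.4)
  st2 <- decay_step(st, 0.2, 1)
  expect_s3_class(st2, "quality_state")
  expect_equal(st2$t, 1)
  expect_lt(st2$c, st$c)
})

test_that("shelf_life matches the logarithmic form and its worked cases", {
  expect_equal(shelf_life(3, tomato, 0.2), 0)       # threshold reached
  expect_equal(shelf_life(2, tomato, 0.2), 0)       # below threshold: clamp
  expect_equal(shelf_life(12.4, tomato, 0.2), 5 * log(12.4 / 3),
               tolerance = 1e-12)                    # 7.0954 days at 20 degC
  sl30 <- shelf_life(12.4, tomato, arrhenius_rate(tomato, 30))
  expect_equal(round(sl30), 3)                       # about 3 days @ 30 degC
  # strictly decreasing in k
  ks <- seq(0.1, 1.5, by = 0.1)
  sls <- vapply(ks, function(k) shelf_life(12.4, tomato, k), numeric(1))
  expect_true(all(diff(sls) < 0))
  expect_error(shelf_life(12.4, tomato, 0), "positive")
})

test_that("shelf-life bounds are ordered and widen with accuracy", {
  sb0 <- shelf_life_bounds(12.4, tomato, 20, 0)
  expect_equal(unname(sb0), rep(5 * log(12.4 / 3), 3), tolerance = 1e-12)
  sb <- shelf_life_bounds(12.4, tomato, 20, 2)
  expect_true(sb[["SL_lo"]] <= sb[["SL"]] && sb[["SL"]] <= sb[["SL_hi"]])
  expect_true(sb[["SL_lo"]] < 5 * log(12.4 / 3) &&
                5 * log(12.4 / 3) < sb[["SL_hi"]])
  widths <- vapply(0:3, function(a) {
    s <- shelf_life_bounds(12.4, tomato, 20, a)
    s[["SL_hi"]] - s[["SL_lo"]]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("fit_rate recovers decay rates from quality series", {
  # noiseless self-consistency
  t <- seq(0, 5, by = 0.25)
  c_true <- 12.4 * exp(-0.2 * t)
  est <- fit_rate(t, c_true)
  expect_equal(est$k, 0.2, tolerance = 1e-10)
  # two-point series: exact slope
  est2 <- fit_rate(c(0, 2), c(12.4, 12.4 * exp(-0.9)))
  expect_equal(est2$k, 0.45, tolerance = 1e-12)
  expect_true(is.na(est2$se))
  # 2% multiplicative noise, n = 100: within 5% of truth at a fixed seed
  set.seed(42)
  tn <- seq(0, 5, length.out = 100)
  cn <- 12.4 * exp(-0.2 * tn) * (1 + rnorm(100, 0, 0.02))
  estn <- fit_rate(tn, cn)
  expect_lt(abs(estn$k - 0.2) / 0.2, 0.05)
  expect_error(fit_rate(c(0, 0, 1), c(3, 2, 1)), "increasing")
  expect_error(fit_rate(c(0, 1), c(1, -1)), "positive")
})

test_that("kinetic parameter validation enforces the physical invariants", {
  expect_error(kinetic_params(-0.2, 20, 64.8, 12.4, 3), "positive")
  expect_error(kinetic_params(0.2, 20, -1, 12.4, 3), "activation")
  expect_error(kinetic_params(0.2, 20, 64.8, 2, 3), "c0 >= c_eq")
  expect_silent(kinetic_params(0.2, 20, 64.8, 3, 3))  # expired-at-start legal
})
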