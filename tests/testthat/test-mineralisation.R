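test_that("law calibration meets its construction targets", {
  law <- calibrate_mineralisation_law(Tsec = 8)
  expect_equal(law$c_max, 0.30 / 0.3989, tolerance = 1e-10)
  expect_equal(round(law$c_max, 4), 0.7521)
  expect_equal(law$c1, 0.45)
  expect_equal(law$t1, 10 / log(20), tolerance = 1e-10)
  # M(Tsec) = 0.95 c_max by construction, checked numerically
  expect_equal(evaluate_law(law, 8 * 365.25) / law$c_max, 0.95,
               tolerance = 1e-8)
  # calcium cap ~30 wt%
  expect_equal(ca_from_ash(law$c_max), 30, tolerance = 1e-3)
  expect_lt(law$t1, law$t2)
})

test_that("longer Tsec gives larger t2 and pointwise slower mineralisation", {
  laws <- lapply(c(2, 4, 8, 12), calibrate_mineralisation_law)
  t2s <- vapply(laws, `[[`, numeric(1), "t2")
  expect_true(all(diff(t2s) > 0))
  tau <- seq(1, 4000, by = 50)
  for (i in 1:3) {
    expect_true(all(evaluate_law(laws[[i + 1]], tau) <
                      evaluate_law(laws[[i]], tau)))
  }
})

test_that("law evaluation matches a direct double-exponential computation", {
  law <- calibrate_mineralisation_law(Tsec = 8)
  tau <- c(0, law$t1, 50, 365, 3000)
  direct <- law$c1 * (1 - exp(-tau / law$t1)) +
    (law$c_max - law$c1) * (1 - exp(-tau / law$t2))
  expect_equal(evaluate_law(law, tau), direct)
  expect_equal(evaluate_law(law, 0), 0)
  expect_equal(evaluate_law(law, 1e9), law$c_max, tolerance = 1e-10)
  expect_error(evaluate_law(law, -1), "non-negative")
})

test_that("law is strictly increasing and bounded on a dense grid", {
  law <- calibrate_mineralisation_law(Tsec = 4)
  tau <- seq(0, 20 * 365.25, length.out = 4000)
  m <- evaluate_law(law, tau)
  expect_true(all(diff(m) > 0))
  expect_true(all(m < law$c_max))
})

test_that("numerical inverse round-trips through the law", {
  law <- calibrate_mineralisation_law(Tsec = 8)
  for (a in c(0, 0.1, 0.45, 0.70, 0.74)) {
    tau <- inverse_law(law, a)
    expect_equal(evaluate_law(law, tau), a, tolerance = 1e-9)
  }
  expect_error(inverse_law(law, law$c_max), "c_max")
})

test_that("infeasible calibrations are reported", {
  expect_error(calibrate_mineralisation_law(Tsec = 10 / 365.25 / 2),
               "infeasible")
})

test_that("advance_mineralisation respects lag, active mask and freezing", {
  law <- calibrate_mineralisation_law(Tsec = 8)
  tau <- matrix(c(-15, 0, 100, law$tau_freeze, NA, 5), 2, 3)
  active <- matrix(FALSE, 2, 3)
  active[2, 3] <- TRUE
  up <- advance_mineralisation(tau, law, active = active, dt = 10)
  expect_equal(up$tau_m[1, 1], -5)         # lag not elapsed, clock advances
  expect_equal(up$alpha[1, 1], 0)          # ... but no mineral yet
  expect_equal(up$tau_m[2, 1], 10)
  expect_equal(up$tau_m[1, 2], 110)
  expect_equal(up$alpha[1, 2], evaluate_law(law, 110))
  expect_equal(up$tau_m[2, 2], law$tau_freeze)  # frozen at the cap
  expect_true(is.na(up$tau_m[1, 3]))       # marrow untouched
  expect_equal(up$tau_m[2, 3], 5)          # active BMU pixel untouched
})

test_that("a formed pixel follows M once lag has elapsed", {
  law <- calibrate_mineralisation_law(Tsec = 8)
  Mlt <- 10
  tau <- matrix(-Mlt, 1, 1)
  # advance to t = Mlt + t1 after formation
  steps <- Mlt + law$t1
  up <- advance_mineralisation(tau, law, dt = steps)
  expect_equal(up$alpha[1, 1], evaluate_law(law, law$t1))
})

test_that("alpha is non-decreasing across repeated advances", {
  law <- calibrate_mineralisation_law(Tsec = 2)
  tau <- matrix(c(-10, 0, 500, 2000), 2, 2)
  prev <- advance_mineralisation(tau, law, dt = 1)
  for (i in 1:50) {
    nxt <- advance_mineralisation(prev$tau_m, law, dt = 30)
    expect_true(all(nxt$alpha >= prev$alpha - 1e-14))
    prev <- nxt
  }
})

test_that("initial bone at alpha 0.70 keeps mineralising toward the cap", {
  law <- calibrate_mineralisation_law(Tsec = 8)
  tau0 <- inverse_law(law, 0.70)
  a_5y <- evaluate_law(law, tau0 + 5 * 365.25)
  expect_gt(a_5y, 0.70)
  expect_lt(a_5y, law$c_max)
  expect_gt(ca_from_ash(a_5y), 29)  # never-remodelled bone nears 30 wt%
})
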