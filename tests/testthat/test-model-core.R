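test_that("rate laws reproduce their limiting values exactly", {
  expect_identical(g_b(0, 2), 1)
  expect_identical(g_b(0, 3.7), 1)
  expect_identical(g_d(0, 2), 0)
  expect_identical(f1(0, b1 = 2.3, c1 = 1.5, n = 2), 0)
  expect_identical(f2(0, a2 = 0.4, c2 = 1), 0.4)
  expect_identical(f3b(0, b3 = 11.5, m3 = 221, n3 = 2), 0)
  expect_identical(f3d(0, a3 = 2.3, m3 = 221, n4 = 2), 2.3)
})

test_that("rate laws match hand-computed values and half-saturation points", {
  expect_equal(g_b(1, n1 = 7), 0.5)
  expect_equal(g_b(2, n1 = 2), 0.2)
  expect_equal(g_d(1, n2 = 5), 0.5)
  expect_equal(g_d(3, n2 = 2), 0.9)
  expect_equal(f1(1, b1 = 2.3, c1 = 1.5, n = 2), 0.92)
  expect_equal(f1(1.5^(1 / 2), b1 = 2.3, c1 = 1.5, n = 2), 2.3 / 2)
  expect_equal(f2(1, a2 = 0.4, c2 = 1), 0.2)
  expect_equal(f2(2.38e-10, a2 = 4.78e4, c2 = 2.38e-10), 4.78e4 / 2)
  expect_equal(f3b(221, b3 = 11.5, m3 = 221, n3 = 2), 11.5 / 2)
  expect_equal(f3d(221, a3 = 2.3, m3 = 221, n4 = 2), 2.3 / 2)
  # with equal maximal rates, vessel birth and death balance at P = m3
  expect_equal(f3b(1.02, 1, 1.02, 2), f3d(1.02, 1, 1.02, 2))
})

test_that("rate laws are monotone in the documented direction", {
  E <- 10^seq(-6, 6, length.out = 60)
  expect_true(all(diff(g_b(E, 2.5)) < 0))
  expect_true(all(diff(g_d(E, 2.5)) > 0))
  expect_true(all(diff(f1(E, 2.3, 1.5, 2)) > 0))
  expect_true(all(diff(f2(E, 0.4, 1)) < 0))
  expect_true(all(diff(f3b(E, 1, 1.02, 2)) > 0))
  expect_true(all(diff(f3d(E, 1, 1.02, 2)) < 0))
})

test_that("Hill evaluations survive extreme arguments without overflow", {
  expect_true(g_b(1e12, 4) >= 0 && g_b(1e12, 4) < 1e-40)
  expect_equal(f1(1e12, b1 = 4.48e9, c1 = 3.32e3, n = 2), 4.48e9,
               tolerance = 1e-12)
  expect_equal(f3b(1e15, b3 = 11.5, m3 = 221, n3 = 2), 11.5,
               tolerance = 1e-12)
  expect_equal(f3d(1e15, a3 = 2.3, m3 = 221, n4 = 2), 0,
               tolerance = 1e-20)
})

test_that("negative arguments are a domain error", {
  expect_error(g_b(-1, 2), "non-negative")
  expect_error(g_d(-0.1, 2), "non-negative")
  expect_error(f1(-1, 1, 1, 1), "non-negative")
  expect_error(f2(-1, 1, 1), "non-negative")
  expect_error(f3b(-1, 1, 1, 1), "non-negative")
  expect_error(f3d(-1, 1, 1, 1), "non-negative")
})

test_that("state accessors enforce non-negativity and E is undefined at N = 0", {
  expect_error(system_state(-1, 0, 0), "non-negative")
  s <- system_state(2, 1, 3)
  expect_equal(state_E(s), 1.5)
  expect_error(state_E(system_state(0, 1, 3)), "undefined")
})

test_that("propensities vanish at absorbing states", {
  pr <- propensities(c(N = 0, P = 0, V = 0), bench$params)
  expect_identical(unname(pr$rates), rep(0, 6))
  # a fully absorbed state keeps zero rates even with P, V > 0
  pr <- propensities(c(N = 0, P = 5, V = 2), bench$params)
  expect_identical(unname(pr$rates), rep(0, 6))
  # avascular states cannot regrow vessels
  pr <- propensities(c(N = 2, P = 1, V = 0), bench$params)
  expect_identical(unname(pr$rates[c("V_birth", "V_death")]),
                   c(0, 0))
  # without VEGF the vessels only die
  pr <- propensities(c(N = 2, P = 0, V = 3), bench$params)
  expect_equal(unname(pr$rates[["V_death"]]), 1.0 * 3)
  expect_identical(unname(pr$rates[["V_birth"]]), 0)
})

test_that("propensities are non-negative for random valid states", {
  for (s in 1:100) {
    pr <- propensities(random_state(s), random_params(s + 500))
    expect_true(all(pr$rates >= 0))
  }
})

test_that("drift equals the signed sum of propensities", {
  for (s in 1:100) {
    p <- random_params(s)
    st <- random_state(s + 1000)
    pr <- propensities(st, p)
    expect_equal(unname(drift(st, p)),
                 unname(drop(pr$stoich %*% pr$rates)),
                 tolerance = 1e-12)
  }
})

test_that("hand-evaluated drift component on the benchmark set", {
  d <- drift(c(N = 1.5, P = 0.9, V = 3.0), bench$params)
  expect_equal(d[["P"]], 1.5 * f2(2, 0.4, 1) - 0.34 * 0.9,
               tolerance = 1e-14)
})

test_that("absolute-mode drift is the system-size rescaling of concentration-mode drift", {
  for (s in 1:25) {
    p <- random_params(s + 2000)
    omega <- 10^stats::runif(1, 0, 4)
    p_abs <- params_to_absolute(p, omega)
    st <- random_state(s + 3000)
    st_abs <- st * omega
    expect_equal(unname(drift(st_abs, p_abs)),
                 unname(omega * drift(st, p)),
                 tolerance = 1e-10)
  }
})

test_that("compiled channel rates agree with the R rate laws", {
  for (s in 1:50) {
    p <- random_params(s + 4000)
    st <- random_state(s + 5000)
    a_cpp <- angiokin:::.rates_cpp(unclass(p), st[["N"]], st[["P"]],
                                   st[["V"]])
    a_r <- angiokin:::reaction_rates(st[["N"]], st[["P"]], st[["V"]], p)
    expect_equal(a_cpp, unname(a_r), tolerance = 1e-12)
  }
})

test_that("parameter validation rejects non-positive constants", {
  expect_error(kinetic_params(alpha = 0, delta_N = 1, K = 1, b1 = 1,
                              c1 = 1, a2 = 1, c2 = 1, delta_P = 1,
                              b3 = 1, a3 = 1, m3 = 1), "positive")
  expect_error(kinetic_params(alpha = 1, delta_N = 1, K = 1, b1 = 1,
                              c1 = 1, a2 = 1, c2 = 1, delta_P = 1,
                              b3 = 1, a3 = 1, m3 = 1, n3 = -2),
               "positive")
})

test_that("packaged fixtures carry the published parameterisations", {
  p <- llc$params
  expect_equal(p$alpha, 0.675)
  expect_equal(p$delta_N, 3.58e-8)
  expect_equal(p$delta_P, 8.91)
  expect_equal(p$a2, 4.78e4)
  expect_equal(p$c2, 2.38e-10)
  expect_equal(p$b1, 4.48e9)
  expect_equal(p$c1, 3.32e3)
  expect_equal(p$a3, 2.3)
  expect_equal(p$b3, 11.5)
  expect_equal(p$m3, 221)
  expect_equal(p$K * solve_gamma(p), 7.86e7, tolerance = 1e-12)
  expect_identical(p$mode, "absolute")
  expect_identical(c(p$n, p$n1, p$n2, p$n3, p$n4), rep(2, 5))
  b <- bench$params
  expect_equal(unlist(unclass(b)[c("alpha", "delta_N", "delta_P", "K",
                                   "b1", "c1", "a2", "c2", "a3", "m3",
                                   "b3", "n", "n1", "n2", "n3", "n4")]),
               c(alpha = 1, delta_N = 1.1, delta_P = 0.34, K = 1,
                 b1 = 2.3, c1 = 1.5, a2 = 0.4, c2 = 1, a3 = 1,
                 m3 = 1.02, b3 = 1, n = 2, n1 = 1, n2 = 2, n3 = 2,
                 n4 = 2))
  expect_equal(llc$initial, c(N = 8.29e8, P = 10, V = 1))
  expect_equal(bench$initial, c(N = 1.5, P = 0.9, V = 3.0))
  expect_equal(bench_c3$initial, c(N = 2.2, P = 1.0, V = 3.5))
})

test_that("parameter sets round-trip through JSON and YAML files", {
  for (ext in c("json", "yaml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(llc$params, f)
    back <- read_params(f)
    expect_equal(unclass(back), unclass(llc$params))
    unlink(f)
  }
  expect_error(read_params(tempfile(fileext = ".txt")), "extension")
})
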