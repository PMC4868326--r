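test_that("gamma solves the cell birth-death balance", {
  # closed form for equal exponents
  p <- with_params(bench$params, n1 = 2, n2 = 2, alpha = 1, delta_N = 1)
  expect_equal(solve_gamma(p), 1, tolerance = 1e-12)
  g_llc <- solve_gamma(llc$params)
  expect_equal(g_llc, (0.675 / 3.58e-8)^(1 / 2), tolerance = 1e-10)
  # benchmark has n1 = 1, n2 = 2: check the root by its residual
  g <- solve_gamma(bench$params)
  expect_lt(abs(1 * g_b(g, 1) - 1.1 * g_d(g, 2)), 1e-12)
  for (s in 1:20) {
    p <- random_params(s + 6000)
    g <- solve_gamma(p)
    expect_lt(abs(p$alpha * g_b(g, p$n1) - p$delta_N * g_d(g, p$n2)),
              1e-12 * max(p$alpha, p$delta_N))
  }
})

test_that("Ptilde solves the vessel birth-death balance", {
  # equal maximal rates put the balance exactly at m3
  p <- with_params(bench$params, a3 = 1, b3 = 1)
  expect_equal(solve_Ptilde(p), 1.02, tolerance = 1e-12)
  # equal exponents give the closed form m3 (a3/b3)^(1/n3)
  expect_equal(solve_Ptilde(llc$params), 221 * (2.3 / 11.5)^(1 / 2),
               tolerance = 1e-10)
  for (s in 1:20) {
    p <- random_params(s + 7000)
    Pt <- solve_Ptilde(p)
    expect_lt(abs(f3b(Pt, p$b3, p$m3, p$n3) - f3d(Pt, p$a3, p$m3, p$n4)),
              1e-12 * p$a3)
  }
})

test_that("h approaches a2*K - delta_P*Ptilde/gamma as E -> 0", {
  hp <- h_eval(llc$params,
               E_grid = exp(seq(log(1e-14), log(1e12),
                                length.out = 600L)))
  h0 <- llc$params$a2 * llc$params$K -
    llc$params$delta_P * hp$Ptilde / hp$gamma
  expect_equal(hp$h[1], h0, tolerance = 1e-3)
})

test_that("the fitted Lewis-lung model has a single vascular morphology", {
  hp <- h_eval(llc$params)
  expect_length(hp$roots, 1)
  ss <- enumerate_states(llc$params)
  labs <- vapply(ss$states, `[[`, "", "label")
  stab <- vapply(ss$states, `[[`, "", "stability")
  expect_identical(labs, c("A", "B", "C"))
  expect_identical(stab, c("unstable", "unstable", "stable"))
  # avascular-state coordinates follow Kbar*gamma = 7.86e7
  B <- ss$states[[2]]
  expect_equal(B$N, 7.86e7, tolerance = 1e-10)
  expect_equal(B$P, 4.78e4 * 7.86e7 / 8.91, tolerance = 1e-10)
  expect_identical(B$V, 0)
})

test_that("strong VEGF suppression leaves one small dormant state", {
  p <- with_params(llc$params, delta_P = 2e4)
  hp <- h_eval(p)
  expect_length(hp$roots, 1)
  expect_gt(hp$roots, 1e-4)
  expect_lt(hp$roots, 1e-3)
})

test_that("the benchmark set carries three vascular states with alternating stability", {
  ss <- enumerate_states(bench$params)
  cs <- Filter(function(s) s$label == "C", ss$states)
  expect_length(cs, 3)
  E <- vapply(cs, `[[`, 0, "E")
  stab <- vapply(cs, `[[`, "", "stability")[order(E)]
  expect_identical(stab, c("stable", "unstable", "stable"))
  # every C sits at the shared VEGF balance level
  expect_true(all(abs(vapply(cs, `[[`, 0, "P") - solve_Ptilde(bench$params))
                  < 1e-8))
})

test_that("the trivial state is always an unstable equilibrium", {
  for (p in list(llc$params, bench$params, random_params(42))) {
    a <- enumerate_states(p)$states[[1]]
    expect_identical(a$label, "A")
    expect_identical(a$stability, "unstable")
    expect_identical(c(a$N, a$P, a$V), c(0, 0, 0))
  }
})

test_that("h has at most three positive roots across random parameter sets", {
  for (s in 1:1000) {
    hp <- h_eval(random_params(s + 8000),
                 E_grid = exp(seq(log(1e-10), log(1e10),
                                  length.out = 400L)))
    expect_lte(length(hp$roots), 3)
  }
})

test_that("h-slope verdicts agree with Jacobian eigenvalues", {
  for (s in 1:100) {
    p <- random_params(s + 9000)
    # enumerate_states warns if the two stability routes disagree
    expect_no_warning(ss <- enumerate_states(p))
    for (st in ss$states) {
      if (st$label != "C" || st$stability == "marginal") next
      re_max <- max(Re(st$diagnostics$jacobian_eigs))
      band <- 1e-9 * (1 + max(abs(st$diagnostics$jacobian_eigs)))
      if (abs(re_max) <= band) next
      expect_identical(st$stability,
                       if (re_max < 0) "stable" else "unstable")
    }
  }
})

test_that("stable benchmark states are attractors in practice", {
  ss <- enumerate_states(bench$params)
  for (st in Filter(function(s) s$label == "C" &&
                    s$stability == "stable", ss$states)) {
    ic <- c(N = st$N * 1.01, P = st$P * 0.99, V = st$V * 1.01)
    res <- run_to_steady(bench$params, ic, t_max = 1e4, tol = 1e-9)
    expect_true(res$converged)
    expect_equal(unname(res$state), c(st$N, st$P, st$V),
                 tolerance = 1e-6)
  }
})

test_that("the Lewis-lung vascular state is a fixed point of the flow", {
  st <- enumerate_states(llc$params)$states[[3]]
  d <- drift(c(N = st$N, P = st$P, V = st$V), llc$params)
  # drift per species relative to that species' turnover scale
  expect_lt(abs(d[["P"]]) / (llc$params$delta_P * st$P), 1e-8)
  expect_lt(abs(d[["V"]]) / (llc$params$a3 * st$V), 1e-8)
  expect_lt(abs(d[["N"]]) / (llc$params$alpha * st$N), 1e-8)
})

test_that("VEGF-degradation folds are detected by scan and closed form alike", {
  cf <- critical_delta_P(llc$params)
  # lower fold: a second (small, stable) vascular state appears
  expect_equal(unname(cf[["lower"]]), 160, tolerance = 0.1)
  # upper fold: the closed form sits near 1.9e4 (the printed value is
  # ~1.2e4; both are reported by the bifurcation sidecar)
  expect_gt(cf[["upper"]], 1e4)
  scan <- bifurcation_scan(llc$params, "delta_P",
                           10^seq(0, 5, length.out = 120))
  expect_equal(nrow(scan$critical), 2)
  expect_equal(scan$critical$value[1], unname(cf[["lower"]]),
               tolerance = 1e-3)
  expect_equal(scan$critical$value[2], unname(cf[["upper"]]),
               tolerance = 1e-3)
  # one stable state below the window, two inside, one above
  expect_identical(range(scan$n_stable), c(1L, 2L))
  f <- tempfile(fileext = ".csv")
  write_bifurcation_csv(scan, f)
  side <- jsonlite::read_json(paste0(f, ".critical.json"),
                              simplifyVector = TRUE)
  expect_equal(unname(side$closed_form$lower), unname(cf[["lower"]]))
  expect_equal(unname(side$closed_form$upper), unname(cf[["upper"]]))
  unlink(c(f, paste0(f, ".critical.json")))
})

test_that("beyond the upper fold the surviving state merges with the avascular level", {
  p <- with_params(llc$params, delta_P = 2e4)
  ss <- enumerate_states(p)
  cs <- Filter(function(s) s$label == "C", ss$states)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$N, p$K * solve_gamma(p), tolerance = 1e-3)
})

test_that("a cell-death sweep of the benchmark reveals a coexistence window", {
  scan <- bifurcation_scan(bench$params, "delta_N",
                           seq(0.5, 3, length.out = 80))
  expect_gte(max(scan$n_stable), 2)
  expect_gte(nrow(scan$critical), 1)
  # hysteresis: within the window two stable vascular branches coexist
  two <- scan$states[scan$states$stable &
                     scan$states$label == "C", ]
  counts <- table(two$param_value)
  expect_gte(max(counts), 2)
})
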