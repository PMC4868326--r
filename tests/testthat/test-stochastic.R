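# A parameter set in which every channel except VEGF decay is
# negligibly slow: the protein then follows a pure linear death
# process with known analytic law.
decay_only <- kinetic_params(alpha = 1e-12, delta_N = 1e-12, K = 1,
                             b1 = 1e-12, c1 = 1, a2 = 1e-12, c2 = 1,
                             delta_P = 0.5, b3 = 1e-12, a3 = 1e-12,
                             m3 = 1, mode = "absolute")

test_that("exact simulation reproduces the linear death process", {
  P0 <- 200
  ens <- run_ensemble(decay_only, c(N = 1, P = P0, V = 0), t_end = 2,
                      n = 2000, engine = "ssa", base_seed = 17,
                      t_grid = c(1, 2))
  for (j in 1:2) {
    tt <- c(1, 2)[j]
    m <- mean(ens$states[, j, "P"]); v <- stats::var(ens$states[, j, "P"])
    mu <- P0 * exp(-0.5 * tt)
    se <- sqrt(P0 * exp(-0.5 * tt) * (1 - exp(-0.5 * tt)) / 2000)
    expect_lt(abs(m - mu), 3 * se)
    # binomial thinning variance of the death process
    expect_equal(v, P0 * exp(-0.5 * tt) * (1 - exp(-0.5 * tt)),
                 tolerance = 0.15)
  }
})

test_that("the all-zero state generates no events under either engine", {
  tr <- run_ssa(bench$params, c(N = 0, P = 0, V = 0), t_end = 5,
                seed = 1, t_grid = c(2.5, 5))
  expect_true(all(as.matrix(tr[, c("N", "P", "V")]) == 0))
  expect_identical(attr(tr, "events"), 0)
  tr <- run_cle(bench$params, c(N = 0, P = 0, V = 0), t_end = 5,
                seed = 1, t_grid = c(2.5, 5))
  expect_true(all(as.matrix(tr[, c("N", "P", "V")]) == 0))
})

test_that("SSA demands integer counts and positive CLE steps", {
  expect_error(run_ssa(bench$params, c(N = 1.5, P = 1, V = 1), 1),
               "integer")
  expect_error(run_cle(bench$params, c(N = 1, P = 1, V = 1), 1,
                       dt = 0), "positive")
})

test_that("state A and the avascular set are absorbing under both engines", {
  p <- fixture_params("benchmark_fig4", omega = 10)
  for (s in 1:15) {
    tr <- run_ssa(p, round(bench_c3$initial * 10), t_end = 400,
                  seed = s, t_grid = seq(0, 400, by = 2))
    for (sp in c("N", "V")) {
      z <- which(tr[[sp]] == 0)
      if (length(z)) expect_true(all(tr[[sp]][z[1]:nrow(tr)] == 0))
    }
    # the fully absorbed state has every species at zero
    z <- which(tr$N == 0)
    if (length(z))
      expect_true(all(tr$P[z[1]:nrow(tr)] == 0) &&
                  all(tr$V[z[1]:nrow(tr)] == 0))
  }
  for (s in 1:15) {
    tr <- run_cle(p, bench_c3$initial, t_end = 400, seed = s,
                  t_grid = seq(0, 400, by = 2), dt = 1e-3)
    for (sp in c("N", "V")) {
      z <- which(tr[[sp]] == 0)
      if (length(z)) expect_true(all(tr[[sp]][z[1]:nrow(tr)] == 0))
    }
  }
})

test_that("a vessel-free start keeps V at zero under the CLE", {
  tr <- run_cle(bench$params, c(N = 1.5, P = 0.9, V = 0), t_end = 20,
                seed = 3, t_grid = seq(0, 20, by = 1))
  expect_true(all(tr$V == 0))
  # while N and P keep fluctuating
  expect_gt(stats::sd(tr$N), 0)
})

test_that("the CLE with silenced noise reproduces the deterministic flow", {
  grid <- c(0, 5, 10)
  tr <- run_cle(bench$params, bench_c3$initial, t_end = 10, dt = 1e-4,
                seed = 1, t_grid = grid, noise_scale = 0)
  ode <- integrate_ode(bench$params, bench_c3$initial, grid)
  expect_equal(tr$N, ode$N, tolerance = 1e-4)
  expect_equal(tr$P, ode$P, tolerance = 1e-4)
  expect_equal(tr$V, ode$V, tolerance = 1e-4)
  ens <- run_ensemble(bench$params, bench_c3$initial, t_end = 5, n = 5,
                      engine = "cle", base_seed = 9, t_grid = c(0, 5),
                      dt = 1e-3, noise_scale = 0)
  expect_identical(tail(ens$extinct_fraction, 1), 0)
  for (i in 2:5)
    expect_identical(ens$states[i, , ], ens$states[1, , ])
})

test_that("ensembles are bit-reproducible under a fixed base seed", {
  p <- fixture_params("benchmark_fig4", omega = 100)
  e1 <- run_ensemble(p, bench_c3$initial, t_end = 5, n = 20,
                     engine = "cle", base_seed = 101,
                     t_grid = c(2.5, 5), dt = 1e-3)
  e2 <- run_ensemble(p, bench_c3$initial, t_end = 5, n = 20,
                     engine = "cle", base_seed = 101,
                     t_grid = c(2.5, 5), dt = 1e-3)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$extinct_fraction, e2$extinct_fraction)
  e3 <- run_ensemble(p, bench_c3$initial, t_end = 5, n = 20,
                     engine = "cle", base_seed = 102,
                     t_grid = c(2.5, 5), dt = 1e-3)
  expect_false(identical(e1$states, e3$states))
  s1 <- run_ssa(p, round(bench_c3$initial * 100), t_end = 5, seed = 7,
                t_grid = c(5))
  s2 <- run_ssa(p, round(bench_c3$initial * 100), t_end = 5, seed = 7,
                t_grid = c(5))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("absorption fractions are monotone and consistently bounded", {
  p <- fixture_params("benchmark_fig4", omega = 10)
  ens <- run_ensemble(p, bench_c3$initial, t_end = 300, n = 150,
                      engine = "cle", base_seed = 5,
                      t_grid = seq(0, 300, by = 10), dt = 1e-3)
  expect_true(all(diff(ens$extinct_fraction) >= 0))
  expect_true(all(diff(ens$avascular_fraction) >= 0))
  expect_true(all(ens$extinct_fraction <= ens$avascular_fraction))
  expect_true(all(ens$extinct_fraction >= 0 &
                  ens$extinct_fraction <= 1))
})

test_that("SSA ensemble means approach the deterministic solution as the system grows", {
  ode <- integrate_ode(bench$params, bench_c3$initial, c(0, 10))
  target <- ode$N[2]
  gaps <- vapply(c(10, 100, 1000), function(om) {
    p <- fixture_params("benchmark_fig4", omega = om)
    n <- if (om == 1000) 300 else 400
    ens <- run_ensemble(p, round(bench_c3$initial * om), t_end = 10,
                        n = n, engine = "ssa", base_seed = 23,
                        t_grid = c(10), keep_states = TRUE)
    abs(mean(ens$states[, 1, "N"]) / om - target) / target
  }, 0)
  expect_true(all(diff(gaps) < 0))
})

test_that("at small system size the CLE overestimates switching relative to the SSA", {
  p <- fixture_params("benchmark_fig4", omega = 10)
  ic <- round(bench_c3$initial * 10)
  low_basin <- function(states) mean(states[, 1, "N"] < 1.2 * 10)
  e_ssa <- run_ensemble(p, ic, t_end = 150, n = 150, engine = "ssa",
                        base_seed = 31, t_grid = c(150))
  e_cle <- run_ensemble(p, ic, t_end = 150, n = 150, engine = "cle",
                        base_seed = 31, t_grid = c(150), dt = 1e-3)
  expect_gte(low_basin(e_cle$states), low_basin(e_ssa$states))
})

test_that("noise intensity follows the closed form and the nutrient ordering", {
  # constant-rate birth-death at equilibrium: intensity sqrt(2 r / X)
  p <- with_params(decay_only, a2 = 0.5 * 300, delta_P = 0.5)
  traj <- trajectory(data.frame(t = 0:3, N = rep(1, 4),
                                P = rep(300, 4), V = rep(0, 4)), "ode")
  ni <- noise_intensity(p, traj)
  expect_equal(ni$P, rep(sqrt(2 * 0.5 * 300) / 300, 4),
               tolerance = 1e-6)
  # raising E at fixed N increases the tumour-cell intensity through
  # the extra nutrient supply f1(E)
  i_at <- function(E) {
    tr <- trajectory(data.frame(t = 0, N = 1e9, P = 100, V = 1e9 * E),
                     "ode")
    noise_intensity(llc$params, tr)$N
  }
  expect_gt(i_at(100), i_at(0.1))
  expect_error(noise_intensity(llc$params,
                               trajectory(data.frame(t = 0:1, N = c(1, 0),
                                                     P = 0:1, V = 0:1),
                                          "ode")),
               "N > 0")
})

test_that("Lewis-lung tumour-cell noise surges transiently between days two and four", {
  tr <- integrate_ode(llc$params, llc$initial, seq(0.5, 7, by = 0.1),
                      t0 = 0)
  ni <- noise_intensity(llc$params, tr)
  pk <- ni$t[which.max(ni$N)]
  expect_gte(pk, 1.5); expect_lte(pk, 4.5)
  # non-monotone: quiet start, surge, decay
  expect_lt(ni$N[1], max(ni$N) / 50)
  expect_lt(ni$N[nrow(ni)], max(ni$N) / 2)
})
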