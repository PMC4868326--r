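#' Chemical-Langevin simulation of one realization
#'
#' Euler-Maruyama integration of the chemical Langevin equation: each
#' species' increment is its net drift plus a Gaussian term with
#' standard deviation `sqrt(sum of that species' channel rates) *
#' sqrt(dt)`, the three noises independent.  In concentration mode the
#' diffusion carries the `omega^-1/2` prefactor; in absolute mode the
#' prefactor is 1.  After every step species are clipped at zero; a
#' species whose update lands at or below `absorb_threshold` is
#' absorbed — `N`-absorption zeroes the whole system (state A), and
#' `V`-absorption is permanent (avascular trap), reflecting that both
#' drift and noise of `V` vanish at `V = 0`.
#'
#' @param params an [kinetic_params()] object.
#' @param initial named vector `(N, P, V)` in the parameters' native
#'   units.
#' @param t_end final time (days).
#' @param dt Euler step (days), default `1e-3` (resolves the fastest
#'   LLC scales: VEGF decay ~9/day, vessel growth 11.5/day).
#' @param seed integer seed; the stream is independent of R's RNG.
#' @param t_grid recording times; default 200 evenly spaced points.
#' @param t0 start time (days).
#' @param absorb_threshold absorption level (default 0, the CLE's
#'   intrinsic absorbing boundary).
#' @param noise_scale multiplies the diffusion term (0 recovers the
#'   deterministic limit exactly).
#' @return An `ak_trajectory` with attributes `extinct`, `avascular`,
#'   `t_extinct`, `t_avascular`.
#' @export
run_cle <- function(params, initial, t_end, dt = 1e-3, seed = 1L,
                    t_grid = NULL, t0 = 0, absorb_threshold = 0,
                    noise_scale = 1) {
  stopifnot(inherits(params, "ak_params"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  y0 <- as_y0(initial)
  if (is.null(t_grid)) t_grid <- seq(t0, t_end, length.out = 201L)
  res <- .cle_run(unclass(params), y0, t0, t_end, dt, t_grid,
                  as.double(seed), 0L, absorb_threshold, noise_scale)
  tr <- data.frame(t = t_grid, N = res$states[, 1],
                   P = res$states[, 2], V = res$states[, 3])
  out <- trajectory(tr, "cle", params = params, seed = seed)
  attr(out, "extinct") <- res$extinct
  attr(out, "avascular") <- res$avascular
  attr(out, "t_extinct") <- res$t_extinct
  attr(out, "t_avascular") <- res$t_avascular
  out
}

#' Exact Gillespie simulation of one realization
#'
#' Direct-method stochastic simulation over the six reaction channels:
#' exponential waiting times with the total-propensity parameter and
#' channel choice proportional to propensity.  The state is integer
#' counts; in concentration mode the initial counts should be
#' `round(concentration * omega)` and recorded states are returned as
#' counts.  Terminates at `t_end` or when the total rate reaches zero
#' (absorbing state).
#'
#' @inheritParams run_cle
#' @param initial named vector of integer counts.
#' @param max_events event-count guard; exceeding it marks the
#'   trajectory `truncated`.  At Lewis-lung population sizes the exact
#'   simulation is impractical (event rates ~1e12/day) and the
#'   chemical-Langevin engine is the supported choice.
#' @return An `ak_trajectory` with attributes `extinct`, `avascular`,
#'   `events`, `truncated`.
#' @export
run_ssa <- function(params, initial, t_end, seed = 1L, t_grid = NULL,
                    t0 = 0, max_events = 1e8) {
  stopifnot(inherits(params, "ak_params"))
  y0 <- as_y0(initial)
  if (any(y0 != round(y0)))
    stop("SSA initial state must be integer counts", call. = FALSE)
  if (is.null(t_grid)) t_grid <- seq(t0, t_end, length.out = 201L)
  res <- .ssa_run(unclass(params), y0, t0, t_end, t_grid,
                  as.double(seed), 0L, max_events)
  if (res$truncated)
    warning("SSA stopped after ", format(res$events),
            " events before t_end", call. = FALSE)
  tr <- data.frame(t = t_grid, N = res$states[, 1],
                   P = res$states[, 2], V = res$states[, 3])
  out <- trajectory(tr, "ssa", params = params, seed = seed)
  attr(out, "extinct") <- res$extinct
  attr(out, "avascular") <- res$avascular
  attr(out, "events") <- res$events
  attr(out, "truncated") <- res$truncated
  out
}

as_y0 <- function(initial) {
  y0 <- c(unname(initial[["N"]]), unname(initial[["P"]]),
          unname(initial[["V"]]))
  if (any(!is.finite(y0)) || any(y0 < 0))
    stop("invalid initial state", call. = FALSE)
  y0
}

#' Seeded ensemble of stochastic realizations
#'
#' Runs `n` independent realizations (per-realization streams derived
#' from `base_seed`, so results do not depend on evaluation order) and
#' summarises: recorded marginals at `t_grid`, and the fractions of
#' realizations absorbed at the extinct state A and at the avascular
#' trap `(N, P, 0)` as functions of time.  Both absorptions are
#' irreversible, so the fractions are non-decreasing.
#'
#' @inheritParams run_cle
#' @param n number of realizations (>= 1).
#' @param engine `"cle"` or `"ssa"`.
#' @param base_seed integer; realization `i` uses stream `(base_seed, i)`.
#' @param keep_states if `FALSE`, per-time marginals are dropped
#'   (fractions only); saves memory for large ensembles.
#' @param max_events per-realization SSA event guard.
#' @return An object of class `ak_ensemble`: list with `t`, `n`,
#'   `engine`, `base_seed`, `extinct_fraction`, `avascular_fraction`,
#'   `t_extinct`, `t_avascular` (per-realization absorption times for
#'   the CLE engine), and `states` (an `n x length(t) x 3` array
#'   unless dropped).
#' @export
run_ensemble <- function(params, initial, t_end, n, engine = c("cle", "ssa"),
                         base_seed = 1L, t_grid = NULL, dt = 1e-3,
                         t0 = 0, absorb_threshold = 0, noise_scale = 1,
                         keep_states = TRUE, max_events = 1e8) {
  stopifnot(inherits(params, "ak_params"), n >= 1)
  engine <- match.arg(engine)
  y0 <- as_y0(initial)
  if (is.null(t_grid)) t_grid <- seq(t0, t_end, length.out = 101L)
  nt <- length(t_grid)
  states <- if (keep_states)
    array(NA_real_, c(n, nt, 3),
          dimnames = list(NULL, NULL, c("N", "P", "V"))) else NULL
  t_ext <- t_av <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (engine == "cle") {
      res <- .cle_run(unclass(params), y0, t0, t_end, dt, t_grid,
                      as.double(base_seed), i, absorb_threshold,
                      noise_scale)
      t_ext[i] <- res$t_extinct
      t_av[i] <- res$t_avascular
    } else {
      res <- .ssa_run(unclass(params), y0, t0, t_end, t_grid,
                      as.double(base_seed), i, max_events)
      # absorption time from the recorded (absorbing) marginals
      jN <- which(res$states[, 1] <= 0)
      jV <- which(res$states[, 3] <= 0)
      t_ext[i] <- if (length(jN)) t_grid[jN[1]] else NA_real_
      t_av[i] <- if (length(jV)) t_grid[jV[1]] else NA_real_
    }
    if (keep_states) states[i, , ] <- res$states
  }
  frac <- function(tt) vapply(t_grid, function(z)
    mean(!is.na(tt) & tt <= z), 0)
  structure(list(t = t_grid, n = n, engine = engine,
                 base_seed = base_seed, dt = dt,
                 extinct_fraction = frac(t_ext),
                 avascular_fraction = frac(t_av),
                 t_extinct = t_ext, t_avascular = t_av,
                 states = states, params = params, initial = y0),
            class = "ak_ensemble")
}

#' @export
print.ak_ensemble <- function(x, ...) {
  cat("<ak_ensemble>", x$engine, "n =", x$n,
      " t in [", min(x$t), ",", max(x$t), "]\n")
  cat("  extinct fraction at t_end:  ",
      utils::tail(x$extinct_fraction, 1), "\n")
  cat("  avascular fraction at t_end:",
      utils::tail(x$avascular_fraction, 1), "\n")
  invisible(x)
}

#' Fraction of realizations absorbed into the non-growing basin
#'
#' Realizations absorbed at the extinct state A or trapped in the
#' avascular set `(N, P, 0)` by time `t`.  For the fitted Lewis-lung
#' parameters the tumour-cell death rate is so small that state A is
#' unreachable on observable timescales, and vascular collapse while
#' the nascent vessel count is of order one is the model's only
#' spontaneous tumour-loss pathway; this function reports that loss
#' fraction.
#'
#' @param ensemble an `ak_ensemble`.
#' @param t evaluation time(s); defaults to the recording grid.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
absorbed_fraction <- function(ensemble, t = ensemble$t) {
  ta <- pmin(ensemble$t_extinct, ensemble$t_avascular, na.rm = TRUE)
  ta[is.infinite(ta)] <- NA_real_
  vapply(t, function(z) mean(!is.na(ta) & ta <= z), 0)
}

#' Per-time marginal histogram of an ensemble
#'
#' @param ensemble an `ak_ensemble` with recorded states.
#' @param species `"N"`, `"P"` or `"V"`.
#' @param time recording time (matched to the nearest grid point).
#' @param breaks passed to [graphics::hist()] interface of
#'   [base::cut()]; default 30 equal-width bins.
#' @return Data frame `t, species, bin_left, bin_right, count`.
#' @export
ensemble_histogram <- function(ensemble, species, time, breaks = 30) {
  stopifnot(!is.null(ensemble$states))
  j <- which.min(abs(ensemble$t - time))
  x <- ensemble$states[, j, species]
  hh <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(t = ensemble$t[j], species = species,
             bin_left = hh$breaks[-length(hh$breaks)],
             bin_right = hh$breaks[-1], count = hh$counts)
}

#' Write ensemble fractions (and optional histograms) as CSV
#'
#' @param ensemble an `ak_ensemble`.
#' @param path CSV path for the fractions table
#'   (`t,extinct_fraction,avascular_fraction`).
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(data.frame(t = ensemble$t,
                              extinct_fraction = ensemble$extinct_fraction,
                              avascular_fraction = ensemble$avascular_fraction),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analytic relative noise intensity along a deterministic trajectory
#'
#' For each species `X`, the ratio of the Langevin diffusion
#' coefficient to the population,
#' `sqrt(sum of X's channel rates) / X` (times `omega^-1/2` in
#' concentration mode), evaluated along a deterministic trajectory.
#' For the tumour cells this is
#' `sqrt((alpha g_b + delta_N g_d) / N)`, which grows with the
#' effective nutrient supply `f1(E)` at fixed `N` (larger `f1` relaxes
#' the crowding ratio and raises the birth rate).
#'
#' @param params an [kinetic_params()] object.
#' @param traj an `ak_trajectory` with `N > 0` throughout.
#' @return Data frame `t, N, P, V` of relative intensities (`V` is
#'   `NA` where the trajectory has `V = 0`).
#' @export
noise_intensity <- function(params, traj) {
  stopifnot(inherits(params, "ak_params"))
  df <- as.data.frame(traj)
  if (any(df$N <= 0))
    stop("noise intensity requires N > 0 along the trajectory",
         call. = FALSE)
  pref <- if (params$mode == "concentration") 1 / sqrt(params$omega) else 1
  out <- data.frame(t = df$t, N = NA_real_, P = NA_real_, V = NA_real_)
  for (i in seq_len(nrow(df))) {
    a <- reaction_rates(df$N[i], df$P[i], df$V[i], params)
    out$N[i] <- pref * sqrt(a[["N_birth"]] + a[["N_death"]]) / df$N[i]
    out$P[i] <- if (df$P[i] > 0)
      pref * sqrt(a[["P_prod"]] + a[["P_decay"]]) / df$P[i] else NA_real_
    out$V[i] <- if (df$V[i] > 0)
      pref * sqrt(a[["V_birth"]] + a[["V_death"]]) / df$V[i] else NA_real_
  }
  out
}
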