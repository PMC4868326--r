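#' Trajectory container
#'
#' A trajectory is a data frame of time-ordered state samples with the
#' integration/simulation provenance attached as attributes:
#' `provenance` (`"ode"`, `"cle"` or `"ssa"`), `seed` (or `NA`), and
#' `params` (the [kinetic_params()] used).
#'
#' @param samples data frame with strictly increasing `t` and species
#'   columns.
#' @param provenance one of `"ode"`, `"cle"`, `"ssa"`.
#' @param params the generating parameter set.
#' @param seed RNG seed, or `NA` for deterministic provenance.
#' @return The data frame with class `ak_trajectory` prepended.
#' @export
trajectory <- function(samples, provenance = c("ode", "cle", "ssa"),
                       params = NULL, seed = NA) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(samples), "t" %in% names(samples))
  if (is.unsorted(samples$t, strictly = TRUE))
    stop("trajectory times must be strictly increasing", call. = FALSE)
  structure(samples,
            class = c("ak_trajectory", class(samples)),
            provenance = provenance, params = params, seed = seed)
}

#' @export
print.ak_trajectory <- function(x, ...) {
  cat("<ak_trajectory> provenance =", attr(x, "provenance"),
      " rows =", nrow(x), " t in [", min(x$t), ",", max(x$t), "]\n")
  utils::str(utils::head(as.data.frame(x)))
  invisible(x)
}

ode_parm_vector <- function(params) {
  p <- unclass(params)
  unlist(p[c("alpha", "delta_N", "K", "b1", "c1", "a2", "c2",
             "delta_P", "b3", "a3", "m3", "n", "n1", "n2", "n3",
             "n4")], use.names = FALSE)
}

#' Integrate the macroscopic ODE system
#'
#' Stiff-capable integration (via [deSolve::lsoda()]) of the
#' deterministic limit of the reaction scheme, in the parameters'
#' native units (counts in absolute mode).  Output is returned exactly
#' on the caller-supplied grid.  Small integrator undershoots below
#' zero (within one absolute tolerance) are clipped to zero.
#'
#' @param params an [kinetic_params()] object.
#' @param initial an [system_state()] or named vector `(N, P, V)`.
#' @param t_grid increasing vector of output times (days).
#' @param t0 time at which `initial` holds (default: first grid point).
#' @param rtol relative tolerance (default `1e-8`).
#' @param atol absolute tolerance per species; defaults to
#'   `1e-12 * pmax(1, initial)` so each species' floor scales with its
#'   initial magnitude.
#' @return An `ak_trajectory` with columns `t`, `N`, `P`, `V`.
#' @export
integrate_ode <- function(params, initial, t_grid, t0 = t_grid[1],
                          rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(params, "ak_params"))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  if (t0 > t_grid[1])
    stop("t0 must not exceed the first output time", call. = FALSE)
  y0 <- c(N = unname(initial[["N"]]), P = unname(initial[["P"]]),
          V = unname(initial[["V"]]))
  if (any(y0 < 0) || any(!is.finite(y0)))
    stop("invalid initial state", call. = FALSE)
  if (is.null(atol)) atol <- 1e-12 * pmax(1, abs(y0))
  times <- unique(c(t0, t_grid))
  sol <- deSolve::lsoda(y0, times, func = "ak_ode_rhs",
                        parms = ode_parm_vector(params),
                        dllname = "angiokin", initfunc = "ak_ode_init",
                        rtol = rtol, atol = atol, maxsteps = 20000L)
  di <- diagnostics_ok(sol, utils::tail(times, 1))
  if (!di$ok)
    stop("ODE integration failed; last good time ", di$t_last,
         call. = FALSE)
  out <- as.data.frame(sol)
  out <- out[match(t_grid, out$time), ]
  names(out)[1] <- "t"
  for (s in c("N", "P", "V")) {
    bad <- out[[s]] < 0
    out[[s]][bad & out[[s]] > -max(atol)] <- 0
  }
  rownames(out) <- NULL
  trajectory(out, "ode", params = params)
}

diagnostics_ok <- function(sol, t_end) {
  t_last <- max(sol[, 1])
  ok <- abs(t_last - t_end) <= 1e-10 * max(1, abs(t_end)) &&
    !any(!is.finite(sol))
  list(ok = ok, t_last = t_last)
}

#' Integrate the (N, P, E) form of the dynamics
#'
#' For `N > 0` the vessel equation can be rewritten for the effective
#' vessel density `E = V/N`:
#' `dE/dt = (f3b(P) - f3d(P) - alpha g_b + delta_N g_d) E`
#' (chain rule on `V/N`), coupled to the usual `N` and `P` equations.
#' `E = 0` is an invariant manifold of this form.  The run is an error
#' if `N` reaches zero, where the change of variables is invalid.
#'
#' @param params an [kinetic_params()] object.
#' @param initial named vector with `N > 0`, `P`, `E`.
#' @inheritParams integrate_ode
#' @return An `ak_trajectory` with columns `t`, `N`, `P`, `E`.
#' @export
integrate_E_form <- function(params, initial, t_grid,
                             rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(params, "ak_params"))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  y0 <- c(N = unname(initial[["N"]]), P = unname(initial[["P"]]),
          E = unname(initial[["E"]]))
  t0 <- t_grid[1]
  if (y0[["N"]] <= 0) stop("E-form requires N(0) > 0", call. = FALSE)
  if (is.null(atol)) atol <- 1e-12 * pmax(1, abs(y0))
  p <- params
  rhs <- function(t, y, parms) {
    N <- max(y[["N"]], 0); P <- max(y[["P"]], 0); E <- max(y[["E"]], 0)
    x <- N / (p$K + f1(E, p$b1, p$c1, p$n))
    net_N <- p$alpha * g_b(x, p$n1) - p$delta_N * g_d(x, p$n2)
    list(c(net_N * N,
           f2(E, p$a2, p$c2) * N - p$delta_P * P,
           (f3b(P, p$b3, p$m3, p$n3) - f3d(P, p$a3, p$m3, p$n4) - net_N) * E))
  }
  times <- t_grid
  sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol)
  di <- diagnostics_ok(sol, utils::tail(times, 1))
  if (!di$ok)
    stop("E-form integration failed; last good time ", di$t_last,
         call. = FALSE)
  out <- as.data.frame(sol)
  out <- out[match(t_grid, out$time), ]
  names(out)[1] <- "t"
  if (any(out$N <= 0))
    stop("N reached 0: the E-form is invalid there", call. = FALSE)
  for (s in c("P", "E")) {
    bad <- out[[s]] < 0
    out[[s]][bad & out[[s]] > -max(atol)] <- 0
  }
  rownames(out) <- NULL
  trajectory(out, "ode", params = params)
}

#' Run the deterministic dynamics to a steady state
#'
#' Integrates in doubling windows until the drift satisfies
#' `max|drift| < tol * (1 + max|state|)` sustained over one time unit,
#' or `t_max` is reached.
#'
#' @inheritParams integrate_ode
#' @param t_max maximum integration horizon (days).
#' @param tol steady-state drift tolerance (relative, default `1e-8`).
#' @return A list with `state` (named vector at the final time),
#'   `t` (arrival time), and `converged` (logical).
#' @export
run_to_steady <- function(params, initial, t_max = 1e4, tol = 1e-8,
                          rtol = 1e-8) {
  y <- c(N = unname(initial[["N"]]), P = unname(initial[["P"]]),
         V = unname(initial[["V"]]))
  t0 <- 0; win <- 1
  steady_at <- function(y) {
    d <- drift(y, params)
    max(abs(d)) < tol * (1 + max(abs(y)))
  }
  while (t0 < t_max) {
    win <- min(win, t_max - t0)
    tr <- integrate_ode(params, y, t0 + c(win / 2, win), t0 = t0,
                        rtol = rtol)
    y_mid <- unlist(tr[1, c("N", "P", "V")])
    y <- unlist(tr[2, c("N", "P", "V")])
    t0 <- t0 + win
    if (win >= 1 && steady_at(y) && steady_at(y_mid))
      return(list(state = y, t = t0, converged = TRUE))
    win <- win * 2
  }
  list(state = y, t = t0, converged = steady_at(y))
}

#' Write / read a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV has the header `t,N,P,V` (or the trajectory's own columns),
#' one row per grid point, `.` decimal, UTF-8.  The sidecar
#' `<path>.meta.json` records parameters, seed, provenance and
#' tolerances so the run can be reproduced exactly.
#'
#' @param traj an `ak_trajectory`.
#' @param path CSV output path.
#' @param tolerances optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, tolerances = NULL) {
  utils::write.csv(as.data.frame(traj)[, , drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  meta <- list(provenance = attr(traj, "provenance"),
               seed = attr(traj, "seed"),
               params = unclass(attr(traj, "params")),
               tolerances = tolerances)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
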