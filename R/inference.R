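#' Convert tumour volume to cell count (and back)
#'
#' Assumes spherical tumour cells of radius `cell_radius_um`
#' (default 3.5 um, i.e. 7 um diameter) densely filling the measured
#' volume, with no packing-fraction correction: a 2 mm diameter tumour
#' then holds `(2000/7)^3 ~ 2.33e7` cells and a 3 mm one `~7.87e7`.
#'
#' @param volume_mm3 tumour volume(s) in mm^3 (> 0).
#' @param cells cell count(s) (> 0).
#' @param cell_radius_um cell radius in micrometres (> 0).
#' @return `volume_to_cells()` returns cell counts;
#'   `cells_to_volume()` returns mm^3.
#' @export
volume_to_cells <- function(volume_mm3, cell_radius_um = 3.5) {
  if (any(volume_mm3 <= 0) || cell_radius_um <= 0)
    stop("volume and radius must be positive", call. = FALSE)
  r_mm <- cell_radius_um / 1000
  volume_mm3 / (4 / 3 * pi * r_mm^3)
}

#' @rdname volume_to_cells
#' @export
cells_to_volume <- function(cells, cell_radius_um = 3.5) {
  if (any(cells <= 0) || cell_radius_um <= 0)
    stop("cells and radius must be positive", call. = FALSE)
  r_mm <- cell_radius_um / 1000
  cells * (4 / 3 * pi * r_mm^3)
}

#' Relative mean-square error between data and model series
#'
#' `MSE = (1/M) sum_i ((x_i^data - x_i^model) / x_i^data)^2` — the
#' dimensionless, scale-invariant objective minimised by the fit.
#'
#' @param data_values measured values (nonzero).
#' @param model_values model values at the same times.
#' @return The scalar MSE (multiply by 100 to quote as `%`).
#' @export
growth_mse <- function(data_values, model_values) {
  if (length(data_values) != length(model_values))
    stop("series lengths differ", call. = FALSE)
  if (any(data_values == 0))
    stop("relative error undefined for zero data values", call. = FALSE)
  mean(((data_values - model_values) / data_values)^2)
}

#' Particle swarm optimisation (ring topology)
#'
#' Compact PSO with constriction-style coefficients (inertia 0.72,
#' cognitive = social = 1.49), reflective bound handling and a ring
#' (lbest) neighbourhood of one particle per side — the slower
#' information flow of the ring keeps multiple basins alive on
#' multimodal objectives.  Used by [pso_fit()] over log10-transformed
#' parameters.  Self-seeded: restores R's RNG state on exit.
#'
#' @param fn objective, taking a numeric vector in `[lower, upper]`.
#' @param lower,upper finite bound vectors.
#' @param n_particles swarm size.
#' @param iters number of iterations.
#' @param inertia,c_cog,c_soc PSO coefficients.
#' @param seed integer seed.
#' @return List with `par`, `value` and `trace` (best objective after
#'   each iteration).
#' @export
pso_optim <- function(fn, lower, upper, n_particles = 60L, iters = 300L,
                      inertia = 0.72, c_cog = 1.49, c_soc = 1.49,
                      seed = 1L) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  d <- length(lower)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  span <- upper - lower
  X <- matrix(stats::runif(n_particles * d), n_particles, d)
  X <- sweep(sweep(X, 2, span, "*"), 2, lower, "+")
  Vel <- matrix(stats::runif(n_particles * d, -1, 1), n_particles, d)
  Vel <- sweep(Vel, 2, span / 10, "*")
  fX <- apply(X, 1, fn)
  Pbest <- X; fP <- fX
  g <- which.min(fP)
  trace <- numeric(iters)
  ring <- cbind(c(n_particles, seq_len(n_particles - 1)),
                seq_len(n_particles),
                c(seq(2, n_particles), 1))
  for (it in seq_len(iters)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    nb <- ring[cbind(seq_len(n_particles),
                     max.col(-matrix(fP[ring], n_particles, 3),
                             ties.method = "first"))]
    Gmat <- Pbest[nb, , drop = FALSE]
    Vel <- inertia * Vel + c_cog * r1 * (Pbest - X) +
      c_soc * r2 * (Gmat - X)
    X <- X + Vel
    for (j in seq_len(d)) {        # reflective bounds
      lo <- X[, j] < lower[j]
      X[lo, j] <- pmin(2 * lower[j] - X[lo, j], upper[j])
      Vel[lo, j] <- -Vel[lo, j]
      hi <- X[, j] > upper[j]
      X[hi, j] <- pmax(2 * upper[j] - X[hi, j], lower[j])
      Vel[hi, j] <- -Vel[hi, j]
    }
    fX <- apply(X, 1, fn)
    imp <- fX < fP
    Pbest[imp, ] <- X[imp, ]; fP[imp] <- fX[imp]
    g <- which.min(fP)
    trace[it] <- fP[g]
  }
  list(par = Pbest[g, ], value = fP[g], trace = trace,
       pbest = Pbest, fpbest = fP)
}

#' Fit model parameters to a tumour-growth dataset
#'
#' Minimises the relative mean-square error between the measured cell
#' counts and the deterministic solution sampled at the data times,
#' over a chosen subset of parameters with finite positive bounds,
#' using particle-swarm optimisation in log10 parameter space.
#' Volume data are converted to cell counts with
#' [volume_to_cells()].  By default the integration starts at the
#' first data time from `(N = first data point, P = 10, V = 1)`; a
#' synthetic dataset carries its generator's true initial state and
#' start time in metadata and those are used instead, making noiseless
#' recovery a pure parameter-estimation problem.
#'
#' @param data an `ak_growth` dataset (see [generate_growth_data()] or
#'   [read_growth_csv()]).
#' @param params baseline [kinetic_params()]; non-fitted fields stay
#'   fixed.
#' @param fit names of the fitted fields.
#' @param bounds 2-row matrix (rows `lower`, `upper`) with one column
#'   per fitted field.
#' @param n_particles,iters,seed forwarded to [pso_optim()].
#' @param polish_k number of distinct swarm personal bests refined by
#'   a Nelder-Mead descent after the swarm search (0 disables); the
#'   growth objective has long curved valleys that the swarm locates
#'   but does not descend to machine precision.
#' @param initial optional named `(N, P, V)` start state overriding
#'   the defaults.
#' @param t0 time of `initial`.
#' @param rtol ODE tolerance used inside the objective.
#' @return An object of class `ak_fit`: list with `params` (fitted
#'   set), `estimates`, `mse`, `mse_percent`, `bounds`, `trace`,
#'   `seed`.
#' @export
pso_fit <- function(data, params, fit, bounds, n_particles = 60L,
                    iters = 300L, seed = 1L, polish_k = 5L,
                    initial = NULL, t0 = NULL, rtol = 1e-8) {
  stopifnot(inherits(params, "ak_params"),
            all(fit %in% names(unclass(params))),
            is.matrix(bounds), nrow(bounds) == 2,
            ncol(bounds) == length(fit))
  if (any(bounds <= 0) || any(!is.finite(bounds)))
    stop("bounds must be finite and positive", call. = FALSE)
  df <- as.data.frame(data)
  cells <- if (attr(data, "kind") == "volume")
    volume_to_cells(df$value) else df$value
  meta_init <- attr(data, "initial")
  meta_t0 <- attr(data, "t0")
  if (is.null(initial)) {
    if (!is.null(meta_init)) {
      initial <- meta_init
      if (is.null(t0)) t0 <- meta_t0
    } else {
      initial <- c(N = cells[1], P = 10, V = 1)
      if (is.null(t0)) t0 <- df$t[1]
    }
  } else if (is.null(t0)) t0 <- df$t[1]

  obj <- function(lp) {
    q <- unclass(params)
    q[fit] <- as.list(10^lp)
    class(q) <- "ak_params"
    v <- Inf
    # capture the solver's console chatter for failing particles
    utils::capture.output(
      v <- suppressWarnings(tryCatch({
        tr <- integrate_ode(q, initial, df$t, t0 = t0, rtol = rtol)
        growth_mse(cells, tr$N)
      }, error = function(e) Inf)), type = "output")
    v
  }
  lo <- log10(bounds[1, ]); hi <- log10(bounds[2, ])
  opt <- pso_optim(obj, lo, hi, n_particles = n_particles,
                   iters = iters, seed = seed)
  if (polish_k > 0) {
    pen <- function(lp) {                 # finite out-of-box penalty
      d <- sum(pmax(lo - lp, 0)^2 + pmax(lp - hi, 0)^2)
      if (d > 0) 1e6 * (1 + d) else {
        v <- obj(lp)
        if (is.finite(v)) v else 1e8
      }
    }
    ord <- order(opt$fpbest)
    starts <- list(); taken <- NULL
    for (i in ord) {
      lp <- opt$pbest[i, ]
      if (is.null(taken) ||
          all(apply(taken, 1, function(z) sqrt(sum((z - lp)^2))) > 0.5)) {
        starts[[length(starts) + 1]] <- lp
        taken <- rbind(taken, lp)
      }
      if (length(starts) >= polish_k) break
    }
    for (lp in starts) {
      nm <- if (length(lp) == 1L)
        stats::optim(lp, pen, method = "Brent", lower = lo, upper = hi)
      else
        stats::optim(lp, pen, method = "Nelder-Mead",
                     control = list(maxit = 500L, reltol = 1e-15))
      if (nm$value < opt$value) {
        opt$value <- nm$value
        opt$par <- pmin(pmax(nm$par, lo), hi)
      }
    }
    opt$value <- obj(opt$par)
  }
  est <- stats::setNames(10^opt$par, fit)
  q <- unclass(params); q[fit] <- as.list(est); class(q) <- "ak_params"
  structure(list(params = q, estimates = est, mse = opt$value,
                 mse_percent = 100 * opt$value,
                 bounds = bounds, trace = opt$trace, seed = seed,
                 initial = initial, t0 = t0),
            class = "ak_fit")
}

#' @export
print.ak_fit <- function(x, ...) {
  cat("<ak_fit> MSE =", format(x$mse, digits = 4),
      paste0("(", format(x$mse_percent, digits = 4), "%)\n"))
  print(signif(x$estimates, 4))
  invisible(x)
}

#' Perturbation sensitivity analysis
#'
#' Samples each listed parameter independently and uniformly within
#' `+/- perturbation` of its value, integrates the deterministic
#' dynamics, and reports the Pearson correlation between each
#' parameter's relative perturbation and each output (`N`, `P`,
#' `E = V/N`) at the requested times.  Parameters with all
#' `|correlation| < 0.2` are flagged low-influence.
#'
#' @param params baseline [kinetic_params()].
#' @param initial named `(N, P, V)` start state.
#' @param perturbation half-width of the relative perturbation
#'   (in `(0, 0.5)`; default 0.02, i.e. +/-2%).
#' @param n number of perturbed samples (>= 100).
#' @param times output times in days (default days 5, 15, 30,
#'   spanning the early, mid and late growth phases).
#' @param fields parameters to perturb (default: the 11 continuous
#'   rate/scale constants; Hill exponents stay fixed).
#' @param seed integer seed (R RNG, restored on exit).
#' @param rtol ODE tolerance.
#' @return An object of class `ak_sensitivity`: list with `table`
#'   (data frame `parameter, output, time, correlation,
#'   low_influence`), `n_failed`, and the call settings.
#' @export
sensitivity <- function(params, initial, perturbation = 0.02, n = 200L,
                        times = c(5, 15, 30),
                        fields = c("alpha", "delta_N", "K", "b1", "c1",
                                   "a2", "c2", "delta_P", "b3", "a3",
                                   "m3"),
                        seed = 1L, rtol = 1e-8) {
  stopifnot(inherits(params, "ak_params"),
            perturbation > 0, perturbation < 0.5, n >= 100)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  k <- length(fields)
  U <- matrix(stats::runif(n * k, -perturbation, perturbation), n, k,
              dimnames = list(NULL, fields))
  outs <- array(NA_real_, c(n, length(times), 3),
                dimnames = list(NULL, NULL, c("N", "P", "E")))
  failed <- 0L
  for (i in seq_len(n)) {
    q <- unclass(params)
    for (j in seq_len(k)) q[[fields[j]]] <- q[[fields[j]]] * (1 + U[i, j])
    class(q) <- "ak_params"
    tr <- tryCatch(integrate_ode(q, initial, times, t0 = 0, rtol = rtol),
                   error = function(e) NULL)
    if (is.null(tr)) { failed <- failed + 1L; next }
    outs[i, , "N"] <- tr$N
    outs[i, , "P"] <- tr$P
    outs[i, , "E"] <- tr$V / tr$N
  }
  rows <- list()
  for (f in fields) for (jt in seq_along(times)) for (o in c("N", "P", "E")) {
    y <- outs[, jt, o]
    ok <- is.finite(y)
    r <- if (sum(ok) > 2 && stats::sd(y[ok]) > 0)
      stats::cor(U[ok, f], y[ok]) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      parameter = f, output = o, time = times[jt], correlation = r)
  }
  tab <- do.call(rbind, rows)
  infl <- tapply(abs(tab$correlation), tab$parameter,
                 function(v) max(v, na.rm = TRUE))
  tab$low_influence <- infl[tab$parameter] < 0.2
  structure(list(table = tab, n = n, n_failed = failed,
                 perturbation = perturbation, times = times,
                 fields = fields, seed = seed),
            class = "ak_sensitivity")
}

#' @export
print.ak_sensitivity <- function(x, ...) {
  cat("<ak_sensitivity> n =", x$n, " failed =", x$n_failed, "\n")
  agg <- tapply(abs(x$table$correlation), x$table$parameter,
                max, na.rm = TRUE)
  print(sort(round(agg, 3), decreasing = TRUE))
  invisible(x)
}

#' Write a sensitivity table as CSV
#'
#' Columns `parameter,output,time,correlation`.
#'
#' @param sens an `ak_sensitivity`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(sens, path) {
  utils::write.csv(sens$table[, c("parameter", "output", "time",
                                  "correlation")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
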