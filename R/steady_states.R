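#' Tumour-cell balance ratio gamma
#'
#' The unique positive root of `alpha g_b(gamma) = delta_N g_d(gamma)`:
#' the crowding ratio `N/(K + f1(E))` at which tumour-cell birth and
#' death balance.  Uniqueness follows from `g_b` decreasing and `g_d`
#' increasing.  When `n1 = n2` the root is `(alpha/delta_N)^(1/n1)`.
#'
#' @param params an [kinetic_params()] object.
#' @return The scalar `gamma`.
#' @export
solve_gamma <- function(params) {
  p <- params
  F <- function(lg) {
    g <- exp(lg)
    p$alpha * g_b(g, p$n1) - p$delta_N * g_d(g, p$n2)
  }
  root <- log_root(F, lo = -60, hi = 60)
  exp(root)
}

#' Steady-state VEGF level P-tilde
#'
#' The unique positive root of `f3b(P) = f3d(P)` — the VEGF level at
#' which vessel-cell birth and death balance.  Every positive steady
#' state `C_i` sits at this protein level.  For `n3 = n4` the closed
#' form is `m3 (a3/b3)^(1/n3)`; in particular `P = m3` when
#' `a3 = b3`.
#'
#' @param params an [kinetic_params()] object.
#' @return The scalar `Ptilde` (same units as `m3`).
#' @export
solve_Ptilde <- function(params) {
  p <- params
  F <- function(lp) {
    P <- exp(lp)
    f3b(P, p$b3, p$m3, p$n3) - f3d(P, p$a3, p$m3, p$n4)
  }
  exp(log_root(F, lo = log(p$m3) - 60, hi = log(p$m3) + 60))
}

# root of a monotone-increasing-through-zero function of a log
# variable; bracket by expansion then uniroot at machine precision
log_root <- function(F, lo, hi) {
  flo <- F(lo); fhi <- F(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi))
    stop("root bracketing failed", call. = FALSE)
  stats::uniroot(F, c(lo, hi), tol = .Machine$double.eps^0.9,
                 maxiter = 2000L)$root
}

#' Steady-state level function Phi(E)
#'
#' `Phi(E) = f2(E) (K + f1(E))`.  Positive steady states `C_i` are the
#' solutions of `Phi(E) = delta_P Ptilde / gamma`, i.e. the zeros of
#' the auxiliary function `h(E) = Phi(E) - delta_P Ptilde / gamma`.
#' The local extrema of `Phi` therefore give the fold (saddle-node)
#' levels of the VEGF degradation rate in closed form.
#'
#' @param E effective vessel density grid (>= 0).
#' @param params an [kinetic_params()] object.
#' @return `Phi(E)`.
#' @export
phi_level <- function(E, params) {
  p <- params
  f2(E, p$a2, p$c2) * (p$K + f1(E, p$b1, p$c1, p$n))
}

#' Evaluate the steady-state auxiliary function h over a grid
#'
#' Evaluates `h(E) = f2(E)(K + f1(E)) - delta_P Ptilde / gamma` on a
#' (log-spaced by default) grid, locates its positive roots by
#' bracketed root refinement, and its local extrema `E_M` (maximum)
#' and `E_m` (minimum) when present.  With Hill-form `f1` and `f2`
#' there are at most three positive roots.
#'
#' @param params an [kinetic_params()] object.
#' @param E_grid ascending positive grid; default 600 log-spaced
#'   points over `[1e-12, 1e12]`.
#' @return An object of class `ak_hprofile`: list with `E`, `h`,
#'   `level` (`delta_P Ptilde / gamma`), `roots` (ascending), `E_M`,
#'   `E_m` (or `NA`), `gamma`, `Ptilde`.
#' @export
h_eval <- function(params, E_grid = NULL) {
  p <- params
  if (is.null(E_grid))
    E_grid <- exp(seq(log(1e-12), log(1e12), length.out = 600L))
  if (length(E_grid) < 2L)
    stop("need at least 2 grid points", call. = FALSE)
  if (any(E_grid <= 0) || is.unsorted(E_grid, strictly = TRUE))
    stop("E grid must be positive ascending", call. = FALSE)
  gamma <- solve_gamma(p)
  Ptilde <- solve_Ptilde(p)
  level <- p$delta_P * Ptilde / gamma
  hfun <- function(E) phi_level(E, p) - level
  h <- hfun(E_grid)

  # roots: sign changes on the grid, refined by uniroot
  sc <- which(h[-length(h)] * h[-1] < 0)
  roots <- vapply(sc, function(i)
    stats::uniroot(hfun, c(E_grid[i], E_grid[i + 1]),
                   tol = 1e-12 * E_grid[i])$root, 0)
  roots <- sort(c(roots, E_grid[h == 0]))
  if (length(roots) > 1) {           # merge near-duplicates
    keep <- c(TRUE, diff(roots) / roots[-length(roots)] > 1e-8)
    roots <- roots[keep]
  }

  # local extrema of h (equivalently of Phi): slope sign changes
  slope <- diff(h) / diff(E_grid)
  ext <- which(slope[-length(slope)] * slope[-1] < 0)
  E_M <- E_m <- NA_real_
  for (i in ext) {
    opt_int <- c(E_grid[i], E_grid[i + 2])
    if (slope[i] > 0) {             # rising then falling: maximum
      o <- stats::optimize(hfun, opt_int, maximum = TRUE,
                           tol = 1e-10 * E_grid[i])
      E_M <- o$maximum
    } else {
      o <- stats::optimize(hfun, opt_int, maximum = FALSE,
                           tol = 1e-10 * E_grid[i])
      E_m <- o$minimum
    }
  }
  structure(list(E = E_grid, h = h, level = level, roots = roots,
                 E_M = E_M, E_m = E_m, gamma = gamma, Ptilde = Ptilde,
                 params = p),
            class = "ak_hprofile")
}

h_slope_at <- function(params, E, gamma, Ptilde) {
  # central finite difference of h (= of Phi) at E, relative step
  dE <- 1e-6 * E
  (phi_level(E + dE, params) - phi_level(E - dE, params)) / (2 * dE)
}

#' Numerical Jacobian of the macroscopic drift
#'
#' Central finite differences with per-component step
#' `1e-6 * (1 + |state|)`.
#'
#' @param params an [kinetic_params()] object.
#' @param state named vector `(N, P, V)`.
#' @return A 3 x 3 matrix.
#' @export
jacobian_at <- function(params, state) {
  y <- c(N = unname(state[["N"]]), P = unname(state[["P"]]),
         V = unname(state[["V"]]))
  J <- matrix(0, 3, 3, dimnames = list(names(y), names(y)))
  for (j in seq_along(y)) {
    hstep <- 1e-6 * (1 + abs(y[j]))
    yp <- y; yp[j] <- y[j] + hstep
    ym <- y; ym[j] <- max(y[j] - hstep, 0)
    J[, j] <- (drift(yp, params) - drift(ym, params)) / (yp[j] - ym[j])
  }
  J
}

#' Enumerate and classify the steady states
#'
#' Returns the trivial state `A = (0,0,0)` (always unstable as an
#' equilibrium of the deterministic flow, though absorbing for the
#' stochastic dynamics), the avascular state
#' `B = (K gamma, a2 K gamma / delta_P, 0)` (stable iff
#' `f3b(P_B) < f3d(P_B)`), and one vascularised state `C_i` per
#' positive root `E_i` of `h`, with `N = gamma (K + f1(E_i))`,
#' `P = Ptilde`, `V = E_i N`, stable iff `h'(E_i) < 0`.  Each `C_i`
#' verdict is cross-checked against the eigenvalues of the numerical
#' Jacobian; a root sitting on a near-flat slope is flagged
#' `"marginal"` with no verdict.
#'
#' @param params an [kinetic_params()] object.
#' @param E_grid optional grid forwarded to [h_eval()].
#' @return An object of class `ak_steady_states`: list of records with
#'   fields `label`, `N`, `P`, `V`, `E`, `stability`, `diagnostics`
#'   (`gamma`, `Ptilde`, `h_slope`, `jacobian_eigs`).
#' @export
enumerate_states <- function(params, E_grid = NULL) {
  p <- params
  hp <- h_eval(p, E_grid)
  gamma <- hp$gamma; Ptilde <- hp$Ptilde
  h_scale <- max(abs(hp$level), p$a2 * p$K)

  states <- list()
  states[[1]] <- list(label = "A", N = 0, P = 0, V = 0, E = NA_real_,
                      stability = "unstable",
                      diagnostics = list(gamma = gamma, Ptilde = Ptilde,
                                         h_slope = NA_real_,
                                         jacobian_eigs = NULL))
  N_B <- p$K * gamma
  P_B <- p$a2 * N_B / p$delta_P
  b_stable <- f3b(P_B, p$b3, p$m3, p$n3) < f3d(P_B, p$a3, p$m3, p$n4)
  states[[2]] <- list(label = "B", N = N_B, P = P_B, V = 0, E = 0,
                      stability = if (b_stable) "stable" else "unstable",
                      diagnostics = list(gamma = gamma, Ptilde = Ptilde,
                                         h_slope = NA_real_,
                                         jacobian_eigs = NULL))
  for (E_i in hp$roots) {
    N_i <- gamma * (p$K + f1(E_i, p$b1, p$c1, p$n))
    st <- list(label = "C", N = N_i, P = Ptilde, V = E_i * N_i, E = E_i)
    sl <- h_slope_at(p, E_i, gamma, Ptilde)
    eigs <- eigen(jacobian_at(p, c(N = st$N, P = st$P, V = st$V)),
                  only.values = TRUE)$values
    if (abs(sl) * E_i < 1e-12 * h_scale) {
      st$stability <- "marginal"
    } else {
      verdict_h <- if (sl < 0) "stable" else "unstable"
      re_max <- max(Re(eigs))
      band <- 1e-9 * (1 + max(abs(eigs)))
      if (abs(re_max) > band) {
        verdict_j <- if (re_max < 0) "stable" else "unstable"
        if (verdict_j != verdict_h)
          warning("h-slope and Jacobian stability verdicts disagree at E = ",
                  signif(E_i, 6), call. = FALSE)
      }
      st$stability <- verdict_h
    }
    st$diagnostics <- list(gamma = gamma, Ptilde = Ptilde,
                           h_slope = sl, jacobian_eigs = eigs)
    states[[length(states) + 1]] <- st
  }
  structure(list(states = states, params = p, h_profile = hp),
            class = "ak_steady_states")
}

#' @export
print.ak_steady_states <- function(x, ...) {
  cat("<ak_steady_states>", length(x$states), "states\n")
  for (s in x$states)
    cat(sprintf("  %s: N=%.6g P=%.6g V=%.6g E=%s  [%s]\n",
                s$label, s$N, s$P, s$V,
                if (is.na(s$E)) "-" else format(signif(s$E, 6)),
                s$stability))
  invisible(x)
}

#' Write a steady-state report as JSON
#'
#' One record per state with its label, coordinates, `E`, stability
#' verdict and diagnostics (`gamma`, `Ptilde`, `h_slope`, Jacobian
#' eigenvalue real parts).
#'
#' @param states an `ak_steady_states` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_steady_states_json <- function(states, path) {
  recs <- lapply(states$states, function(s) {
    eig <- s$diagnostics$jacobian_eigs
    list(label = s$label, N = s$N, P = s$P, V = s$V,
         E = if (is.na(s$E)) NULL else s$E,
         stability = s$stability,
         gamma = s$diagnostics$gamma,
         Ptilde = s$diagnostics$Ptilde,
         h_slope = if (is.na(s$diagnostics$h_slope)) NULL else
           s$diagnostics$h_slope,
         jacobian_re = if (is.null(eig)) NULL else Re(eig))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Closed-form fold levels of the VEGF degradation rate
#'
#' At a fold, a local extremum of `Phi(E) = f2(E)(K + f1(E))` equals
#' the level `delta_P Ptilde / gamma`, so the critical degradation
#' rates are `delta_Pcr = Phi(E_ext) gamma / Ptilde` with `E_ext` a
#' local extremum of `Phi`.  The local minimum gives the lower fold
#' (where a small stable vascularised state appears alongside the
#' large one) and the local maximum gives the upper fold (where the
#' large state is lost).
#'
#' @param params an [kinetic_params()] object.
#' @param E_grid optional grid forwarded to [h_eval()].
#' @return Named vector `c(lower = ..., upper = ...)` (`NA` when the
#'   corresponding extremum does not exist).
#' @export
critical_delta_P <- function(params, E_grid = NULL) {
  hp <- h_eval(params, E_grid)
  fac <- hp$gamma / hp$Ptilde
  c(lower = if (is.na(hp$E_m)) NA_real_ else
      phi_level(hp$E_m, params) * fac,
    upper = if (is.na(hp$E_M)) NA_real_ else
      phi_level(hp$E_M, params) * fac)
}

#' Sweep a parameter and detect stability transitions
#'
#' Runs [enumerate_states()] over a grid of values of one parameter,
#' tracks the number of stable states, and refines every change point
#' by bisection on the stable-state count to a relative width of
#' `1e-4`.  For sweeps of `delta_P` the closed-form fold levels from
#' [critical_delta_P()] are reported alongside the bisection values.
#'
#' @param params an [kinetic_params()] object.
#' @param param name of the swept field of `params`.
#' @param grid positive ascending vector of parameter values.
#' @param E_grid optional grid forwarded to [h_eval()].
#' @return An object of class `ak_bifurcation`: list with `param`,
#'   `grid`, `states` (data frame: `param_value`, `label`, `N`, `P`,
#'   `V`, `E`, `stable`), `n_stable` per grid value, `critical`
#'   (data frame of refined change points with brackets), and
#'   `closed_form` (for `delta_P` sweeps).
#' @export
bifurcation_scan <- function(params, param, grid, E_grid = NULL) {
  stopifnot(param %in% names(unclass(params)))
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be positive ascending", call. = FALSE)
  at <- function(v) {
    q <- unclass(params); q[[param]] <- v
    class(q) <- "ak_params"
    enumerate_states(q, E_grid)
  }
  rows <- list(); n_stable <- integer(length(grid))
  for (i in seq_along(grid)) {
    ss <- at(grid[i])
    for (s in ss$states)
      rows[[length(rows) + 1]] <- data.frame(
        param_value = grid[i], label = s$label, N = s$N, P = s$P,
        V = s$V, E = if (is.na(s$E)) NA_real_ else s$E,
        stable = identical(s$stability, "stable"))
    n_stable[i] <- sum(vapply(ss$states,
                              function(s) identical(s$stability, "stable"),
                              TRUE))
  }
  count_at <- function(v)
    sum(vapply(at(v)$states,
               function(s) identical(s$stability, "stable"), TRUE))
  crit <- list()
  for (i in which(diff(n_stable) != 0)) {
    lo <- grid[i]; hi <- grid[i + 1]
    c_lo <- n_stable[i]
    while ((hi - lo) / lo > 1e-4) {
      mid <- sqrt(lo * hi)
      if (count_at(mid) == c_lo) lo <- mid else hi <- mid
    }
    crit[[length(crit) + 1]] <- data.frame(
      value = sqrt(lo * hi), bracket_lo = lo, bracket_hi = hi,
      n_stable_below = n_stable[i], n_stable_above = n_stable[i + 1])
  }
  crit <- if (length(crit)) do.call(rbind, crit) else
    data.frame(value = numeric(0), bracket_lo = numeric(0),
               bracket_hi = numeric(0), n_stable_below = integer(0),
               n_stable_above = integer(0))
  structure(list(param = param, grid = grid,
                 states = do.call(rbind, rows), n_stable = n_stable,
                 critical = crit,
                 closed_form = if (param == "delta_P")
                   critical_delta_P(params, E_grid) else NULL,
                 params = params),
            class = "ak_bifurcation")
}

#' Write a bifurcation scan as CSV plus a JSON sidecar
#'
#' CSV columns: `param_value,label,N,P,V,E,stable`; the sidecar
#' `<path>.critical.json` records the swept parameter, the refined
#' critical values and (for `delta_P`) the closed-form fold levels.
#'
#' @param scan an `ak_bifurcation` object.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_bifurcation_csv <- function(scan, path) {
  utils::write.csv(scan$states, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(param = scan$param,
         critical = scan$critical,
         closed_form = as.list(scan$closed_form)),
    paste0(path, ".critical.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
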