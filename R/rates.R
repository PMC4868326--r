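#' Hill-type rate laws of the angiogenesis reaction scheme
#'
#' The six elementary rate laws controlling the reaction channels:
#' * `g_b(x, n1) = 1/(1 + x^n1)` — proliferation throttle, decreasing
#'   in the crowding ratio `x = N/(K + f1(E))`, `g_b(0) = 1`;
#' * `g_d(x, n2) = x^n2/(1 + x^n2)` — death switch, increasing,
#'   `g_d(0) = 0`;
#' * `f1(E) = b1 E^n/(c1 + E^n)` — effective nutrient supply through
#'   the vasculature, increasing from 0 to `b1`;
#' * `f2(E) = a2 c2/(c2 + E)` — per-cell VEGF secretion, decreasing
#'   from `a2` to 0;
#' * `f3b(P) = b3 P^n3/(m3^n3 + P^n3)` — vessel-cell birth, increasing
#'   from 0 to `b3`;
#' * `f3d(P) = a3 m3^n4/(m3^n4 + P^n4)` — vessel-cell death, decreasing
#'   from `a3` to 0.
#'
#' All are evaluated in a divide-through form that is stable for
#' arguments up to ~1e12 (`E`) and ~1e15 (`P`).  Negative arguments are
#' a domain error.
#'
#' @param x crowding ratio (dimensionless, >= 0).
#' @param E effective vessel density `V/N` (dimensionless, >= 0).
#' @param P VEGF level (>= 0, counts or concentration per the mode).
#' @param n,n1,n2,n3,n4 Hill exponents (> 0).
#' @param b1,c1,a2,c2,b3,a3,m3 rate-law constants, see
#'   [kinetic_params()].
#' @return Numeric vector of rate-law values.
#' @name rate_laws
NULL

chk_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and non-negative", call. = FALSE)
  x
}

# u^m / (a^m + u^m) evaluated in log space: immune to overflow of the
# raw powers for any positive exponent and arguments up to ~1e300
hill_up <- function(u, a, m) stats::plogis(m * (log(u) - log(a)))
hill_down <- function(u, a, m) stats::plogis(m * (log(a) - log(u)))

#' @rdname rate_laws
#' @export
g_b <- function(x, n1) {
  chk_nonneg(x, "x")
  hill_down(x, 1, n1)
}

#' @rdname rate_laws
#' @export
g_d <- function(x, n2) {
  chk_nonneg(x, "x")
  hill_up(x, 1, n2)
}

#' @rdname rate_laws
#' @export
f1 <- function(E, b1, c1, n) {
  chk_nonneg(E, "E")
  b1 * hill_up(E, c1^(1 / n), n)
}

#' @rdname rate_laws
#' @export
f2 <- function(E, a2, c2) {
  chk_nonneg(E, "E")
  a2 / (1 + E / c2)
}

#' @rdname rate_laws
#' @export
f3b <- function(P, b3, m3, n3) {
  chk_nonneg(P, "P")
  b3 * hill_up(P, m3, n3)
}

#' @rdname rate_laws
#' @export
f3d <- function(P, a3, m3, n4) {
  chk_nonneg(P, "P")
  a3 * hill_down(P, m3, n4)
}

# Channel order used throughout the package (rows N, P, V):
#   1 tumour-cell birth, 2 tumour-cell death, 3 VEGF secretion,
#   4 VEGF decay, 5 vessel-cell birth, 6 vessel-cell death.

#' Stoichiometry matrix of the reaction network
#'
#' @return A 3 x 6 integer matrix (rows `N`, `P`, `V`; one `+1`/`-1`
#'   per channel) in the package's canonical channel order: tumour-cell
#'   birth and death, VEGF secretion and decay, vessel-cell birth and
#'   death.
#' @export
stoichiometry <- function() {
  S <- matrix(0L, 3, 6,
              dimnames = list(c("N", "P", "V"),
                              c("N_birth", "N_death", "P_prod",
                                "P_decay", "V_birth", "V_death")))
  S["N", "N_birth"] <- 1L; S["N", "N_death"] <- -1L
  S["P", "P_prod"] <- 1L;  S["P", "P_decay"] <- -1L
  S["V", "V_birth"] <- 1L; S["V", "V_death"] <- -1L
  S
}

# Core channel rates with N, P, V in the parameters' native units
# (counts in absolute mode, concentrations otherwise).  A state with
# N = 0 is treated as fully absorbed: every channel rate is zero,
# which sidesteps the undefined E = V/N there.
reaction_rates <- function(N, P, V, params) {
  p <- params
  if (N <= 0) return(stats::setNames(numeric(6), colnames(stoichiometry())))
  E <- V / N
  x <- N / (p$K + f1(E, p$b1, p$c1, p$n))
  c(N_birth = p$alpha * g_b(x, p$n1) * N,
    N_death = p$delta_N * g_d(x, p$n2) * N,
    P_prod  = f2(E, p$a2, p$c2) * N,
    P_decay = p$delta_P * P,
    V_birth = f3b(P, p$b3, p$m3, p$n3) * V,
    V_death = f3d(P, p$a3, p$m3, p$n4) * V)
}

#' Reaction-channel propensities of the jump process
#'
#' Event rates (events per day) of the six reaction channels for a
#' state given in absolute counts, together with the stoichiometric
#' change vectors.  In concentration mode the Hill arguments are the
#' concentrations `N/omega` etc. while the returned rates remain event
#' rates.  A state with `N = 0` is fully absorbed (all rates zero);
#' channels whose population prefactor is zero have rate zero, so an
#' avascular state `(N, P, 0)` can never regrow vessels.
#'
#' @param state an [system_state()] object or named vector with `N`,
#'   `P`, `V` (counts; integers for the exact simulation).
#' @param params an [kinetic_params()] object.
#' @return A list with `rates` (named numeric of length 6) and
#'   `stoich` (3 x 6 matrix).
#' @export
propensities <- function(state, params) {
  stopifnot(inherits(params, "ak_params"))
  N <- unname(state[["N"]]); P <- unname(state[["P"]]); V <- unname(state[["V"]])
  if (any(!is.finite(c(N, P, V))) || any(c(N, P, V) < 0))
    stop("invalid state", call. = FALSE)
  om <- params$omega
  rates <- if (params$mode == "absolute" || om == 1)
    reaction_rates(N, P, V, params)
  else
    om * reaction_rates(N / om, P / om, V / om, params)
  list(rates = rates, stoich = stoichiometry())
}

#' Macroscopic drift of the angiogenesis model
#'
#' Net deterministic rates `(dN/dt, dP/dt, dV/dt)`, i.e. the signed sum
#' of the channel rates — the right-hand side of the macroscopic ODE
#' system (and of its absolute-number form when `params$mode` is
#' `"absolute"`).  The state is given in the parameters' native units.
#' A state with `N = 0` is treated as absorbed and returns zero drift.
#'
#' @inheritParams propensities
#' @return Named numeric vector `(N, P, V)` of time derivatives.
#' @export
drift <- function(state, params) {
  stopifnot(inherits(params, "ak_params"))
  N <- unname(state[["N"]]); P <- unname(state[["P"]]); V <- unname(state[["V"]])
  if (any(!is.finite(c(N, P, V))) || any(c(N, P, V) < 0))
    stop("invalid state", call. = FALSE)
  drop(stoichiometry() %*% reaction_rates(N, P, V, params))
}
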