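#' Kinetic parameter set for the angiogenesis reaction scheme
#'
#' Builds and validates the full constant set of the microscopic model:
#' tumour-cell proliferation/death (`alpha`, `delta_N`, `K`, `b1`, `c1`,
#' Hill exponents `n`, `n1`, `n2`), VEGF production/degradation (`a2`,
#' `c2`, `delta_P`) and vessel-cell turnover (`b3`, `a3`, `m3`, `n3`,
#' `n4`), plus the system size `omega` relating concentrations to
#' molecule/cell counts.
#'
#' Two unit conventions are supported.  In `mode = "concentration"` the
#' state variables are dimensionless concentrations and fluctuations
#' scale as `omega^-1/2`.  In `mode = "absolute"` the state variables are
#' absolute counts and `K`, `b1`, `m3` are understood as the count-scale
#' (system-size folded) values `K*omega`, `b1*omega`, `m3*omega`; `omega`
#' is then fixed at 1.
#'
#' @param alpha maximal tumour-cell proliferation rate (day^-1).
#' @param delta_N maximal tumour-cell death rate (day^-1).
#' @param K characteristic avascular tumour size (cells in absolute
#'   mode, concentration otherwise).
#' @param b1 maximal nutrient supply through the vasculature (same
#'   units as `K`).
#' @param c1 switching value of `E^n` for nutrient shortage
#'   (dimensionless).
#' @param a2 maximal VEGF production rate (proteins cell^-1 day^-1).
#' @param c2 switching value of `E` for VEGF production (dimensionless).
#' @param delta_P VEGF degradation rate (day^-1).
#' @param b3 maximal vessel-cell growth rate (day^-1).
#' @param a3 maximal vessel-cell death rate (day^-1).
#' @param m3 characteristic VEGF level for vessel turnover (proteins in
#'   absolute mode, concentration otherwise).
#' @param n,n1,n2,n3,n4 Hill exponents (positive reals).
#' @param omega system size relating concentrations to counts (> 0);
#'   forced to 1 in absolute mode.
#' @param mode `"concentration"` or `"absolute"`.
#' @return An object of class `ak_params` (a named list).
#' @seealso [fixture_params()] for the packaged parameterisations,
#'   [params_to_absolute()] for the unit rescaling.
#' @export
kinetic_params <- function(alpha, delta_N, K, b1, c1, a2, c2, delta_P,
                           b3, a3, m3,
                           n = 2, n1 = 2, n2 = 2, n3 = 2, n4 = 2,
                           omega = 1,
                           mode = c("concentration", "absolute")) {
  mode <- match.arg(mode)
  p <- list(alpha = alpha, delta_N = delta_N, K = K, b1 = b1, c1 = c1,
            a2 = a2, c2 = c2, delta_P = delta_P, b3 = b3, a3 = a3,
            m3 = m3, n = n, n1 = n1, n2 = n2, n3 = n3, n4 = n4,
            omega = omega, mode = mode)
  if (mode == "absolute") p$omega <- 1
  validate_params(p)
  class(p) <- "ak_params"
  p
}

validate_params <- function(p) {
  rate_fields <- c("alpha", "delta_N", "K", "b1", "c1", "a2", "c2",
                   "delta_P", "b3", "a3", "m3")
  exp_fields <- c("n", "n1", "n2", "n3", "n4")
  for (f in c(rate_fields, exp_fields, "omega")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", f, "' must be a single finite positive number",
           call. = FALSE)
  }
  if (!p$mode %in% c("concentration", "absolute"))
    stop("mode must be 'concentration' or 'absolute'", call. = FALSE)
  invisible(p)
}

#' @export
print.ak_params <- function(x, ...) {
  cat("<ak_params> mode =", x$mode, " omega =", x$omega, "\n")
  flds <- setdiff(names(x), c("mode", "omega"))
  vals <- vapply(flds, function(f) format(x[[f]], digits = 6), "")
  cat(paste0("  ", format(flds, width = 8), " = ", vals), sep = "\n")
  invisible(x)
}

#' Rescale a concentration-mode parameter set to absolute numbers
#'
#' Folds the system size into the three scale parameters
#' (`K -> K*omega`, `b1 -> b1*omega`, `m3 -> m3*omega`) so that the
#' dynamics can be written directly for counts, after which `omega` is
#' treated as 1.
#'
#' @param params an `ak_params` object in concentration mode.
#' @param omega system size to fold in; defaults to `params$omega`.
#' @return An `ak_params` object in absolute mode.
#' @export
params_to_absolute <- function(params, omega = params$omega) {
  stopifnot(inherits(params, "ak_params"))
  if (params$mode == "absolute") return(params)
  q <- unclass(params)
  q$K <- q$K * omega
  q$b1 <- q$b1 * omega
  q$m3 <- q$m3 * omega
  q$omega <- 1
  q$mode <- "absolute"
  class(q) <- "ak_params"
  q
}

#' Packaged parameter fixtures
#'
#' `fixture_params("llc_table3")` returns the parameter set estimated
#' for the Lewis lung carcinoma (absolute-number mode): alpha = 0.675,
#' delta_N = 3.58e-8, delta_P = 8.91, a2 = 4.78e4, c2 = 2.38e-10,
#' b1 = 4.48e9 cells, c1 = 3.32e3, a3 = 2.3, b3 = 11.5, m3 = 221
#' proteins, all Hill exponents 2, and K chosen so that the avascular
#' capacity K*gamma equals 7.86e7 cells.
#'
#' `fixture_params("benchmark_fig4")` returns the bistable benchmark
#' set (concentration mode): alpha = 1.0, delta_N = 1.1, delta_P = 0.34,
#' K = 1.0, b1 = 2.3, c1 = 1.5, a2 = 0.4, c2 = 1.0, a3 = 1.0,
#' m3 = 1.02, b3 = 1.0, n = 2, n1 = 1, n2 = 2, n3 = n4 = 2.
#'
#' @param name one of `"llc_table3"`, `"benchmark_fig4"`.
#' @param omega system size for the benchmark set (ignored for the LLC
#'   set, which is already in absolute numbers).
#' @return An `ak_params` object.
#' @export
fixture_params <- function(name = c("llc_table3", "benchmark_fig4"),
                           omega = 1) {
  name <- match.arg(name)
  if (name == "llc_table3") {
    gamma <- sqrt(0.675 / 3.58e-8)        # closed form, n1 = n2
    kinetic_params(alpha = 0.675, delta_N = 3.58e-8,
                   K = 7.86e7 / gamma, b1 = 4.48e9, c1 = 3.32e3,
                   a2 = 4.78e4, c2 = 2.38e-10, delta_P = 8.91,
                   b3 = 11.5, a3 = 2.3, m3 = 221,
                   n = 2, n1 = 2, n2 = 2, n3 = 2, n4 = 2,
                   mode = "absolute")
  } else {
    kinetic_params(alpha = 1.0, delta_N = 1.1, K = 1.0, b1 = 2.3,
                   c1 = 1.5, a2 = 0.4, c2 = 1.0, delta_P = 0.34,
                   b3 = 1.0, a3 = 1.0, m3 = 1.02,
                   n = 2, n1 = 1, n2 = 2, n3 = 2, n4 = 2,
                   omega = omega, mode = "concentration")
  }
}

#' Read or write a parameter set as flat JSON or YAML
#'
#' The on-disk dialect is a flat mapping with exactly the model's
#' symbol names (`alpha`, `delta_N`, `K`, `b1`, `c1`, `n`, `n1`, `n2`,
#' `a2`, `c2`, `delta_P`, `b3`, `a3`, `m3`, `n3`, `n4`, `omega`,
#' `mode`).  Format is chosen from the file extension (`.json`, `.yaml`
#' or `.yml`).
#'
#' @param path file path.
#' @param params an `ak_params` object (for writing).
#' @return `read_params()` returns an `ak_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported parameter file extension: ", ext, call. = FALSE))
  needed <- c("alpha", "delta_N", "K", "b1", "c1", "a2", "c2",
              "delta_P", "b3", "a3", "m3", "n", "n1", "n2", "n3", "n4")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("parameter file misses fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  do.call(kinetic_params, c(raw[needed],
                            list(omega = if (is.null(raw$omega)) 1 else raw$omega,
                                 mode = if (is.null(raw$mode)) "concentration" else raw$mode)))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "ak_params"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stop("unsupported parameter file extension: ", ext, call. = FALSE))
  invisible(path)
}

#' System state (N, P, V) at a time point
#'
#' A valid state has non-negative tumour cells `N`, VEGF proteins `P`
#' and vessel cells `V`.  The effective vessel density `E = V/N`
#' (vessel cells available per tumour cell, a proxy for per-cell
#' nutrient supply) is only defined for `N > 0`; [state_E()] errors on
#' `N = 0` rather than returning a number.
#'
#' @param N,P,V species values (counts or concentrations, >= 0).
#' @param t time in days.
#' @return A named numeric vector of class `ak_state`.
#' @export
system_state <- function(N, P, V, t = 0) {
  s <- c(t = t, N = N, P = P, V = V)
  if (any(!is.finite(s))) stop("state must be finite", call. = FALSE)
  if (any(s[c("N", "P", "V")] < 0))
    stop("species values must be non-negative", call. = FALSE)
  class(s) <- "ak_state"
  s
}

#' @rdname system_state
#' @param state an `ak_state` or named vector with entries N and V.
#' @export
state_E <- function(state) {
  N <- unname(state[["N"]])
  if (N <= 0) stop("E = V/N is undefined at N = 0", call. = FALSE)
  unname(state[["V"]]) / N
}
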