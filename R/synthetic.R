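#' Configuration for the pseudo-experimental growth-data generator
#'
#' Describes how a tumour-growth dataset is synthesised: the source
#' parameter set and initial state, the sampling schedule, the noise
#' model, and the output kind.  The defaults emulate a Lewis-lung
#' volume-growth experiment: implantation of `8.29e8` cells followed
#' by 15 measurements between days 7 and 35 with 10% multiplicative
#' lognormal noise.
#'
#' @param params source [kinetic_params()] (default the packaged LLC
#'   set).
#' @param initial named `(N, P, V)` start state.
#' @param times sampling days (strictly increasing).
#' @param t0 time of `initial`.
#' @param noise `"none"` or `"lognormal"` (mean-one multiplicative).
#' @param cv coefficient of variation of the noise (>= 0).
#' @param seed integer seed.
#' @param kind `"cells"` or `"volume"` (mm^3, converted with
#'   [cells_to_volume()]).
#' @return A list of class `ak_generator_config`.
#' @export
generator_config <- function(params = fixture_params("llc_table3"),
                             initial = c(N = 8.29e8, P = 10, V = 1),
                             times = seq(7, 35, length.out = 15),
                             t0 = 0,
                             noise = c("lognormal", "none"),
                             cv = 0.1, seed = 1L,
                             kind = c("cells", "volume")) {
  noise <- match.arg(noise); kind <- match.arg(kind)
  stopifnot(inherits(params, "ak_params"), cv >= 0,
            !is.unsorted(times, strictly = TRUE))
  structure(list(params = params, initial = as_y0(initial),
                 times = times, t0 = t0, noise = noise, cv = cv,
                 seed = seed, kind = kind),
            class = "ak_generator_config")
}

#' Generate a pseudo-experimental tumour-growth dataset
#'
#' Integrates the deterministic dynamics from the configured initial
#' state, samples the tumour-cell count at the configured times,
#' optionally converts to volume, and applies mean-one multiplicative
#' lognormal noise with the configured coefficient of variation
#' (volumes are positive and measurement error scales with size).
#' The generator truth (parameters, initial state, start time, noise
#' settings) is recorded in the dataset's attributes.
#'
#' @param config an [generator_config()].
#' @return An object of class `ak_growth`: data frame `t, value` with
#'   attributes `kind`, `params`, `initial`, `t0`, `noise`, `cv`,
#'   `seed`.
#' @export
generate_growth_data <- function(config) {
  stopifnot(inherits(config, "ak_generator_config"))
  tr <- integrate_ode(config$params,
                      c(N = config$initial[1], P = config$initial[2],
                        V = config$initial[3]),
                      config$times, t0 = config$t0)
  value <- tr$N
  if (config$kind == "volume") value <- cells_to_volume(value)
  if (config$noise == "lognormal" && config$cv > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(config$seed)
    s2 <- log(1 + config$cv^2)
    value <- value * stats::rlnorm(length(value),
                                   meanlog = -s2 / 2, sdlog = sqrt(s2))
  }
  growth_dataset(config$times, value, kind = config$kind,
                 params = config$params, initial = config$initial,
                 t0 = config$t0, noise = config$noise, cv = config$cv,
                 seed = config$seed)
}

growth_dataset <- function(t, value, kind, params = NULL,
                           initial = NULL, t0 = NULL, noise = NULL,
                           cv = NULL, seed = NULL) {
  if (is.unsorted(t, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(value <= 0))
    stop("measurements must be positive", call. = FALSE)
  structure(data.frame(t = t, value = value),
            class = c("ak_growth", "data.frame"),
            kind = kind, params = params,
            initial = if (is.null(initial)) NULL else
              c(N = unname(initial[1]), P = unname(initial[2]),
                V = unname(initial[3])),
            t0 = t0, noise = noise, cv = cv, seed = seed)
}

#' Named simulation fixtures (parameters plus initial condition)
#'
#' `"llc_table3"`: the fitted Lewis-lung parameter set with its
#' implantation initial condition `(8.29e8 cells, 10 proteins,
#' 1 vessel cell)`.  `"benchmark_fig4"`: the bistable benchmark set
#' with initial condition `(1.5, 0.9, 3.0)`.  `"benchmark_c3_ic"`:
#' the benchmark set started at `(2.2, 1.0, 3.5)`, close to its
#' largest stable vascularised state.
#'
#' @param name fixture name.
#' @param omega system size for the benchmark fixtures.
#' @return List with `params` ([kinetic_params()]) and `initial`
#'   (named vector, in the parameters' native units).
#' @export
generate_fixture <- function(name, omega = 1) {
  known <- c("llc_table3", "benchmark_fig4", "benchmark_c3_ic")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  switch(name,
    llc_table3 = list(params = fixture_params("llc_table3"),
                      initial = c(N = 8.29e8, P = 10, V = 1)),
    benchmark_fig4 = list(params = fixture_params("benchmark_fig4",
                                                  omega = omega),
                          initial = c(N = 1.5, P = 0.9, V = 3.0)),
    benchmark_c3_ic = list(params = fixture_params("benchmark_fig4",
                                                   omega = omega),
                           initial = c(N = 2.2, P = 1.0, V = 3.5)))
}

#' Read or write a growth dataset as CSV
#'
#' Dialect: header `t_days,cells` or `t_days,volume_mm3`, one row per
#' measurement.
#'
#' @param path CSV path.
#' @param data an `ak_growth` dataset (for writing).
#' @return `read_growth_csv()` returns an `ak_growth`;
#'   `write_growth_csv()` returns `path` invisibly.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"t_days" %in% names(df))
    stop("expected a 't_days' column", call. = FALSE)
  kind <- if ("cells" %in% names(df)) "cells"
  else if ("volume_mm3" %in% names(df)) "volume"
  else stop("expected a 'cells' or 'volume_mm3' column", call. = FALSE)
  growth_dataset(df$t_days,
                 if (kind == "cells") df$cells else df$volume_mm3,
                 kind = kind)
}

#' @rdname read_growth_csv
#' @export
write_growth_csv <- function(data, path) {
  stopifnot(inherits(data, "ak_growth"))
  df <- data.frame(t_days = data$t)
  if (attr(data, "kind") == "cells") df$cells <- data$value
  else df$volume_mm3 <- data$value
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
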