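# Shared test utilities: random-but-reproducible parameter sets and
# states for property-style checks.

random_params <- function(seed) {
  set.seed(seed)
  r <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  kinetic_params(alpha = r(0.1, 10), delta_N = r(0.1, 10),
                 K = r(0.1, 100), b1 = r(0.1, 100), c1 = r(0.1, 10),
                 a2 = r(0.1, 10), c2 = r(0.01, 10),
                 delta_P = r(0.1, 10), b3 = r(0.1, 10),
                 a3 = r(0.1, 10), m3 = r(0.1, 10),
                 n = stats::runif(1, 1, 4), n1 = stats::runif(1, 1, 4),
                 n2 = stats::runif(1, 1, 4), n3 = stats::runif(1, 1, 4),
                 n4 = stats::runif(1, 1, 4),
                 mode = "concentration")
}

random_state <- function(seed, scale = 10) {
  set.seed(seed)
  c(N = stats::runif(1, 1e-3, scale), P = stats::runif(1, 0, scale),
    V = stats::runif(1, 0, scale))
}

llc <- generate_fixture("llc_table3")
bench <- generate_fixture("benchmark_fig4")
bench_c3 <- generate_fixture("benchmark_c3_ic")

with_params <- function(params, ...) {
  q <- unclass(params)
  mods <- list(...)
  q[names(mods)] <- mods
  class(q) <- "ak_params"
  q
}
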