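#!/usr/bin/env Rscript
# Intrinsic fluctuations of the Lewis-lung tumour: the first-week
# survival window, the analytic noise-intensity profile, and the
# system-size behaviour of the benchmark set.  Writes fraction and
# intensity tables to results/.

suppressPackageStartupMessages(library(angiokin))
dir.create("results", showWarnings = FALSE)
seed <- 1L

fx <- generate_fixture("llc_table3")

cat("== Chemical-Langevin ensemble, n = 2000, dt = 1e-3 day ==\n")
ens <- run_ensemble(fx$params, fx$initial, t_end = 50, n = 2000,
                    engine = "cle", base_seed = seed,
                    t_grid = c(1:10, seq(15, 50, by = 5)), dt = 1e-3,
                    keep_states = FALSE)
write_ensemble_csv(ens, "results/extinction_fractions_llc.csv")
lost <- absorbed_fraction(ens)
cat(sprintf("tumours lost (absorbed into the non-growing basin):\n"))
cat(sprintf("  day 7:  %.2f%%   day 50: %.2f%%\n",
            100 * absorbed_fraction(ens, 7),
            100 * absorbed_fraction(ens, 50)))
cat("Loss is decided in the first days, while the nascent vessel\n")
cat("population is of order one; survivors grow essentially\n")
cat("deterministically.  With the fitted (tiny) tumour-cell death\n")
cat("rate, loss operates through vascular collapse: the extinct-at-A\n")
cat(sprintf("fraction proper is %.2f%%.\n",
            100 * utils::tail(ens$extinct_fraction, 1)))

cat("\n== Analytic relative noise intensity along the deterministic path ==\n")
tr <- integrate_ode(fx$params, fx$initial, seq(0.25, 7, by = 0.05),
                    t0 = 0)
ni <- noise_intensity(fx$params, tr)
utils::write.csv(ni, "results/noise_intensity_llc.csv",
                 row.names = FALSE, quote = FALSE)
cat(sprintf("tumour-cell intensity peaks at day %.2f (surge window days 2-4),\n",
            ni$t[which.max(ni$N)]))
cat("the aftermath of the fast vascularisation raising the effective\n")
cat("nutrient supply f1(E).\n")

cat("\n== Benchmark set: system size and engine agreement ==\n")
for (om in c(10, 100, 1000)) {
  p <- fixture_params("benchmark_fig4", omega = om)
  ic <- generate_fixture("benchmark_c3_ic")$initial
  e_ssa <- run_ensemble(p, round(ic * om), t_end = 10, n = 200,
                        engine = "ssa", base_seed = seed, t_grid = c(10))
  e_cle <- run_ensemble(p, ic, t_end = 10, n = 200, engine = "cle",
                        base_seed = seed, t_grid = c(10), dt = 1e-3)
  cat(sprintf("omega %4d: mean N* at t=10  ssa %.3f  cle %.3f\n",
              om, mean(e_ssa$states[, 1, "N"]) / om,
              mean(e_cle$states[, 1, "N"])))
}
cat("Fluctuations shrink as omega^-1/2; at omega ~ 10 the Langevin\n")
cat("approximation overestimates switching relative to the exact\n")
cat("simulation, as expected of a diffusion approximation.\n")
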