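#!/usr/bin/env Rscript
# Tumour morphologies of the fitted Lewis-lung model, untreated and
# under strong VEGF suppression.  Writes JSON reports to results/.

suppressPackageStartupMessages(library(angiokin))
dir.create("results", showWarnings = FALSE)

fx <- generate_fixture("llc_table3")

cat("== Untreated Lewis lung carcinoma (delta_P = 8.91/day) ==\n")
ss <- enumerate_states(fx$params)
print(ss)
write_steady_states_json(ss, "results/steady_states_llc.json")
gamma <- solve_gamma(fx$params)
cat(sprintf("gamma = %.4g; Ptilde = %.4g proteins (close to 100)\n",
            gamma, solve_Ptilde(fx$params)))
cat("The only stable state is the large vascularised tumour C;\n")
cat("A (extinct) and B (avascular) are unstable, so natural growth\n")
cat("runs to the vascular morphology.\n\n")

cat("== Strong VEGF suppression (delta_P = 2e4/day, bevacizumab-like) ==\n")
p_sup <- fx$params; p_sup$delta_P <- 2e4; class(p_sup) <- "ak_params"
ss_sup <- enumerate_states(p_sup)
print(ss_sup)
write_steady_states_json(ss_sup, "results/steady_states_llc_suppressed.json")
dormant <- Filter(function(s) s$label == "C", ss_sup$states)[[1]]
cat(sprintf("Dormant tumour: N = %.3g cells (avascular capacity K*gamma = %.3g),\n",
            dormant$N, fx$params$K * gamma))
cat(sprintf("E = %.2e (vs ~2.5e5 untreated): the vasculature is effectively gone.\n",
            dormant$E))

cat("\n== Benchmark bistable set (three vascular morphologies) ==\n")
bss <- enumerate_states(fixture_params("benchmark_fig4"))
print(bss)
write_steady_states_json(bss, "results/steady_states_benchmark.json")
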