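#!/usr/bin/env Rscript
# Thermal-history and DSC analysis: cooling/warming rates vs CCR/CWR, the
# controlled-rate-freezer program, and ice fractions from thermograms.

library(nanowarm)
dir.create("results", showWarnings = FALSE)
seed <- 1

cat("== Cooling and nanowarming thermal histories ==\n")
for (s in c("cooling", "nanowarming")) {
  res <- run_scenario(s, seed = seed, out_dir = "results")
  f <- res$results$fit; chk <- res$results$check
  cat(sprintf("%-12s mean rate %6.1f C/min vs critical %2g C/min -> %s (margin %.2f)\n",
              s, f$magnitude, res$params$critical,
              if (chk$pass) "PASS" else "FAIL", chk$margin))
}

prog <- vitrification_program()
cat(sprintf("\nFreezer program spans %.2f min; setpoint at t = 20 min is %g C (annealing).\n",
            program_duration(prog), freezer_setpoints(prog, 20)))
tt <- seq(0, program_duration(prog), by = 0.25)
write.csv(data.frame(time_min = tt, setpoint_C = freezer_setpoints(prog, tt)),
          "results/thermal_freezer_program.csv", row.names = FALSE)

cat("\n== DSC ice fractions and critical rate ==\n")
dsc <- run_scenario("dsc", seed = seed, out_dir = "results")
print(dsc$results$points)
cat(sprintf("Log-linear interpolation puts the critical rate at %.2f C/min (ice fraction threshold %g%%).\n",
            dsc$results$critical$rate, dsc$results$critical$threshold))
cat("Wrote results/cooling_*.csv, results/nanowarming_*.csv, results/dsc_*.csv, results/thermal_freezer_program.csv\n")
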