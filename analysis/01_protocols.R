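#!/usr/bin/env Rscript
# CPA loading/unloading protocol construction and arithmetic.
#
# Builds the VMP loading and unloading schedules from their stage parameters,
# verifies the stage arithmetic (155 and 165 min totals, 120-min unloading
# ramp), evaluates the concentration timelines, and applies the nanoparticle
# flow-rate QC rule to an example flow pair.

library(nanowarm)
dir.create("results", showWarnings = FALSE)

loading <- vmp_loading_protocol()
unloading <- vmp_unloading_protocol()

cat("== CPA perfusion protocols ==\n")
print(loading)
print(unloading)
cat(sprintf("\nLoading takes %g min; unloading %g min.\n",
            total_duration(loading), total_duration(unloading)))
cat(sprintf("Unloading VMP ramp spans %g min at -35 mM/min; mannitol ramps out at %g mM/min.\n",
            ramp_duration(4200, 0, -35), unloading$segments[[2]]$adjunct$rate))

grid_l <- concentration_at(loading, seq(0, total_duration(loading), by = 1))
grid_u <- concentration_at(unloading, seq(0, total_duration(unloading), by = 1))
write.csv(grid_l, "results/protocol_loading_profile.csv", row.names = FALSE)
write.csv(grid_u, "results/protocol_unloading_profile.csv", row.names = FALSE)

qc <- flow_qc(loading_flow = 1.2, unloading_flow = 0.8)
cat(sprintf("\nIONP flow QC example: unloading/loading ratio %.2f -> %s (rule: > %.2f).\n",
            qc$ratio, if (qc$pass) "keep" else "exclude", qc$threshold))

write.csv(data.frame(protocol = c("loading", "unloading"),
                     total_min = c(total_duration(loading),
                                   total_duration(unloading)),
                     n_segments = c(length(loading$segments),
                                    length(unloading$segments))),
          "results/protocol_durations.csv", row.names = FALSE)
cat("Wrote results/protocol_*.csv\n")
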