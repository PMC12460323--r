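#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds the 48-unit (6 x 8 lattice) x 30-year panel with nonstationary
# coefficient surfaces — the stand-in for a state-level incidence panel —
# and writes the panel CSV, the GAL contiguity weights, and the ground
# truth needed by the later stages.

suppressPackageStartupMessages(library(spatioepi))

out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_nonstationary_panel(nrows = 6, ncols = 8, years = 30,
                                    noise_sd = 0.5, seed = 2024)
write_panel(sim$panel, file.path(out_dir, "panel.csv"))
write_gal(sim$weights, file.path(out_dir, "weights.gal"))

truth <- data.frame(unit = sim$panel$unit, year = sim$panel$year,
                    sim$truth$beta)
write.csv(truth, file.path(out_dir, "truth_beta.csv"), row.names = FALSE)

message(sprintf("wrote %d records over %d units x %d years to %s",
                nrow(sim$panel), length(unique(sim$panel$unit)),
                length(unique(sim$panel$year)), out_dir))
message("outcome summary:")
print(summary(sim$panel$outcome))
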