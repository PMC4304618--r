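#!/usr/bin/env Rscript
# Generate the datasets every later step consumes:
#  - the noiseless reference plate set (all sole sugars, all 15 pairs,
#    external-cAMP titrations, the CRP-site-mutant rhaB variant)
#  - a 20-replicate-day noisy version of the sole-sugar conditions, for
#    the day-to-day error calibration
#  - the five sub-saturating arabinose dynamics mixtures
suppressPackageStartupMessages(library(sugarhier))

out <- "results"
dir.create(out, showWarnings = FALSE)
ct <- default_constants()

message("reference conditions (noiseless) ...")
ref <- make_dataset(reference_scenarios(ct), ct, no_noise())
write_timeseries(ref, file.path(out, "timeseries_reference.csv"))
write_platemap(ref, file.path(out, "platemap_reference.json"), ct)
message("  ", nrow(ref$map), " wells, ",
        length(unique(ref$map$condition)), " conditions")

message("replicate-day conditions (default noise, 20 days, seed 1) ...")
scen20 <- lapply(ct$sugars$name, function(s) {
  scenario_sole(s, ct, include_mutant = FALSE, n_replicate_days = 20)
})
names(scen20) <- paste0("sole_", ct$sugars$name)
days <- make_dataset(scen20, ct, noise_model(seed = 1))
write_timeseries(days, file.path(out, "timeseries_replicate_days.csv"))

message("dynamics mixtures (0.005% arabinose + saturating partner) ...")
dyn <- make_dataset(dynamics_scenarios(ct), ct, no_noise())
write_timeseries(dyn, file.path(out, "timeseries_dynamics.csv"))

message("done; time series written under ", out, "/")
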