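#!/usr/bin/env Rscript
# Classify the activation dynamics of the five sub-saturating arabinose
# mixtures: is the partner system expressed together with araB
# (simultaneous) or only after the arabinose phase ends (sequential)?
suppressPackageStartupMessages(library(sugarhier))

out <- "results"
ct <- default_constants()
dyn <- read_timeseries(file.path(out, "timeseries_dynamics.csv"), ct)
scen <- dynamics_scenarios(ct)
p <- ct$promoters

partners <- setdiff(ct$sugars$name[order(ct$sugars$rank)], "arabinose")
res <- lapply(partners, function(s) {
  cls <- condition_dynamics(
    dyn, condition_id(scen[[paste0("dyn_ara_", s)]]),
    "araB", p$name[p$cognate_sugar == s], ct
  )
  tibble::tibble(partner = s, second_reporter = p$name[p$cognate_sugar == s],
                 overlap = cls$overlap, classification = cls$classification)
})
res <- dplyr::bind_rows(res)
readr::write_tsv(res, file.path(out, "dynamics_classification.tsv"))

for (k in seq_len(nrow(res))) {
  message(sprintf("arabinose + %-9s overlap %.2f -> %s",
                  res$partner[k], res$overlap[k], res$classification[k]))
}
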