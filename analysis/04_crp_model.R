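#!/usr/bin/env Rscript
# Fit each promoter's linear CRP-cAMP input function (normalized promoter
# activity vs normalized CRP-reporter activity), predict the pairwise
# hierarchy by leave-one-out regression, and quantify the differential-
# activation picture: the CRP level each system needs for full activation
# and the slope gain of the CRP-site-mutant rhaB variant.
suppressPackageStartupMessages(library(sugarhier))

out <- "results"
ct <- default_constants()
summaries <- readr::read_tsv(file.path(out, "summaries_reference.tsv"),
                             show_col_types = FALSE)
ranking <- rank_sugars(summaries, ct)

dataset <- build_crp_dataset(summaries, ct)
readr::write_tsv(dataset, file.path(out, "crp_dataset.tsv"))

loo <- loo_predict(dataset, ranking, ct)
write_matrix_tsv(loo$predicted_matrix, file.path(out, "loo_predicted_matrix.tsv"))
readr::write_tsv(loo$predictions, file.path(out, "loo_predictions.tsv"))

fits <- dplyr::bind_rows(lapply(loo$fits, function(f) {
  tibble::tibble(promoter = f$promoter, slope = f$slope,
                 intercept = f$intercept, n_points = f$n_points,
                 crp_needed_for_max = crp_required_for_max(f))
}))
readr::write_tsv(fits, file.path(out, "input_function_fits.tsv"))

message(sprintf("leave-one-out R^2 = %.3f (Pearson r^2 = %.3f)",
                loo$r2, loo$r2_pearson))
req <- setNames(fits$crp_needed_for_max, fits$promoter)
message(sprintf("CRP needed for max, ribose vs lactose: %.2f-fold",
                req[["rbsD"]] / req[["lacZ"]]))
message(sprintf("mutant rhaB slope: %+.1f%% vs wild type",
                compare_variant_slopes(loo$fits[["rhaB"]],
                                       loo$fits[["rhaB_mut"]])))
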