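#!/usr/bin/env Rscript
# Rank the sugars by the growth rate they support alone and build the two
# matrices: the pairwise hierarchy matrix (each reporter in its cognate
# sugar paired with every other sugar, row-normalized to cognate alone)
# and the cross-activation matrix (each reporter on each sole sugar).
suppressPackageStartupMessages(library(sugarhier))

out <- "results"
ct <- default_constants()
summaries <- readr::read_tsv(file.path(out, "summaries_reference.tsv"),
                             show_col_types = FALSE)

ranking <- rank_sugars(summaries, ct)
message("hierarchy (fastest first): ", paste(ranking$sugars, collapse = " > "))

pm <- pair_matrix(summaries, ranking, ct)
cm <- cross_matrix(summaries, ranking, ct)
write_matrix_tsv(pm, file.path(out, "pair_matrix.tsv"))
write_matrix_tsv(cm, file.path(out, "cross_matrix.tsv"))

low <- pm[lower.tri(pm)]
message(sprintf("repressed entries span %.2f-%.2f of cognate activity",
                min(low), max(low)))
message(sprintf("dominance score: %.3f", dominance_score(pm)))
message(sprintf("median cross-activation: %.0f%%",
                100 * median(cm[row(cm) != col(cm)])))
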