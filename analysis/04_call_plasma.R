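#!/usr/bin/env Rscript
# Plasma positivity calling: per-assay background model (mean + 3 SD of
# non-target consensus MAFs), per-mutation detection at the 0.05%
# inclusive VAF threshold, and sample-level classification (positive when
# one or more panel mutations confirm).

suppressPackageStartupMessages(library(umimrd))

res <- run_cohort("results/cohort", out_dir = "results/monitoring")

calls <- res$mutation_calls
sc <- res$sample_calls
message(nrow(sc), " plasma samples called over ",
        length(unique(calls$mutation_id)), " verified panel mutations")
message("  positive samples: ", sum(sc$positive, na.rm = TRUE),
        "; negative: ", sum(!sc$positive, na.rm = TRUE),
        "; not evaluable: ", sum(is.na(sc$positive)))
det <- calls[!is.na(calls$detected) & calls$detected, ]
message("  detected mutation calls: ", nrow(det),
        " (VAF ", paste0(signif(100 * range(det$vaf), 2), collapse = "%-"),
        "%)")
message("tables written to results/monitoring/")
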