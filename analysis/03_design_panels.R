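#!/usr/bin/env Rscript
# Patient-specific panel design: score tumor variant candidates (VAF,
# COSMIC membership, location, predicted impact), select 2-8 per patient,
# and verify each selected mutation in the tumor by barcode consensus.
# Patients with no verified mutation are flagged ineligible, mirroring
# the study design.  (04_call_plasma.R consumes the verified panels via
# run_cohort; this script reports the panel/verification stage.)

suppressPackageStartupMessages(library(umimrd))

cohort_dir <- "results/cohort"
res <- run_cohort(cohort_dir)

panels <- dplyr::bind_rows(res$panels)
dir.create("results", showWarnings = FALSE)
write_tsv_report(panels, "results/panels.tsv")

n_ver <- sum(panels$verified, na.rm = TRUE)
message(nrow(panels), " panel mutations designed across ",
        length(res$panels), " patients; ", n_ver, " verified in tumor (",
        round_half_up(100 * n_ver / nrow(panels)), "%)")
message("ineligible (no verified mutations): ",
        paste(res$ineligible, collapse = ", "))
for (pid in names(res$panels)) {
  p <- res$panels[[pid]]
  message(sprintf("  %s: %d assays, tumor VAF %s", pid, nrow(p),
                  paste(sprintf("%.0f%%", 100 * p$tumor_vaf), collapse = "/")))
}
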