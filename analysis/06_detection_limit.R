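#!/usr/bin/env Rscript
# Detection-limit experiment: replicate plasma libraries at true VAF 0.1%
# and matched VAF-0 controls (25,000 molecules, ~30 reads/family,
# sequencing error 0.3%/base, polymerase error 1e-5/base/cycle), run
# through consensus and calling with default rules.  The method claims
# reliable detection at 0.1% VAF; the controls check specificity.

suppressPackageStartupMessages(library(umimrd))

seed <- 2025L
layout <- read_layout()
set.seed(seed)
ref <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
off <- 41L
alt <- setdiff(c("A", "C", "G", "T"), substr(ref, off, off))[1]

run_one <- function(rep_seed, vaf) {
  vtab <- if (vaf > 0)
    data.frame(offset = off, ref = substr(ref, off, off), alt = alt, vaf = vaf)
  cfg <- sim_config("DL", ref, vtab, n_molecules = 25000L,
                    reads_to_sample = 750000L, pcr_cycles = 10L,
                    polymerase_error_rate = 1e-5, sequencing_error_rate = 3e-3,
                    seed = rep_seed)
  tr <- simulate_molecules(cfg)
  tagged <- extract_barcodes(amplify_and_sequence(tr, cfg), layout, "DL")$tagged
  pu <- consensus_pileup(tagged, ref)
  bg <- estimate_background(pu, panel_offsets = off)
  pn <- tibble::tibble(assay_id = "DL", offset = off,
                       ref = substr(ref, off, off), alt = alt)
  cl <- call_mutations(pu, pn, bg)
  tibble::tibble(seed = rep_seed, true_vaf = vaf,
                 realized_vaf = if (vaf > 0) tr$variants$realized_vaf else 0,
                 est_vaf = cl$vaf,
                 informative = cl$informative_families,
                 background = bg$threshold,
                 positive = classify_sample(cl)$positive)
}

rows <- list()
for (s in 1:3) {
  rows[[length(rows) + 1L]] <- run_one(seed + s, 0.001)
  rows[[length(rows) + 1L]] <- run_one(seed + 10L + s, 0)
}
tab <- dplyr::bind_rows(rows)
dir.create("results", showWarnings = FALSE)
write_tsv_report(tab, "results/detection_limit.tsv", meta = list(seed = seed))
print(as.data.frame(tab))

stopifnot(all(tab$positive[tab$true_vaf > 0]),
          !any(tab$positive[tab$true_vaf == 0]))
message("0.1% VAF detected in all replicates; all VAF-0 controls negative")
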