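#!/usr/bin/env Rscript
# Generate the synthetic monitoring cohort: 8 patients, 2-8 barcoded
# amplicon assays each, tumor verification libraries, baseline and
# longitudinal plasma draws with scripted true VAFs.  Everything below
# results/cohort is simulator output with known ground truth.

suppressPackageStartupMessages(library(umimrd))

cohort_dir <- "results/cohort"
seed <- 20181215 %% 1e6

message("simulating cohort into ", cohort_dir, " (seed ", seed, ") ...")
t0 <- Sys.time()
simulate_cohort(cohort_dir, seed = seed)
message("done in ", format(round(Sys.time() - t0, 1)))

samples <- read_tsv_report(file.path(cohort_dir, "samples.tsv"))
assays <- read_tsv_report(file.path(cohort_dir, "assays.tsv"))
truth <- read_tsv_report(file.path(cohort_dir, "truth.tsv"))

message(nrow(samples), " libraries' worth of samples (",
        sum(samples$type == "tumor"), " tumor, ",
        sum(samples$type == "plasma"), " plasma); ",
        nrow(assays), " assays across ", length(unique(assays$patient_id)),
        " patients")
message("scripted positive mutation-samples: ", sum(truth$true_vaf > 0),
        " of ", nrow(truth))
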