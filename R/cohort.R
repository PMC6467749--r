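# Synthetic cohort generator.
#
# Emits a fully synthetic 8-patient cohort mirroring the structure of a
# tumor-informed ctDNA monitoring study: per-patient tumor variant calls,
# 2-8 barcoded amplicon assays, a tumor verification library, a baseline
# plasma draw just before treatment, and longitudinal post-treatment draws
# whose scripted true VAFs encode the canonical monitoring narratives
# (baseline-negative early-stage disease, failure to clear after surgery,
# a pre-recurrence rise, distant metastases without plasma signal, and one
# patient whose candidate mutations fail tumor verification).  All values
# are synthetic reconstructions, not patient data.

GENE_POOL <- c("TP53", "PIK3CA", "NOTCH1", "CDKN2A", "FAT1", "ATM", "CDK8",
               "ARID1B", "FANCA", "RASA1", "NSD1", "SMARCA4", "XRCC2",
               "BCL10", "CASP8", "HRAS", "KMT2D", "EGFR")

# Per-patient narrative scripts.  `baseline_present`: which panel mutations
# (by rank) shed detectably at baseline.  `plasma`: day -> "pos" samples
# carry the scripted positive VAF for `pos_muts`, 0 for the rest.
cohort_script <- function() {
  list(
    P01 = list(stage = "IVA", n_assays = 2L, baseline_present = 1:2,
               plasma = list(c(day = 21, pos = 0), c(day = 180, pos = 0),
                             c(day = 300, pos = 0), c(day = 397, pos = 1)),
               pos_muts = 1:2,
               events = c(adjuvant_therapy = 30, clinical_recurrence_local = 384,
                          last_followup = 420)),
    P02 = list(stage = "IVA", n_assays = 6L, baseline_present = 1:6,
               plasma = list(c(day = 21, pos = 1)),
               pos_muts = 2:3,
               events = c(clinical_recurrence_local = 43, last_followup = 60)),
    P03 = list(stage = "IVA", n_assays = 3L, baseline_present = 1:2,
               plasma = list(c(day = 21, pos = 0), c(day = 180, pos = 0),
                             c(day = 365, pos = 0)),
               pos_muts = integer(),
               events = c(last_followup = 540)),
    P04 = list(stage = "I", n_assays = 2L, baseline_present = integer(),
               plasma = list(c(day = 21, pos = 0), c(day = 180, pos = 0),
                             c(day = 365, pos = 1), c(day = 540, pos = 1)),
               pos_muts = 1:2,
               events = c(clinical_recurrence_local = 521, last_followup = 560)),
    P05 = list(stage = "IVA", n_assays = 3L, baseline_present = 1:2,
               plasma = list(c(day = 42, pos = 0), c(day = 180, pos = 0)),
               pos_muts = integer(),
               events = c(adjuvant_therapy = 30, clinical_recurrence_distant = 287,
                          last_followup = 300)),
    P06 = list(stage = "IVA", n_assays = 2L, baseline_present = 1:2,
               plasma = list(c(day = 21, pos = 0), c(day = 90, pos = 0)),
               pos_muts = integer(),
               events = c(adjuvant_therapy = 35, clinical_recurrence_distant = 208,
                          last_followup = 240)),
    P07 = list(stage = "IVB", n_assays = 2L, baseline_present = integer(),
               plasma = list(),
               pos_muts = integer(),
               events = c(last_followup = 180), unverified = TRUE),
    P08 = list(stage = "IVA", n_assays = 8L, baseline_present = 1:5,
               plasma = list(c(day = 21, pos = 0), c(day = 180, pos = 0)),
               pos_muts = integer(),
               events = c(adjuvant_therapy = 28, last_followup = 400))
  )
}

#' Generate a synthetic monitoring cohort on disk
#'
#' Writes a complete synthetic fixture cohort: candidate tumor variant
#' tables, assay definitions, clinical event tables, a sample manifest and
#' per-library FASTQ files (one per sample x assay) with known scripted
#' true VAFs, plus a ground-truth table.  Regeneration with the same seed
#' is byte-identical.  Depth parameters default to a deliberately scaled
#' demonstration cohort; see the package vignette for the rationale.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling the whole cohort.
#' @param n_molecules Founding molecules per library.
#' @param reads_per_family Mean reads per barcode family; the number of
#'   sampled reads is `n_molecules * reads_per_family`.
#' @param pcr_cycles,polymerase_error_rate,sequencing_error_rate Simulator
#'   error process parameters (see [sim_config()]).
#' @param layout A [read_layout()].
#' @return `dir`, invisibly.
#' @export
simulate_cohort <- function(dir, seed = 1L, n_molecules = 2000L,
                            reads_per_family = 15L, pcr_cycles = 8L,
                            polymerase_error_rate = 1e-5,
                            sequencing_error_rate = 3e-3,
                            layout = read_layout()) {
  dir.create(file.path(dir, "fastq"), recursive = TRUE, showWarnings = FALSE)
  script <- cohort_script()
  seed <- as.integer(seed)

  patients <- list(); variants <- list(); assays <- list()
  samples <- list(); events <- list(); truth_rows <- list()
  sim_jobs <- list()

  withr::with_seed(seed, {
    for (pid in names(script)) {
      sc <- script[[pid]]
      k <- sc$n_assays
      n_cand <- k + sample(2:4, 1L)
      genes <- sample(GENE_POOL, n_cand)
      cand <- tibble::tibble(
        patient_id = pid,
        gene = genes,
        chrom = paste0("chr", sample(1:22, n_cand, replace = TRUE)),
        pos = sample.int(2e8, n_cand),
        ref = sample(DNA_BASES, n_cand, replace = TRUE),
        alt = NA_character_,
        tumor_vaf = stats::runif(n_cand, 0.05, 0.30),
        in_cosmic = stats::runif(n_cand) < 0.6,
        location_class = sample(c("exonic", "intronic", "UTR", "splice",
                                  "intergenic"), n_cand, replace = TRUE,
                                prob = c(0.6, 0.15, 0.1, 0.1, 0.05)),
        impact_class = sample(c("high", "moderate", "low", "none"), n_cand,
                              replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
      )
      cand$alt <- vapply(cand$ref, function(r)
        sample(setdiff(DNA_BASES, r), 1L), "")
      variants[[pid]] <- cand
      patients[[pid]] <- tibble::tibble(patient_id = pid, stage = sc$stage,
                                        n_assays = k)

      sel <- select_panel(score_candidates(cand), k = k)
      # one assay per selected mutation; one deliberately long amplicon
      lens <- sample(60:76, k, replace = TRUE)
      if (pid == "P02") lens[[1L]] <- 95L
      asy <- tibble::tibble(
        patient_id = pid,
        assay_id = paste0(pid, "_", sel$gene),
        gene = sel$gene, chrom = sel$chrom,
        offset = pmin(pmax(as.integer(round(lens / 2)), 15L), lens - 15L),
        ref = sel$ref, alt = sel$alt, tumor_vaf = sel$tumor_vaf,
        insert = random_dna(k, 1L)  # placeholder, filled below
      )
      asy$insert <- vapply(seq_len(k), function(i) {
        s <- random_dna(1L, lens[[i]])
        substr(s, asy$offset[[i]], asy$offset[[i]]) <- asy$ref[[i]]
        s
      }, "")
      asy$start <- sel$pos - asy$offset + 1L
      asy$end <- asy$start + lens - 1L
      assays[[pid]] <- asy

      # scripted per-mutation baseline and recurrence shedding levels
      base_vaf <- stats::runif(k, 0.01, 0.03)
      base_vaf[setdiff(seq_len(k), sc$baseline_present)] <- 0
      rec_vaf <- stats::runif(k, 0.01, 0.025)

      ev <- tibble::tibble(patient_id = pid,
                           event = c("treatment", names(sc$events)),
                           day = as.integer(c(0, sc$events)))
      events[[pid]] <- ev

      add_sample <- function(sample_id, day, type, vafs) {
        samples[[length(samples) + 1L]] <<-
          tibble::tibble(sample_id = sample_id, patient_id = pid,
                         day = day, type = type)
        for (i in seq_len(k)) {
          sim_jobs[[length(sim_jobs) + 1L]] <<-
            list(sample_id = sample_id, assay = asy[i, ], vaf = vafs[[i]])
        }
      }
      tumor_vafs <- if (isTRUE(sc$unverified)) rep(0, k) else asy$tumor_vaf
      add_sample(paste0(pid, "_T"), NA_integer_, "tumor", tumor_vafs)
      add_sample(paste0(pid, "_B"), -1L, "plasma", base_vaf)
      for (ps in sc$plasma) {
        vafs <- rep(0, k)
        if (ps[["pos"]] == 1) vafs[sc$pos_muts] <- rec_vaf[sc$pos_muts]
        add_sample(sprintf("%s_D%03d", pid, ps[["day"]]),
                   as.integer(ps[["day"]]), "plasma", vafs)
      }
    }
  })

  # simulate each library with a seed derived from the cohort seed
  for (j in seq_along(sim_jobs)) {
    job <- sim_jobs[[j]]
    a <- job$assay
    vtab <- NULL
    if (job$vaf > 0)
      vtab <- tibble::tibble(offset = a$offset, ref = a$ref, alt = a$alt,
                             vaf = job$vaf)
    cfg <- sim_config(
      assay_id = a$assay_id, reference_insert = a$insert, variants = vtab,
      n_molecules = n_molecules,
      reads_to_sample = n_molecules * reads_per_family,
      barcode_length = layout$barcode_length, pcr_cycles = pcr_cycles,
      polymerase_error_rate = polymerase_error_rate,
      sequencing_error_rate = sequencing_error_rate,
      seed = (seed * 1009L + 2L * j) %% .Machine$integer.max
    )
    tr <- simulate_molecules(cfg)
    reads <- amplify_and_sequence(tr, cfg, layout)
    write_fastq(reads[c("read_id", "sequence")],
                file.path(dir, "fastq",
                          paste0(job$sample_id, "__", a$assay_id, ".fastq")))
    truth_rows[[j]] <- tibble::tibble(
      sample_id = job$sample_id, assay_id = a$assay_id, true_vaf = job$vaf,
      realized_vaf = if (nrow(tr$variants)) tr$variants$realized_vaf[[1L]] else 0,
      n_molecules = n_molecules
    )
  }

  meta <- list(seed = seed, n_molecules = n_molecules,
               reads_per_family = reads_per_family)
  write_tsv_report(dplyr::bind_rows(patients), file.path(dir, "patients.tsv"), meta)
  write_tsv_report(dplyr::bind_rows(variants), file.path(dir, "variants.tsv"), meta)
  write_tsv_report(dplyr::bind_rows(assays), file.path(dir, "assays.tsv"), meta)
  write_tsv_report(dplyr::bind_rows(samples), file.path(dir, "samples.tsv"), meta)
  write_tsv_report(dplyr::bind_rows(events), file.path(dir, "events.tsv"), meta)
  write_tsv_report(dplyr::bind_rows(truth_rows), file.path(dir, "truth.tsv"), meta)
  invisible(dir)
}
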