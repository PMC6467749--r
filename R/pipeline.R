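#' Run the full monitoring pipeline over a cohort directory
#'
#' Executes the per-patient flow end to end on a cohort laid out as by
#' [simulate_cohort()]: tumor variant calls are scored and the panel
#' selected, panel mutations are verified in the tumor by barcode
#' consensus, and each plasma library is consensus-called, screened
#' against its assay background model, and classified; per-patient
#' timelines and the cohort summary are derived from the resulting sample
#' calls.  Patients with no verified tumor mutation are flagged ineligible
#' and excluded from plasma monitoring.
#'
#' @param cohort_dir Directory containing `patients.tsv`, `variants.tsv`,
#'   `assays.tsv`, `samples.tsv`, `events.tsv` and `fastq/`.
#' @param out_dir Optional output directory; when given, panel, call and
#'   summary tables (TSV), timelines (JSON) and a run manifest are written.
#' @param rules A [consensus_rules()].
#' @param layout A [read_layout()].
#' @param weights A [panel_weights()].
#' @param vaf_threshold Plasma detection threshold (fraction, default 5e-4).
#' @param verification_threshold Tumor verification threshold (default 0.01).
#' @return A list: `panels`, `sample_calls`, `mutation_calls`, `timelines`
#'   (named list of [build_timeline()] objects), `summary`
#'   ([cohort_summary()] output), and `ineligible` (patient ids).
#' @export
run_cohort <- function(cohort_dir, out_dir = NULL,
                       rules = consensus_rules(), layout = read_layout(),
                       weights = panel_weights(), vaf_threshold = 5e-4,
                       verification_threshold = 0.01) {
  req <- file.path(cohort_dir,
                   c("patients.tsv", "variants.tsv", "assays.tsv",
                     "samples.tsv", "events.tsv"))
  missing <- req[!file.exists(req)]
  if (length(missing))
    stop("cohort input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  variants <- read_tsv_report(file.path(cohort_dir, "variants.tsv"))
  assays <- read_tsv_report(file.path(cohort_dir, "assays.tsv"))
  samples <- read_tsv_report(file.path(cohort_dir, "samples.tsv"))
  events <- read_tsv_report(file.path(cohort_dir, "events.tsv"))

  pileup_for <- function(sample_id, assay) {
    fq <- file.path(cohort_dir, "fastq",
                    paste0(sample_id, "__", assay$assay_id, ".fastq"))
    if (!file.exists(fq)) return(NULL)
    reads <- read_fastq(fq)
    tagged <- extract_barcodes(reads, layout, assay_id = assay$assay_id)$tagged
    consensus_pileup(tagged, assay$insert, rules)
  }

  panels <- list(); sample_calls <- list(); mutation_calls <- list()
  timelines <- list(); ineligible <- character(0)

  for (pid in unique(variants$patient_id)) {
    pa <- assays[assays$patient_id == pid, ]
    ranked <- score_candidates(variants[variants$patient_id == pid, ], weights)
    sel <- select_panel(ranked, k = nrow(pa))
    # attach the physical assay designed for each selected mutation;
    # selected mutations without a designed assay drop out of the panel
    m <- match(paste(sel$chrom, sel$gene), paste(pa$chrom, pa$gene))
    panel <- sel[!is.na(m), ]
    pm <- pa[m[!is.na(m)], ]
    panel$assay_id <- pm$assay_id
    panel$offset <- pm$offset
    panel$insert <- pm$insert
    panel <- classify_assay(dplyr::mutate(panel, start = pm$start, end = pm$end))

    tumor_sample <- samples$sample_id[samples$patient_id == pid &
                                        samples$type == "tumor"]
    tumor_pileups <- list()
    if (length(tumor_sample) == 1L) {
      for (i in seq_len(nrow(panel)))
        tumor_pileups[[panel$assay_id[[i]]]] <-
          pileup_for(tumor_sample, panel[i, ])
    }
    panel <- verify_in_tumor(panel, tumor_pileups, verification_threshold)
    panels[[pid]] <- panel
    if (!attr(panel, "eligible")) {
      ineligible <- c(ineligible, pid)
      next
    }
    vpanel <- panel[!is.na(panel$verified) & panel$verified, ]

    plasma <- samples[samples$patient_id == pid & samples$type == "plasma", ]
    for (s in seq_len(nrow(plasma))) {
      calls <- list()
      for (i in seq_len(nrow(vpanel))) {
        arow <- vpanel[i, ]
        pu <- pileup_for(plasma$sample_id[[s]], arow)
        if (is.null(pu)) next
        bg <- estimate_background(pu, panel_offsets = arow$offset)
        calls[[i]] <- call_mutations(
          pu, arow[c("assay_id", "gene", "offset", "ref", "alt")], bg,
          vaf_threshold)
      }
      calls <- dplyr::bind_rows(calls)
      if (!nrow(calls)) next
      calls$sample_id <- plasma$sample_id[[s]]
      calls$mutation_id <- calls$assay_id
      mutation_calls[[length(mutation_calls) + 1L]] <- calls
      sample_calls[[length(sample_calls) + 1L]] <-
        classify_sample(calls, plasma$sample_id[[s]], pid, plasma$day[[s]])
    }
  }

  sample_calls <- dplyr::bind_rows(sample_calls)
  mutation_calls <- dplyr::bind_rows(mutation_calls)

  for (pid in setdiff(unique(sample_calls$patient_id), ineligible)) {
    timelines[[pid]] <- build_timeline(
      sample_calls[sample_calls$patient_id == pid, ],
      events[events$patient_id == pid, ],
      mutation_calls)
  }
  summary <- if (length(timelines)) cohort_summary(timelines) else NULL

  res <- list(panels = panels, sample_calls = sample_calls,
              mutation_calls = mutation_calls, timelines = timelines,
              summary = summary, ineligible = ineligible)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- list(rules = unclass(rules), layout = unclass(layout),
                vaf_threshold = vaf_threshold,
                verification_threshold = verification_threshold)
    meta <- list(config_hash = rlang::hash(cfg))
    write_tsv_report(dplyr::bind_rows(panels), file.path(out_dir, "panels.tsv"),
                     meta)
    write_tsv_report(sample_calls, file.path(out_dir, "sample_calls.tsv"), meta)
    write_tsv_report(mutation_calls, file.path(out_dir, "mutation_calls.tsv"),
                     meta)
    if (!is.null(summary)) {
      write_tsv_report(summary$patients, file.path(out_dir, "patients_summary.tsv"),
                       meta)
      write_tsv_report(summary$summary, file.path(out_dir, "cohort_summary.tsv"),
                       meta)
    }
    jsonlite::write_json(
      lapply(timelines, function(tl)
        tl[c("patient_id", "baseline_day", "baseline_positive", "clearance",
             "molecular_recurrence_day", "clinical_recurrence_day",
             "lead_time_days")]),
      file.path(out_dir, "timelines.json"), auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(
      c(list(tool = paste0("umimrd ", utils::packageVersion("umimrd"))), cfg,
        list(config_hash = rlang::hash(cfg), ineligible = ineligible)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
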