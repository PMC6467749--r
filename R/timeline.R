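CLINICAL_EVENTS <- c("treatment", "adjuvant_therapy",
                     "clinical_recurrence_local",
                     "clinical_recurrence_distant", "last_followup")
RECURRENCE_EVENTS <- c("clinical_recurrence_local", "clinical_recurrence_distant")

#' Assemble a patient's monitoring timeline
#'
#' Combines ordered plasma sample calls with clinical events (days are
#' integers relative to definitive treatment at day 0; negative days are
#' pre-treatment) and derives:
#'
#' * `baseline_positive` — status of the latest pre-treatment sample
#'   (day <= 0), the draw taken just prior to resection;
#' * `clearance` — whether the first evaluable post-treatment sample is
#'   negative;
#' * `molecular_recurrence_day` — day of the first positive post-treatment
#'   sample, or `NA`;
#' * `clinical_recurrence_day` — day of the first clinical recurrence
#'   event (local or distant), or `NA`;
#' * `lead_time_days` — clinical minus molecular recurrence day: positive
#'   when molecular detection precedes clinical recurrence, negative when
#'   it follows.
#'
#' Samples that are not evaluable (positive = `NA`) are skipped when
#' determining clearance and molecular recurrence.  Input ordering is
#' irrelevant; samples are sorted internally.
#'
#' @param samples Tibble of per-sample calls for one patient (e.g. rows
#'   from [classify_sample()]): columns `sample_id`, `patient_id`, `day`,
#'   `positive`.
#' @param events Tibble of clinical events: columns `patient_id`, `event`
#'   (one of treatment, adjuvant_therapy, clinical_recurrence_local,
#'   clinical_recurrence_distant, last_followup), `day`.  Exactly one
#'   `treatment` event at day 0 is required.
#' @param mutation_calls Optional tibble of per-mutation calls across
#'   samples (columns `sample_id`, `mutation_id`, `detected`), used to
#'   count panel mutations detected at baseline.
#' @return An object of class `patient_timeline`.
#' @export
build_timeline <- function(samples, events, mutation_calls = NULL) {
  stopifnot(all(c("sample_id", "patient_id", "day", "positive") %in%
                  names(samples)),
            all(c("patient_id", "event", "day") %in% names(events)))
  if (!nrow(samples)) stop("at least one plasma sample is required", call. = FALSE)
  pid <- unique(c(samples$patient_id, events$patient_id))
  if (length(pid) != 1L)
    stop("samples and events must belong to a single patient", call. = FALSE)
  if (!all(events$event %in% CLINICAL_EVENTS))
    stop("unknown clinical event type", call. = FALSE)
  trt <- events$day[events$event == "treatment"]
  if (length(trt) != 1L || trt != 0L)
    stop("exactly one treatment event at day 0 is required", call. = FALSE)
  if (anyDuplicated(samples$day))
    stop("duplicate sample days for patient ", pid, call. = FALSE)

  samples <- samples[order(samples$day), ]
  samples$day <- as.integer(samples$day)

  pre <- samples[samples$day <= 0L, ]
  baseline_day <- if (nrow(pre)) pre$day[[nrow(pre)]] else NA_integer_
  baseline_positive <- if (nrow(pre)) pre$positive[[nrow(pre)]] else NA

  post <- samples[samples$day > 0L & !is.na(samples$positive), ]
  clearance <- if (nrow(post)) !post$positive[[1L]] else NA
  pos_days <- post$day[post$positive]
  molecular_recurrence_day <- if (length(pos_days)) min(pos_days) else NA_integer_

  rec_days <- events$day[events$event %in% RECURRENCE_EVENTS]
  clinical_recurrence_day <- if (length(rec_days)) as.integer(min(rec_days))
                             else NA_integer_

  lead <- if (!is.na(molecular_recurrence_day) && !is.na(clinical_recurrence_day))
    as.integer(clinical_recurrence_day - molecular_recurrence_day)
  else NA_integer_

  n_panel <- NA_integer_
  n_baseline_detected <- NA_integer_
  if (!is.null(mutation_calls) && !is.na(baseline_day)) {
    base_id <- pre$sample_id[[nrow(pre)]]
    mc <- mutation_calls[mutation_calls$sample_id == base_id, ]
    n_panel <- length(unique(mc$mutation_id))
    n_baseline_detected <- sum(mc$detected, na.rm = TRUE)
  }

  structure(
    list(patient_id = pid, samples = samples, events = events,
         baseline_day = baseline_day, baseline_positive = baseline_positive,
         clearance = clearance,
         molecular_recurrence_day = molecular_recurrence_day,
         clinical_recurrence_day = clinical_recurrence_day,
         lead_time_days = lead,
         n_panel_mutations = n_panel,
         n_baseline_detected = n_baseline_detected),
    class = "patient_timeline"
  )
}

#' Lead time between molecular and clinical recurrence
#'
#' Days from the first positive post-treatment plasma sample to the
#' clinical recurrence event.  Positive values mean ctDNA detection
#' preceded clinical recurrence; negative values mean it followed.  `NA`
#' when either day is missing.
#'
#' @param timeline A [build_timeline()] result.
#' @return Integer days or `NA`.
#' @export
lead_time <- function(timeline) {
  stopifnot(inherits(timeline, "patient_timeline"))
  timeline$lead_time_days
}

#' @export
print.patient_timeline <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else format(v)
  cat(sprintf("patient %s: %d samples (day %s..%s)\n", x$patient_id,
              nrow(x$samples), min(x$samples$day), max(x$samples$day)))
  cat(sprintf("  baseline (day %s): %s\n", fmt(x$baseline_day),
              if (is.na(x$baseline_positive)) "not evaluable"
              else if (x$baseline_positive) "ctDNA positive" else "ctDNA negative"))
  cat(sprintf("  clearance: %s | molecular recurrence day: %s | clinical: %s | lead: %s d\n",
              fmt(x$clearance), fmt(x$molecular_recurrence_day),
              fmt(x$clinical_recurrence_day), fmt(x$lead_time_days)))
  invisible(x)
}

#' Summarize a monitored cohort
#'
#' Counts and percentages over a list of patient timelines: baseline ctDNA
#' positivity, panel mutations detected at baseline, clinical and
#' molecular recurrence, and lead times.  Percentages are rounded half-up
#' to whole percent for display (e.g. 6/7 patients -> 86).
#'
#' @param timelines List of [build_timeline()] objects.
#' @return A list with `patients` (one row per patient), `summary` (one
#'   row) and `lead_times` (patients with both recurrence days).
#' @export
cohort_summary <- function(timelines) {
  stopifnot(length(timelines) >= 1L,
            all(vapply(timelines, inherits, TRUE, "patient_timeline")))
  patients <- dplyr::bind_rows(lapply(timelines, function(tl) {
    tibble::tibble(
      patient_id = tl$patient_id,
      baseline_positive = tl$baseline_positive,
      clearance = tl$clearance,
      molecular_recurrence_day = tl$molecular_recurrence_day,
      clinical_recurrence_day = tl$clinical_recurrence_day,
      lead_time_days = tl$lead_time_days,
      n_panel_mutations = tl$n_panel_mutations,
      n_baseline_detected = tl$n_baseline_detected
    )
  }))
  n <- nrow(patients)
  n_base_eval <- sum(!is.na(patients$baseline_positive))
  n_base_pos <- sum(patients$baseline_positive, na.rm = TRUE)
  n_mut <- sum(patients$n_panel_mutations, na.rm = TRUE)
  n_mut_base <- sum(patients$n_baseline_detected, na.rm = TRUE)
  n_clin <- sum(!is.na(patients$clinical_recurrence_day))
  n_mol <- sum(!is.na(patients$molecular_recurrence_day))
  lead <- patients[!is.na(patients$lead_time_days),
                   c("patient_id", "molecular_recurrence_day",
                     "clinical_recurrence_day", "lead_time_days")]
  summary <- tibble::tibble(
    n_patients = n,
    n_baseline_positive = n_base_pos,
    baseline_positive_pct = if (n_base_eval)
      round_half_up(100 * n_base_pos / n_base_eval) else NA_real_,
    n_panel_mutations = n_mut,
    n_baseline_detected = n_mut_base,
    baseline_mutation_pct = if (n_mut)
      round_half_up(100 * n_mut_base / n_mut) else NA_real_,
    n_clinical_recurrence = n_clin,
    n_molecular_recurrence = n_mol,
    n_molecular_before_clinical = sum(lead$lead_time_days > 0)
  )
  list(patients = patients, summary = summary, lead_times = lead)
}
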