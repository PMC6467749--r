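#!/usr/bin/env Rscript
# Longitudinal monitoring: per-patient timelines (baseline status,
# post-treatment clearance, molecular recurrence) and the cohort summary
# with lead times between molecular and clinical recurrence.

suppressPackageStartupMessages(library(umimrd))

res <- run_cohort("results/cohort", out_dir = "results/monitoring")
fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

for (pid in names(res$timelines)) {
  tl <- res$timelines[[pid]]
  print(tl)
  ggplot2::ggsave(file.path(fig_dir, paste0("timeline_", pid, ".png")),
                  plot_timeline(tl), width = 7, height = 2.5, dpi = 150)
}

cs <- res$summary
message("--- cohort summary ---")
message(sprintf("baseline ctDNA positive: %d/%d patients (%d%%)",
                cs$summary$n_baseline_positive, cs$summary$n_patients,
                cs$summary$baseline_positive_pct))
message(sprintf("panel mutations detected at baseline: %d/%d (%d%%)",
                cs$summary$n_baseline_detected, cs$summary$n_panel_mutations,
                cs$summary$baseline_mutation_pct))
message(sprintf("clinical recurrence: %d patients; molecular recurrence: %d; molecular first: %d",
                cs$summary$n_clinical_recurrence,
                cs$summary$n_molecular_recurrence,
                cs$summary$n_molecular_before_clinical))
if (nrow(cs$lead_times)) {
  message("lead times (days, positive = ctDNA first):")
  for (i in seq_len(nrow(cs$lead_times)))
    message(sprintf("  %s: %+d", cs$lead_times$patient_id[[i]],
                    cs$lead_times$lead_time_days[[i]]))
}
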