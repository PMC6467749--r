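mk_samples <- function(days, positive, pid = "HN") {
  tibble::tibble(sample_id = sprintf("%s_s%d", pid, seq_along(days)),
                 patient_id = pid, day = as.integer(days), positive = positive)
}
mk_events <- function(..., pid = "HN") {
  ev <- c(treatment = 0, ...)
  tibble::tibble(patient_id = pid, event = names(ev), day = as.integer(ev))
}

test_that("timelines derive baseline, clearance and recurrence correctly", {
  # baseline positive, all post-op negative, no recurrence: cleared
  tl <- build_timeline(mk_samples(c(-1, 21, 180), c(TRUE, FALSE, FALSE)),
                       mk_events(last_followup = 365))
  expect_true(tl$baseline_positive)
  expect_true(tl$clearance)
  expect_true(is.na(tl$molecular_recurrence_day))
  expect_true(is.na(lead_time(tl)))

  # failure to clear: positive 3 weeks post-op, clinical recurrence day 43
  tl2 <- build_timeline(mk_samples(c(-1, 21), c(TRUE, TRUE)),
                        mk_events(clinical_recurrence_local = 43))
  expect_false(tl2$clearance)
  expect_equal(tl2$molecular_recurrence_day, 21L)
  expect_equal(lead_time(tl2), 22L)   # detection preceded recurrence by 22 d

  # baseline-negative early-stage course: molecular recurrence at ~1 year
  # precedes clinical recurrence by 156 days despite negative baseline
  tl3 <- build_timeline(
    mk_samples(c(-1, 21, 180, 365, 540), c(FALSE, FALSE, FALSE, TRUE, TRUE)),
    mk_events(clinical_recurrence_local = 521, last_followup = 560))
  expect_false(tl3$baseline_positive)
  expect_equal(tl3$molecular_recurrence_day, 365L)
  expect_equal(lead_time(tl3), 156L)

  # molecular detection after clinical recurrence: negative lead time
  tl4 <- build_timeline(
    mk_samples(c(-1, 21, 300, 397), c(TRUE, FALSE, FALSE, TRUE)),
    mk_events(clinical_recurrence_local = 384, last_followup = 420))
  expect_equal(lead_time(tl4), -13L)

  # not-evaluable samples are skipped for clearance and recurrence
  tl5 <- build_timeline(mk_samples(c(-1, 21, 60), c(TRUE, NA, FALSE)),
                        mk_events(last_followup = 90))
  expect_true(tl5$clearance)
})

test_that("sample ordering is internal and bad inputs are rejected", {
  s <- mk_samples(c(180, -1, 21), c(FALSE, TRUE, TRUE))
  ev <- mk_events(clinical_recurrence_local = 43)
  tl_a <- build_timeline(s, ev)
  tl_b <- build_timeline(s[c(3, 1, 2), ], ev)
  expect_equal(tl_a[c("baseline_positive", "clearance",
                      "molecular_recurrence_day", "lead_time_days")],
               tl_b[c("baseline_positive", "clearance",
                      "molecular_recurrence_day", "lead_time_days")])

  expect_error(build_timeline(mk_samples(c(1, 1), c(TRUE, TRUE)), ev),
               "duplicate sample days")
  no_trt <- tibble::tibble(patient_id = "HN", event = "last_followup", day = 90L)
  expect_error(build_timeline(mk_samples(-1, TRUE), no_trt),
               "treatment event")
  expect_error(build_timeline(mk_samples(-1, TRUE),
                              mk_events(last_followup = 10, pid = "OTHER")),
               "single patient")
})

test_that("baseline mutation detection is counted from per-mutation calls", {
  s <- mk_samples(c(-1, 21), c(TRUE, FALSE))
  mc <- tibble::tibble(
    sample_id = rep(c("HN_s1", "HN_s2"), each = 3),
    mutation_id = rep(c("m1", "m2", "m3"), 2),
    detected = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  tl <- build_timeline(s, mk_events(last_followup = 60), mc)
  expect_equal(tl$n_panel_mutations, 3L)
  expect_equal(tl$n_baseline_detected, 2L)
})

test_that("cohort summary computes half-up rounded cohort fractions", {
  # 7 patients with verified mutations, 6 baseline positive -> 86%;
  # 22 panel mutations, 15 detected at baseline -> 68%
  n_mut <- c(2, 6, 3, 2, 3, 2, 4)         # 22 mutations
  det <- c(2, 6, 0, 0, 2, 2, 3)           # 15 detected at baseline
  base_pos <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  tls <- lapply(1:7, function(i) {
    pid <- paste0("HN0", i)
    s <- mk_samples(c(-1, 21), c(base_pos[i], FALSE), pid = pid)
    mc <- tibble::tibble(sample_id = rep(s$sample_id[1], n_mut[i]),
                         mutation_id = paste0("m", seq_len(n_mut[i])),
                         detected = seq_len(n_mut[i]) <= det[i])
    build_timeline(s, mk_events(last_followup = 400, pid = pid), mc)
  })
  cs <- cohort_summary(tls)
  expect_equal(cs$summary$n_patients, 7L)
  expect_equal(cs$summary$n_baseline_positive, 6)
  expect_equal(cs$summary$baseline_positive_pct, 86)   # 6/7 = 85.7 -> 86
  expect_equal(cs$summary$n_panel_mutations, 22)
  expect_equal(cs$summary$n_baseline_detected, 15)
  expect_equal(cs$summary$baseline_mutation_pct, 68)   # 15/22 = 68.2 -> 68
  expect_equal(nrow(cs$lead_times), 0L)                # no recurrences: no rows
  expect_equal(cs$summary$n_molecular_before_clinical, 0)
})

test_that("lead-time sign convention over a mixed-recurrence cohort", {
  t_pos <- build_timeline(mk_samples(c(-1, 21), c(TRUE, TRUE), pid = "A"),
                          mk_events(clinical_recurrence_local = 43, pid = "A"))
  t_neg <- build_timeline(mk_samples(c(-1, 397), c(TRUE, TRUE), pid = "B"),
                          mk_events(clinical_recurrence_local = 384, pid = "B"))
  cs <- cohort_summary(list(t_pos, t_neg))
  expect_equal(sort(cs$lead_times$lead_time_days), c(-13L, 22L))
  expect_equal(cs$summary$n_molecular_before_clinical, 1)
})
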