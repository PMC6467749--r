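#' Estimate assay background noise from non-panel positions
#'
#' The detection rule requires a mutation to stand above the assay's own
#' background noise.  Background is modelled from the consensus minor
#' allele frequencies at positions *not* targeted by any panel mutation:
#' the per-assay threshold is `max(mean + n_sd * SD, 0)` over the
#' informative non-panel MAFs, a standard position-noise model (alternatives
#' such as per-position maxima or matched-control subtraction can be
#' substituted upstream).  With fewer than `min_positions`
#' informative non-panel positions the model falls back to a threshold of
#' 0 with a warning.
#'
#' @param pileup A [consensus_pileup()].
#' @param panel_offsets Integer vector of panel-mutation positions within
#'   this assay's insert (excluded from the noise estimate).
#' @param n_sd Number of standard deviations above the mean (default 3).
#' @param min_positions Minimum informative non-panel positions required
#'   (default 5).
#' @return A one-row tibble of class `background_model`: `assay_id`,
#'   `n_positions`, `mean_maf`, `sd_maf`, `max_maf`, `threshold`, `method`.
#' @export
estimate_background <- function(pileup, panel_offsets = integer(),
                                n_sd = 3, min_positions = 5L) {
  stopifnot(inherits(pileup, "consensus_pileup"))
  x <- pileup$maf[!(pileup$pos %in% panel_offsets) &
                    pileup$informative_families > 0L & !is.na(pileup$maf)]
  if (length(x) < min_positions) {
    warning("fewer than ", min_positions,
            " informative non-panel positions; background threshold set to 0")
    out <- tibble::tibble(
      assay_id = pileup$assay_id[[1L]], n_positions = length(x),
      mean_maf = NA_real_, sd_maf = NA_real_, max_maf = NA_real_,
      threshold = 0, method = "fallback_zero")
  } else {
    out <- tibble::tibble(
      assay_id = pileup$assay_id[[1L]], n_positions = length(x),
      mean_maf = mean(x), sd_maf = stats::sd(x), max_maf = max(x),
      threshold = max(mean(x) + n_sd * stats::sd(x), 0),
      method = sprintf("mean_plus_%gsd", n_sd))
  }
  class(out) <- c("background_model", class(out))
  out
}

#' Call panel mutations in a plasma consensus pileup
#'
#' A panel mutation is detected when its consensus VAF is at or above
#' `vaf_threshold` (default 0.05%, inclusive) *and* strictly above the
#' assay's background threshold.  Positions with zero informative families
#' are not evaluable: `detected` is `NA`, distinguishing absence of
#' evidence from evidence of absence.
#'
#' @param pileup A [consensus_pileup()] for one assay of a plasma library.
#' @param panel Tibble of panel mutations for this assay, with columns
#'   `assay_id`, `offset`, `ref`, `alt` (plus any identifier columns,
#'   carried through).
#' @param background A `background_model` from [estimate_background()]
#'   (or `NULL` for a zero background).
#' @param vaf_threshold Minimum VAF fraction for detection
#'   (default 5e-4).
#' @return The panel tibble with `vaf`, `informative_families`,
#'   `background_threshold` and `detected` columns.
#' @export
call_mutations <- function(pileup, panel, background = NULL,
                           vaf_threshold = 5e-4) {
  stopifnot(inherits(pileup, "consensus_pileup"),
            all(c("assay_id", "offset", "alt") %in% names(panel)))
  bg <- if (is.null(background)) 0 else background$threshold[[1L]]
  n <- nrow(panel)
  vaf <- rep(NA_real_, n)
  informative <- rep(0L, n)
  for (i in seq_len(n)) {
    vaf[[i]] <- variant_vaf(pileup, panel$offset[[i]], panel$alt[[i]])
    informative[[i]] <-
      pileup$informative_families[[match(panel$offset[[i]], pileup$pos)]]
  }
  panel$vaf <- vaf
  panel$informative_families <- informative
  panel$background_threshold <- bg
  panel$detected <- ifelse(is.na(vaf), NA, vaf >= vaf_threshold & vaf > bg)
  panel
}

#' Classify a plasma sample from its mutation calls
#'
#' A sample is positive when one or more panel mutations are detected
#' (patients with multiple panel mutations need confirmation of at least
#' one).  If every call is not evaluable the sample itself is not
#' evaluable (`positive = NA`).
#'
#' @param calls Tibble of mutation calls from [call_mutations()] (possibly
#'   concatenated across assays), with a `detected` column.
#' @param sample_id,patient_id,day Optional identifiers carried into the
#'   result.
#' @return A one-row tibble: `sample_id`, `patient_id`, `day`,
#'   `n_evaluable`, `n_detected`, `positive` (logical; `NA` = not
#'   evaluable).
#' @export
classify_sample <- function(calls, sample_id = NA_character_,
                            patient_id = NA_character_, day = NA_integer_) {
  if (!nrow(calls)) stop("at least one mutation call is required", call. = FALSE)
  evaluable <- !is.na(calls$detected)
  positive <- if (!any(evaluable)) NA else any(calls$detected[evaluable])
  tibble::tibble(
    sample_id = sample_id, patient_id = patient_id, day = as.integer(day),
    n_evaluable = sum(evaluable),
    n_detected = sum(calls$detected[evaluable]),
    positive = positive
  )
}
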