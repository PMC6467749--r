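#' Scoring weights for tumor mutation candidates
#'
#' The standard selection criteria for patient-specific panel mutations —
#' variant allele frequency, presence in the COSMIC database, genomic
#' location class, and predicted functional impact — are combined as a
#' weighted additive score.  The criteria are qualitative; these defaults make
#' each criterion contribute at most one point and are fully configurable.
#'
#' @param w_vaf Weight of the VAF term `min(VAF / 0.30, 1)` (tumor VAFs in
#'   this setting typically range 5-30%, so 30% saturates the term).
#' @param w_cosmic Weight of the COSMIC-membership indicator.
#' @param w_location Weight of the location term.
#' @param w_impact Weight of the impact term.
#' @param location Named numeric vector of location-class weights.
#' @param impact Named numeric vector of impact-class weights.
#' @return A list of class `panel_weights`.
#' @export
panel_weights <- function(w_vaf = 1, w_cosmic = 1, w_location = 1, w_impact = 1,
                          location = c(exonic = 1, splice = 0.25, UTR = 0.25,
                                       intronic = 0.25, intergenic = 0),
                          impact = c(high = 1, moderate = 0.5, low = 0.1,
                                     none = 0)) {
  structure(list(w_vaf = w_vaf, w_cosmic = w_cosmic, w_location = w_location,
                 w_impact = w_impact, location = location, impact = impact),
            class = "panel_weights")
}

#' Score and rank candidate tumor mutations
#'
#' Candidates are single-nucleotide somatic variants from tumor sequencing
#' (e.g. Mutect2/Strelka calls supplied as a table).  Each receives
#' `score = w_vaf * min(VAF/0.30, 1) + w_cosmic * [in COSMIC] +
#' w_location * loc_weight + w_impact * imp_weight` and candidates are
#' sorted by descending score, ties broken by descending tumor VAF then
#' ascending genomic position — a total order, so permuting the input
#' never changes the resulting panel.
#'
#' @param candidates Tibble with columns `patient_id`, `gene`, `chrom`,
#'   `pos`, `ref`, `alt`, `tumor_vaf`, `in_cosmic` (logical),
#'   `location_class` (exonic/intronic/UTR/intergenic/splice) and
#'   `impact_class` (high/moderate/low/none).
#' @param weights A [panel_weights()].
#' @return The candidate tibble with `selection_score` and `rank` columns,
#'   sorted by rank.  An empty input returns an empty tibble with a
#'   warning.
#' @export
score_candidates <- function(candidates, weights = panel_weights()) {
  stopifnot(inherits(weights, "panel_weights"))
  candidates <- tibble::as_tibble(candidates)
  needed <- c("patient_id", "gene", "chrom", "pos", "ref", "alt", "tumor_vaf",
              "in_cosmic", "location_class", "impact_class")
  if (!all(needed %in% names(candidates)))
    stop("candidates must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (!nrow(candidates)) {
    warning("no candidate mutations supplied; panel will be empty")
    candidates$selection_score <- numeric(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  if (any(candidates$tumor_vaf < 0 | candidates$tumor_vaf > 1))
    stop("tumor_vaf must lie in [0, 1]", call. = FALSE)
  if (any(candidates$ref == candidates$alt))
    stop("ref and alt must differ", call. = FALSE)
  if (any(nchar(candidates$ref) != 1L | nchar(candidates$alt) != 1L))
    stop("only single-nucleotide substitutions are supported", call. = FALSE)

  loc_w <- weights$location[candidates$location_class]
  imp_w <- weights$impact[candidates$impact_class]
  if (anyNA(loc_w)) stop("unknown location_class value", call. = FALSE)
  if (anyNA(imp_w)) stop("unknown impact_class value", call. = FALSE)

  candidates$selection_score <-
    weights$w_vaf * pmin(candidates$tumor_vaf / 0.30, 1) +
    weights$w_cosmic * as.numeric(candidates$in_cosmic) +
    weights$w_location * unname(loc_w) +
    weights$w_impact * unname(imp_w)
  ord <- order(-candidates$selection_score, -candidates$tumor_vaf,
               candidates$pos)
  candidates <- candidates[ord, ]
  candidates$rank <- seq_len(nrow(candidates))
  candidates
}

#' Select the patient-specific mutation panel
#'
#' Takes the top `k` ranked candidates.  Panels target at least two
#' mutations per patient when two or more candidates are available (the
#' typical panel spans 2-8 assays per patient, so `k` is bounded to 8); a
#' single-candidate patient yields a panel of one with a warning rather
#' than a failure.
#'
#' @param ranked Output of [score_candidates()].
#' @param k Target panel size (default 4; clamped to `[2, 8]`).
#' @return Tibble of selected panel mutations with a logical attribute
#'   `undersized` set when fewer than 2 candidates were available.
#' @export
select_panel <- function(ranked, k = 4L) {
  k <- as.integer(k)
  if (is.na(k)) stop("k must be an integer", call. = FALSE)
  k <- min(max(k, 2L), 8L)
  undersized <- nrow(ranked) < 2L
  if (undersized)
    warning("fewer than 2 candidate mutations available; panel of ",
            nrow(ranked))
  panel <- utils::head(ranked[order(ranked$rank), ], k)
  attr(panel, "undersized") <- undersized
  panel
}

#' Define amplicon assays for panel mutations
#'
#' One assay per panel mutation: the target region, its insert sequence,
#' and the offset of the mutation within the insert.
#'
#' @param assays Tibble with columns `assay_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `insert` (the region's sequence).
#' @return The tibble with `length` and `is_short` columns added; see
#'   [classify_assay()].
#' @export
define_assays <- function(assays) {
  assays <- tibble::as_tibble(assays)
  needed <- c("assay_id", "chrom", "start", "end", "insert")
  if (!all(needed %in% names(assays)))
    stop("assays must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (any(assays$end < assays$start))
    stop("assay end must be >= start", call. = FALSE)
  if (any(nchar(assays$insert) != assays$end - assays$start + 1L))
    stop("insert length must equal the target region length", call. = FALSE)
  classify_assay(assays)
}

#' Classify amplicon assays as short or long
#'
#' Short amplicons favor recovery of fragmented cell-free DNA; an assay is
#' short iff its target region is strictly below 80 bp.
#'
#' @param assays Tibble with `start` and `end` columns (1-based inclusive).
#' @return The tibble with `length = end - start + 1` and
#'   `is_short = length < 80` columns.
#' @examples
#' classify_assay(data.frame(start = 1, end = c(79, 80, 95)))$is_short
#' #  TRUE FALSE FALSE
#' @export
classify_assay <- function(assays) {
  assays <- tibble::as_tibble(assays)
  assays$length <- as.integer(assays$end - assays$start + 1L)
  assays$is_short <- assays$length < 80L
  assays
}

#' Verify panel mutations in the tumor by barcode-consensus re-sequencing
#'
#' Panel mutations are confirmed by re-sequencing tumor DNA with the same
#' barcoded assays and requiring a consensus VAF at or above the
#' verification threshold (default 1%, an order of magnitude above the
#' plasma positivity threshold).  A mutation whose assay has no tumor
#' pileup is flagged unverifiable (`verified = NA`), not an error.
#' Patients with zero verified mutations are ineligible for plasma
#' monitoring.
#'
#' @param panel Tibble of panel mutations with columns `assay_id` and
#'   `offset` (mutation position within the assay insert) and `alt`.
#' @param tumor_pileups Named list of [consensus_pileup()] tibbles, one per
#'   assay, from the tumor library.
#' @param threshold Minimum tumor consensus VAF for verification
#'   (default 0.01).
#' @return The panel tibble with `tumor_consensus_vaf` and `verified`
#'   columns and a logical attribute `eligible` (any mutation verified).
#' @export
verify_in_tumor <- function(panel, tumor_pileups, threshold = 0.01) {
  stopifnot(all(c("assay_id", "offset", "alt") %in% names(panel)))
  vaf <- rep(NA_real_, nrow(panel))
  for (i in seq_len(nrow(panel))) {
    pu <- tumor_pileups[[panel$assay_id[[i]]]]
    if (is.null(pu)) next
    vaf[[i]] <- variant_vaf(pu, panel$offset[[i]], panel$alt[[i]])
  }
  panel$tumor_consensus_vaf <- vaf
  panel$verified <- ifelse(is.na(vaf), NA, vaf >= threshold)
  attr(panel, "eligible") <- isTRUE(any(panel$verified, na.rm = TRUE))
  panel
}
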