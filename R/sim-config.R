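#' Configuration for the barcoded amplicon read simulator
#'
#' Describes one simulated amplicon library: the target insert, the true
#' variants spiked into the founding molecule pool, the number of haploid
#' genome-equivalents entering barcoding, and the PCR / sequencing error
#' processes.  Roughly 300 genome-equivalents correspond to 1 ng of input
#' DNA, so the 25-50 ng plasma inputs typical of barcoded amplicon assays
#' correspond to on the order of 10^4 molecules.
#'
#' @param assay_id Assay identifier.
#' @param reference_insert Reference sequence of the target region
#'   (ACGT string, typically 40-120 nt).
#' @param variants `NULL` or a data frame with columns `offset` (1-based
#'   position within the insert), `ref`, `alt` (single bases) and `vaf`
#'   (true variant allele fraction in `[0, 1]`).
#' @param n_molecules Number of founding template molecules (haploid
#'   genome-equivalents) entering barcoding; each receives one random
#'   barcode.
#' @param reads_to_sample Total number of sequencing reads drawn from the
#'   amplified pool.
#' @param barcode_length Barcode length in nt (default 12).
#' @param pcr_cycles Number of PCR doubling cycles before sampling
#'   (default 10).
#' @param polymerase_error_rate Probability of a polymerase substitution
#'   per base per copy event (default 1e-5); errors are inherited by all
#'   descendant copies.
#' @param sequencing_error_rate Probability of a sequencing substitution
#'   per base per read (default 3e-3), independent across reads.
#' @param seed Integer seed; required so that every simulation is
#'   reproducible from its configuration alone.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(
#'   assay_id = "A1",
#'   reference_insert = strrep("ACGT", 15),
#'   variants = data.frame(offset = 30, ref = "T", alt = "A", vaf = 0.01),
#'   n_molecules = 1000, reads_to_sample = 20000, seed = 1
#' )
#' @export
sim_config <- function(assay_id, reference_insert, variants = NULL,
                       n_molecules, reads_to_sample,
                       barcode_length = 12L, pcr_cycles = 10L,
                       polymerase_error_rate = 1e-5,
                       sequencing_error_rate = 3e-3,
                       seed) {
  if (!is.character(assay_id) || length(assay_id) != 1L || is.na(assay_id) ||
      !nzchar(assay_id))
    config_error("assay_id", "must be a non-empty string")
  if (!is_dna_string(reference_insert))
    config_error("reference_insert", "must be a non-empty ACGT string")
  L <- nchar(reference_insert)

  if (is.null(variants)) {
    variants <- tibble::tibble(offset = integer(), ref = character(),
                               alt = character(), vaf = numeric())
  }
  variants <- tibble::as_tibble(variants)
  needed <- c("offset", "ref", "alt", "vaf")
  if (!all(needed %in% names(variants)))
    config_error("variants",
                 paste("must have columns", paste(needed, collapse = ", ")))
  variants$offset <- as.integer(variants$offset)
  if (nrow(variants)) {
    if (anyNA(variants$offset) || any(variants$offset < 1L | variants$offset > L))
      config_error("variants", "offsets must lie within the reference insert")
    if (anyDuplicated(variants$offset))
      config_error("variants", "offsets must be unique")
    insert_base <- substring(reference_insert, variants$offset, variants$offset)
    if (!all(variants$ref == insert_base))
      config_error("variants", "ref base must match the reference insert")
    if (!all(variants$ref %in% DNA_BASES) || !all(variants$alt %in% DNA_BASES))
      config_error("variants", "ref and alt must be single A/C/G/T bases")
    if (any(variants$ref == variants$alt))
      config_error("variants", "ref and alt must differ")
    if (!is.numeric(variants$vaf) || anyNA(variants$vaf) ||
        any(variants$vaf < 0 | variants$vaf > 1))
      config_error("variants", "vaf must lie in [0, 1]")
  }

  n_molecules <- as.integer(n_molecules)
  if (is.na(n_molecules) || n_molecules < 0L)
    config_error("n_molecules", "must be a non-negative integer")
  reads_to_sample <- as.integer(reads_to_sample)
  if (is.na(reads_to_sample) || reads_to_sample < 1L)
    config_error("reads_to_sample", "must be a positive integer")
  barcode_length <- as.integer(barcode_length)
  if (is.na(barcode_length) || barcode_length < 1L)
    config_error("barcode_length", "must be a positive integer")
  pcr_cycles <- as.integer(pcr_cycles)
  if (is.na(pcr_cycles) || pcr_cycles < 0L)
    config_error("pcr_cycles", "must be a non-negative integer")
  for (f in c("polymerase_error_rate", "sequencing_error_rate")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      config_error(f, "must be a probability in [0, 1]")
  }
  if (missing(seed)) config_error("seed", "must be supplied")
  seed <- as.integer(seed)
  if (is.na(seed)) config_error("seed", "must be an integer")

  structure(
    list(assay_id = assay_id, reference_insert = reference_insert,
         variants = variants, n_molecules = n_molecules,
         reads_to_sample = reads_to_sample, barcode_length = barcode_length,
         pcr_cycles = pcr_cycles,
         polymerase_error_rate = polymerase_error_rate,
         sequencing_error_rate = sequencing_error_rate, seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config '%s': %d nt insert, %d variant(s), %d molecules, %d reads, %d PCR cycles\n",
    x$assay_id, nchar(x$reference_insert), nrow(x$variants), x$n_molecules,
    x$reads_to_sample, x$pcr_cycles))
  invisible(x)
}
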