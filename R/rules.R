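#' Consensus-calling rules for barcode families
#'
#' Parameters of the family-size-dependent agreement rule used when
#' collapsing a barcode family to a consensus read.  Families smaller than
#' `min_family_size` are excluded from consensus calling entirely.  Within a
#' retained family the consensus base at a position is the allele whose
#' within-family fraction reaches the applicable threshold:
#' `small_family_fraction` (default 100%) for families of
#' `min_family_size`..`small_family_max` reads, or `large_family_fraction`
#' (default 90%) for families larger than `small_family_max`.  Positions at
#' which no allele reaches the threshold are called `N` and drop out of the
#' variant-allele-frequency denominator.
#'
#' The defaults encode the standard barcoded-amplicon reporting rule:
#' variants appear in consensus sequences only if they compose 100% of the
#' reads in families of 10-20 reads, or at least 90% of reads in families of
#' more than 20 reads.
#'
#' @param min_family_size Minimum number of reads for a family to produce a
#'   consensus read (default 10).
#' @param small_family_max Largest family size governed by the unanimity
#'   rule (default 20); larger families use `large_family_fraction`.
#' @param small_family_fraction Required agreement fraction for small
#'   families (default 1, i.e. unanimity).
#' @param large_family_fraction Required agreement fraction for families
#'   larger than `small_family_max` (default 0.9, inclusive: a fraction of
#'   exactly 0.9 is reported).  Must exceed 0.5 so that at most one allele
#'   can qualify at any position.
#' @return An object of class `consensus_rules`.
#' @examples
#' consensus_rules()
#' @export
consensus_rules <- function(min_family_size = 10L,
                            small_family_max = 20L,
                            small_family_fraction = 1.0,
                            large_family_fraction = 0.9) {
  min_family_size <- as.integer(min_family_size)
  small_family_max <- as.integer(small_family_max)
  if (is.na(min_family_size) || min_family_size < 1L)
    config_error("min_family_size", "must be a positive integer")
  if (is.na(small_family_max) || small_family_max < min_family_size)
    config_error("small_family_max", "must be >= min_family_size")
  for (f in c("small_family_fraction", "large_family_fraction")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      config_error(f, "must be a fraction in (0, 1]")
  }
  if (large_family_fraction <= 0.5)
    config_error("large_family_fraction",
                 "must exceed 0.5 (so the qualifying allele is unique)")
  structure(
    list(min_family_size = min_family_size,
         small_family_max = small_family_max,
         small_family_fraction = small_family_fraction,
         large_family_fraction = large_family_fraction),
    class = "consensus_rules"
  )
}

# Agreement fraction applicable to a family of size n (n >= min_family_size).
required_fraction <- function(rules, n) {
  ifelse(n <= rules$small_family_max,
         rules$small_family_fraction, rules$large_family_fraction)
}

#' @export
print.consensus_rules <- function(x, ...) {
  cat(sprintf(
    "consensus rules: families >= %d reads; agreement %.0f%% for sizes %d-%d, >= %.0f%% above\n",
    x$min_family_size, 100 * x$small_family_fraction, x$min_family_size,
    x$small_family_max, 100 * x$large_family_fraction))
  invisible(x)
}

#' Read structure of a barcoded amplicon library
#'
#' Single-end reads are laid out as `barcode + constant spacer + insert`.
#' The barcode is a random oligonucleotide (12 nt by default) ligated to
#' each template molecule in the early PCR cycles; the constant spacer lets
#' the extractor validate that the barcode boundary is where it expects.
#'
#' @param barcode_length Barcode length in nt (default 12).
#' @param spacer Constant spacer sequence between barcode and insert.
#' @param max_spacer_mismatch Reads whose observed spacer differs from
#'   `spacer` by more than this many bases are rejected (default 1).
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(barcode_length = 12L, spacer = "CTGAGC",
                        max_spacer_mismatch = 1L) {
  barcode_length <- as.integer(barcode_length)
  if (is.na(barcode_length) || barcode_length < 1L)
    config_error("barcode_length", "must be a positive integer")
  if (!is_dna_string(spacer))
    config_error("spacer", "must be a non-empty ACGT string")
  max_spacer_mismatch <- as.integer(max_spacer_mismatch)
  if (is.na(max_spacer_mismatch) || max_spacer_mismatch < 0L)
    config_error("max_spacer_mismatch", "must be a non-negative integer")
  structure(
    list(barcode_length = barcode_length, spacer = spacer,
         spacer_length = nchar(spacer),
         max_spacer_mismatch = max_spacer_mismatch),
    class = "read_layout"
  )
}
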