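#' Extract molecular barcodes from raw reads
#'
#' Splits each read into `barcode + spacer + insert` according to the
#' layout.  Reads shorter than `barcode + spacer + 1` are rejected with
#' reason `"too_short"`; reads whose observed spacer differs from the
#' expected constant by more than `layout$max_spacer_mismatch` bases are
#' rejected with reason `"spacer_mismatch"`.  Rejections are counted, not
#' fatal.
#'
#' @param reads Tibble with columns `read_id` and `sequence` (e.g. from
#'   [read_fastq()] or [amplify_and_sequence()]).
#' @param layout A [read_layout()].
#' @param assay_id Assay the reads belong to (amplicon reads are
#'   assay-anchored; no alignment is performed).
#' @return A list with `tagged` (tibble: `read_id`, `barcode`, `insert`,
#'   `assay_id`) and `rejected` (tibble: `read_id`, `reason`).
#' @export
extract_barcodes <- function(reads, layout = read_layout(), assay_id = "assay") {
  stopifnot(inherits(layout, "read_layout"),
            all(c("read_id", "sequence") %in% names(reads)))
  bl <- layout$barcode_length
  sl <- layout$spacer_length
  len <- nchar(reads$sequence)
  too_short <- len < bl + sl + 1L

  spacer_obs <- substr(reads$sequence[!too_short], bl + 1L, bl + sl)
  mism <- integer(length(spacer_obs))
  if (length(spacer_obs)) {
    sp <- seq_char_matrix(spacer_obs)           # sl x n
    mism <- as.integer(colSums(sp != charToRaw(layout$spacer)))
  }
  bad_spacer_idx <- which(!too_short)[mism > layout$max_spacer_mismatch]

  ok <- !too_short
  ok[bad_spacer_idx] <- FALSE
  tagged <- tibble::tibble(
    read_id = reads$read_id[ok],
    barcode = substr(reads$sequence[ok], 1L, bl),
    insert = substr(reads$sequence[ok], bl + sl + 1L, len[ok]),
    assay_id = assay_id
  )
  rejected <- tibble::tibble(
    read_id = c(reads$read_id[too_short], reads$read_id[bad_spacer_idx]),
    reason = c(rep("too_short", sum(too_short)),
               rep("spacer_mismatch", length(bad_spacer_idx)))
  )
  list(tagged = tagged, rejected = rejected)
}

#' Group tagged reads into barcode families
#'
#' Exact-match grouping on `(assay_id, barcode)`; no barcode error
#' correction is applied by default (exact matching is the conservative
#' reading when the chemistry's error-correction behaviour is unspecified).
#' Single-mismatch merging of small families into larger ones is available
#' behind `merge_single_mismatch`, default off.
#'
#' @param tagged Tibble of tagged reads from [extract_barcodes()].
#' @param merge_single_mismatch If `TRUE`, a barcode observed fewer times
#'   than `min_family_size` that is within Hamming distance 1 of a unique
#'   larger family's barcode is merged into that family.
#' @param min_family_size Only used when merging (default 10).
#' @return Tibble with one row per family: `assay_id`, `barcode`, `size`,
#'   and `family_id`.  Family sizes sum to the number of input reads.
#' @export
group_families <- function(tagged, merge_single_mismatch = FALSE,
                           min_family_size = 10L) {
  stopifnot(all(c("barcode", "assay_id") %in% names(tagged)))
  if (merge_single_mismatch) tagged <- merge_barcodes(tagged, min_family_size)
  fams <- dplyr::count(tagged, .data$assay_id, .data$barcode, name = "size")
  fams$family_id <- seq_len(nrow(fams))
  fams
}

# Hamming-distance-1 merge of sub-threshold barcodes into a unique large
# neighbour.  O(small * large) string comparisons; intended for modest
# family counts, and off by default.
merge_barcodes <- function(tagged, min_family_size) {
  counts <- dplyr::count(tagged, .data$assay_id, .data$barcode, name = "size")
  small <- counts[counts$size < min_family_size, ]
  large <- counts[counts$size >= min_family_size, ]
  if (!nrow(small) || !nrow(large)) return(tagged)
  map <- stats::setNames(character(0), character(0))
  for (i in seq_len(nrow(small))) {
    cand <- large[large$assay_id == small$assay_id[[i]], "barcode", drop = TRUE]
    d <- hamming1(small$barcode[[i]], cand)
    if (sum(d) == 1L)
      map[[small$barcode[[i]]]] <- cand[d][[1L]]
  }
  hit <- tagged$barcode %in% names(map)
  tagged$barcode[hit] <- unname(map[tagged$barcode[hit]])
  tagged
}

hamming1 <- function(x, pool) {
  if (!length(pool)) return(logical(0))
  m <- seq_char_matrix(pool)
  colSums(m != charToRaw(x)) == 1L
}

#' Consensus call for one barcode family
#'
#' Reference implementation of the per-family consensus rule, applied
#' position by position (the rule is positional: a family can report a
#' variant at one base and be ambiguous at another).  Families smaller than
#' `rules$min_family_size` are excluded.  At each position, the base whose
#' within-family fraction reaches the applicable agreement threshold
#' (unanimity for families of 10-20 reads, >= 90% for larger families,
#' under the default rules) becomes the consensus base; if no base
#' qualifies the consensus base is `N`.  `N` bases in member reads count
#' toward the family size denominator but can never be the consensus.
#'
#' @param inserts Character vector of the family's member read inserts
#'   (equal lengths).
#' @param rules A [consensus_rules()].
#' @return A list with `consensus` (string over ACGTN), `family_size`, and
#'   `excluded` (`TRUE` when the family is below the minimum size, in which
#'   case `consensus` is `NA`).
#' @examples
#' # 15-read family: unanimity required, one dissenting read masks the base
#' consensus_family(rep("ACGT", 15))$consensus         # "ACGT"
#' consensus_family(c(rep("ACGT", 14), "AAGT"))$consensus  # "ANGT"
#' @export
consensus_family <- function(inserts, rules = consensus_rules()) {
  stopifnot(inherits(rules, "consensus_rules"), length(inserts) >= 1L)
  n <- length(inserts)
  if (n < rules$min_family_size)
    return(list(consensus = NA_character_, family_size = n, excluded = TRUE))
  frac <- required_fraction(rules, n)
  m <- seq_char_matrix(inserts)                 # L x n
  base_raw <- charToRaw(paste(DNA_BASES, collapse = ""))
  counts <- vapply(base_raw, function(b) rowSums(m == b), numeric(nrow(m)))
  if (nrow(m) == 1L) counts <- matrix(counts, nrow = 1L)
  top <- max.col(counts, ties.method = "first")
  top_count <- counts[cbind(seq_len(nrow(m)), top)]
  call <- ifelse(top_count / n >= frac, DNA_BASES[top], "N")
  list(consensus = paste(call, collapse = ""), family_size = n,
       excluded = FALSE)
}

#' Build a per-position consensus pileup for one assay
#'
#' Groups tagged reads into barcode families (exact match), applies the
#' family consensus rule of [consensus_family()] to every family of at
#' least `rules$min_family_size` reads, and tallies consensus bases per
#' position: counts of consensus families by allele, the number of
#' informative families (non-`N` consensus calls), and the minor allele
#' frequency (largest non-reference family count over informative
#' families; `NA` where no family is informative).
#'
#' Internally the tally is sparse — only read bases that differ from the
#' reference are materialized — which makes deep libraries cheap; the
#' result is identical to applying [consensus_family()] to every family
#' (the package tests enforce this equivalence against a brute-force
#' oracle).
#'
#' @param tagged Tibble of tagged reads for a single assay
#'   ([extract_barcodes()]); mixed assays raise an error.
#' @param reference Reference insert sequence the reads are anchored to;
#'   all inserts must have the same length as the reference.
#' @param rules A [consensus_rules()].
#' @return A tibble of class `consensus_pileup` with one row per position:
#'   `assay_id`, `pos` (1-based within the insert), `ref`, family counts
#'   `A`, `C`, `G`, `T`, `N`, `informative_families`, and `maf`.
#'   Attributes `n_families`, `n_families_passing` and `n_reads_used`
#'   record the family accounting.
#' @export
consensus_pileup <- function(tagged, reference, rules = consensus_rules()) {
  stopifnot(inherits(rules, "consensus_rules"),
            all(c("barcode", "insert", "assay_id") %in% names(tagged)))
  if (!is_dna_string(reference))
    stop("reference must be a non-empty ACGT string", call. = FALSE)
  assay <- unique(tagged$assay_id)
  if (length(assay) > 1L)
    stop("mixed assays in pileup input: ", paste(assay, collapse = ", "),
         call. = FALSE)
  if (length(assay) == 0L) assay <- NA_character_
  L <- nchar(reference)
  ref_bases <- strsplit(reference, "")[[1L]]

  if (nrow(tagged) && !all(nchar(tagged$insert) == L))
    stop("all inserts must match the reference length (assay-anchored reads)",
         call. = FALSE)

  fam <- integer(0)
  fsizes <- integer(0)
  if (nrow(tagged)) {
    fam <- match(tagged$barcode, unique(tagged$barcode))
    fsizes <- tabulate(fam)
  }
  passing <- which(fsizes >= rules$min_family_size)
  n_pass <- length(passing)

  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c(DNA_BASES, "N")))

  if (n_pass > 0L) {
    keep <- fam %in% passing
    ridx <- which(keep)
    fam_kept <- match(fam[ridx], passing)       # 1..n_pass
    sizes <- fsizes[passing]

    m <- seq_char_matrix(tagged$insert[ridx])
    mm <- which(m != charToRaw(reference), arr.ind = TRUE)

    # every (family, position) cell without a mismatch is unanimously
    # reference; only cells with mismatches need the threshold test
    deltas <- sparse_consensus_deltas(mm, m, fam_kept, sizes, L, rules)

    ref_counts <- rep(n_pass, L)
    if (nrow(deltas)) {
      tab <- table(factor(deltas$base, levels = c(DNA_BASES, "N")),
                   factor(deltas$pos, levels = seq_len(L)))
      counts <- counts + t(tab)
      ref_counts <- ref_counts - as.integer(colSums(tab))
    }
    ref_col <- match(ref_bases, DNA_BASES)
    counts[cbind(seq_len(L), ref_col)] <- counts[cbind(seq_len(L), ref_col)] +
      ref_counts
  }

  informative <- as.integer(rowSums(counts[, DNA_BASES, drop = FALSE]))
  nonref <- counts[, DNA_BASES, drop = FALSE]
  nonref[cbind(seq_len(L), match(ref_bases, DNA_BASES))] <- 0L
  top_nonref <- apply(nonref, 1L, max)
  maf <- ifelse(informative > 0L, top_nonref / informative, NA_real_)

  out <- tibble::tibble(
    assay_id = assay, pos = seq_len(L), ref = ref_bases,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
    T = counts[, "T"], N = counts[, "N"],
    informative_families = informative, maf = maf
  )
  attr(out, "n_families") <- length(fsizes)
  attr(out, "n_families_passing") <- n_pass
  attr(out, "n_reads_used") <- if (n_pass) sum(fsizes[passing]) else 0L
  attr(out, "rules") <- rules
  class(out) <- c("consensus_pileup", class(out))
  out
}

# Threshold test for all (family, position) cells containing at least one
# non-reference base.  Returns a tibble of consensus calls that deviate
# from the reference: base in ACGT (variant) or "N" (no allele qualified).
sparse_consensus_deltas <- function(mm, m, fam_kept, sizes, L, rules) {
  empty <- tibble::tibble(fam = integer(), pos = integer(), base = character())
  if (!nrow(mm)) return(empty)
  pos <- mm[, 1L]
  f <- fam_kept[mm[, 2L]]
  b <- strsplit(rawToChar(m[mm]), "")[[1L]]
  key <- (f - 1) * L + pos

  d <- dplyr::count(tibble::tibble(key = key, base = b), .data$key, .data$base)
  tot <- dplyr::count(tibble::tibble(key = key), .data$key)   # mismatches per cell

  # best non-reference ACGT allele per cell (N in reads can never be the
  # consensus; whichever allele is picked on a count tie is irrelevant,
  # since at most one allele can reach a fraction > 0.5)
  d_acgt <- d[d$base %in% DNA_BASES, ]
  ord <- order(d_acgt$key, -d_acgt$n)
  best <- d_acgt[ord, ][!duplicated(d_acgt$key[ord]), ]

  cell_key <- tot$key
  cell_fam <- as.integer((cell_key - 1) %/% L) + 1L
  cell_pos <- as.integer((cell_key - 1) %% L) + 1L
  s <- sizes[cell_fam]
  frac <- required_fraction(rules, s)

  i <- match(cell_key, best$key)
  alt_n <- ifelse(is.na(i), 0L, best$n[i])
  alt_b <- ifelse(is.na(i), NA_character_, best$base[i])
  ref_n <- s - tot$n

  alt_wins <- alt_n / s >= frac
  ref_wins <- ref_n / s >= frac
  stopifnot(!any(alt_wins & ref_wins))  # unique qualifier while fraction > 0.5

  out_base <- ifelse(alt_wins, alt_b, "N")
  keep <- !ref_wins
  tibble::tibble(fam = cell_fam[keep], pos = cell_pos[keep],
                 base = out_base[keep])
}

#' Variant allele frequency from a consensus pileup
#'
#' The fraction of informative consensus families carrying the alternate
#' allele at a position.
#'
#' @param pileup A [consensus_pileup()].
#' @param position 1-based position within the assay insert.
#' @param alt Alternate allele (one of A/C/G/T, different from the
#'   reference base at the position).
#' @return The VAF as a fraction, or `NA_real_` when no family is
#'   informative at the position (undefined VAF).
#' @examples
#' \dontrun{variant_vaf(pileup, 47, "A")}
#' @export
variant_vaf <- function(pileup, position, alt) {
  stopifnot(inherits(pileup, "consensus_pileup"))
  if (!alt %in% DNA_BASES) stop("alt must be one of A/C/G/T", call. = FALSE)
  row <- pileup[pileup$pos == position, ]
  if (nrow(row) != 1L) stop("position outside the assay insert", call. = FALSE)
  if (row$ref == alt) stop("alt equals the reference base", call. = FALSE)
  if (row$informative_families == 0L) return(NA_real_)
  row[[alt]] / row$informative_families
}
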