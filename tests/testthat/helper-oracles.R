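# Independent brute-force oracles: literal, per-position tallies over
# split character vectors, sharing no code with the package's sparse
# implementation.

oracle_consensus_family <- function(inserts, rules = consensus_rules()) {
  n <- length(inserts)
  if (n < rules$min_family_size) return(NULL)
  frac <- if (n <= rules$small_family_max) rules$small_family_fraction
          else rules$large_family_fraction
  chars <- strsplit(inserts, "")
  L <- nchar(inserts[[1]])
  out <- character(L)
  for (j in seq_len(L)) {
    col <- vapply(chars, `[[`, "", j)
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    winner <- names(tab)[as.integer(tab) / n >= frac]
    out[[j]] <- if (length(winner) == 1L) winner else "N"
  }
  paste(out, collapse = "")
}

oracle_pileup <- function(tagged, reference, rules = consensus_rules()) {
  L <- nchar(reference)
  fams <- split(tagged$insert, tagged$barcode)
  cons <- Filter(Negate(is.null),
                 lapply(fams, oracle_consensus_family, rules = rules))
  counts <- matrix(0L, nrow = L, ncol = 5L,
                   dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (cs in cons) {
    ch <- strsplit(cs, "")[[1]]
    for (j in seq_len(L)) counts[j, ch[[j]]] <- counts[j, ch[[j]]] + 1L
  }
  refc <- strsplit(reference, "")[[1]]
  informative <- integer(L); maf <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    informative[[j]] <- sum(counts[j, c("A", "C", "G", "T")])
    if (informative[[j]] > 0) {
      nonref <- counts[j, setdiff(c("A", "C", "G", "T"), refc[[j]])]
      maf[[j]] <- max(nonref) / informative[[j]]
    }
  }
  list(counts = counts, informative = informative, maf = maf,
       n_passing = length(cons))
}

# Random tagged reads: `n_barcodes` families over a reference, with
# per-base substitution noise and optional alt-carrying families.
random_tagged <- function(n_reads, n_barcodes, reference, noise = 0.02,
                          assay_id = "A1") {
  L <- nchar(reference)
  barcodes <- unique(replicate(n_barcodes,
    paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")))
  bc <- sample(barcodes, n_reads, replace = TRUE)
  inserts <- vapply(seq_len(n_reads), function(i) {
    ch <- strsplit(reference, "")[[1]]
    hit <- which(runif(L) < noise)
    for (j in hit) ch[[j]] <- sample(setdiff(c("A", "C", "G", "T", "N"), ch[[j]]), 1)
    paste(ch, collapse = "")
  }, "")
  tibble::tibble(read_id = paste0("r", seq_len(n_reads)), barcode = bc,
                 insert = inserts, assay_id = assay_id)
}

# Build a family of `size` reads with `k` alt reads at `offset`.
alt_family <- function(reference, size, k, offset, alt) {
  ref_read <- reference
  alt_read <- reference
  substr(alt_read, offset, offset) <- alt
  c(rep(alt_read, k), rep(ref_read, size - k))
}

# Assemble a consensus_pileup-shaped tibble directly from allele counts
# (used to probe the calling layer with exact VAFs).
manual_pileup <- function(reference, pos, alt, alt_families, informative,
                          assay_id = "A1") {
  L <- nchar(reference)
  refc <- strsplit(reference, "")[[1]]
  out <- tibble::tibble(
    assay_id = assay_id, pos = seq_len(L), ref = refc,
    A = 0L, C = 0L, G = 0L, T = 0L, N = 0L,
    informative_families = as.integer(informative), maf = 0)
  for (j in seq_len(L)) out[[refc[[j]]]][[j]] <- as.integer(informative)
  out[[alt]][[pos]] <- as.integer(alt_families)
  out[[refc[[pos]]]][[pos]] <- as.integer(informative - alt_families)
  out$maf[[pos]] <- alt_families / informative
  class(out) <- c("consensus_pileup", class(out))
  out
}

ref_seq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
}
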