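#' Draw the founding molecule pool for a simulated amplicon library
#'
#' Each founding template molecule receives one random barcode of
#' `barcode_length` nt, and its allele at every configured variant position
#' is drawn independently with probability equal to the variant's true VAF.
#' The realized molecular VAF (mutant molecules / total molecules) is
#' recorded per variant and is the ground truth against which downstream
#' VAF estimates are judged.
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth`: a list with
#'   `molecules` (tibble: `molecule_id`, `barcode`), `alleles` (character
#'   matrix, one row per molecule, one column per variant), and `variants`
#'   (the config variant table plus `mutant_molecules` and `realized_vaf`).
#' @seealso [amplify_and_sequence()]
#' @export
simulate_molecules <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_molecules
  nv <- nrow(config$variants)
  withr::with_seed(config$seed, {
    barcodes <- random_dna(n, config$barcode_length)
    alleles <- matrix(character(0), nrow = n, ncol = 0)
    realized <- config$variants
    realized$mutant_molecules <- integer(nv)
    realized$realized_vaf <- numeric(nv)
    if (nv > 0L && n > 0L) {
      alleles <- matrix("", nrow = n, ncol = nv)
      colnames(alleles) <- paste0("v", config$variants$offset)
      for (j in seq_len(nv)) {
        mut <- stats::runif(n) < config$variants$vaf[[j]]
        alleles[, j] <- ifelse(mut, config$variants$alt[[j]],
                               config$variants$ref[[j]])
        realized$mutant_molecules[[j]] <- sum(mut)
        realized$realized_vaf[[j]] <- sum(mut) / n
      }
    }
  })
  structure(
    list(assay_id = config$assay_id,
         n_molecules = n,
         barcode_length = config$barcode_length,
         molecules = tibble::tibble(molecule_id = seq_len(n),
                                    barcode = barcodes),
         alleles = alleles,
         variants = realized),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth '%s': %d molecules", x$assay_id, x$n_molecules))
  if (nrow(x$variants))
    cat(sprintf("; realized VAF %s",
                paste(sprintf("%.4g", x$variants$realized_vaf), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Amplify the molecule pool and sample sequencing reads
#'
#' Models library construction as deterministic doubling: every molecule is
#' copied once per PCR cycle, and each copy event introduces independent
#' polymerase substitutions at `polymerase_error_rate` per base, which are
#' inherited by all descendant copies (the barcode-correlated error mode
#' that family consensus is designed to reject).  `reads_to_sample` reads
#' are then drawn uniformly from the final pool and each receives
#' independent sequencing substitutions at `sequencing_error_rate` per
#' base.  Both error processes act on the insert; the barcode and spacer
#' are carried through unchanged, so every read traces to exactly one
#' founding molecule by its barcode.
#'
#' Because doubling gives every founder the same number of descendants,
#' uniform sampling from the pool is realized without materializing it:
#' each read picks a founder uniformly and an independent random lineage
#' (one branch choice per cycle), and polymerase error events — drawn per
#' founder with the correct per-cycle weights — are inherited by exactly
#' the sampled reads whose lineage passes through the erroneous copy.
#'
#' @param truth A `ground_truth` from [simulate_molecules()].
#' @param config The same [sim_config()] the truth was generated from.
#' @param layout A [read_layout()]; its `barcode_length` must match the
#'   config.
#' @return A tibble with one row per read: `read_id`, `molecule_id`
#'   (founding molecule), and `sequence` (`barcode + spacer + insert`).
#' @export
amplify_and_sequence <- function(truth, config, layout = read_layout()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"),
            inherits(layout, "read_layout"))
  if (truth$assay_id != config$assay_id || truth$n_molecules != config$n_molecules)
    stop("ground truth was not produced from this configuration", call. = FALSE)
  if (layout$barcode_length != config$barcode_length)
    stop("read layout barcode length does not match configuration", call. = FALSE)
  n <- truth$n_molecules
  if (n == 0L)
    stop("empty amplified pool: no molecules to sequence", call. = FALSE)

  L <- nchar(config$reference_insert)
  R <- config$reads_to_sample
  cyc <- config$pcr_cycles

  withr::with_seed(config$seed + 1L, {
    # founder insert sequences: reference with per-molecule variant alleles
    founder_seq <- rep(config$reference_insert, n)
    for (j in seq_len(nrow(config$variants))) {
      off <- config$variants$offset[[j]]
      substr(founder_seq, off, off) <- truth$alleles[, j]
    }

    founder_of <- sample.int(n, R, replace = TRUE)
    mat <- seq_char_matrix(founder_seq[founder_of])   # L x R raw matrix

    # polymerase errors: events on the founder's amplification tree
    if (cyc > 0L && config$polymerase_error_rate > 0) {
      copy_events <- 2^cyc - 1           # per founder
      n_events <- stats::rbinom(n, copy_events * L, config$polymerase_error_rate)
      ev_founder <- rep(which(n_events > 0L), n_events[n_events > 0L])
      K <- length(ev_founder)
      if (K > 0L) {
        # cycle t holds 2^(t-1) of the tree's copy events
        ev_cycle <- sample.int(cyc, K, replace = TRUE, prob = 2^(seq_len(cyc) - 1))
        ev_pos <- sample.int(L, K, replace = TRUE)
        # each read's lineage: one branch bit per cycle (TRUE = the new copy)
        path <- matrix(stats::runif(R * cyc) < 0.5, nrow = R)
        reads_of <- split(seq_len(R), founder_of)
        ord <- order(ev_cycle)           # ancestors first, so later events overwrite
        for (e in ord) {
          rr <- reads_of[[as.character(ev_founder[[e]])]]
          if (is.null(rr)) next
          te <- ev_cycle[[e]]
          prefix <- c(stats::runif(te - 1L) < 0.5, TRUE)
          for (b in seq_len(te)) {
            rr <- rr[path[rr, b] == prefix[[b]]]
            if (!length(rr)) break
          }
          if (!length(rr)) next
          mat[ev_pos[[e]], rr] <- random_other_base(mat[ev_pos[[e]], rr[[1L]]])
        }
      }
    }

    # sequencing errors: independent per read
    if (config$sequencing_error_rate > 0) {
      n_err <- stats::rbinom(R, L, config$sequencing_error_rate)
      with_err <- which(n_err > 0L)
      if (length(with_err)) {
        err_read <- rep(with_err, n_err[with_err])
        err_pos <- as.integer(stats::runif(length(err_read)) * L) + 1L
        idx <- cbind(err_pos, err_read)
        mat[idx] <- random_other_base(mat[idx])
      }
    }

    inserts <- raw_to_strings(mat)
  })

  tibble::tibble(
    read_id = paste0("r", seq_len(R)),
    molecule_id = founder_of,
    sequence = paste0(truth$molecules$barcode[founder_of], layout$spacer, inserts)
  )
}
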