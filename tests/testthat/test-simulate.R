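ref <- ref_seq(60, seed = 7)

base_cfg <- function(...) {
  args <- utils::modifyList(
    list(assay_id = "A1", reference_insert = ref,
         variants = data.frame(offset = 30, ref = substr(ref, 30, 30),
                               alt = setdiff(c("A", "C", "G", "T"),
                                             substr(ref, 30, 30))[1],
                               vaf = 0.5),
         n_molecules = 200L, reads_to_sample = 4000L, pcr_cycles = 6L,
         polymerase_error_rate = 0, sequencing_error_rate = 0, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

test_that("configuration errors name the offending field", {
  expect_error(base_cfg(sequencing_error_rate = 1.2), "sequencing_error_rate")
  expect_error(base_cfg(polymerase_error_rate = -1e-3), "polymerase_error_rate")
  expect_error(base_cfg(reads_to_sample = 0), "reads_to_sample")
  expect_error(base_cfg(reference_insert = "ACGX"), "reference_insert")
  expect_error(
    base_cfg(variants = data.frame(offset = 99, ref = "A", alt = "C", vaf = 0.1)),
    "variants")
  expect_error(  # ref base must match the insert
    base_cfg(variants = data.frame(offset = 3,
                                   ref = setdiff(c("A", "C", "G", "T"),
                                                 substr(ref, 3, 3))[1],
                                   alt = substr(ref, 3, 3), vaf = 0.1)),
    "variants")
  expect_error(sim_config("A1", ref, NULL, 100, 1000), "seed")
})

test_that("molecule pool matches the configured size and VAFs", {
  # VAF 0: a mutant molecule is a zero-probability event
  cfg0 <- base_cfg(n_molecules = 100L)
  cfg0$variants$vaf <- 0
  tr0 <- simulate_molecules(cfg0)
  expect_equal(nrow(tr0$molecules), 100L)
  expect_equal(tr0$variants$mutant_molecules, 0L)
  expect_true(all(tr0$alleles[, 1] == cfg0$variants$ref))

  # VAF 0.5 at n = 10000: realized count within 3 binomial SD of 5000
  cfg <- base_cfg(n_molecules = 10000L)
  tr <- simulate_molecules(cfg)
  expect_lt(abs(tr$variants$mutant_molecules - 5000), 3 * sqrt(10000 * 0.25))
  expect_equal(tr$variants$realized_vaf,
               tr$variants$mutant_molecules / 10000)

  # determinism: identical config -> identical ground truth
  expect_identical(simulate_molecules(cfg), simulate_molecules(cfg))
})

test_that("error-free amplification reproduces founder alleles exactly", {
  cfg <- base_cfg()
  tr <- simulate_molecules(cfg)
  reads <- amplify_and_sequence(tr, cfg)
  expect_equal(nrow(reads), cfg$reads_to_sample)

  lay <- read_layout()
  insert <- substr(reads$sequence, lay$barcode_length + lay$spacer_length + 1L,
                   nchar(reads$sequence))
  founder_allele <- tr$alleles[reads$molecule_id, 1]
  expect_identical(substr(insert, 30, 30), founder_allele)

  # conservation: every read's barcode is a ground-truth barcode and
  # belongs to the founder it claims
  expect_identical(substr(reads$sequence, 1, 12),
                   tr$molecules$barcode[reads$molecule_id])

  # raw-read VAF equals the family-sampling-weighted molecular VAF
  expect_equal(mean(substr(insert, 30, 30) == cfg$variants$alt),
               mean(founder_allele == cfg$variants$alt))
})

test_that("family sizes and sequencing errors match their sampling models", {
  # mean reads per family ~ reads_to_sample / n_molecules within 10%
  cfg <- base_cfg(n_molecules = 500L, reads_to_sample = 25000L,
                  variants = NULL)
  tr <- simulate_molecules(cfg)
  reads <- amplify_and_sequence(tr, cfg)
  sizes <- table(reads$molecule_id)
  expect_lt(abs(mean(sizes) - 50) / 50, 0.10)

  # per-base mismatch rate vs founder within 3 binomial SE of the rate
  cfg2 <- base_cfg(n_molecules = 300L, reads_to_sample = 6000L,
                   sequencing_error_rate = 0.01, variants = NULL)
  tr2 <- simulate_molecules(cfg2)
  reads2 <- amplify_and_sequence(tr2, cfg2)
  lay <- read_layout()
  ins <- substr(reads2$sequence, lay$barcode_length + lay$spacer_length + 1L,
                nchar(reads2$sequence))
  L <- nchar(ref)
  mism <- sum(vapply(seq_len(L), function(j)
    sum(substr(ins, j, j) != substr(ref, j, j)), 0))
  n_bases <- L * nrow(reads2)
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(mism / n_bases - 0.01), 3 * se)
})

test_that("simulation is reproducible and FASTQ output byte-identical", {
  cfg <- base_cfg(n_molecules = 50L, reads_to_sample = 500L,
                  polymerase_error_rate = 1e-4, sequencing_error_rate = 5e-3)
  tr <- simulate_molecules(cfg)
  r1 <- amplify_and_sequence(tr, cfg)
  r2 <- amplify_and_sequence(tr, cfg)
  expect_identical(r1, r2)

  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_fastq(f1)
  expect_identical(back$read_id, r1$read_id)
  expect_identical(back$sequence, r1$sequence)
})

test_that("an empty molecule pool cannot be sequenced", {
  cfg <- base_cfg(n_molecules = 0L, variants = NULL)
  tr <- simulate_molecules(cfg)
  expect_error(amplify_and_sequence(tr, cfg), "empty amplified pool")
})

test_that("polymerase errors are barcode-correlated within families", {
  # with only polymerase errors (no sequencing noise), an error present in
  # one read of a family recurs in other reads of the same family far more
  # often than the raw per-base rate would allow independently
  cfg <- base_cfg(n_molecules = 100L, reads_to_sample = 10000L,
                  pcr_cycles = 8L, polymerase_error_rate = 2e-4,
                  sequencing_error_rate = 0, variants = NULL)
  tr <- simulate_molecules(cfg)
  reads <- amplify_and_sequence(tr, cfg)
  lay <- read_layout()
  ins <- substr(reads$sequence, lay$barcode_length + lay$spacer_length + 1L,
                nchar(reads$sequence))
  mism_per_read <- vapply(seq_len(nchar(ref)), function(j)
    substr(ins, j, j) != substr(ref, j, j), logical(nrow(reads)))
  err_reads <- which(rowSums(mism_per_read) > 0)
  expect_gt(length(err_reads), 0)
  # at least one error is shared by >= 2 reads of one family at a position
  pos_fam <- unique(data.frame(
    fam = reads$molecule_id[row(mism_per_read)[mism_per_read]],
    pos = col(mism_per_read)[mism_per_read]))
  dup <- nrow(data.frame(fam = reads$molecule_id[row(mism_per_read)[mism_per_read]],
                         pos = col(mism_per_read)[mism_per_read])) - nrow(pos_fam)
  expect_gt(dup, 0)
})
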