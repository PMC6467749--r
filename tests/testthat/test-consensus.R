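lay <- read_layout()

test_that("barcode extraction recovers simulator barcodes and rejects bad reads", {
  ref <- ref_seq(50, seed = 3)
  cfg <- sim_config("A1", ref, NULL, n_molecules = 40L,
                    reads_to_sample = 400L, pcr_cycles = 4L,
                    polymerase_error_rate = 0, sequencing_error_rate = 0,
                    seed = 5L)
  tr <- simulate_molecules(cfg)
  reads <- amplify_and_sequence(tr, cfg)
  ex <- extract_barcodes(reads, lay, assay_id = "A1")
  expect_equal(nrow(ex$rejected), 0L)
  expect_identical(ex$tagged$barcode, tr$molecules$barcode[reads$molecule_id])
  expect_true(all(nchar(ex$tagged$barcode) == 12L))  # 12-nt default barcode

  # too-short reads are rejected, not fatal
  short <- tibble::tibble(read_id = "s1", sequence = "ACGTA")
  ex2 <- extract_barcodes(short, lay)
  expect_equal(nrow(ex2$tagged), 0L)
  expect_equal(ex2$rejected$reason, "too_short")

  # spacer mismatch > 1 base rejects; exactly 1 mismatch passes
  bc <- strrep("A", 12)
  good <- paste0(bc, lay$spacer, ref)
  sp1 <- lay$spacer; substr(sp1, 1, 1) <- setdiff(c("A","C","G","T"),
                                                  substr(sp1, 1, 1))[1]
  sp2 <- sp1; substr(sp2, 2, 2) <- setdiff(c("A","C","G","T"),
                                           substr(sp2, 2, 2))[1]
  mixed <- tibble::tibble(
    read_id = c("g", "m1", "m2"),
    sequence = c(good, paste0(bc, sp1, ref), paste0(bc, sp2, ref)))
  ex3 <- extract_barcodes(mixed, lay)
  expect_setequal(ex3$tagged$read_id, c("g", "m1"))
  expect_equal(ex3$rejected$reason, "spacer_mismatch")
  expect_identical(ex3$tagged$insert[ex3$tagged$read_id == "g"], ref)
})

test_that("family grouping counts exactly and conserves reads", {
  tg <- tibble::tibble(
    read_id = paste0("r", 1:30),
    barcode = rep(c(strrep("A", 12), strrep("C", 12), strrep("G", 12)), each = 10),
    insert = strrep("T", 20), assay_id = "A1")
  fams <- group_families(tg)
  expect_equal(nrow(fams), 3L)
  expect_equal(fams$size, rep(10L, 3))

  expect_equal(nrow(group_families(tg[0, ])), 0L)

  set.seed(11)
  tg2 <- random_tagged(400, 25, ref_seq(30), noise = 0.05)
  expect_equal(sum(group_families(tg2)$size), nrow(tg2))
})

test_that("family consensus applies the family-size agreement thresholds literally", {
  ref <- ref_seq(40, seed = 9)
  off <- 17L
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, off, off))[1]

  # families of 10-20 reads: variant reported only at 100% agreement
  full <- consensus_family(alt_family(ref, 15, 15, off, alt))
  expect_equal(substr(full$consensus, off, off), alt)
  near <- consensus_family(alt_family(ref, 15, 14, off, alt))
  expect_equal(substr(near$consensus, off, off), "N")
  # all other positions are untouched
  expect_equal(substr(near$consensus, 1, off - 1), substr(ref, 1, off - 1))

  # families > 20 reads: >= 90% reports, below does not
  expect_equal(substr(consensus_family(alt_family(ref, 25, 23, off, alt))$consensus,
                      off, off), alt)   # 92%
  expect_equal(substr(consensus_family(alt_family(ref, 25, 22, off, alt))$consensus,
                      off, off), "N")   # 88%
  # boundary: exactly 90% (27/30) is reported ("at least 90%")
  expect_equal(substr(consensus_family(alt_family(ref, 30, 27, off, alt))$consensus,
                      off, off), alt)
  # a family of exactly 20 reads falls under the unanimity rule
  expect_equal(substr(consensus_family(alt_family(ref, 20, 19, off, alt))$consensus,
                      off, off), "N")
  expect_equal(substr(consensus_family(alt_family(ref, 20, 20, off, alt))$consensus,
                      off, off), alt)

  # families below the minimum size are excluded entirely
  expect_true(consensus_family(alt_family(ref, 9, 9, off, alt))$excluded)
})

test_that("pileup MAF arithmetic and degenerate denominators", {
  ref <- ref_seq(10, seed = 2)
  pu <- manual_pileup(ref, pos = 4, alt = setdiff(c("A","C","G","T"),
                                                  substr(ref, 4, 4))[1],
                      alt_families = 2, informative = 1000)
  expect_equal(pu$maf[[4]], 0.002)

  # position where every family calls N: MAF undefined
  tg <- tibble::tibble(read_id = paste0("r", 1:12),
                       barcode = strrep("A", 12),
                       insert = rep(c("AC", "AG"), 6), assay_id = "A1")
  pu2 <- consensus_pileup(tg, "AT", consensus_rules(min_family_size = 10))
  expect_equal(pu2$informative_families[2], 0L)
  expect_true(is.na(pu2$maf[2]))
  expect_true(is.na(variant_vaf(pu2, 2, "C")))
  # position 1 is unanimous A (non-reference would be counted if present)
  expect_equal(pu2$A[1], 1L)

  expect_error(consensus_pileup(tibble::tibble(
    read_id = c("a", "b"), barcode = strrep("A", 12), insert = "AT",
    assay_id = c("x", "y")), "AT"), "mixed assays")
})

test_that("sparse pileup equals the brute-force oracle on small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    ref <- ref_seq(12)
    n_reads <- sample(20:50, 1)
    tg <- random_tagged(n_reads, sample(2:4, 1), ref, noise = 0.08)
    # spike an alt-unanimous family to exercise variant reporting
    altb <- setdiff(c("A", "C", "G", "T"), substr(ref, 5, 5))[1]
    alt_ins <- ref; substr(alt_ins, 5, 5) <- altb
    tg <- rbind(tg, tibble::tibble(
      read_id = paste0("x", 1:12), barcode = strrep("T", 12),
      insert = alt_ins, assay_id = "A1"))
    pu <- consensus_pileup(tg, ref)
    orc <- oracle_pileup(tg, ref)
    expect_equal(as.matrix(pu[, c("A", "C", "G", "T", "N")]),
                 orc$counts, ignore_attr = TRUE)
    expect_equal(pu$informative_families, orc$informative)
    expect_equal(pu$maf, orc$maf)
    expect_equal(attr(pu, "n_families_passing"), orc$n_passing)
  }
})

test_that("consensus VAF recovers simulated ground truth", {
  ref <- ref_seq(60, seed = 21)
  off <- 30L
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, off, off))[1]
  cfg <- sim_config("A1", ref,
                    data.frame(offset = off, ref = substr(ref, off, off),
                               alt = alt, vaf = 0.01),
                    n_molecules = 5000L, reads_to_sample = 125000L,
                    pcr_cycles = 8L, seed = 31L)
  tr <- simulate_molecules(cfg)
  tg <- extract_barcodes(amplify_and_sequence(tr, cfg), lay, "A1")$tagged
  pu <- consensus_pileup(tg, ref)
  est <- variant_vaf(pu, off, alt)
  v <- tr$variants$realized_vaf
  se <- sqrt(v * (1 - v) / pu$informative_families[[off]])
  expect_lt(abs(est - v), 3 * se)
})

test_that("adding an alt-supporting family never decreases the VAF", {
  set.seed(99)
  ref <- ref_seq(20)
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 8, 8))[1]
  alt_ins <- ref; substr(alt_ins, 8, 8) <- alt
  base <- random_tagged(60, 4, ref, noise = 0.01)
  vaf0 <- variant_vaf(consensus_pileup(base, ref), 8, alt)
  for (i in 1:3) {
    extra <- tibble::tibble(read_id = paste0("e", i, "_", 1:15),
                            barcode = paste0(strrep(c("A","C","G")[i], 11), "T"),
                            insert = alt_ins, assay_id = "A1")
    base <- rbind(base, extra)
    vaf1 <- variant_vaf(consensus_pileup(base, ref), 8, alt)
    expect_gte(vaf1, if (is.na(vaf0)) 0 else vaf0)
    vaf0 <- vaf1
  }
})
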