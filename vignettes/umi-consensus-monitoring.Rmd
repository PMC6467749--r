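---
title: "Barcode-consensus error suppression and ctDNA recurrence monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-consensus error suppression and ctDNA recurrence monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Circulating tumor DNA (ctDNA) is a minority fraction of plasma cell-free
DNA — often well below 1% — so detecting a patient's tumor mutations in a
blood draw requires calling variant alleles at frequencies far below the
raw error rate of PCR and sequencing (~0.1-1% per base).  Molecular
barcoding solves this: a random 12-nt oligonucleotide tags each template
molecule in the early PCR cycles, so all reads descending from one
molecule share a barcode and can be grouped into a *barcode family*.  A
true variant is present in (essentially) every read of its family;
polymerase and sequencer errors appear in only a subset, and are
discarded by a family-level agreement rule.  `umimrd` implements this
whole chain — read simulation, barcode-family consensus, per-base
pileups, patient-specific panel design, plasma positivity calling, and
longitudinal recurrence monitoring — as composable functions over plain
tibbles, exercised entirely on synthetic reads with known ground truth.

## The consensus model

Reads are grouped by exact barcode match per assay.  Families below 10
reads are discarded (too little internal evidence).  Within a retained
family, the consensus base at each position is the allele whose
within-family fraction reaches the applicable threshold:

* families of **10-20 reads**: unanimity (**100%** of reads);
* families of **more than 20 reads**: **at least 90%** of reads
  (inclusive — exactly 90% qualifies).

Positions where no allele qualifies are called `N`.  The rule is
positional: a family can report a variant at one base and be ambiguous at
another.  Because the large-family threshold exceeds 50%, at most one
allele can ever qualify; this uniqueness is asserted, not handled.

Consensus calls are tallied into a per-position pileup: allele counts
over families, *informative families* (non-`N` calls), and the minor
allele frequency (largest non-reference count / informative families).
A variant's VAF is its alt-family count over informative families —
`N` positions drop out of the denominator so that sub-threshold noise
inflates neither allele.  Coordinates are 1-based within the assay
insert, matching VCF convention for the genomic positions they map to.

Why this suppresses errors: a sequencing error hits one read, so its
within-family fraction is ~1/size and never reaches 90%; a polymerase
error in PCR cycle *t* is inherited by about 2^-t of the family, so even
a first-cycle error tops out near 50%.  Only a mutation present in the
founding molecule can be unanimous.

```{r}
library(umimrd)
consensus_family(c(rep("ACGT", 14), "AAGT"))$consensus  # "ANGT": 14/15 < 100%
```

## The simulator

`sim_config()` + `simulate_molecules()` + `amplify_and_sequence()`
generate FASTQ-ready reads with ground truth:

1. each of `n_molecules` founding molecules gets a random 12-nt barcode,
   and its allele at each variant position is an independent Bernoulli
   draw at the true VAF (the realized molecular VAF is recorded — it is
   the oracle for recovery tests);
2. PCR is deterministic doubling for `pcr_cycles` cycles; every copy
   event introduces substitutions at `polymerase_error_rate` per base,
   inherited by descendants.  This is the simplest model that produces
   barcode-correlated early-cycle errors — the failure mode barcoding
   addresses;
3. `reads_to_sample` reads are drawn uniformly from the final pool
   (sampling with replacement; the pool is orders of magnitude larger
   than the sample), each with independent sequencing substitutions at
   `sequencing_error_rate` per base.

Reads are laid out `barcode(12) + constant 6-nt spacer + insert`; the
spacer lets the extractor validate the barcode boundary (reads with >1
spacer mismatch are rejected, counted, not fatal).  Qualities are
constant Q30 symbols because no rule in the pipeline consults them.

Implementation note: the 2^cycles pool is never materialized.  Since
doubling gives every founder equally many descendants, a sampled read is
a uniform founder plus an independent uniform lineage (one branch bit per
cycle); polymerase error events are drawn per founder as
Binomial((2^c − 1)·L, rate), assigned a cycle with weight 2^(t−1) and a
random lineage prefix, and inherited by exactly the sampled reads whose
lineage matches.  This is exact for the stated model, not an
approximation of a different one.

Both error processes act on the insert only.  Barcode-altering errors
would merely create tiny spurious families (removed by the 10-read
minimum) while breaking the invariant that every read's barcode traces
to a founding molecule — the simulator keeps that invariant exact so that
every downstream stage can be tested against ground truth by barcode.

Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `barcode_length` | 12 nt | standard barcoded-amplicon chemistry |
| `pcr_cycles` | 10 | pool ≫ sampled reads; more cycles only shrink each error's footprint |
| `polymerase_error_rate` | 1e-5 /base/cycle | high-fidelity polymerase |
| `sequencing_error_rate` | 3e-3 /base | typical Illumina substitution rate |
| `n_molecules` | (required) | ~300 genome-equivalents per ng of input DNA; 25-50 ng plasma input ≈ 10^4 molecules |

One integer seed in the config drives everything; molecule drawing uses
`seed` and amplification `seed + 1`, so regeneration is byte-identical
per stage and a truth object can be re-sequenced deterministically.

## Panel design and tumor verification

Tumor variant calls (SNVs with VAF, COSMIC membership, location class
and predicted impact) are combined additively:
`score = w_vaf · min(VAF/0.30, 1) + w_cosmic · [COSMIC] + w_loc ·
loc_weight + w_imp · imp_weight`, all weights defaulting to 1, location
weights exonic 1 / splice, UTR, intronic 0.25 / intergenic 0, impact
weights high 1 / moderate 0.5 / low 0.1 / none 0.  The selection
criteria are qualitative — no canonical weights exist — so these
defaults give each criterion at most one point and are configurable.  The VAF term saturates at 30%
because tumor VAFs in this setting typically span 5-30%.  Ties break by
VAF (desc) then position (asc), making the ranking a total order —
permuting the input can never change a panel.  Panels take the top
2-8 candidates ("total number of mutations identified" is read as
governing panel size only, not the score).  A single-candidate patient
yields a panel of one with a warning, not a failure.

Selected mutations are verified by re-sequencing tumor DNA with the same
barcoded assays: verification requires a tumor consensus VAF ≥ 1% — no
standard numeric cutoff exists; 1% sits an order of magnitude above the
plasma threshold and two orders below real tumor VAFs, so it separates
presence from assay failure cleanly.  Patients with zero verified
mutations are ineligible for monitoring.  Visual IGV-style inspection of
variant sites is replaced by an accept-all automated filter stub (visual
QC is not implementable as an algorithm).  Assays are *short* iff their
target region is strictly below 80 bp — short amplicons recover more of
the fragmented cell-free DNA.

## Plasma calling

A panel mutation is **detected** when its consensus VAF is

* at or above **0.05%** (inclusive: "0.05% or above"), and
* strictly above the assay's **background threshold**.

Background is `max(mean + 3·SD, 0)` of the consensus MAFs at informative
non-panel positions of the same assay — a standard position-noise model,
chosen because "background noise" has no canonical definition for these
assays; with
fewer than 5 informative non-panel positions it falls back to 0 with a
warning.  The 0.1% figure quoted for the method is its validated
detection limit; 0.05% is the reporting threshold applied to calls — the
package keeps them as independent parameters (`vaf_threshold`, and the
detection-limit experiment's simulated VAF).  The 0.05% rule is applied
per mutation, as written, not to a pooled panel-level statistic.

A sample is **positive** when one or more panel mutations are detected.
Positions with zero informative families are *not evaluable* (`NA`),
distinguished from negative: absence of evidence is not evidence of
absence, and longitudinal plots distinguish missing draws from negative
ones.

## Timelines

Days are integers relative to definitive treatment (day 0); the baseline
sample is the latest draw at day ≤ 0.  Clearance is judged on the first
*evaluable* post-treatment sample; molecular recurrence is the first
positive post-treatment sample; lead time is clinical minus molecular
recurrence day (positive = ctDNA first).  Both sign cases are exercised
in the tests: detection 22 days before clinical recurrence (+22), and a
draw 13 days after diagnosed recurrence (−13).  Summary percentages are
rounded half-up to whole percent for display (6/7 → 86%, 15/22 → 68%).

## The synthetic cohort

`simulate_cohort()` writes an 8-patient fixture cohort mirroring the
study's *structure* (all values synthetic): 2-8 assays per patient, one
deliberately long 95-bp amplicon, tumor VAFs 5-30%, one patient whose
candidates fail tumor verification, a baseline-negative early-stage
course whose molecular recurrence precedes clinical recurrence by 156
days, a non-clearing course with +22 days lead, a cleared course that
turns positive 13 days after diagnosed recurrence, and two distant
metastases without plasma signal.  Five recurrence courses are scripted
(three local plus two distant); the cohort is a structural
reconstruction, not data.

Two deliberate departures from assay-realistic magnitudes, both consequences
of depth scaling: the default cohort simulates 2,000 molecules and ~15
reads/family per library (instead of ~10^4 molecules / ~30 reads) to
keep a full 113-library cohort affordable, and scripted shedding VAFs
are 1-3% (instead of the 0.1-0.3% typical of recurrence draws) so
that a "positive" script is unambiguous at that depth — at 2,000
molecules a 0.15% VAF would be absent from the tube entirely in ~5% of
draws, which would make fixture truth stochastic.  The
detection-limit experiment is where the real magnitudes are exercised:
25,000 molecules, ~30 reads/family, sequencing error 0.3%/base, VAF
0.1% vs 0, three replicate seeds each — all-positive / all-negative is
required and achieved.

What passing on this cohort does *not* show about real data: the
simulator draws i.i.d. substitution errors (no context-dependent error
hotspots, no indels, no strand bias, no quality correlation), families
are sampled uniformly (no amplification bias or polymerase stalling),
and barcodes are error-free (no barcode collisions beyond the birthday
rate, no hopping).  Real libraries violate all of these to some degree;
the background model and the verification threshold are the knobs that
absorb such violations, and they are deliberately configurable.

## Numerical choices and degenerate inputs

* Agreement is tested as `count / size >= fraction` — never
  `count >= fraction * size`, which misclassifies the exact-90% boundary
  (0.9 × 30 exceeds 27 in floating point).
* `N` bases in member reads count toward the family-size denominator but
  can never be the consensus allele.
* Empty inputs: an empty read stream gives an empty family table; a
  pileup over zero passing families has all-zero counts and undefined
  MAF everywhere; `variant_vaf` at zero informative families is `NA`,
  and a sample whose calls are all `NA` is itself not evaluable.
* Barcode grouping is exact-match; Hamming-distance-1 merging into a
  unique large neighbour exists behind `merge_single_mismatch = TRUE`
  (default off — exact matching is the conservative reading).
* Duplicate sample days and missing treatment events are errors, not
  warnings: they indicate corrupted clinical tables.

## Problem sizes

The bundled analyses use: 113 libraries of 30,000 reads (cohort
scripts), 750,000-read libraries for the detection-limit experiment,
125,000-read libraries at 5,000 molecules for VAF-recovery checks
(VAFs 0.1%, 0.5%, 1%, 10%, each within 3 binomial SE of realized
truth), and ≤50-read instances for brute-force oracle equivalence of
the consensus caller.  These sizes were chosen so every analysis recomputes
in minutes on one core while keeping ≥ 2 × 10^4 families wherever a
sub-0.1% frequency must be resolved.

## Known limitations

Single-end substitution-only model; no duplex (two-strand) consensus; no
alignment (reads are assay-anchored amplicons); COSMIC membership is an
input flag, not a live query; no survival modelling downstream of the
timelines.  The consensus thresholds implement the reporting rule
literally — including that a family of exactly 20 reads falls under the
unanimity rule — where other barcode-consensus implementations may draw
that boundary differently.
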