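---
title: "Quantifying ctDNA with spike-in-calibrated amplicon sequencing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ctDNA with spike-in-calibrated amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcall)
```

## The measurement problem

Circulating tumor DNA (ctDNA) is a minority species in plasma cell-free DNA:
a clinically interesting sample may contain one mutant molecule per 100,000
wild-type genome equivalents. An assay that physically enriches mutant
sequences before sequencing changes the problem: after enrichment, read
counts no longer reflect input molecule counts, because each mutation is
enriched by a large and imperfectly known factor and the sequencing run
divides its depth unevenly across amplicons and samples. `panelcall`
implements the data-analysis half of such an assay for a fixed 46-mutation
hotspot panel (*BRAF*, *EGFR*, *KRAS*, *PIK3CA*), and its core idea is
calibration by **internal positive controls (IPCs)**: synthetic molecules of
each mutant sequence, each tagged with a random identifier, spiked into every
sample at a known copy number before amplification. Whatever the process does
to mutant molecules it also does to IPCs, so the observed IPC read counts
measure the end-to-end *cluster yield* per founder molecule, and dividing
mutant read counts by that yield recovers absolute input copies.

## Pipeline model

For each sequenced pool the pipeline performs, in order:

1. **Merging.** Forward and reverse reads are merged at their best ungapped
   overlap: the longest overlap of at least `min_overlap` (default 20) bases
   with mismatch fraction at most `max_mismatch_frac` (default 0.1).
   Disagreements resolve toward the higher-quality base, ties toward read 1.
   Pairs with no admissible overlap are counted as merge failures, never
   silently dropped.
2. **Demultiplexing.** The inline 8-base sample barcode (read-1 prefix) is
   matched against the manifest's barcode set within `barcode_max_mismatch`
   (default 1) mismatches. The packaged barcode set has minimum pairwise
   Hamming distance 3, so assignments at this tolerance are unambiguous; the
   precondition (minimum distance > twice the tolerance) is enforced.
3. **Amplicon assignment.** Each barcode-stripped cluster is assigned to the
   amplicon with the smallest Levenshtein distance, computed with the
   amplicon's IPC identifier span treated as a wildcard — that span carries a
   random N-mer on IPC molecules by design, so its bases carry no alignment
   information. Clusters whose best distance exceeds
   `max_edit_frac * length` (default 0.3) stay unaligned. The default
   `"screen"` method shortlists amplicons by forward-primer prefix distance
   before computing edit distances; with distinct primers it returns the
   exhaustive answer at a fraction of the cost, and both methods are checked
   against an independent dynamic-programming oracle in the test suite.
4. **Classification.** For each mutation on the assigned amplicon, a cluster
   carries that mutation when it matches the mutant amplicon sequence exactly
   over a window of `flank_match` (default 10) reference bases on each side
   of the alt allele. With a non-reference identifier span it is an IPC of
   that mutation; with a reference span it is a mutant (MUT); matching the
   reference at every variant locus makes it wild-type (WT); anything else —
   including an alt allele with divergent flanks, the signature of chimeric
   or mis-merged clusters — is conservatively UNASSIGNED. Complex *EGFR*
   exon-19 deletions are represented as plain
   `(offset, ref_allele, alt_allele)` replacements so one code path
   classifies all 46 mutations; a cluster carrying two panel mutations on one
   amplicon is counted once per mutation, since all quantitation is
   per-mutation.
5. **Identifier collapse.** Sequencing errors inside the identifier create
   spurious low-abundance identifiers one base away from a real founder.
   These are absorbed by the directional rule standard for unique molecular
   identifiers: identifier *a* merges into *b* when they differ at one base
   and `count(b) >= 2 * count(a)`. A symmetric "merge into any more abundant
   neighbour" rule was rejected because two genuine founders can be sequence
   neighbours with comparable abundance; the directional ratio leaves such
   pairs intact while still absorbing error singletons.
6. **Quantitation.** For mutation *m* in sample *s*, with mutant cluster
   count `C` and IPC bins (unique identifier x barcode x mutation
   combinations) totalling `T` clusters over `B` bins:
   * yield `Y = T / founders`, where `founders` is `B` corrected upward for
     founders that produced no cluster (zero-truncated Poisson inversion of
     the mean bin size `T/B`) and for identifier collisions (inversion of
     the expected-distinct-identifier curve `K(1 - (1 - 1/K)^s)`,
     `K = 4^identifier_len`), capped at the known spike-in count. The naive
     uncorrected mode (`correct = FALSE`) is also available because it is
     unknown whether the original analysis corrected;
   * input copies `N = C / Y`; zero IPC clusters make the yield — and all
     downstream quantities — *missing*, never zero;
   * abundance `A = 100 * N / G` percent, with `G` the input genome
     equivalents, from DNA mass at 3.3 pg per haploid genome
     (config-overridable) or supplied directly. IPCs are synthetic spike-ins
     and are excluded from `G`;
   * plasma normalization `N * 5 / plasma_ml` copies per 5 mL.
7. **Calling.** Per-mutation limits of detection come from wild-type
   background runs: `LOD = max(100 / G_standard, mean + 3 * SD)` of the
   background abundance (sample SD, n−1 denominator, at least two runs, per
   mutation rather than pooled — the published per-mutation LODs imply
   heterogeneous backgrounds). A mutation is positive only when
   `N >= 1` **and** `A > LOD` (strict, following "greater than"); mutations
   with missing yield are reported "not evaluable", never negative, and the
   raw margin `A - LOD` is always reported so near-LOD signals remain
   inspectable.

## The simulator

`simulate_sample()` generates the study conditions so the whole pipeline is
testable without the instrument. Founder molecules are wild-type (one per
amplicon per genome equivalent), mutants at exactly the configured copy
numbers, and IPCs with per-founder random identifiers. Each founder is
amplified to `2^pcr_cycles_pre` molecules (default 10 cycles — a limited
pre-enrichment amplification); each amplified molecule independently survives
`enrich_cycles` (default 20) enrichment cycles with probability `retain_mut`
(default 0.9, mutant and IPC molecules) or `retain_wt` (default
`0.9 * 10^(-4/20)`), so the expected enrichment factor is
`(retain_mut/retain_wt)^enrich_cycles = 1e4`, the scale implied by a
single-copy detection limit at 100,000 genome equivalents. Reads are drawn
from the surviving pool, substitution errors are applied per read at the
accumulated per-lineage rate `1 - (1 - per_base_error_per_cycle)^cycles`
(default per-cycle rate 1e-4, lumping polymerase and readout error), and
read pairs cover each molecule from both ends with a guaranteed overlap.
Every sample carries a full founder-level ground-truth table, and runs are
byte-reproducible from the seed.

What the simulator deliberately does **not** model: polymerase indel errors
and stutter, chimera formation, quality-score miscalibration (qualities are
constant), amplification efficiency bias between amplicons, jackpot errors
from early PCR cycles (errors are independent per read, so clonal error
structure is absent), and the physics of the enrichment device (retention is
phenomenological). Passing tests therefore demonstrate that the *analysis* is
correct and calibrated under a clean generative model; they do not
demonstrate robustness to those wet-lab artifacts on real instrument data.

## Numerical and design choices

* **Yield inversion.** The zero-truncated Poisson mean equation
  `lambda/(1 - exp(-lambda)) = T/B` is solved by `uniroot` to 1e-10; `T = B`
  (all singleton bins) maps to `lambda -> 0`, where the dropout correction
  diverges — the spike-in cap makes this safe. Founder estimates are capped
  at the known spike-in count because error-derived bins can otherwise push
  the estimate above the number of molecules actually added.
* **Tie-breaks.** Equal edit distance to two amplicons resolves to the
  lexicographically smallest amplicon id and is flagged.
* **Degenerate inputs.** Zero requested depth yields empty FASTQ and a valid
  truth table; an empty mutation table is a valid panel; empty cluster sets
  produce empty bins; a single background run is an error (SD undefined)
  rather than a silent zero.
* **Synthetic references.** The assay's true primer and amplicon sequences
  are not public, so packaged amplicons are seeded random sequences with
  every mutation's reference allele pinned at its offset (conflicting
  overlapping pins are an error). The packaged FASTA is regenerable
  bit-identically with `synthesize_references(seed = 7)`; the catalogue
  itself (mutation names, genes, published LODs) is the assay's published
  table. The identifier length and span are panel parameters (default: 8
  bases, placed between the forward primer and the first variant locus).

## Detection exactly at the single-copy limit

With a clean background the LOD equals the single-copy allele fraction
`100/G`, and the call rule requires abundance strictly above it. The
IPC-calibrated estimator is unbiased, so for a sample containing *exactly
one* mutant copy the copy estimate is centred at 1 and the positive-call
probability is approximately the probability that a Poisson-like count
exceeds its own mean — about one half, by construction, independent of
depth, spike-in level or enrichment factor. This is the standard behaviour
of any unbiased detector at its own decision boundary: the single-copy LOD
is the *limit* of detection, not a level of reliable detection. From two
input copies upward the estimate clears the threshold by several standard
deviations and calls become essentially deterministic, which is what the
test suite asserts; a characterization requiring majority detection of
exactly one copy under this call rule cannot be satisfied, and the package
documents that fact rather than hiding it by relaxing the strict inequality.

## Problem sizes used by the test suite

The suite runs everything at desk scale: unit tests use a two-amplicon
panel with a few thousand reads per sample; the titration-recovery check
uses 10/100/1000 input copies with 20 replicates at 4,000 reads; the
specificity check simulates 47 wild-type samples at 10,000 reads against an
8-run background; the single-copy experiment uses the full 46-mutation panel
at 100,000 reads per replicate. These sizes keep each property statistically
decidable (recovery tolerances are set at 3 standard errors or 10% of truth)
while the whole suite completes in minutes.

## Known limitations

* Yield correction assumes clusters per founder are exchangeable Poisson
  draws; true per-founder intensities vary with enrichment survival, which
  makes the dropout correction slightly approximate (the titration tests
  bound the net bias well inside 10%).
* Classification requires exact window matches, so clusters with an error
  near the variant lose their label; mutant and IPC clusters lose
  symmetrically, which cancels in the copy estimate, leaving only a small
  conservative residual (mutant clusters with an error inside the identifier
  span are binned as IPCs).
* Multi-sample pools are processed as one read set; per-sample error
  profiles are not modelled.
* The concordance and monitoring reports operate on call tables; the
  packaged 19-patient comparison fixture covers the tissue qPCR worked
  example only.
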