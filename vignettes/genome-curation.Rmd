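---
title: "Transposon mining, repeat cataloguing and map-guided curation of a draft plant genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transposon mining, repeat cataloguing and map-guided curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inilcurate)
```

## Scope and model

`inilcurate` implements the curation layer that turns a scaffolded draft
plant assembly into an annotated, chromosome-scale release, modelled on
the finishing of the Japanese morning glory (*Ipomoea nil*) genome. Four
analysis stages share one set of containers (a `DNAStringSet` assembly,
0-based half-open interval tables, marker tables):

1. **Tpn1/CACTA transposon mining.** Class-II CACTA elements are
   delimited by ~28-bp terminal inverted repeats (TIRs), flanked by a
   3–5-bp target-site duplication (TSD) created on insertion, and carry
   sub-terminal repetitive regions (SRRs; tandem 122-bp units near the
   5′ end, 104-bp units near the 3′ end) that are *cis*-requirements
   for transposition. The miner scans both strands for seed TIRs by
   ungapped Hamming matching, pairs convergent hits into candidate
   spans, validates a duplicated target site on the flanks, assesses
   the SRRs, and classifies each element as putatively active (both
   SRRs intact) or rearranged/inactive.
2. **Tandem-repeat landscape.** Monomer-seeded detection of telomeric
   (`AAACCCT`), centromeric (~173-bp monomer) and rDNA arrays, with the
   cataloguing rules used for chromosome-scale assemblies: telomere
   status per scaffold end, centromeric stretches > 3 kb merged within
   50 kb and the longest stretch per chromosome reported, 18S–5.8S–25S
   units chained into nucleolar organizer regions (NORs), and 5S
   copies clustered separately.
3. **Map-guided curation.** An F2 genotype matrix is filtered by the
   80/80 call-rate rule and a 150-bp flank-repeat screen; scaffolds
   whose markers point to two linkage groups are split at the
   intervening assembly gap (or in three parts at contig level, where
   the middle part remains chimeric); surviving scaffolds are ordered
   and oriented along each linkage group into pseudo-chromosomes with
   AGP v2.0 output.
4. **Assembly QC.** N50/L50 statistics, BAC-end paired best-hit scoring
   (combined-score maximisation under an inward-facing, bounded-insert
   constraint), and EST coverage summaries.

A fifth, first-class module — the **synthetic forge** — generates
genomes with planted features and exact truth tables so that each stage
is testable at desk scale.

## Matching model and parameters

The TIR/SRR searches in the original study used BLAST with unstated
parameters. Here matching is a deterministic ungapped Hamming scan
(`Biostrings::matchPattern` with `max.mismatch`, no indels), which is
oracle-checkable and fully adequate for 28-bp seeds. Parameters that
matter, with defaults:

* `max_mismatches = 3` of 28 TIR bases. A 28-mer within 3 mismatches of
  a random background occurs with probability ~1e-12 per offset, so
  genome-scale false TIR hits are negligible.
* `min_span = 60`, `max_span = 50000` bases for TIR pairing, bracketing
  the family's observed 161–40,619 bp extremes.
* TSD preference: exact 5-mer, then exact 4-mer, then exact 3-mer, then
  3-mer with one mismatch. This reproduces the observed regime (almost
  all TSDs 3 bp, rare 5 bp, a minority mismatched) without inflating
  long TSD calls by chance.
* SRR window `subterminal_window = 600` bases at each element end;
  `present` needs ≥ 2 tandem copies at ≤ 10% per-unit divergence on the
  expected orientation, copies that are too few or inverted give
  `rearranged`, none give `absent`. The window is clipped to the whole
  element span rather than half of it: a minimal intact element
  (two 28-bp TIRs plus 2×122 + 2×104 SRR bases ≈ 520 bp) would lose
  part of an SRR block to a half-span clip and be misclassified; with
  full-span clipping the two windows may overlap on short elements,
  which is harmless because each is searched for a different unit.
* Overlapping candidate spans are resolved greedily: lowest total TIR
  mismatches, then lowest TSD Hamming distance, then longest span,
  then leftmost. Accepted elements never overlap.

Tandem-array detection is monomer-seeded rather than a de-novo repeat
finder: all downstream cataloguing rules start from a known monomer,
and a seeded detector is exactly reproducible. Any rotation of the
monomer is found (a phase-shifted array contains the monomer as a
substring across unit boundaries), boundaries are extended while the
sequence continues the monomer phase, and copy number is reported
fractionally as span / monomer length. At an array boundary a few
background bases may continue the phase by chance (probability 1/4 per
base), so detected spans can exceed planted spans by a couple of bases
— never by a full monomer — and truth-recovery checks use a one-monomer
tolerance. Period inference for unknown monomers minimises the
normalised self-alignment mismatch fraction over lags, taking the
smallest lag within 0.01 of the optimum so that harmonics of the true
period cannot win by noise, and giving up (no periodicity) above a 0.25
mismatch fraction.

Chimera detection requires `min_block = 2` consecutive markers per
linkage-group block, so an isolated mis-mapped marker flags a scaffold
but never splits it. When several gaps lie between two blocks the
longest (leftmost on ties) is taken as the junction. Contig-level
(gap-free) transitions are split in three, the middle part retaining
the unknown junction; BAC-end anchors may tighten, but never override,
the marker block edges. Scaffold orientation in pseudo-chromosome
construction uses the sign of the Kendall concordance between marker
genome position and cM; scaffolds with fewer than two informative
markers, or tied concordance, are included unoriented (kept forward and
flagged). Joins use 100 Ns by default. The 80/80 filter iterates
marker-then-sample dropping to a fixed point, since removing a poorly
genotyped sample can rescue a marker.

BAC-end pairing defines "combined score" as the sum of the two hits'
native scores (bit score for BLAST-6 input, residue matches for PAF)
and requires inward-facing hits with an insert of at most 400 kb (4×
the expected ~100 kb BAC insert). Because the headline same-scaffold
percentage can be read with two denominators, both are reported: over
pairs with both reads aligned and over all pairs.

## What the forge emulates, and what it does not

The forge draws random background at a configurable base composition
(default 32/18/18/32, a plant-like AT-rich genome) and plants:

* **Elements** with the full anatomy TSD + TIR + SRR×k + interior +
  SRR×k + TIR + TSD, on either strand, lengths log-uniform over
  161–40,619 bp — a distribution whose mean (~7.3 kb) sits near the
  observed family average of ~7 kb. An intact element's fixed parts
  (two TIRs, two SRR blocks of at least two units) sum to ~520 bp, so
  draws below that are raised to the structural minimum; only
  SRR-rearranged elements can reach the short end of the range.
  Rearranged elements carry an inverted 3′ SRR block. TSD bases are
  drawn with P(A) = P(T) = 0.316, P(C) = P(G) = 0.184, back-solved so
  that a 3-bp TSD contains at least one A/T with probability
  1 − 0.368³ ≈ 0.95. Elements are laid out at least 50,020 bp apart
  (just above the pairing `max_span`): two closer elements could, with
  ~2% probability per pair, present coincidentally compatible flank
  TSDs, making the nomination of a spurious cross-element span
  well-formed and exact truth recovery ill-posed. Real genomes do
  contain nested and adjacent elements; resolving those is beyond what
  planted-truth testing can certify and is a known limitation.
* **Telomeric arrays** at scaffold ends, **centromeric arrays** (one
  per chromosome, fresh random ~173-bp monomer, 2% per-base unit
  divergence), and **rDNA** NOR units plus a 5S cluster, with
  component-labelled alignment tables as the rDNA detector input.
* **Chimeric scaffolds** joining half of one chromosome to half of
  another across an N gap (or directly, for contig-mode events), with
  linkage markers on both sides and exact junction truth.
* **F2 genotypes** under the Haldane map function
  r = (1 − e^(−2d))/2 (no interference; the minimal standard model for
  testing map logic), genotypes in the Mendelian 1:2:1 regime with
  configurable missingness.
* **BAC-end pairs** with inserts from a positive-truncated
  Normal(100 kb, 10 kb), inward-facing, optionally displaced
  cross-scaffold.

Each feature class draws from its own RNG stream derived from the
master seed, so enabling telomeres never moves planted element
positions, and output is byte-identical across runs for a fixed
configuration. The forge does **not** emulate read-level error,
RepeatMasker-scale repeat proportions of a real plant genome (~63%
repetitive in morning glory), sequence similarity between element
interiors (captured host fragments), or segregation distortion —
passing planted-truth tests therefore certifies the bookkeeping and the
detection rules, not performance on the full complexity of real
repeats.

## Numerical and degenerate-input conventions

* All internal coordinates are 0-based half-open; GFF3 and AGP are
  1-based inclusive, converted only at read/write.
* Lowercase (soft-masked) sequence is preserved on I/O and treated as
  ordinary sequence by every matcher; N never matches a seed base.
* Gap runs shorter than `min_gap_len = 10` are not split candidates.
* An empty element catalog reports count 0 with a `ratios_undefined`
  flag instead of NaN ratios; a marker table filtered to nothing warns
  and flags rather than errors.
* A scaffold still carrying markers of two linkage groups at
  pseudo-chromosome stage is a hard error: chimera resolution must run
  first.
* Ties in overlap resolution, gap choice and orientation are broken
  deterministically (documented above), so every pipeline stage is
  reproducible bit-for-bit.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the full pipeline on a
forged 5-Mb genome (5 × 1 Mb chromosomes) with 50 intact and 5
rearranged planted elements; oracle-equivalence checks cover 100 random
50-kb sequences against an exhaustive sliding-window scan; the chimera
suite plants 10 gap-junction chimeras among 20 clean 50-kb scaffolds;
TSD composition uses 2,000 draws; recombination uses 200 progeny (400
gametes) at a 10-cM interval; BAC pairing uses 500 simulated pairs.
These sizes give tight binomial bounds (e.g. 3σ ≈ 0.015 for the TSD
fraction) while a full run stays around a minute.

## Worked example

```{r example, eval = FALSE}
cfg <- forge_config(seed = 11, n_chromosomes = 5,
                    chromosome_len = 1e6,
                    tpn = list(n_intact = 50, n_rearranged = 5))
fg <- forge_genome(cfg)
catalog <- nominate_elements(fg$assembly, fg$tir_seeds, fg$srr_seeds)
catalog
#> tpn_catalog: 55 elements (mean 6109 bp, range 518-30370 bp;
#>   5 rearranged, 0 in genes)
```

The catalog's spans and activity classes match `fg$truth` exactly; see
`tests/testthat/test-acceptance.R` for the full recovery check and
`scripts/acceptance.R` for the reproducible summary report.

## Known limitations

* TIR matching is substitution-only; a TIR disrupted by an indel is
  missed (the seeded-search design shares this property with the
  original BLAST-based screen at high identity).
* Transposase (TnpA/TnpD) content is a catalog flag to be populated
  from user-supplied translated-search hits; no translated aligner is
  included.
* The monomer-seeded array detector cannot discover a novel satellite
  without a seed or a periodic window for `infer_monomer()`.
* The contig-level split places boundaries at marker/anchor positions;
  the middle part is guaranteed to contain the junction but its length
  depends entirely on marker density.
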