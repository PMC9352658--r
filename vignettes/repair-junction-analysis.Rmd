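---
title: "Characterizing Cas9 repair junctions and the TMEJ deletion signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing Cas9 repair junctions and the TMEJ deletion signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmejscan)
```

## The problem

A chromosomal double-strand break induced by Cas9 is repaired by competing
pathways that leave distinguishable sequence scars. Nonhomologous end joining
(NHEJ) produces small indels, most characteristically a +1 insertion at the
cut. Polymerase theta-mediated end joining (TMEJ) requires 5'-to-3' end
resection and produces deletions whose boundaries fall on short (2-6 bp)
repeated sequences flanking the cut — microhomology-mediated deletions
(MHDs) — as well as templated insertions (TINS) copied, directly or
inverted, from sequence near the break. Because MHDs are also made at some
rate by other pathways, the defining evidence that a junction carries a TMEJ
contribution is *differential depletion*: its abundance drops in
Polq-deficient cells.

`tmejscan` implements the computational side of this analysis: junction
reconstruction from amplicon sequencing reads, identification of the
Polq-depleted deletion signature with false-discovery control, pathway
classification and subtraction-based contribution estimates, and the
arithmetic of the accompanying qPCR/ddPCR assays (signature quantification,
exonuclease-sensitivity resection fractions, gene targeting, clonogenic
survival). A synthetic-data generator produces every input with known ground
truth, so the whole pipeline is testable without any sequencing data.

## Junction reconstruction

Reads are expected to be single merged sequences spanning the junction
(paired-end merging, if any, is upstream of this package). The library
layout is `6 bp barcode + 1-8 bp spacer + forward primer + template`;
`trim_reads()` anchors each read at an exact primer match within the
barcode+spacer window, records the barcode (exact-match demultiplexing, no
error correction), and removes everything through the primer.

`call_junctions()` reconstructs the repair junction of each trimmed read
against the reference amplicon by **exact anchor matching**: scanning
outward from the cut site for an upstream and a downstream anchor of
`anchor_length` (default 10) nucleotides whose reference placements minimize
the total deletion `del_left + del_right`. Coordinates are 0-based,
half-open; `cut_site` stores the resolved blunt-cut coordinate (the number
of bases left of the cut), not the PAM.

Details that pin down the reconstruction uniquely:

* Anchor k-mers are searched in the read with overlapping occurrences
  allowed. The upstream anchor takes its **leftmost** occurrence and the
  downstream anchor its **rightmost**: a read's own flank always precedes
  (follows) any templated copy of flanking sequence inside an insertion, so
  these choices pick the true flank match even when the insertion contains a
  copy of an anchor.
* Anchors must not overlap in the read; the insertion is the read sequence
  strictly between them.
* Among decompositions with minimal total deletion, the caller prefers the
  shortest insertion, then the largest `del_left`.
* For clean deletions, the **microhomology** is the sequence shared by the
  two deletion boundaries (the number of registers over which the junction
  can slide), computed by extending boundary identity in both directions and
  capped at the deletion length. The deletion is then canonicalized by
  left-aligning it, so all registers of the same physical event collapse to
  one `junction_key` (`del_left:del_right:insertion`). Events carrying both
  an insertion and a deletion get microhomology 0: the overlap between
  anchor matches is empty whenever intervening sequence exists.

An independent brute-force enumeration of *all* anchor placements (in the
test suite) agrees with this search on 100% of 500 randomly constructed toy
locus/read cases, including unalignable reads.

Two exclusion filters follow, applied to the reconstructed junction region
(the read between the outer anchor ends):

* **Ambiguity**: any IUPAC ambiguity code (N, W, S, R, K, or any other
  non-ACGT base) in the junction region excludes the read
  (`AMBIGUOUS_BASE`).
* **Substitution artifact**: a read that is colinear with the reference
  across the junction (called insertion length equals called deletion
  length) and carries an isolated substitution 3-10 nt from the break —
  distances measured in reference coordinates, on either side — with both
  adjacent bases matching the reference, is consistent with polymerase error
  during amplification and excluded (`SUBSTITUTION_ARTIFACT`). Genuine clean
  deletions are never colinear, so this filter cannot remove them. Two
  adjacent substitutions fail the neighbor condition and are retained.

Filters commute: ambiguity takes precedence, and each filter's predicate is
computed independently of the other's outcome. Reads failing any filter are
excluded from both numerator and denominator of all downstream fractions.
Reads with no exact anchor pair on one or both sides are `UNALIGNABLE` and
likewise excluded (the attrition table on each `junction_table` records how
many).

## The TMEJ signature and classification

`tmej_signature()` tests every deletion-only junction (positive deletion,
empty insertion) for depletion in the Polq-null condition. The per-junction
test is a **one-sided exact conditional test** on the pooled 2x2 table
(junction count vs all other repair reads, wild type vs null), i.e. the
hypergeometric tail probability; replicates are pooled by summing counts
(no dispersion model — a deliberate simplification for sparse junction
counts). The Benjamini-Hochberg step-up rule at FDR 10% defines the
signature set. One-sided p-values are used because only depletion is
evidence of TMEJ; insertion-bearing junctions (including TINS) are not
admitted to the signature, per its deletion-only definition.

`classify_junctions()` assigns `TMEJ` to signature members (membership takes
precedence: a 4 bp deletion that is significantly Polq-depleted counts as
TMEJ), then `NHEJ` to junctions with total indel length (deletion +
insertion) below 5 bp and microhomology below 2 bp, and `OTHER` to the rest
(large indels, templated insertions, long-microhomology deletions without
significant Polq dependence). Per-sample class fractions are computed over
all PASS repair reads and sum to 1; `tmej_contribution()` reports signed
percentage-point differences against a designated calibrator condition
(canonically vehicle-treated wild type), so the three deltas of any
condition sum to 0.

## Assay arithmetic

* `relative_signature()`: delta-delta Ct with a fixed amplification
  efficiency of 2 (perfect doubling; standard-curve fitting is out of
  scope). The result is invariant to adding a constant to every Ct.
* `spike_in_normalized_tmej()`: extrachromosomal TMEJ joining efficiency
  normalized by the NHEJ spike-in control, as a fraction of the calibrator
  pair; invariant to common transfection-efficiency scaling.
* `poisson_concentration()`: the ddPCR estimator
  `lambda = -ln(1 - positives/total)`. Wells measuring one quantity are
  merged by summing positives and totals *before* the transform (the
  merged-well estimator), not by averaging per-well lambdas.
* `ssdna_fraction()`: resected fraction past a flank distance as the drop of
  the reference-normalized flank ratio after exonuclease I treatment,
  `(lambda_flank/lambda_ref)_mock - (lambda_flank/lambda_ref)_exoI`. Ratios
  are normalized per treatment before subtraction, making the estimate
  invariant to rescaling droplet counts. Negative sampling noise is clamped
  to `[0, 1]` with a logged message, since the true fraction is
  non-negative; at small true fractions this clamping biases single-well
  estimates upward, which is why distal flank distances should be measured
  with several merged technical-replicate wells.
* `psti_resistant_fraction()`: the restriction-resistance variant
  (`lambda_flankPstI/lambda_ref` on PstI-digested DNA) recovers the same
  resected fraction.
* `broken_deleted_fractions()`: `1 - lambda_intact/lambda_ref` and
  `1 - lambda_flank_mock/lambda_ref`, clamped.
* `gene_targeting_fraction()` and `clonogenic_survival()`: the band
  intensity and plating-efficiency ratios.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuned per run.

`make_locus()` builds a random 240 bp amplicon with the cut at one third of
its length (so a 150 nt read from the forward primer retains a downstream
anchor even after a 30 nt templated insertion), planting five microhomology
pairs of lengths 4, 3, 5, 2, 6 bp at fixed offsets flanking the cut. The
construction is verified by scan and resampled until it holds: every 10-mer
in the amplicon is unique (anchors are unambiguous), each planted repeat is
maximal (the microhomology is exactly as planted), and each planted deletion
junction is its own minimal-deletion reconstruction. The first and last
20 bp serve as primers.

`simulate_reads()` draws read classes from a mixture whose default is
calibrated to a wild-type vehicle-treated experiment: 35% intact reads, and
among repair reads 19% MHD (spread over the five planted junctions), 42% +1
insertions, 21% small (1-4 bp) no-microhomology deletions, 5% templated
insertions (5-30 nt copied directly or inverted from within 50 nt of the
cut), and 13% long (5-40 bp) no-microhomology deletions. Candidate
deletions whose junction admits a smaller-deletion reinterpretation through
accidental flank homology are rejected and redrawn, so every truth record is
the minimal-deletion reconstruction of its read. Substitution errors are
injected at 1e-3 per base (typical post-filter short-read accuracy) and one
ambiguity base per read at 2e-3; read length is fixed at 150 nt from the
forward primer (a single-end stand-in for merged reads), and base qualities
are not modeled.

`simulate_two_conditions()` multiplies the Polq-dependent class
probabilities (`mhd`, `tins`) by a depletion factor in the null condition
and re-channels the lost mass to the NHEJ classes. The default factor is
12.7/19 ~ 0.67: the residual abundance of signature deletions observed in
Polq-deficient cells, reflecting that these products are also made by other
pathways. `scale_tmej_mixture(..., classes = "mhd")` emulates conditions
(e.g. PARP inhibition) in which signature deletions drop and NHEJ rises
while the "other" fraction is unchanged. `simulate_junction_table()` is the
count-level twin (multinomial draws over a fixed junction panel), used where
read-level detail is irrelevant, e.g. null calibration of the depletion
test. `simulate_ddpcr()` and `simulate_qpcr()` generate droplet-count and
Ct tables from programmed truths.

What the generator does *not* emulate: PCR amplification bias and chimeras,
quality-score structure, paired-end artifacts, indel sequencing errors, and
junctions lacking exact 10 nt anchors. Passing tests therefore demonstrate
correctness of the reconstruction and statistics under the stated error
model, not robustness to every artifact of real libraries.

## Validation design and problem sizes

The test suite validates, at sizes chosen to keep the full run around a
minute:

* **Oracle equivalence** — 500 random toy locus/read cases against a
  brute-force enumeration of all anchor placements; exact agreement
  required.
* **Parameter recovery** — an end-to-end two-condition run (10,000 reads
  per condition, depletion factor 0.25, FDR 10%) must recover at least 90%
  of planted TMEJ junction keys into the signature and reproduce the class
  fractions within binomial 95% bounds of the generating mixture. This run
  disables error injection: the binomial-bound comparison is derived from
  the generative model and is exact only for uncorrupted reads, while error
  handling is validated separately by the filter checks. (With the default
  1e-3 error rate the same run shifts roughly 1-3 percentage points of
  repair reads into `OTHER` via corrupted junction keys — visible, and
  expected, in the study-condition numbers reported by
  `scripts/acceptance.R`.)
* **False-discovery control** — 200 count-level null simulations (both
  conditions drawn from the same 60-key junction panel, 5,000 repair reads
  each); the mean realized false-discovery proportion must stay within
  Monte-Carlo error of the nominal 10%. The exact conditional test is
  discrete and conservative, so the realized rate sits well below nominal.
* **Filter performance** — every isolated substitution read at distances
  3-10 nt (both sides, all alternative bases) must be excluded; no clean
  junction read may be.
* **ddPCR estimator** — mean lambda over 500 seeds of 20,000-droplet wells
  at lambda = 0.5 within 1%; resection fractions recovered within
  Monte-Carlo confidence of programmed truths.
* **Closed forms** — delta-delta Ct, gene targeting, clonogenic survival,
  and BH step-up on worked examples.

## Numerical and design choices

* Anchor length 10 nt, exposed as a locus parameter; no support for
  junctions lacking exact anchors (no general-purpose aligner).
* Tie-breaks in the caller (shortest insertion, largest `del_left`,
  leftmost/rightmost anchor occurrences, left-aligned registers) make the
  reconstruction deterministic; the brute-force oracle implements the same
  definitions independently.
* Deletions lying entirely to one side of the cut are representable only as
  deletion+insertion events; Cas9 repair junctions span the cut, so this is
  immaterial in practice.
* The substitution-artifact window (3-10 nt) is measured in reference
  coordinates; read and reference coordinates coincide on the colinear
  reads the filter targets.
* Fractions are clamped to `[0, 1]` with a logged message; clamping is a
  sign of sampling noise, not of model failure.
* Replicate junction tables are pooled by summing; technical-replicate
  assay values are aggregated by mean.
* All randomness flows through explicit `seed` arguments; generators save
  and restore the caller's RNG state.

## Limitations

Beyond the generator's simplifications listed above: the depletion test
ignores replicate-to-replicate dispersion (a junction with strong
between-replicate variability can reach significance more easily than a
dispersion-aware model would allow); barcode demultiplexing is exact-match
only; the signature is locus-specific and should be re-derived per locus
and experiment; and subclassification of `OTHER` (e.g. Polq-independent
alternative end joining) is out of scope.
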