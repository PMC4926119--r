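---
title: "Methods: small RNA processing, hairpin prediction, and differential miRNA calling in mirweed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA processing, hairpin prediction, and differential miRNA calling in mirweed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mirweed` implements a complete small RNA (sRNA) sequencing analysis for
miRNA discovery and differential expression in a herbicide-resistance
setting: one sensitive weed pool against three resistant pools, one
pooled library each. This vignette explains the models and procedures,
the parameters that matter, the synthetic-data generator that stands in
for real libraries, and the numerical and design choices the package
makes where the procedure left room.

## Read cleaning and accounting

Raw reads are insert + 3′ adapter (+ downstream bases). The trimmer
reports the leftmost position at which at least 8 nt of the adapter
prefix align with at most one mismatch, and keeps the prefix before it.
A read without a match is kept whole when it is already ≤ 30 nt (the
adapter may simply not have been reached) and otherwise carries no
recoverable insert.

Each read is then assigned to exactly one outcome, in a fixed order:

1. `low_quality` — mean base quality of the insert < 20,
2. `n_read` — insert contains an N,
3. `too_short` — insert < 18 nt,
4. `too_long` — insert (or matchless raw read) > 30 nt,
5. `clean`.

Two readings of "base quality < 20" were possible (any base vs. the
read mean); the package reads it as *mean* insert quality, the common
sRNA-pipeline default, configurable via `min_quality`. The fixed
precedence makes the outcome categories disjoint, so the accounting
identity `clean = total − low_quality − n − short − long` holds exactly
and is asserted, not assumed. Matchless long reads are binned as
`too_long` rather than given their own category, keeping the summary to
the conventional five columns. Cleaning is per read, so the statistics
are invariant to input order.

Clean reads collapse to *unique tags* (distinct sequences with
per-library read counts); per-library tag-count sums equal the clean
totals by construction and are tested.

## Category annotation and conserved miRNAs

Unique tags are annotated against per-category reference sets (rRNA,
tRNA, snRNA, snoRNA; then mature miRNAs) by an exhaustive ungapped
Hamming scan: the full tag against every equal-length reference window.
At tag lengths of 18–30 nt with ≤2 mismatches this is exact and strictly
stronger than a heuristic seeded aligner, and it removes the external
BLAST dependency. Non-coding RNA sets are scanned on both strands with 0
mismatches by default (degraded fragments are exact substrings);
mature-miRNA matching allows 2 mismatches and ±2 nt length difference
(isomiR ends), both configurable.

Each tag is assigned to the first matching category in a configurable
precedence (default rRNA > tRNA > snRNA > snoRNA > mature miRNA >
unannotated), so category counts per library sum exactly to clean reads;
percentages are `round(100 · count/total, 2)`. Counts are weighted by
read copies by default (`weight = "tags"` counts each unique tag once).
An "intron" class is not modelled; such tags fall to `unannotated`.
Conserved miRNAs are mature-reference hits grouped into families by
their `miR<number>` designation and renamed with a species prefix
(default `bsy-`).

## Hairpin (novel miRNA) prediction

Unannotated tags with ≥ `min_count` supporting reads (default 5 — a
MIREAP-class support requirement that also keeps the scan tractable) are
exact-mapped to the transcriptome on both strands; tags hitting more
than 20 loci are discarded as repeats. Around each locus three candidate
precursor windows are cut (tag ± both flanks, 5′ flank only, 3′ flank
only; flank 150 nt, window capped at 320 nt — typical plant pre-miRNA
scale). Each window is folded and the mature/star duplex is measured; a
candidate is called novel when **all four** criteria hold, with
inclusive bounds because each is stated as a limit:

| criterion | bound | meaning |
|---|---|---|
| precursor MFE | ≤ −20 kcal/mol | stem-loop stability |
| miRNA/miRNA\* common pairs | ≥ 16 | duplex pairing |
| bulges in the duplex | ≤ 4 | interior unpaired runs, both sides |
| duplex asymmetry | ≤ 4 nt | \|unpaired on miRNA side − on star side\| |

One call is made per distinct mature sequence (best-MFE window), and
names `novel-bsy-miR-<k>` are assigned in descending read support, so
calls are invariant to candidate order.

### The folding engine

Structures are pseudoknot-free, pairs are Watson–Crick or G:U, hairpin
loops are ≥ 3 nt. The energy model is a deliberately simplified
nearest-neighbor scheme: stacking free energies for the 21 distinct
WC/G:U stacks (stored as a versioned CSV in `inst/extdata/`, expanded to
the full 6×6 table by the antiparallel symmetry
`stack(p,q) = stack(flip q, flip p)`) plus affine loop penalties —
hairpin `5.4 + 0.15·(L−3)`, bulge `3.8 + 0.45·(L−1)`, internal
`2.6 + 0.4·(L−2)`, multibranch `3.4 + 0.4·branches + 0.1·unpaired`
(kcal/mol, 37 °C nominal). It is *not* Turner 2004: the −20 kcal/mol
gate is calibrated against this table, which is small enough to be
oracle-checkable yet ranks stems sensibly (G:C stacks ≈ −3.3, A:U ≈
−1, G:U near 0). Bulge/internal loops are capped at 30 unpaired nt, the
standard dynamic-programming restriction.

The minimum-free-energy structure is computed by a Zuker-style dynamic
program (compiled code) with hairpin/stack/internal/multibranch
decomposition and traceback; on exact energy ties the recursion prefers
leaving bases unpaired, so a sequence with no stabilizing structure
folds to the open chain with MFE 0, and a lone isolated pair (which
costs a positive hairpin penalty) is never reported.

Correctness is established by two independent routes, both in the test
suite: true exhaustive structure enumeration with a standalone
loop-decomposition energy evaluator for sequences up to ~18–22 nt (where
enumeration is feasible), and an independently coded plain-R dynamic
program over the same energy table (`fold_mfe_reference()`) for 500
random sequences of 15–40 nt. Enumeration pins the model semantics;
the second implementation guards the compiled recursion. A further
property — extending a sequence never raises its MFE, since any
structure embeds in the extension — is tested with complementary stem
extensions.

### Duplex statistics

Given the folded window and the mature arm, the star arm is the set of
positions pairing with the mature arm extended by a 2-nt 3′ overhang
(Dicer-product geometry). Common pairs are the mature positions paired
into the star; bulges are maximal unpaired runs strictly inside the
paired span, counted on both sides; asymmetry is the absolute difference
of interior unpaired counts. A mature arm that pairs with itself spans
the hairpin loop and the candidate is silently rejected — a geometric
impossibility, not an error.

## Target prediction

The duplex model is gap-free: a transcript window of miRNA length,
antiparallel, so miRNA position 1 (5′ end) pairs the window's last
base. Per-position states are match (WC), wobble (G:U), or mismatch,
with penalties 0 / 0.5 / 1. A site is accepted iff all five rules hold:
≤ 4 mismatches; no run of 3+ consecutive mismatches ("no more than 2
adjacent"); ≤ 1 mismatch at positions 1–9; no mismatch at positions
10–11; weighted penalty ≤ 2.5 over positions 1–12. Wobbles count 0.5
only in the weighted 5′-region penalty — the only reading under which a
half-point bound like 2.5 is realizable, and the standard plant
convention — and are not mismatches for the count rules. Scanning is
sense-strand only (targets are mRNAs); the best accepted site per
(miRNA, transcript) is the one minimizing the 5′-region penalty, ties
to the smallest coordinate. The decisions are monotone — adding a
mismatch never turns a rejection into an acceptance — and the rule
evaluation is tested exhaustively against a direct implementation over
all ≤3-mismatch placements on a 21-nt duplex.

## Differential expression

TPM is `count / clean_reads × 10⁶` per library. At comparison time,
zeros are revised to 0.01; a (miRNA, R-vs-S) pair in which **both**
values are < 1 TPM is excluded — the other reading (either value < 1)
would discard strongly induced miRNAs, contradicting the calls the
procedure is meant to produce. Fold change is `log₂(R/S)`,
antisymmetric under swap. When replicate vectors are available on both
sides, Welch's unequal-variance t-test (delegated to `stats::t.test`,
with the zero-variance edge handled explicitly) supplies a two-sided p,
and a call requires p < 0.05 **and** |log₂FC| ≥ 1. With one pooled
library per population — the motivating design — there are no
replicates; the module then warns and calls on fold change alone rather
than inventing a p value. Raw p values are used by default (a
Benjamini–Hochberg option exists, off by default). Note that at three
replicates per side the Welch–Satterthwaite approximation is
conservative: its true type-I error is near 0.035 rather than 0.05,
which the null-simulation test measures directly.

## qPCR quantification

For each replicate, ΔCt = target Ct − combined reference Ct, where the
combined reference is the arithmetic mean of the three reference-gene
Cts (CAP, GAPDH, UBQ) — equivalent to a geometric mean of reference
quantities and the standard multi-reference convention; no combination
rule was prescribed, so this default is configurable. ΔΔCt subtracts
the calibrator group's mean ΔCt, and relative expression is 2^−ΔΔCt
(efficiency fixed at 2, the classic method's assumption). The whole
computation is invariant to adding a constant to every Ct, and the
calibrator's expected value is 1 by construction. Group significance
uses Welch's t on per-replicate 2^−ΔΔCt values versus the calibrator,
flagged at p < 0.05 plus ≥2-fold change.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not any particular sequencing run:

* **Transcriptome** — i.i.d. sequences at 56% GC (the assembly-level GC
  content of the study organism), 200–2000 bp.
* **Hairpins** — precursors built as arm + short A/C loop (which cannot
  pair internally) + reverse-complement arm, so every planted precursor
  passes the four criteria by construction; loci never overlap.
* **Libraries** — default four pools (S, R1–R3) × 10⁵ reads. Clean-read
  composition is multinomial around expected TPM abundances (base TPM
  uniform in 500–5000) with contaminant fractions rRNA 0.60, tRNA 0.03,
  snRNA 5×10⁻⁴, snoRNA 10⁻⁴, drawn as random 18–30 nt substrings of the
  category references — how degraded ncRNA actually appears in sRNA
  libraries. Controlled fractions of reads are planted to fail each
  cleaning filter (1% low quality, 0.1% N, 5% short, 2% adapter-free
  long reads). Three planted miRNAs carry a 4-fold R-vs-S effect
  (alternating up/down). Inserts destined to survive cleaning are
  rejection-sampled so no spurious adapter-prefix match (inside the
  insert or across the insert–adapter junction) can change their fate —
  without this, generator truth and filter outcomes could not be
  compared exactly.
* **qPCR** — Ct = baseline − log₂(abundance) + Gaussian noise per
  replicate, reference genes constant up to noise, censoring at 40
  cycles.

Library sizes are ~10⁵ reads rather than the ~10⁷ of a real run:
proportions, not totals, carry the signal, and this size keeps the full
suite in minutes. Pooling 10 plants per population suggests a
within-pool variance component; whether to model it is genuinely open,
and the generator's default is none (abundances are exact expectations),
which makes recovery tests sharp. What passing recovery tests therefore
shows is that the *pipeline logic* is correct under its own assumptions
— perfect-stem precursors, uniform base composition, error-free inserts.
They do not show robustness to sequencing error profiles, isomiR
heterogeneity, bulged precursors at the criterion boundary, or real
Rfam/miRBase reference complexity.

Determinism: every generator takes an explicit integer seed, and equal
seeds give byte-identical FASTQ/TSV output.

## Problem sizes and budgets

The shipped tests run the default preset once (4 × 10⁵ reads,
10 hairpins, 3 differential miRNAs), check folding against enumeration
at ≤ 18 nt and against the independent DP on 500 sequences ≤ 40 nt,
evaluate all 1 562 ≤3-mismatch target configurations, and use 1000
null replicates for type-I checks; the whole suite completes in a few
minutes on one CPU, as does the acceptance script.

## Known limitations

* The energy model is intentionally lite; absolute MFEs differ from
  Turner-parameter folders, so the −20 kcal/mol gate is meaningful only
  under this table.
* Multi-locus tags are resolved by evaluating every locus (≤ 20), not by
  an abundance-weighted assignment.
* The gap-free target model cannot represent bulged target sites; only
  the five mismatch rules are implemented.
* Without replicates, differential calls are fold-change-only and carry
  no error control; the replicate-aware path exists for designs that
  supply them.
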