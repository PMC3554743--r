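---
title: "Methods: two-library small RNA analysis in srnapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA analysis in srnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

srnapipe analyses a pair of small RNA sequencing libraries — in the
motivating application, a doxorubicin-resistant hepatocellular carcinoma
line (library B, "resistant") against its parent (library A) — from raw
50-nt reads to differentially expressed known and novel miRNAs, their
predicted targets and enriched terms. This vignette explains the models
behind each stage, the tunable parameters, and the design decisions that
were genuinely open.

## Read cleaning and tags

Reads are `insert + 3' adapter + downstream filler`. `trim_adapter()`
scans each read left to right for the first position where a prefix of the
adapter matches with at most `floor(0.1 × overlap)` mismatches and at
least 6 bases of overlap; the leftmost acceptable position wins, which for
ordinary reads is also the longest-overlap match. Reads whose adapter
starts at base 1 are adapter-dimer contaminants; reads without an
acceptable match are rejected. The quality gate drops reads with any base
below Q20 in the first 36 cycles; the source pipeline only says "low
quality reads", so the threshold is configurable and documented rather
than inferred. Inserts with N are discarded because downstream mapping is
exact. Only 18–30 nt inserts are retained (bounds inclusive), the size
window of miRNA/siRNA/piRNA species. Every rejection class is counted so
`reads_in = rejected + retained` holds exactly per library — the test
suite asserts this conservation on simulated libraries.

Distinct insert sequences become *tags* with per-library counts
(`collapse_tags()`); all later statistics are tag-based. Library summaries
report read-weighted length histograms, first-base composition by length,
positionwise base composition, and common/specific fractions in both
unique-tag and read-weighted space (the three fractions sum to 1 in each
space).

## Mapping and priority annotation

`map_tags()` reports every exact, full-length occurrence of a tag on both
genome strands (Biostrings `PDict`/`matchPDict` with a trusted band, which
stands in for the reference aligner of the original workflow). Exact
matching is the conventional choice for miRNA tags; a mismatch-tolerant
mode was considered and deliberately left out of the default path because
every downstream count in this design assumes unambiguous assignment.

`assign_category()` gives each tag exactly one category by the priority
rule `rRNA etc (GenBank > Rfam) > known miRNA > repeat > exon > intron`,
applied over *all* of a tag's hits; the remaining mapped tags are
`unannotated` (the novel-miRNA pool) and unmappable tags are `unmapped`.
Three strand conventions matter and are fixed as follows: miRNA overlap
requires the same strand (a tag antisense to a miRNA is not that miRNA);
exon and intron overlaps are split into sense/antisense categories with
sense ranked above antisense; ncRNA and repeat overlap ignores strand.
Multi-mapping tags are counted once, at their highest-priority hit, never
fractionally — this mirrors the one-annotation-per-tag rule. The
"GenBank > Rfam" clause is realised as two separately labelled ncRNA
sources checked in order. A read-weighted rRNA fraction ≥ 40% fails the
library QC mark ("less than 40%" is strict, so exactly 40% fails).

Known mature miRNAs are quantified by `quantify_known()`: a tag counts
toward a mature arm when it has a same-strand hit whose 5' end lies within
±2 nt of the annotated mature 5' end (isomiR wobble; the source does not
state a window) and the hit falls inside the parent precursor. A tag
matching several arms goes to the one with the smallest 5' offset. TPM is
`count / total clean reads × 10⁶`, so 1 TPM is one transcript per million
tags.

Coordinates are 1-based inclusive in GFF3 and in the R API; BED output is
0-based half-open.

## The folding model and novel-miRNA gates

`fold_rna()` computes a minimum-free-energy, pseudoknot-free secondary
structure under a simplified nearest-neighbour model authored in this
package: stacking free energies for the six canonical/wobble pairs
(Turner-like values, symmetrised so a helix scores identically from either
strand), hairpin/bulge/internal loop penalties tabulated to 30 nt with
`1.079 × log(L/Lmax)` extrapolation, and an affine multiloop term
(offset 3.4, 0.4 per branch). The dynamic program is the classic interval
recursion with interior loops capped at 30 unpaired bases; multiloop
segments must contain at least one branch, so a "multiloop" can never
substitute for a hairpin penalty. Ties are broken toward fewer pairs, and
the empty structure (0 kcal/mol) is always admissible, so the MFE is never
positive. The same decomposition is implemented a second time, by direct
loop parsing, in `structure_energy()`; the tests require the DP to equal
exhaustive enumeration over all structures for short sequences and to
equal `structure_energy()` on its own output everywhere. The energy table
ships as data (`energy_params()`, YAML round-trip available) because the
−20 kcal/mol gate is only meaningful relative to a stated model: under
this table a designed 20+ bp stem folds in the −40 to −60 kcal/mol range
while unstructured sequences sit near zero, so the gate separates designed
hairpins from background comfortably.

The input contract of `fold_rna()` accepts 1–2000 nt. The pipeline itself
only folds precursor windows of roughly 50–170 nt, but the documented
enumeration check folds sequences of 14 nt and below, so the function does
not impose the pipeline's window bounds.

Novel candidates are built by `cluster_unannotated()` (same-strand hits
merged at gaps ≤ 10 nt — wide enough to fuse the two arms of one hairpin
across its loop), `extract_precursor()` (two windows per cluster, stack on
the 5' arm and stack on the 3' arm, default 70 nt flanks, clipped at
chromosome ends) and `call_novel()`, which applies four gates:

* `hairpin_shape` — the putative mature arm (the modal-5'-end tag of the
  stack) must contribute ≥ 16 pairs to a stem closing a 3–20 nt loop, with
  ≤ 4 unpaired arm bases after excluding the 2-nt 3' overhang;
* `mfe_pass` — window MFE strictly below −20 kcal/mol;
* `dicer_pass` — ≥ 70% of the stack's reads share the modal 5' end
  (5'-end homogeneity is the signature of Dicer processing);
* `expression_pass` — ≥ 1 TPM in *both* libraries (inclusive). Whether
  the original analysis required both samples is ambiguous (it reports
  per-sample novel counts larger than the shared set), so
  `require_both_samples = FALSE` switches to either-library detection and
  both sets can be reported.

The verdict is the conjunction of the four flags (asserted row-wise in the
tests); called candidates are named `novel-miR-1…N` by descending total
count, a rank-by-abundance convention chosen because the original
numbering scheme is not described. A planted hairpin with a perfect
reverse-complement stem is also its own reverse complement's hairpin, so
each hidden locus may be called on both strands; calls are reported per
strand rather than deduplicated, which affects neither recall nor the
no-annotated-overlap check.

## Differential expression

With one library per condition there are no replicates, so the test is the
exact conditional binomial: under the null of equal relative abundance,
conditional on `n = count_A + count_B`, `count_B ~ Binomial(n, q)` with
`q = total_B / (total_A + total_B)`. The two-sided p-value sums the
probabilities of all outcomes no more likely than the observed one
(minimum-likelihood convention, the same as `binom.test`; two-sided exact
tests have several conventions, so this one is declared explicitly and
cross-checked against both an explicit summation oracle and `binom.test`).
The original publication cites prior work without formulas; this choice is
the replicate-free standard, equivalent in spirit to the classic
two-library count test.

Benjamini–Hochberg adjustment is the step-up
`adj_i = min(1, min_{j≥i} m·p_(j)/j)`, implemented in the package and
tested against its definition and `p.adjust`. Known and novel miRNAs are
adjusted separately, mirroring their separate reporting. A miRNA is `Up`
(`Down`) at adjusted *P* < 0.05 and log2 fold change ≥ 1 (≤ −1), where the
fold change is `TPM_B / TPM_A` with a 0.01-TPM floor applied to zero sides
only — library-specific miRNAs therefore get large finite fold changes
instead of infinities, and no miRNA below 2-fold is ever called. The DE
universe is miRNAs with nonzero count in at least one library; the subset
detected in both is reported separately. Summary counts include the
">16-fold" tallies (|log2FC| > 4, strict).

## Targets and enrichment

Four in-house parameterizations emulate independent prediction tools so
the ≥3-of-4 consensus rule is testable offline: M1 = 7mer-m8 (perfect
complement of miRNA positions 2–8), M2 = 8mer (7mer-m8 plus an A opposite
position 1), M3 = 7mer-A1 or 7mer-m8 with ≥ 4 contiguous complementary
bases of miRNA 13–17 within 16 nt upstream of the site, M4 = 7mer-m8 with
a miRNA:site-window duplex energy below −14 kcal/mol under the package's
own energy model (the duplex is folded as miRNA + weakly pairing linker +
window). Externally produced per-tool gene lists can be merged instead
(`merge_tool_predictions()`), reproducing the literal external-tool
workflow. The retained set at support ≥ 3 is by construction a subset of
the set at support ≥ 2.

Enrichment is the hypergeometric upper tail (at least `k` of `n` targets
in a term of size `K` over a universe of `N`), Bonferroni-corrected over
the terms tested, as in the original tables. The universe is the genes
with a supplied 3'UTR — enrichment must condition on testable genes. The
percentage column divides by the number of retained targets with at least
one term annotation, a declared choice because the original tables'
percentages are internally inconsistent with their stated totals.

## The synthetic generator

`build_genome()`/`simulate_libraries()` emulate the statistical structure
the analysis assumes: a single-chromosome genome carrying designed
stem-loops (perfect 22-bp reverse-complement stems, 8-nt loops, so both
arms are fully paired), ncRNA features split between GenBank- and
Rfam-labelled sources, repeats and exon/intron gene models; hidden
hairpins are built identically but left out of the annotation as the
novel-prediction truth set. Mature 5p arms start with U with probability
0.8 by default (and end with A, so the 3p arm starts with U too),
reflecting the strong 5'-U bias of real 22-nt small RNAs. Reads mix miRNA
arms (5p:3p at 80:20), hidden arms, ncRNA/genic fragments (16–34 nt, so
the length filter is exercised), genome-absent noise (rejection-sampled,
guaranteeing a deterministic unmapped path) and adapter-dimers; expected
miRNA counts are exactly `library_size × TPM/10⁶`, with library-B weights
scaled by each miRNA's true log2 fold change and the noise class absorbing
the residual mass so the configured fold changes are exact in expectation.
Counts are multinomial; qualities are constant high; sequencing error is
off by default (an optional uniform substitution rate exists) because the
cleaning stage discards low-quality reads and no error model is described
for the original data. The noise/contaminant mixture fractions are free
parameters since the real contamination rates are not reported; the
defaults (52/15/16/5/9/3% for miRNA/hidden/ncRNA/genic/noise/dimer) were
chosen once as a realistic-looking cell-line profile and are not tuned.

What the generator does *not* emulate: isomiR end heterogeneity beyond the
planted exact arms, 5'-adapter read-through, indels, quality-score decay,
multi-chromosome genomes, and imperfect (bulged) precursor stems. Passing
tests therefore demonstrate the pipeline's logic under its stated
assumptions, not robustness to every artefact of real libraries.

Problem sizes are desk-scale by choice: default libraries of 5×10⁴ reads
on a 5×10⁴ nt genome (the motivating study sequenced ~14 M reads per
library against the human genome); statistical suites use 100 seeds with
200–500 features per run. These sizes make every property — conservation,
oracle equivalence, FDR control, recall of planted hairpins — cheap to
re-verify while leaving the per-read and per-tag logic identical to a
full-scale run.

## Numerical choices and degenerate inputs

* Folding ties go to fewer pairs; interior loops are capped at 30
  unpaired bases (standard practice; removes an O(n⁴) term).
* `two_library_test` refuses double-zero counts (the conditional test is
  undefined); `de_table` excludes such rows upstream.
* An empty tag table yields an all-zero summary with a warning rather
  than an error; empty FASTQ libraries are valid outputs.
* Cluster windows are clipped at chromosome bounds; extraction of a
  zero-flank window returns exactly the cluster span.
* All randomness flows from the configuration seed; rebuilding with the
  same configuration is byte-identical, which the tests assert on the
  FASTA/GFF3/FASTQ/TSV outputs.

## Known limitations

The exact test models technical (sampling) variation only; with one
library per condition, biological variability is not estimable, and
p-values at high counts are anti-conservative in the usual way for
replicate-free designs. The energy model is intentionally reduced (no
dangles, no sequence-dependent loop terms, no coaxial stacking), so
absolute MFE values differ from full thermodynamic folders even though the
−20 kcal/mol gate behaves equivalently on designed stems. Target
prediction emulates seed-match tools; it does not reproduce
conservation-based or trained scoring. These boundaries are deliberate:
each replaced component is either the package's own documented model or an
interface for user-supplied external results.
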