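---
title: "Reference-free RRBS methylation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free RRBS methylation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdeduce)
```

# Overview

`methdeduce` analyses RRBS data from organisms without a usable reference
genome. The core idea exploits a structural property of RRBS: MspI cuts
`C^CGG` irrespective of methylation of the central CpG, so every sequenced
fragment starts and ends at a restriction site. Reads from the same genomic
fragment therefore share their 5' anchor, and clustering reads by similarity
— after erasing the bisulfite signal by converting every C to T — recovers
one consensus sequence per fragment. Those consensus sequences, concatenated
with N spacers, serve as the *deduced genome* against which alignment,
methylation calling and differential analysis proceed exactly as they would
with a real reference.

This vignette documents the models, parameter choices, numerical decisions
and limitations. The companion test suite and `scripts/acceptance.R` compute
every empirical claim referenced here; this document states none that they
do not verify.

# The deduced genome

## Consensus rules and thresholds

The builder applies, in order:

1. **Pre-filter.** Exact duplicate sequences within a sample collapse to one
   representative (copy counts are retained). A converted key (the read with
   all Cs replaced by Ts) must be supported by at least `min_multiplicity`
   (default 2) representatives across all samples, which suppresses
   singleton sequencing errors. The published description ("occurs at least
   twice among four samples") is ambiguous about the counting unit; we count
   per-sample representatives in total across samples and expose the
   threshold as a parameter. Reads containing N are excluded from genome
   building but still participate in alignment.
2. **Preliminary grouping.** Reads sharing a converted key are combined; a
   position becomes C when at least 5% of the member reads (weighted by copy
   counts — copies, not distinct sequences) carry a C. The 5% boundary is
   inclusive.
3. **Similarity clustering.** Converted keys are compared ungapped and
   anchored at position 0 — both read ends are MspI cut sites, and RRBS
   aligners effectively forbid gaps — with the mismatch ratio computed over
   the shorter sequence, so a read that is a prefix of a longer fragment can
   join its cluster. Keys merge into the largest existing group whose seed
   is strictly below 8% mismatch; processing order is descending read
   support with lexicographic tie-breaks, making the outcome deterministic
   where the original behavior depended on aligner ordering.
4. **Refinement.** Members strictly above 5% mismatch against their group
   consensus are removed and re-clustered among themselves until no member
   exceeds the threshold. Each split strictly reduces a group, so the loop
   terminates; a 100-iteration cap guards against regressions.
5. **Strand merging.** Bisulfite conversion destroys reverse-complement
   identity, so the two strands of one fragment cluster separately. Strand
   partners are recognized among consensus sequences that start with
   `[CT]GG` and end with `[CT][CT]G` (the bisulfite images of the MspI
   termini) and become identical under the degenerate transform C→T, G→A
   (one reversed and A/T-swapped). The merged sequence takes the forward
   partner and sets C at every T position where the literal reverse
   complement of the partner shows a C: a G on the opposite strand is
   untouched by bisulfite and is direct evidence of a genomic C. This is
   what restores never-methylated Cs covered by both strands.
6. **Concatenation.** Fragments are ordered by read support (ties
   lexicographic) and joined with 50 Ns — matching the read length, so no
   alignment can bridge two fragments.

A genomic C that is unmethylated in *every* sample and covered on only one
strand reads entirely as T and is irrecoverably absent from the deduced
genome; this is an inherent limitation of reference-free analysis, and it is
why observed non-CpG "conversion rates" against a deduced genome understate
true conversion — the package measures conversion with spike-in controls
instead.

## Reconstruction guarantee

Under an error-free simulation in which every size-selected fragment is
fully covered by reads from both strands and fragments are mutually more
than 8% divergent, the builder returns exactly one fragment per library
molecule, string-equal to the genomic sequence (in one orientation): forward
reads fix the backbone, the 5% rule preserves partially methylated CpGs, and
strand merging restores the remaining Cs. The acceptance suite asserts this
per fragment against a brute-force oracle that applies the consensus rules
directly to the raw reads, independent of the clustering code.

# The simulator

The simulator generates a first-order-Markov genome whose stationary base
composition equals the requested GC content while the C→G transition is
inflated so the CpG dinucleotide frequency is `cpg_enrichment` (default 3)
times the base-composition expectation — a simple stand-in for CpG islands.
Fragmentation is an exact in-silico MspI digest. Only internal fragments
(both ends cut sites) enter the library, since adapter ligation requires the
CG overhang, and size selection (default 40–220 bp, the usual RRBS window)
acts on digest-fragment length. Each sequenced molecule spans the fragment
plus the two fill-in bases at the 3' end, because MspI leaves 5'-CG
overhangs: without this both strand reads could not carry the `[CT]GG` /
`[CT][CT]G` termini the strand-merge step requires. Fill-in cytosines are
emitted from the genomic strand (the end-repair unmethylated-fill-in
artifact is not modeled).

Methylation is drawn once per CpG per DNA molecule — both strands of a
molecule agree, which matters for strand-merging tests — and the emitted
base follows `P(C) = m(1 - over) + (1 - m)(1 - conv)` at CpGs; non-CpG Cs
convert at `conv`. Defaults `conversion_rate = 0.995`,
`overconversion_rate = 0.005` and `error_rate = 0.001` reflect routine
bisulfite chemistry and Illumina error rates. Read depth per fragment per
sample is Poisson with mean `depth` (default 30); strands are chosen with
equal probability; reads are truncated to `read_length` (default 50 bp,
single-end). Spike-in controls (one CpG-methylated, one unmethylated 60-mer,
at a default mass fraction of 0.1%) allow conversion-rate estimation that
does not depend on the deduced genome.

The simulator does *not* model PCR duplicates, adapter read-through
chimeras, cycle-dependent quality profiles, SNPs or repeat families. Passing
tests therefore demonstrate the correctness of the algorithms under clean
conditions, not robustness to every artifact of real libraries; the
repetitive-element merging behavior discussed for real data is outside the
simulated regime.

## Test scales

Full-coverage checks (genome reconstruction, methylation recovery) simulate
a 100 kb genome (roughly 130 size-selected fragments), 4 samples in 2
groups, depth 30, and reads of 222 bp so each molecule — fragment plus the
two fill-in bases — is spanned end to end by single reads; that full
spanning is the stated precondition of the reconstruction property, not a
claim about typical read lengths. Pipeline-level tests use the realistic
50 bp reads, where fragments longer than the read yield one deduced fragment
per strand end — expected behavior, since only molecules shorter than the
read can be strand-merged.

# Alignment and calling

Alignment uses exact 16-mer seeds on the C→T-converted forward frame and
the G→A-converted frame (for reverse-complement hits), with ungapped
full-length verification under the asymmetric rule: genome C may read T
(forward) and genome G may read A (reverse-complement); the reverse
asymmetries are mismatches. The mismatch budget is 8% of the read length
(inclusive). Ties between equally good loci are resolved by a seeded random
choice by default — mirroring the random single-hit reporting of the
original mapper, with `best-unique` available to drop ambiguous reads.
Seeding is per sample, derived from the master seed, so multi-worker and
serial runs are byte-identical.

Calling merges the two strands of a CpG into one site: forward reads vote
with C/T at the C, reverse-complement reads with G/A at the paired G.
Anything else (N, mismatching base) votes for neither. Duplicate reads are
kept — RRBS fragments legitimately share start positions, so duplicate
removal would discard signal. Sites are filtered to coverage 8–200
(inclusive); fragment levels pool reads (summed counts), not site means, so
high-coverage sites carry proportionally more weight. Non-CpG contexts (CHG,
CHH) can be called from forward-strand evidence; with a deduced genome their
apparent levels reflect residual under-conversion, not biology, and must not
be used as a conversion proxy.

# Differential methylation

Per site, a two-group linear model on methylation levels yields the mean
difference and pooled residual variance `s²` on `d` degrees of freedom.
Variances are shrunk by empirical Bayes towards a prior `s₀²` with `d₀`
degrees of freedom estimated by moment matching of the scaled-F distribution
of the `s²` on the log scale (Newton inversion of the trigamma function);
the posterior variance is `(d₀s₀² + d s²)/(d₀ + d)` and the moderated t has
`d₀ + d` degrees of freedom (capped at the summed residual df). Forcing
`prior_df = 0` recovers the textbook pooled t exactly, which the tests
assert to 1e-10; the default estimator is cross-checked against the limma
implementation. Levels are proportions, so the linear model is an
approximation; at coverage 30 and four replicates per group the all-null
type-I error stays within binomial noise of the nominal 5% (asserted).

Site p-values are BH-adjusted, then combined per fragment with a
coverage-weighted chi-squared statistic `K = Σ wᵢ(−2 ln pᵢ)` (weights
normalized to 1), whose null is approximated by a scaled chi-squared matched
to mean 2 and variance `4Σwᵢ²`; with equal weights this is monotone in
Fisher's statistic, and with one site it is the identity. Combining
*adjusted* p-values follows the published order of operations. Fragments are
ranked separately by combined p, |log₂ fold change| (with ε = 0.01 against
log 0 — fold changes of proportions are otherwise undefined at 0) and
|mean difference|, using competition ranking ("1224") for ties; the
fragment's priority is the *worst* of the three, so only fragments good on
all measures reach the top. Selection gates are strict: mean coverage > 2,
combined p < 0.05, top 500 per direction.

The planted-signal scenario used for calibration plants Δm = 0.4 at 50 of
1000 fragments with baselines drawn from Uniform(0.2, 0.6) (so the shifted
group stays inside [0, 1]) and null baselines from Uniform(0.2, 0.8) — the
intermediate methylation range where cell-type differences are found in
practice; coverage 30, four samples per group. Under these conditions at
least 90% of planted fragments reach the top 100 combined ranks (asserted).

# Motif enrichment

Sequences are scored by the average odds score: at each offset the product
over motif positions of motif frequency over background frequency, averaged
over all offsets on both strands (the reverse strand via the
reverse-complemented matrix; both-strand scanning is a package choice — the
original tooling's strand handling is not documented — and a single-strand
variant would only change scores by the strand average). N positions
contribute a factor of 1. Background probabilities are the order-0
composition of the union of the two input sets. Enrichment is a one-sided
rank-sum test (exact for both sets ≤ 20 without ties, normal approximation
with tie and continuity correction otherwise), BH-adjusted across motifs,
significance at adjusted p < 0.05.

Base-composition bias is controlled with Markov-shuffled backgrounds: for
each of 50 iterations and each order (0 and 1), models fitted to each input
set generate matched random sets (matching each original sequence's length,
rather than a fixed 50, and the set's size — the published "length ∼50"
leaves the distribution open), and the test is re-run shuffled vs shuffled.
The 100 iterations are pooled when applying the fractions (the published
accounting of "50 iterations each" is ambiguous; the fractions are
configurable). A motif significant in more than 60% of iterations is removed
as a composition artifact; the threshold is exclusive, monotone (raising it
never removes more motifs), and exercised at its boundary in the tests.
Motifs enriched against their own shuffles in at least 95% of iterations for
*both* input sets are reported as shared (enriched in both directions), with
the least significant p across iterations. Order-1 transition rows for
contexts never observed are smoothed to uniform; observed rows are used
as-is so degenerate inputs (e.g. a dinucleotide repeat) reproduce
themselves.

# Determinism and parallelism

Every stochastic step takes an explicit seed; per-sample and per-stage seeds
derive deterministically from the master seed, so the entire output tree is
byte-identical across runs and across `threads` settings (asserted on
md5 sums). Work may be partitioned by sample (alignment, calling); any
schedule preserving output identity is acceptable, and the serial path is
the reference.

# Known limitations

* Cs unmethylated in all samples and covered on one strand only are absent
  from the deduced genome (fewer covered CpGs than a reference-based
  analysis would report).
* Highly similar repeats can merge into one fragment; partially overlapping
  fragments can double-count a CpG. No de novo assembly is attempted.
* The differential model is a linear model on proportions, not a
  beta-binomial count model; paired designs and covariates are out of scope.
* Two-group comparisons only.
* The aligner is ungapped; indel-bearing reads are dropped rather than
  clipped.
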