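---
title: "Locus-scale epigenomic profiling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-scale epigenomic profiling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilocus)
```

# Scope

`epilocus` analyses one plant locus at a time — the motivating system is a
multicopy maize-style gene whose regulatory regions carry transposon
fragments and are silenced by overlapping RNA-directed DNA methylation
(RdDM) and non-RdDM mechanisms. Three measurement modalities are covered,
each with the estimator a bench epigeneticist would compute by hand, plus a
seeded synthetic-data generator that stands in for the wet-lab inputs so
that every stage can be tested against known truth.

# Coordinate frame

All computation is in 1-based array coordinates along the locus sequence.
Reported coordinates are TSS-relative with no position 0: the transcription
start site is +1 and the base immediately upstream is −1. The conversion is
applied only at I/O boundaries (`to_tss_coord()` / `from_tss_coord()`), and
a TSS-relative 0 is always an error.

# Bisulfite clone methylation

## Model

A bisulfite amplicon clone is the readout of one DNA molecule on one strand:
at a cytosine site, C means the cytosine was methylated (protected from
conversion), T means unmethylated and converted; any other base is an
ambiguous call, excluded from both numerator and denominator. Context is
assigned from the reference (CG, CHG, CHH with H ∈ {A, C, T}; the minus
strand applies the mirrored rules to the upstream bases). The per-context
percent pools all clones of a sample:

$$\mathrm{percent}(c) = 100 \cdot
  \frac{\#\{\text{methylated calls in context } c\}}
       {\#\{\text{informative calls in context } c\}}$$

A context with zero informative calls is reported as missing, never as 0.

## Statistics

The biological replicate (plant) is the statistical unit: technical clones
are pooled within a plant, and genotypes are compared by a classical
equal-variance two-sided Student t-test on the replicate-level percents,
flagged significant at P ≤ 0.05. With two replicates per group the Welch
approximation has degenerate degrees of freedom, which is one reason the
classical test is the right match for this design; a group with a single
replicate (e.g. a lone control plant) is reported with mean only, no t or P.
Standard errors are `sd/sqrt(n)` over replicates.

Two exports exist for per-site plots: clone-pooled fractions (counts summed
across replicates before dividing — the default) and replicate-averaged
fractions. Both are provided because with balanced clone counts they agree,
but with unequal clone recovery they can differ slightly.

## Incomplete conversion

With conversion rate $r$ and true methylation probability $p$, the expected
estimate is $p + (1-p)(1-r)$: unconverted unmethylated cytosines inflate
the estimate. The generator exposes `conversion_rate` (default 0.99, a
typical commercial-kit efficiency) and the test suite checks the closed
form at $r = 0.95$, $p = 0.4 \rightarrow 0.43$. No conversion spike-in is
modelled, so the rate cannot be estimated from the data — it is a knob, not
an inference.

## Masking and ambiguity

Nested-PCR primer footprints are not knowable from the sequence alone, so
primer masking is a configurable interval list (`mask` in
`summarize_profile()`), empty by default. A clone with more than 10%
ambiguous calls is flagged in the log but kept (threshold
`ambiguity_warn_rate`); dropping clones silently would bias percent
estimates in small clone sets.

# Small RNA profiling

## Pipeline

Raw reads are trimmed at the leftmost exact occurrence of the first 8
adapter bases (`k` configurable); inserts outside 18–30 nt are rejected
with a reason. A read is structural if it is an exact substring of any
tRNA/rRNA/snRNA/snoRNA reference record or its reverse complement.
Remaining reads are aligned to the single locus copy by perfect match only
— every zero-mismatch occurrence on either strand is a hit, implemented as
a hash index of all 18–30 nt locus substrings so lookups are O(1) per read.
For a tandemly repeated multicopy gene one copy stands in for all copies,
so multi-hit reads are counted at every position (an aggregate profile); a
per-read mode that divides by hit count is available but not the default.

## Normalization

The denominator is genome-matched non-structural reads. In the synthetic
setting the locus is the genome, so this is operationally "non-structural
reads with a perfect locus match": planted source reads match by
construction and the unmatchable-noise fraction does not, and the analysis
never consults truth labels. `rpm` scales this denominator to one million.
`rpm_22anchor` additionally rescales each library so its 22-nt class equals
the reference library's: when the mutant loses most 24-nt siRNAs, plain
per-million normalization inflates every other size class, and the 22-nt
class — dominated by sources unaffected by the mutation — is the stable
anchor. The anchor is a single scalar per library, so within-library
size-class ratios are untouched. Whether the anchor ratio is computed on
RPM-normalized or raw 22-nt counts is an open choice; both are implemented
(`anchor_on`), RPM-then-anchor is the default. The reference library
defaults to the first library, which in the default study design is a
wild-type library.

## Binning and the grid anchor

Hits are assigned once each to the 50-bp bin containing their 5′ start
(for minus-strand hits the 5′ end is the rightmost matched coordinate);
bins are half-open on a grid of TSS-relative values congruent to
`anchor_offset` modulo the width. The arithmetic runs on the printed
TSS-relative integers themselves, so the one bin that straddles the TSS
covers width − 1 real positions (coordinate 0 does not exist). This choice
was made because published per-locus bin tables print TSS-relative edges
that are uniform in exactly this sense; `anchor_offset = 24` reproduces
such a grid for the bundled locus model (edges at −1726, …, −26, +24, …,
+5024), while the neutral default is 1.

## Differential calling

A bin is flagged when the wild-type replicate-mean abundance is at least
`min_wt` (default 5, in the normalized unit) and the mutant/wild-type ratio
is at most `max_ratio` (default 0.2; a mutant of exactly 0 always passes).
Maximal runs of adjacent flagged bins merge into regions, labelled with the
overlapping (else nearest) annotated feature. The defaults were chosen so
that a qualitative "lost in the mutant" pattern — wild type clearly
expressed, mutant at most a fifth of it — is what gets reported; both are
caller arguments, not constants.

# qPCR and ChIP-qPCR

Technical replicates are averaged on the Ct scale before any Δ is taken
(standard Livak practice). Relative expression is $2^{-\Delta\Delta C_t}$
with ΔCt = Ct(target) − Ct(control) per biological replicate and ΔΔCt taken
against the calibrator's mean ΔCt, making the calibrator exactly 1 by
construction; SE is computed on the linear scale over biological
replicates. ChIP signal is percent of input with the input Ct first
advanced by $\log_2(1/f)$ cycles for an input fraction $f$ (default 0.01,
but user-supplied for real data since it is protocol-specific); fold
enrichment divides two percents, optionally after subtracting the
no-antibody background floored at 0. Note the dilution re-expression
identity: $(f, C_t^{in})$ and $(f/2, C_t^{in}+1)$ give the same percent —
a more dilute input amplifies later. No amplification-efficiency (Pfaffl)
correction is attempted.

# The synthetic-data generator

## What it emulates

`default_locus_config()` encodes the study conditions: an 11 kb locus, TSS
at array position 5501, a 499-bp distal enhancer at −5135..−4637 that is
heavily CG/CHG-methylated but produces no siRNAs, a proximal enhancer with
an embedded MULE fragment carrying 60-bp inverted repeats, intron-2
sub-regions Int2-1 (196 bp, mutation-insensitive) and Int2-2 (291 bp,
losing CHG/CHH methylation in the mutant), a Stowaway-like MITE with 25-bp
terminal inverted repeats just downstream of Int2-2, three exons, and
Tourist/Harbinger/hAT fragments. Two genotypes are modelled: an
RdDM-proficient wild type (`Mop1`) and an RdDM-deficient mutant (`mop1`)
in which the 24-nt siRNA sources collapse while a genic 21/22-nt background
is unchanged. Methylation is drawn i.i.d. per site per clone from
per-(region, context, genotype) probabilities (an optional block-correlation
knob exists, default off, because no along-molecule correlation structure
is assumed); clones are gap-free by construction, which replaces a
multiple-alignment step — fixed-length amplicon clones make indel modelling
add nothing testable. Small RNA reads are drawn uniformly within their
source interval with a 24-nt-dominated size mix, mixed with 15% structural
reads (substrings of a generated rRNA/tRNA/snoRNA-like reference) and 2%
unmatchable noise, emitted as insert + TruSeq-style 3′ adapter truncated
to 50 nt. The default library design is 3 wild-type + 2 mutant libraries
of 200,000 reads. Ct tables are generated so the Livak and
percent-of-input estimators are unbiased up to Gaussian Ct noise
(sd 0.2 cycles, 3 biological × 3 technical replicates).

## What it does not emulate

No PCR duplicates, no sequencing-error model for sRNA reads beyond the
noise fraction, no bisulfite strand pairing (only the read strand is
simulated), no amplification-efficiency variation, and no genome outside
the locus. Passing tests therefore demonstrate that the estimators recover
their own generative model — the i.i.d. methylation assumption and the
exact-match read model are idealizations, and real clone data (chimeric
clones, conversion hotspots) and real sRNA libraries (mismatches, ambiguous
multimapping across the genome) will be noisier than anything tested here.

## Determinism

Every generator takes an explicit seed and uses an isolated RNG state
(`withr::with_seed`), with sub-streams derived per stage; runs are
byte-identical given config + seed, and the simulation manifest records the
seed, all parameters and an md5 per emitted file.

# Numerical and size choices

Degenerate inputs are defined, not patched around: empty site regions give
empty tables; a context with no informative calls is missing; a library
with a zero denominator or empty 22-nt class is an error naming the
library; mismatched bin grids are an error. Ties in feature lookup (a site
inside two configured regions) resolve to the first-named region in the
configuration. The test suite exercises the stack at deliberately modest
sizes — 500-bp amplicons with 20 clones per replicate, 1,000-sequence
oracle sweeps for context calling and alignment, and twenty seeded
replications of 200,000-read library pairs for the differential caller —
sizes at which the binomial tolerances quoted in the tests (3 SDs of the
planted probability, ≥18/20 or ≥19/20 seeded successes) have the intended
coverage.

# Known limitations

Single locus, exact matching only (no mismatch-tolerant alignment, no
genome-wide step), no methylation segmentation or HMM smoothing, no
melt-curve or efficiency QC for qPCR, and the strand of bisulfite analysis
is always an explicit parameter — amplicon strand cannot be inferred from
clone data and is never guessed.
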