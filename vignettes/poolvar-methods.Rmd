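---
title: "Pooled-population variant detection: models, parameters and design choices"
author: "poolvar developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-population variant detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In experimental evolution, a clonal founder population is propagated
under selection (for example by serial transfer on a defined carbon
source) and the evolved populations are resequenced. Sequencing DNA
extracted from the whole population — rather than from a picked isolate —
captures segregating diversity: a mutation carried by 40% of cells shows
up in roughly 40% of the reads covering its site. `poolvar` detects
SNPs, small indels and large-variant evidence in such pooled data,
estimates each variant's population frequency, automates the
false-positive screens that are usually applied by eye, and ships a
simulator so that the error rates of the whole chain can be measured
in-silico against a known truth.

## The pooled likelihood model

Let a site have `n_ref` reference and `n_alt` alternate retained base
observations and assume a per-base error rate `e` (default `0.001`,
matching Q30 data). If the alternate allele is at frequency `f` in the
pool, a random read covering the site shows the alternate with
probability `f(1-e) + (1-f)e/3` and the reference with probability
`(1-f)(1-e) + f·e/3` (errors are spread uniformly over the three
non-reference bases). The site log-likelihood is the sum of
per-observation log probabilities; only the reference base and the
leading alternate enter, other bases being treated as noise.

Pools are modelled as `h` discrete lineages (`haplotype_number`, default
10), so detection is scored on the frequency grid `{0, 1/h, …, 1}`:

    score = max_f  log L(f)  −  log L(0).

A SNP call is emitted when three conditions hold at once:

* `score ≥ min_score` (default 10 natural-log units),
* `alt_count ≥ min_alt_reads` (default 5),
* the maximum-likelihood **grid** frequency is at least `min_frequency`
  (default 0.05).

Two design decisions here were genuinely open and deserve a record:

1. **The continuous/grid split.** Reported population frequencies in
   this field (90%, 43%, 16%, …) do not lie on a 10-point grid, so
   `af_estimate` is the raw alternate read fraction, while the grid
   serves only the detection score. The discreteness assumption buys a
   natural noise floor — at `e = 0.001`, isolated errors never lift the
   `f = 1/h` grid point above `f = 0` by 10 nats — without constraining
   the estimate.
2. **Where `min_frequency` bites.** Enforcing the 5% floor on the *raw*
   read fraction would cap power at ~50% for a variant truly at 5%
   (binomial sampling puts the observed fraction below the threshold
   half the time), which contradicts the design goal of detecting 5%
   variants with ≥95% confidence. The floor is therefore enforced on the
   maximum-likelihood grid frequency: the caller refuses to *report* a
   frequency below 5%, but an unlucky 4.6% read fraction whose best grid
   explanation is 10% is still a call. The acceptance suite verifies the
   resulting detection floor is exactly 5% at 285-fold coverage.

With the defaults at 285x, the score threshold is the binding constraint
and corresponds to roughly 7 alternate reads; `min_alt_reads = 5` is a
backstop at low coverage. A 5% variant expects ~14 alternate reads, so
power at the floor is ≈0.98, while power at 4% (were it representable)
would fall below 0.95 — the floor is a property of the thresholds, not a
tuned constant.

### Indels

Following the counting rule used in the field, the indel frequency is
`support / (support + non_support)`, where `support` is the number of
reads whose alignment shows the indel and `non_support` the reads
covering the site without it. Indels with fewer than
`min_indel_support_reads` (5) supporting reads, or a support fraction
below `min_indel_support_fraction` (0.05), are rejected as putative
false positives. Insertions anchor to the base on their left; deletions
count support at every spanned site; alleles are reported VCF-style
(anchor base included).

## False-positive filters

Three manual rejection rules are quantified. "Many", "near" and "middle"
have no published numbers — the originals were applied by eye — so each
is an explicit config value, echoed into every output header:

* **`STRAND_CTX`** — a call is flagged when ≥ `min_biased_sites` (3)
  positions within ± `context_window` (10 bp, call site included) carry
  G or C mismatches whose forward/reverse split fails a two-sided exact
  conditional test (hypergeometric, conditioning on the per-strand
  depths) at `strand_bias_alpha = 0.01`. An exact test was chosen
  because mismatch counts at artifact sites range from a handful to
  hundreds; a normal approximation misbehaves at the low end.
* **`READ_POS`** — "never detected in the middle of a read" is relaxed
  to an enrichment rule: mid-read means ≥ `end_zone × read_length`
  (25 bp at 100 bp reads) from both ends, and the call is flagged when
  fewer than `min_mid_read_fraction` (10%) of alternate observations are
  mid-read. Strict zero would be fragile at high depth, where a single
  stray error mid-read would rescue a genuine artifact.
* **`NEAR_SV`** — flagged when within `sv_proximity` (25 bp, closed
  interval) of a site whose combined insertion + deletion + soft-clip
  support reaches `sv_support_min` (5), or of a candidate breakpoint.

Filters annotate; they never remove calls. Founder subtraction likewise
only sets `founder_status` (`in_founder` when the same contig/position/
alternate is present in the founder at ≥ `founder_presence_threshold`,
default 5%), so downstream reporting decides what to hide — whether the
original analyses discarded flagged calls outright is not recorded, and
annotation keeps both options open.

## Structural-variant evidence

Discordant pairs (non-forward/reverse orientation, or implied insert
outside median ± 4 MAD — a robust-statistics convention, since no
envelope is published for this protocol) are clustered when left and
right anchors co-locate within one median insert and the discordance
class matches. Clusters below `min_pairs = 4` are dropped: discordant-
pair callers are false-positive prone when read depth is only ~2.5x the
read length, which is exactly this design's regime. Breakpoints are then
refined to the modal soft-clip coordinate within the candidate window
(≥2 clipped reads sharing a coordinate; ties to the leftmost) — an
automated stand-in for the manual inspection step that pinned exact
breakpoint coordinates in the original protocol. The consensus rule is a
declared stand-in, not a reconstruction of those (unenumerated) manual
criteria.

## Consequence annotation

Gene models come from GFF3 (`rtracklayer`) or are built in code. Coding
SNPs are translated with the bacterial genetic code (table 11) on the
coding strand; coding indels are `frameshift` when length mod 3 ≠ 0.
`promoter_proximal` means within `promoter_window` (default 150 bp — the
field says "promoter regions" without defining them, so the window is
config, reported with every result) upstream of the annotated start on
the gene's strand. Amino-acid numbering starts at the annotated start
codon = position 1; published coordinates for the same mutation
occasionally disagree between numbering conventions, so `poolvar` fixes
one and documents it rather than adjudicating.

## The simulator: what it emulates, and what it does not

The generator reproduces the sequencing design the protocol was built
for: fragments ~Normal(230, 20) bp (the fragment SD is unpublished;
20 bp is a typical sheared-library spread), 100 bp paired-end reads,
285x mean coverage (the founder line's observed depth), flat Q30
qualities consistent with `per_base_error = 0.001`, errors uniform over
the three non-reference bases. A pool is `n_haplotypes` discrete
lineages; a variant requested at frequency `f` is planted on
`round(f × n)` haplotypes (nearest representable fraction, ties toward
zero), and the truth table records both requested and realized
frequency — the estimator is scored against the realized value, because
no estimator can beat the discreteness of the pool. Reads crossing the
junction of an indel ≥ 50 bp are soft-clipped there, as a gapped aligner
renders them; reads left with < 20 aligned bases are unmapped.

Two artifact classes exercise the filters: `strand_biased_cluster`
plants G/C mismatches on forward-strand reads at ≥3 sites within a
stated width, and `read_end_only` plants a mismatch only into reads
where the site falls within the terminal zone. Artifact sites covered by
no eligible read are recorded as unrealized.

Not emulated: sequencer-specific error profiles and quality decay along
the read, PCR duplicates, GC-coverage bias, alignment ambiguity in
repeats (the truth alignment is exact by construction), and the specific
strain mixture the original validation used (its composition is
unpublished; pool composition is a free parameter here). A green
simulation test therefore establishes correctness of the statistical
machinery under the stated read model — not robustness to real-library
pathologies, which is what the three filters are for on real data.

## Evaluation design

`power_curve()` runs the full simulate → pileup → call → filter chain
and aggregates detection by **realized** frequency. This matters for the
headline check: requested integer percents 1-20% on a 20-haplotype pool
realize as {0, 5%, 10%, 15%, 20%} (1-2% round to zero carriers and are
unrealizable by construction), so the detection floor is reported on the
realized grid. Replicate seeds derive from the master seed by fixed
increments and are logged in the result. `eval_report()` scores matched
calls one-to-one (nearest position first; tolerance 0 bp for SNPs, 5 bp
for indels), and `af_agreement()` is the in-silico analogue of
concordance with an orthogonal frequency assay: the fraction of matched
variants within 0.05 of the realized truth. At 285x the binomial
sampling SD of the frequency estimate peaks at ~0.030 (f = 0.5), so
≥90% agreement at tolerance 0.05 is the expected behaviour of a
well-calibrated estimator, and that is what the acceptance suite
demands.

## Numerical and degenerate-input choices

* Coordinates are 1-based, fully closed, everywhere a user sees them;
  FASTQ/SAM/VCF conventions apply at the format boundary.
* `0 × log 0` is taken as 0 in the likelihood, so noiseless columns with
  `e = 0` remain finite at `f ∈ {0, 1}`.
* Ties between equally supported alternate alleles break by summed base
  quality, then lexicographic base order; multi-allelic sites emit one
  call per alternate that passes thresholds independently.
* Overlapping mate pairs contribute once per site; the higher base
  quality wins, ties to the first mate encountered.
* A depth-0 column has no likelihood; `site_loglik` signals an error
  rather than returning a sentinel.
* The mid-read offset statistic is the distance to the *nearer* read
  end, so the read-position rule is symmetric in read orientation.

## Known limitations

* The likelihood is this package's own definition of the pooled model;
  byte-for-byte equivalence with historical pooled callers is not
  claimed (their exact likelihoods and priors are cited in the
  literature, not printed).
* Indel detection relies on the aligner (or simulator) emitting I/D
  CIGAR operations; indels hidden in soft clips are only visible to the
  SV evidence layer.
* SV kind classification covers deletion / insertion / inversion-like
  signatures; insertion-sequence-element family classification and
  split-read assembly are out of scope.
* Thresholds are not auto-recalibrated per dataset; they are explicit
  configuration with defaults chosen for the 285x / 100 bp regime.
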