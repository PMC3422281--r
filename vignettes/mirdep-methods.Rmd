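---
title: "Methods: miRNA target discovery in miRNA-depleted ES cells"
author: "mirdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA target discovery in miRNA-depleted ES cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdep)
library(dplyr)
```

# The analysis problem

Dgcr8 is required for canonical miRNA biogenesis: cells homozygous for
disrupting gene traps lose nearly all canonical miRNAs. This creates two
complementary opportunities that `mirdep` models end to end. First,
comparing small-RNA libraries between heterozygous and Dgcr8-depleted
cells separates canonical miRNAs (depleted) from small RNAs processed
independently of Dgcr8 (retained) — and incidentally flags catalogue
entries that are probably fragments of other ncRNA species. Second,
transfecting a single miRNA mimic into the depleted background reveals
that miRNA's direct targets in a system unconfounded by endogenous miRNA
activity or family redundancy.

Every stage is driven by tabular data (tibbles in, tibbles out) and every
input can be generated by the synthetic-data module with planted ground
truth, which is how the package validates itself.

# Small-RNA quantification

## Read filtering

Raw reads are 3′ adapter-trimmed by exact suffix/prefix match. The
adapter-trimming algorithm is deliberately simple: the longest read
suffix equal to an adapter prefix, requiring at least 6 nt of overlap and
no mismatches; untrimmed reads simply proceed to the length filter, where
a 36-nt read with fewer than 6 adapter bases fails the 16–30 nt window
anyway. This is one of several places where the pipeline names a step
but not an algorithm; the overlap and mismatch parameters are exposed.
Exact-suffix trimming is not idempotent on adversarial inputs (an insert
that happens to end in ≥6 nt of adapter prefix is trimmed again on a
second pass); on realistic libraries the event is vanishingly rare and
the test suite pins idempotence on simulated data.

Reads are then discarded when they contain three Ns inside any 5-base
window or any N within 2 bases of the 3′ end, and when they consist
mostly of short tandem repeats. "Mostly" is made precise as: a maximal
run of period 1, 2 or 3 spanning at least 80% of the read. Reads of
16–30 nt survive and are collapsed to unique sequences with depths.

## Mapping and classification

Unique reads are aligned ungapped, forward strand only, against an ncRNA
panel. A valid alignment needs ≥90% identity over ≥16 aligned bases
covering ≥75% of the read; the 3′ end is unconstrained so non-templated
additions and residual adapter merely lower coverage. The 5′ start is
constrained to position 1 or 2 of the reference feature. For miRNA
hairpins the mature-region start (positions `mature_start`,
`mature_start + 1`) is an additional allowed anchor: mature miRNA reads
begin at the mature 5′ end, not at the hairpin 5′ end, and without this
anchor no mature read could map while the classifier still needs
hairpin-anchored alignments to populate the "miRNA non-mature" class.

Reads mapping to exactly one class take that class; several classes give
`mixed_mapping`. miRNA-class reads are subdivided: `miRNA` when an
alignment to a catalogued hairpin overlaps the mature region by at least
half the read (the published rule says "outside the mature region"
without an overlap threshold; half-read overlap is the package's
definition), `miRNA_non_mature` otherwise, and `miRNA_non_catalog` when
only non-catalogued hairpins are hit.

## Normalization and independence calling

Libraries are rescaled to a reference (WT) library using the summed depth
of the non-miRNA, non-mixed ncRNA classes as anchor; the miRNA non-mature
and non-catalogue classes are miRNA-derived and are also excluded from
the anchor. After scaling, the anchor is identical across libraries by
construction (the tests require agreement to 1e-9).

Independence calling uses two thresholds: heterozygote mean normalized
depth strictly greater than 10 reads, and a homozygote/heterozygote ratio
of at least 2/3 (i.e. down-regulated less than 1.5-fold; up-regulation
passes trivially). The ratio's orientation is fixed by the observation
that a fold change of 0.688 meets the published threshold while 0.645
does not — only the homo/het ∙ ≥ 2/3 reading reproduces that pattern.
Whether the abundance filter should see raw or normalized depths is not
specified anywhere; `mirdep` applies it to normalized depths (scale
factors are near 1 when libraries are sequenced to similar depth), and
the caller accepts raw depths unchanged if preferred.

# Seed classes and UTR scanning

With the miRNA written 5′→3′, the target-strand strings are reverse
complements of miRNA windows: 7mer(2) from positions 2–8; 7mer(1A) from
positions 2–7 followed by an A at the position pairing miRNA base 1 (an
adenine opposite position 1 favours Argonaute binding irrespective of the
miRNA's first base, which is why the A is forced rather than
complemented); 8mer(1A) is their union, so `s8mer1A = s7mer2 + "A"` and
its positions 2–8 equal the 7mer(1A); and 7mer(3) from positions 3–9,
the shifted seed. These identities are property-tested over random
miRNAs.

UTRs are pre-processed before any counting: exact duplicates collapse to
the first id, and low-complexity stretches are masked to lower case. The
masking rule — a 1-, 2- or 3-mer repeating to span at least 15 nt — is
the package's own concrete choice for a step whose original parameters
are not printed; it is exposed as an argument. Masked bases break
matches: a site must lie wholly in unmasked sequence. Counting is nested
(an 8mer site also counts as one 7mer(1A) and one 7mer(2)), because the
target gate only asks for "at least one 7mer(2) or 7mer(1A)". For the
shifted-seed analysis an `exclusive_7mer3_only` flag marks transcripts
whose only sites are isolated 7mer(3) occurrences, excluding composites
where the 7mer(3) extends into a longer site shared with another seed.

# Target calling and quality statistics

The built-in differential expression is a per-transcript Welch t-test on
log2 values with Benjamini–Hochberg adjustment — a deliberately plain
test behind a table contract (`transcript_id`, `log2_fold_change`,
`p_value`, `adjusted_p`, `mean_expression`) that external moderated fits
can fill instead. A transcript is a target when
`log2FC ≤ −log2(1.2)` (inclusive: "at least 1.2-fold"),
`adjusted_p ≤ 0.05` (0.10 for less sensitive platforms), and the UTR
carries a gate seed. Transcripts with no annotated UTR are ineligible and
are excluded from both quality statistics.

Signal-to-noise divides the gate-seed proportion among significant
down-regulated transcripts by the proportion among transcripts changed
less than 1.1-fold (no significance condition on the control set);
sensitivity-above-chance is `observed_with_seed − n_down × prop_control`,
left unclamped so a below-chance list is visibly negative.

# Word-enrichment landscapes

The word universe contains, for each retained miRNA, the two 7-nt windows
of its 8mer(1A): the 7mer(2) string and the 7mer(1A) string. For each
word and each growing leading bin (step `grow`, default 500) of a ranked
UTR list, a one-sided hypergeometric compares the word's count in the bin
against the remainder, over the urn of all k-mer windows. The score is
`−log10 p` for enrichment and `+log10 p` (negative) for depletion; the
smaller tail wins, and the terminal cutoff (empty complement) scores 0 by
convention.

The order-4 Markov correction estimates, per sequence, the word
probability as the product of observed 4-mer frequencies over the word's
windows divided by the interior 3-mer frequencies (the standard Markov
telescoping). Observed counts are rescaled by the ratio of the
library-wide expected rate to the sequence-specific rate and rounded half
away from zero for the urn. This "corrected count unit" mechanism
reproduces the intent — absorbing composition bias — without claiming
bit-level equality with any particular external implementation; the
uncorrected (m = 0) landscape is the exactly testable ground truth, and
the suite verifies both the m = 0 oracle equality and that m = 4
converges to m = 0 on composition-uniform sequences. Words are scored
independently; overlapping words are not jointly corrected. Ties in the
ranking metric keep stable input order.

The Bonferroni threshold is `−log10(α / n_words)` with α = 0.01; whether
the correction should also cover cutoffs is ambiguous, so both scopes are
offered with words-only as default (with 568 words this threshold is
≈ 4.754).

# Preranked GSEA

Hits increment the running score by `|metric|^q / Σ|metric|^q` (q = 1 by
default; q = 0 gives the classic Kolmogorov–Smirnov-like walk), misses
decrement by `1/(N − s)`; the enrichment score is the signed
maximum-magnitude excursion, always in [−1, 1], and the walk returns to 0
at the end. Null scores come from random member sets of equal size drawn
without replacement. The plain estimator `count / n_perm` (floored at
`1/n_perm`) is the default so that 40000 permutations give the stated
2.5×10⁻⁵ resolution; a +1-smoothed estimator is available by flag. NES
divides ES by the mean |null ES| of the same sign — the same-sign
convention is documented here precisely because the original tool's
normalization details are not printed.

# Network influence

Curated interaction networks arrive unweighted with extreme hub degrees
that smear cluster structure. Triangle weighting (`w = 1 + α·t(e)` with
α = 1; α exposed) promotes edges embedded in locally dense
neighbourhoods, after which mutual k-nearest-neighbour reduction keeps an
edge only when its weight ranks in the top k at both endpoints. Ranking
is a total order — weight descending, neighbour id ascending on ties — so
the reduced degree is bounded by k exactly; keeping all tied edges would
break that bound, and determinism requires some tie-break, so the id
order is used and recorded.

MCL iterates expansion (matrix squaring) and inflation (entrywise power,
column renormalization) on the column-stochastic matrix with self-loops
set to each node's maximum incident weight, pruning entries below 1e-5
and stopping when the largest entry change falls below 1e-8 (at most 200
iterations, an error with diagnostics otherwise). Clusters are connected
components of the converged attractor structure, numbered by descending
size. These numeric choices are the package's own — the algorithm is
standard but its knobs are rarely printed — and the test suite pins the
partitions against an independently written dense reference
implementation on planted-partition fixtures. Two-level clustering runs
a coarse pass at inflation 1.3 and subclusters each coarse cluster at
2.0, making the nesting exact by construction.

The support of node v for cluster C is the fraction of v's total incident
edge weight (in the reduced network) carried by edges into C; summing
over a target list and dividing by |C| gives the heatmap cell, and the
shared count |list ∩ C| is printed in the cell. Cluster size counts
nodes, not annotated genes. Since clusters partition the nodes, the
supports of any non-isolated node sum to 1 across clusters — a
conservation law the tests check. Cluster annotation reuses the
hypergeometric over-representation test; the two best terms label a
cluster when their combined length is at most 50 characters, otherwise
the best term alone.

# The synthetic-data module

The generators are pure functions of their seeds and define the
conditions under which the pipeline is validated:

* **Reference panel** — 8 ncRNA classes with class-typical lengths;
  each miRNA hairpin carries a 20–24 nt mature region; 20% of miRNAs are
  flagged as absent from the catalogue.
* **Small-RNA libraries** — per-record abundances drawn once from a
  log-normal (meanlog 0, sdlog 1) shared across genotypes; canonical
  miRNA abundance multiplied by the depletion factor (0.02 for the
  depleted genotype, matching a near-complete loss) except for flagged
  independent miRNAs; reads drawn multinomially at the requested depth;
  miRNA reads start at mature position 1 or 2, other reads at feature
  position 1 or 2; raw reads are fixed 36 nt with adapter read-through
  (a 36-cycle single-ended run), exercising the trimming step; optional
  per-base substitution errors (default 0.001).
* **Transfection experiment** — a stated fraction (default 10%) of
  transcripts receives 1–3 planted gate sites and a mean log2 fold
  change of −1 with i.i.d. normal replicate noise (0.25); all other
  UTRs are rejection-sampled to contain no focal seed, except a small
  fraction (default 5%) of *silent carriers*: transcripts given one gate
  site but no expression effect. Real 3′ UTRs contain many chance,
  non-functional seed matches; without silent carriers the unchanged
  control set would contain no seed-bearing transcripts at strong
  effects and the signal-to-noise denominator would be degenerate by
  construction. Five replicates per condition are the default, chosen
  from a power analysis: at noise 0.25 and effect −1, a Welch t-test
  with BH adjustment at the 1.2-fold/0.05 thresholds needs five
  replicates for >90% per-target power; fewer replicates would make the
  benchmark measure statistical power rather than the caller's logic.
* **Interaction network** — planted-partition graph (within-cluster
  probability `p_in` > between-cluster `p_out`) plus hub nodes wired
  uniformly at random to a stated fraction of all nodes; hubs emulate
  the high-degree nodes that motivate k-NN reduction.
* **Gene sets** — random sets over a universe, optionally one set seeded
  to overlap a given list.

What the simulations do *not* emulate — realistic quality-score error
profiles, indels, paralogous reference families, UTR conservation
structure, correlated expression noise — bounds what passing tests show:
they validate the statistical logic and the implementation, not
performance on any particular real dataset.

# Problem sizes and numerical conventions

The validation suites run at deliberately moderate sizes: planted
transfection recovery uses 1000 transcripts over 20 seeded replicates;
small-RNA recovery uses libraries of 10⁵ reads over 20 seeds; MCL is
pinned against the dense reference on planted fixtures of up to ~40
nodes and planted-influence recovery uses ~48-node networks over 20
seeds; hypergeometric oracles enumerate universes of ≤ 25 elements
(literal subset enumeration) and log-scale tail sums elsewhere. The
package reports probabilities no smaller than 1e-320 on the log10 scale
to avoid −∞ scores; hypergeometric ties between enrichment and depletion
take the enrichment branch; `round half away from zero` is used when
corrected counts enter the urn.

# Known limitations

* The Markov correction is an approximation with its own discretization;
  only the m = 0 landscape is exact, and analyses needing certified
  p-values should use m = 0 on composition-matched inputs.
* The mapper is exhaustive over allowed anchors rather than seeded-hash
  based; it is intended for panel-scale references, not genomes.
* The built-in DE test is unmoderated; small-replicate array data should
  be fitted externally and supplied through the DE-table contract.
* Adapter trimming tolerates no mismatches; heavily error-prone 3′ ends
  would need a dedicated trimmer upstream.
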