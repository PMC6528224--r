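---
title: "Motif alteration signatures: model, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif alteration signatures: model, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmotif)
```

## The problem

Trinucleotide mutational signatures describe *which* point mutations a
mutagenic process produces, as a probability distribution over the 96
strand-collapsed substitution classes (`A[C>A]A`, ..., `T[T>G]T`).
They say nothing directly about *what those mutations do* to regulatory
sequence. `sigmotif` closes that gap for transcription factor binding
motifs: it computes, for every position weight matrix (PWM) and every
mutation class, the probability that one such mutation creates or
disrupts a motif occurrence, and propagates these probabilities through
signatures and per-sample exposures. The result is a background
expectation of motif gain and loss under mutational process alone —
departures from it in real cohorts point to selection or
mechanism-specific targeting.

## The counting model

**Binding definition.** A k-mer binds a PWM when the tail probability
of its log-likelihood-ratio score, under a background model and taking
the better-scoring orientation, is at most a threshold (default
`0.001` for the enumeration phase). Tail probabilities are *exact*:
the score distribution is computed by dynamic programming over an
integerized score grid (4000 bins by default; tests show agreement
with exhaustive 4^w enumeration to machine precision on the grid, and
within 5% relative error of the unrounded tail near p = 1e-4).
Working with the better-scoring orientation makes binding
strand-symmetric, which is what permits collapsing each k-mer with its
reverse complement into one canonical class (lexicographic minimum)
and halving the search space.

**Events.** For each PWM of width `w`, the canonical k-mer space is
partitioned into binding and non-binding sets. Every binding k-mer,
mutated at every interior position (2..w−1) to every alternative base,
yields a disruption event if the mutant is non-binding; creation events
are the symmetric case. End positions are excluded because a mutation
there has no complete trinucleotide context inside the window; this is
exactly the `w − 2` factor in the normalization below. Each event is
weighted by the genomic occurrence count of the *pre-mutation* k-mer
(the sequence that actually exists in the genome); k-mers absent from
the genome are still classified, with weight zero, so the event
catalog is complete and a creation event can land on a sequence the
genome does not contain.

**Normalization.** With `c_genome(t)` the genome count of
pyrimidine-centered trinucleotide `t` (each site counted once,
forward-strand scan, COSMIC convention):

$$\Pr(a \mid tf, m) = \frac{c(a \mid tf, m)}
        {c_{genome}(m_{ref}) \cdot (w(tf) - 2)}$$

Each genomic occurrence of `m_ref` is tested `w − 2` times, so the
ratio is a per-opportunity probability and is bounded by 1. Counts
accumulate as exact integers; this division is the only floating-point
step. The central correctness test in the suite recomputes Φ by brute
force — sliding over every genomic position and mutating every interior
base directly — and requires *exact integer* agreement with the
k-mer-space algorithm.

**Projections.** `S_TF = S_M Φᵀ` and `Ψ = S_TFᵀ E` are plain matrix
products per event kind. Because signature rows and exposure columns
are probability vectors, every projected value is a convex combination
of the underlying Φ row, which the tests assert as interval bounds.

## The SNV caller

Observed variants are assessed locally rather than against the
genome-wide enumeration:

* a second-order Markov background is estimated from ±500 bp of
  reference sequence around the SNV (pseudocount 1 per cell), pooling
  the window with its reverse complement so the model — and every
  p-value built on it — is strand-symmetric. Windows truncated below
  100 usable bases fall back to a genome-wide model with a warning.
* both alleles are scored over all `w` windows covering the variant, in
  both orientations; the per-allele p-value is the minimum (a binding
  site *anywhere* covering the SNV is what detection targets). The
  p-value is exact under the Markov chain, via a 16-context-state
  extension of the score-grid DP.
* a call requires the dual criterion: binding state flips at
  `p ≤ 1e-4` **and** the p-value changes at least 10-fold. Both
  thresholds are configurable; the defaults mirror the two phases of
  the method (0.001 for enumeration, 1e-4 + 10× for calling).

The stricter SNV-phase threshold exists because single-locus calls
have no occurrence-count averaging behind them; the fold condition
suppresses calls that merely graze the threshold.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `threshold_p` | 0.001 | enumeration-phase binding p-value; inclusive comparison (boundary ties are grid artifacts) |
| `binding_p` (SNV) | 1e-4 | per-locus binding call threshold |
| `fold` | 10 | minimum p-value fold change for an SNV call |
| `pseudocount` | 1 per cell | JASPAR counts; avoids −∞ scores |
| background (enumeration) | uniform 0.25 | configurable to genome composition; the k-mer phase is a genome-wide average, so a flat reference is the neutral choice |
| `window` | ±500 bp | SNV background neighborhood |
| `n_bins` | 4000 (2000 SNV phase) | score-grid resolution; chosen so the tail near 1e-4 is resolved well below the decision thresholds |
| `max_exhaustive_k` | 13 | widest motif enumerated exhaustively; beyond it the search must restrict to genomic k-mers and their mutation neighborhood |

## The synthetic-data generator

The generator exists so that every claim the package makes is testable
offline, and its defaults define the test conditions:

* **Genomes** — i.i.d. bases at a target GC content (default 0.41,
  mammalian-like), or an order-2 Markov chain whose transition
  probabilities are derived from a target trinucleotide composition;
  the chain reproduces a self-consistent target within multinomial
  noise at 100 kb. Motif consensus sequences can be planted at
  recorded, non-overlapping positions.
* **PWMs** — per-column Dirichlet draws `1 + sharpness · e_consensus`
  around a sampled consensus base (A/T-biased when `at_rich`), so
  `sharpness → ∞` gives a one-base column and `sharpness = 0` a flat
  one. Hand-crafted extremes (uniform, single-consensus, an AT-rich
  homeobox-like and a mixed paired-box-like motif) cover the entropy
  ends.
* **Signatures** — one-hot, uniform, and symmetric-Dirichlet rows
  (per-class α, default 0.1). For the entropy–imbalance acceptance
  check we use α = 0.5: real COSMIC signatures spread mass over tens
  of classes, and near-degenerate one-class signatures would measure
  signature sparsity rather than motif structure, which is what that
  statistic is about.
* **SNVs** — sites drawn with replacement, class frequencies
  proportional to signature probability × genomic trinucleotide
  abundance, emission strand chosen by the site's own strand. The
  returned table keeps every draw (so class frequencies are exactly
  multinomial); the VCF keeps each site once.

What the generator does *not* emulate: repeat structure, CpG islands,
chromatin context, mutation rate heterogeneity along the genome, or
selection. Passing tests therefore demonstrate the correctness of the
counting and projection machinery and the qualitative entropy/imbalance
behavior — not that real genomes are i.i.d., nor that real cohort
effects are free of selection.

## Numerical and degenerate-input choices

* Score integerization uses one shared rounding for the distribution
  and for query sequences, so a query lands exactly on its grid bin
  and p-values are never off by a boundary.
* `|RD|(0, 0)` is defined as 0 with a warning: the two one-sided limits
  disagree (0 and 2), so a convention is unavoidable; 0 reads as "no
  evidence of imbalance".
* Correlation ties in signature mapping break deterministically by
  target file order, with a message.
* Windows containing ambiguity codes are skipped, never imputed, in
  genome counting, background estimation and SNV scanning alike.
* Exposure tables may arrive as raw counts; they are column-normalized
  at load and the raw scale kept alongside.
* Motif entropy uses base-2 logarithms over the 32 pyrimidine-collapsed
  trinucleotides, pooling each binding k-mer's interior trinucleotides
  with equal weight. Genome-weighted pooling would be a defensible
  alternative; it rescales the axis monotonically and does not change
  the sign of the entropy–imbalance relation the tests check.

## Design decisions that were genuinely open

* **Which side's genome count weights an event.** Creation events are
  weighted by the *non-binding reference* k-mer's count (the sequence
  being mutated), matching the normalization denominator, which counts
  reference trinucleotides. Weighting by the created sequence instead
  would decouple numerator and denominator populations.
* **Canonical-space bookkeeping.** A mutation is applied in the
  canonical orientation, and original and mutant are canonicalized
  independently before set lookup. For palindromic binding k-mers
  (even widths) the two strand-mirrored mutations are distinct events
  that share one mutant class; the per-genomic-position oracle test
  confirms the canonical-space weighting reproduces direct counting
  exactly, which fixes this convention.
* **Per-allele aggregation in the SNV caller.** Minimum over windows
  and orientations. Alternatives (best window of the reference allele
  only, or summed evidence) would make calls asymmetric between
  creation and disruption.
* **Grid-width rule.** The SOM-style heuristic `argmax_w {w² < N}`
  is exposed as a plain function; the package deliberately does not
  train SOMs, cluster motifs (PAM/silhouette) or embed samples
  (UMAP/hdbscan) — these are off-the-shelf analyses downstream of the
  tables this package produces.

## Problem sizes used in the test suite

Test fixtures use genomes of 2–100 kb, motifs of width 6–8, 10–100
synthetic signatures and up to 2000 simulated SNVs; the exhaustive
p-value oracles enumerate up to 4^8 sequences. These sizes keep the
full suite around two to three minutes while still exercising every
code path at exact-arithmetic fidelity; all of them scale up linearly
in code, and `max_exhaustive_k` guards the only exponential step.

## Known limitations

* The genome-wide enumeration phase assumes i.i.d. background for the
  binding definition; a composition-matched background is configurable
  but a positional (e.g. isochore-aware) background is not modeled.
* Only single-nucleotide substitutions are considered: no indels, MNVs,
  or multi-hit interactions within one motif occurrence.
* Motifs wider than `max_exhaustive_k` are counted over genomic k-mers
  and their single-mutation neighborhood only. This is exact (absent
  k-mers carry zero weight in both event kinds), but it means the
  *unweighted* event catalog for such motifs is not materialized.
* Exposures are taken as given (from upstream signature-fitting tools);
  the package does not fit exposures from mutation catalogs.
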