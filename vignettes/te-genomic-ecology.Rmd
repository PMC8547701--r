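---
title: "Modelling the genomic ecology of transposable elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the genomic ecology of transposable elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Transposable elements are usefully viewed as an ecological community:
thousands of families, each a "species" of replicating sequence, competing
for genomic niches under host suppression. This package operationalises
that view for a TE-annotated genome. This vignette explains the models and
conventions the package commits to, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices behind edge cases.

```{r, eval = FALSE}
library(teecology)
```

## Resolving nested annotations

A TE annotation with nesting is ambiguous at the base level: a base inside
a nested insertion is covered by two (or more) copies. `resolve_nesting()`
removes that ambiguity by assigning each base to the **latest-arriving**
copy covering it. Arrival order is derived from topology: a copy contained
inside another must have inserted after it. That is the only ordering the
data supports — two *non*-nested copies never contend for a base, and a
partial (non-containment) overlap is treated as an annotation error rather
than silently resolved.

Consequences the rest of the pipeline relies on:

* the owned segments of all copies are pairwise disjoint, and their total
  length equals the union coverage of the annotation (conservation is
  asserted in the tests against a per-base sweep oracle);
* a copy whose owned bases form two or more runs is *disrupted*; a copy
  contained in another is *within_te*;
* copies with fewer than `min_surviving_bp = 50` owned bases are flagged
  `dropped`: they stay in the segment accounting but are excluded from all
  feature tables and the model.

Two length notions are kept as separate model features, because neither is
canonical: `length_bp` (owned bases) and `span_bp` (start-to-end span
including everything nested inside).

Coordinates are 0-based half-open everywhere in memory; GFF3 (1-based
inclusive) and BED (0-based half-open) conventions are honoured at the IO
boundary only.

## Dating insertions

Two estimators, deliberately kept independent:

* **LTR–LTR (K2P).** The two LTRs of an LTR retrotransposon are identical
  at insertion and diverge afterwards on both sides, so with K2P distance
  *d* between them, age is *T* = *d*/(2μ). Columns containing a gap or N in
  either sequence are excluded (pairwise deletion). When
  1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0 the logarithm is undefined (saturation);
  such copies are reported and excluded rather than clamped.
* **Terminal branch length.** From a per-superfamily phylogeny of copies,
  each copy's terminal branch *b* measures substitutions since divergence
  from its closest relative in the same genome, so *T* = *b*/μ. This is the
  only per-copy estimator available for TIR elements and Helitrons.

The divisor convention (2μ for a two-sided divergence, μ for a single
branch) is a package decision — common dating practice — and both the raw
divergence and the converted age are emitted, so a different convention is
one multiplication away. The default rate μ = 3.3 × 10⁻⁸
substitutions·site⁻¹·year⁻¹ is the standard grass nucleotide rate; it is a
parameter everywhere.

The two estimators disagree in interesting ways on real data (LTR–LTR ages
tend to run older); the pipeline reports their Spearman correlation on
whatever data it is given rather than asserting a value.

## Base composition and methylatable contexts

`compute_composition()` counts cytosines by context (CG, CHG, CHH; H = A, C
or T) on **both strands** — a forward scan of the sequence and of its
reverse complement — and divides by sequence length, so a palindromic CG
contributes one methylatable cytosine per strand and densities can reach 2.
Single-strand counting would halve every value; both-strand counting was
chosen because methylation is strand-symmetric at CG/CHG sites and the
downstream model only needs a consistent convention. A cytosine in the last
one or two bases of a sequence, lacking a complete context window, is left
uncounted; context windows containing N are skipped. The TG/CA dinucleotide
proportion — the deamination footprint of methylated CG — uses overlapping
dinucleotides divided by (length − 1).

For a disrupted copy, composition is computed over its owned segments with
*concatenation-free* pooled counting: counts are summed per segment and
divided by total length, so no context window ever spans a segment
junction. The two 1 kb flanks are pooled the same way into a single
regional value per copy.

## Methylation profiles

Methylation arrives as (or is summarised into) fixed genome-anchored 100 bp
windows per context and tissue; a window with no covered cytosine is
missing, not zero. Per copy, tissue and context the package reports 41
slots: the TE body and 20 flanking windows per side.

Conventions worth knowing:

* the **body mean** weights windows by their covered-cytosine counts
  (`weighted = FALSE` gives equal window weights); with cytosine-count
  weights, a window-aligned TE's body mean equals the plain per-cytosine
  mean, which is how the test oracle checks it;
* **flank windows are genome-anchored bins** walking outward from the bin
  boundary at each edge of the TE *span* (nested children included). They
  are clipped only at chromosome ends; flanks may and do overlap
  neighbouring TEs, as real flank metaprofiles do;
* **imputation** replaces each missing (copy, tissue, context, slot) cell
  with the family mean at that slot, falling back to the superfamily mean
  and then the global mean when a whole family or superfamily is missing.
  Observed cells are never modified, so observed family means are exactly
  preserved (asserted in tests); imputed cells are flagged.

## Expression and τ

Family expression counts (unique + family-resolved multi-mapping reads, an
upstream boundary) are normalised to reads per million per replicate,
averaged over replicates within tissue, and divided by family size for a
per-copy value. Copies inside gene transcripts are excluded from the family
size, and families with only genic copies are dropped — their transcription
cannot be distinguished from the host gene's. The tissue-specificity index
τ = Σᵢ(1 − xᵢ/x_max)/(n − 1) is 0 for constitutive and 1 for single-tissue
expression; an all-zero vector has no defined maximum tissue, so τ is
missing (and later coded −1 by the model stage) rather than 0. Genes run
through the identical summary code path, in whatever normalised unit the
atlas provides.

## Recombination: the monotone map

A genetic map should be non-decreasing in physical position, but a raw
polynomial fit to map points need not be. The package fits an ordinary
least-squares polynomial (degree 7, orthogonal basis on scaled positions),
evaluates it on a dense grid, projects the grid values onto the nearest
non-decreasing sequence by isotonic regression, and serves the result as a
clamped piecewise-linear interpolator. The composition is monotone *by
construction*, exact on linear maps, and close to the unconstrained
polynomial wherever that was already monotone. With fewer points than
polynomial coefficients the fit falls back to isotonic piecewise-linear
interpolation with a warning. A TE's recombination rate is then
(f(end) − f(start)) / (length in Mb), clamped-and-flagged outside the
fitted range.

## The age model and its interpretation

The model stage regresses per-copy age on the assembled features with a
random forest (default 1000 trees), after coding every missing value as −1,
converting logicals to 0/1, and capping the family factor at the 31 largest
families plus `"smaller"` (a 32-level factor is the practical limit for
binary encoding in the forest implementation). Copies are split uniformly
at random 50/50 into train and test; all reported performance and all
interpretation use the held-out half — permuting a feature on the training
half would understate nothing and flatter everything.

* **Permutation importance**: each feature's test-set column is permuted
  (default 20 repeats; the toy pipeline default is 5), and the package
  reports the mean MSE increase, that mean scaled by its standard deviation
  over repeats, and the RMSE increase in kya — an interpretable "years of
  accuracy lost". Zero-variance features get importance 0 and a flag.
  Category importance sums member features' MSE increases over the nine
  feature categories (TE taxonomy, TE base composition, TE methylation and
  chromatin accessibility, TE expression, TE-encoded proteins, nearest gene
  expression, and the regional counterparts).
* **Per-family correlations**: Pearson r of each feature with age within
  each family; a feature fixed within a family yields a missing value, not
  zero. Families can and do differ in sign — a global importance hides
  this.
* **ICE curves**: for a chosen feature, predictions for every test copy at
  20 grid values spanning the central 95 % of the observed feature (2.5th
  to 97.5th percentile), with all other features held at observed values;
  deviations are prediction minus the copy's observed age, summarised as
  per-superfamily means. When a slope is read off an ICE curve (as the
  recovery tests do), it is estimated over the **interior** of the grid
  (grid points 4–17 of 20): tree ensembles cannot extrapolate, so
  predictions flatten at the edges of the feature support and a full-grid
  slope is biased toward zero by roughly 15 % even at n = 5000.

## The synthetic genome

`generate_dataset()` builds every input layer from one seed. Its defaults
are the package's standard toy study conditions: 3 chromosomes × 300 kb,
two families per superfamily with negative-binomially sized families
(shifted so every family has ≥ 2 copies and a tree), 30 % nested
insertions, μ = 3.3 × 10⁻⁸, five tissues (anther, SAM, earshoot, flagleaf,
seedling leaf) with 2–3 replicates and ~10⁶-read libraries. These values
were chosen once, as a scaled-down caricature of a TE-rich plant genome
that still exercises every code path (a few hundred copies, ~40 % TE
occupancy); the methods are size-independent.

What it emulates, and how:

* **Placement**: copies are placed in age order (oldest first); each new
  copy either lands in free sequence (rejection sampling, no overlap) or,
  with the configured probability, strictly inside an existing copy —
  never straddling one — so arrival order equals generation order and a
  nested child is always younger than its parent. One nesting chain of
  depth ≥ 3 is guaranteed whenever nesting is on. Impossible packings
  raise an explicit capacity error.
* **Sequence**: each family has a consensus with its own GC bias, and
  optionally CG→TG/CA deamination (which produces the negative
  p_CG–p_TG/CA correlation across families seen in methylated genomes);
  each copy's sequence is the consensus evolved along a branch μ·age under
  a K80 process with transition:transversion 2:1 — exactly the model the
  K2P estimator inverts, which is what makes age recovery a true oracle
  test rather than a consistency check.
* **LTR pairs and trees**: each LTR copy's two LTRs evolve independently
  from the same ancestral LTR (expected pair divergence 2μ·age); each
  superfamily gets a star tree whose terminal branches are exactly μ·age,
  so terminal-branch dating recovers truth to machine precision.
* **Data layers**: methylation is binomial per window with family-level
  propensities elevated in TE bodies (CHH low throughout) and ~3 % window
  dropout per tissue to exercise imputation; expression is negative
  binomial with a family-level silenced indicator and mostly single-tissue
  activity (high τ, as TE families show); the genetic map is a cumulative
  gamma process; MNase intervals, variants and A/B subgenome blocks are
  simple homogeneous layers.

What it does **not** emulate: realistic karyotypes or sequence homology
between families, insertion-site preference, selection against insertions,
solo-LTR formation, indels in LTR alignments (pairs come pre-aligned and
gap-free), read-level data, and linkage structure in the variant layer.
A green recovery suite therefore shows the *estimators and pipeline* are
correct under their stated models, not that those models capture every
property of a real genome.

`generate_age_features()` is a deliberately minimal harness for the model
stage alone: independent standard-normal features, of which a named few
drive age through linear/quadratic/step effects plus Gaussian noise, with
47 decoys by default. Its recovery conditions (n = 5000, three causal
features, noise SD 10⁵ years) give a signal-to-noise ratio around 3:1 —
strong enough that failure indicates a defect, weak enough that the decoy
comparison is not trivial.

## Numerical choices and edge cases

* Nearest-gene ties break leftmost-start, then lexicographic id; distances
  use the half-open gap (adjacent intervals are 0 apart); a chromosome with
  no genes yields missing distances, never 0.
* Subgenome assignment is by maximal base overlap; exact ties give "none".
* Overlapping MNase intervals are unioned before computing covered bases,
  so proportions never exceed 1.
* K2P saturation and empty alignments raise typed errors; the batch
  interface excludes such copies with a warning instead of failing.
* Trees with missing branch lengths warn and treat them as 0; duplicate
  leaf labels are errors.
* All generator and model randomness flows from explicit integer seeds;
  the pipeline stamps outputs with a config hash and skips up-to-date
  stages unless forced, and reruns are byte-identical.

## Problem sizes used in validation

The test and acceptance suites run the toy conditions above: ~200-copy
genomes for end-to-end runs, 500 simulated LTR pairs for age recovery,
100 random annotations (≤ 100 kb, nesting depth ≤ 4) against the per-base
oracle, 100 random genetic maps for monotonicity, and 20 harness seeds at
n = 5000 for causal-feature recovery with 100-tree forests and 5
permutation repeats (the package defaults of 1000 trees and 20 repeats are
used for reported analyses; the reduced settings are ample for rank
recovery). These sizes are the package's own validation conditions, chosen
to keep the full suite fast on a laptop.

## Known limitations

Arrival order among non-nested copies is unobservable from an annotation,
so "latest arrival" is only defined where nesting defines it. The family
factor cap means small-family effects are absorbed into `"smaller"`. ICE
curves for categorical features (level substitution) are not implemented.
Importance estimates with few permutation repeats have noisy scale
denominators — rank by the MSE increase, not the scaled score, when repeats
are few.
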