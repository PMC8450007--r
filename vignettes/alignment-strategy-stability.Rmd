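---
title: "Comparing alignment strategies in bipartition-support tree space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing alignment strategies in bipartition-support tree space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitscape)
```

# The problem

Deep phylogenies built from ribosomal RNA genes are sensitive to how the
alignment was built and masked. Manual masking, structure-aware automatic
alignment followed by gap/block trimming, confidence-score filtering at a
series of thresholds, and stepwise removal of the fastest-evolving sites all
yield defensible alignments — and sometimes different trees, particularly
for clades prone to long-branch attraction. `splitscape` turns a collection
of such trees into a quantitative comparison: which clades differ, and which
strategy is most stable against its own perturbations.

# Model and procedure

## Trees as support vectors

An unrooted tree over taxon set $T$ is the set of bipartitions (splits)
induced by its internal edges. We store each split in a canonical
orientation (the side *not* containing the first taxon of the sorted
universe) so that a split and its complement map to one key. A tree with
per-edge supports becomes a sparse vector: entry $X_{tb}$ is the support of
split $b$ in tree $t$. Assembling all trees over the union of their splits
gives the trees × bipartitions support matrix.

Splits absent from a tree are coded 0 — "absent" and "unsupported" are
deliberately conflated, since an absent split is exactly one the analysis
gave no support to. This choice (rather than a missing-data marker) is what
lets strategies that *disagree about which splits exist* be compared in one
linear space; an explicit `fill = NA` mode exists but PCA then refuses
incomplete columns. A split present in a tree whose edge carries no support
label is a genuinely missing measurement and is kept as `NA` so it cannot
silently enter the PCA as a zero.

Support scales (bootstrap percent vs posterior probability) must be declared
per collection and can be normalized to percent (`normalize = TRUE`
multiplies probabilities by 100); mixing scales silently would make columns
incommensurable.

## Backbone reduction

With a user-supplied scheme assigning taxa to groups whose monophyly is not
in question, a split is a *backbone* split when every group falls entirely
on one side and at least one group lies on each side. The reduction keeps
the backbone splits that are well supported across the collection: support
$\ge$ `min_support` (default 50 on the percent scale) in at least a
`min_presence` fraction of trees (default 0.5). Both knobs are exposed
because the verbal criterion they operationalize — splits "expressing only
the interrelationships of the main groups, well supported by all analyses" —
admits no single canonical formalization. Unassigned taxa are an error by
default; the wildcard mode (unassigned taxa never violate a group) must be
requested explicitly because it changes results silently otherwise.

## PCA, contributions, stability

Columns are centered and, by default, scaled to unit variance
(`standardize = TRUE`; zero-variance columns are dropped and reported).
The decomposition is the eigendecomposition of the covariance matrix with
denominator $n - 1$; tests cross-check it against the SVD route at $10^{-8}$.
Component signs are fixed by making the largest-magnitude loading positive —
PCA signs are otherwise arbitrary and would break byte-reproducibility.
The contribution of split $j$ to component $k$ is $100\,\ell_{jk}^2$, summing
to 100 per component over the retained splits; the top-contributing splits
name the clades on which the strategies disagree.

Stability of a strategy is its dispersion: the mean pairwise Euclidean
distance among the strategy's tree scores restricted to the first $K = 2$
components (the components one inspects). Mean pairwise distance was chosen
over the trace of the within-group covariance because it is defined for two
points, robust to the choice of $K$, and zero for a single tree; strategies
are ranked ascending, rank 1 = most stable. Per-strategy tree statistics
(total tree length, log-likelihood) are summarized with type-7
(linearly interpolated) quartiles.

## Masking series

Three generators reproduce the common alignment-thinning protocols:

* **gap/block** — keep a column iff its non-gap fraction is at least the
  gap threshold (default 0.5; the boundary is "$\ge$", so a column with
  exactly half gaps survives — the trimAl-compatible reading), then drop
  maximal runs of kept columns shorter than `min_block` (default 3). Runs
  are evaluated once, not recursively, which makes the operation idempotent.
* **score thresholds** — for each cutoff in a strictly ascending series
  (default 0.715, 0.794, 0.900, 0.942, 0.970, 0.973, 0.990, the
  confidence-score series used with GUIDANCE2-style column scores), remove
  columns scoring below it. Outputs are nested by construction.
* **rate stripping** — with per-column rate categories $1..C$ (1 = slowest,
  $C = 8$ matching an 8-category discretized gamma), step $k$ removes the
  $k$ fastest categories; "fastest category" means the highest category
  index, which the site-table reader validates as a contiguous range
  starting at 1.

All three preserve sequence ids and row order and report the kept original
column indices, so masked coordinates map bijectively back.

## Helix analysis

The dot-bracket parser stack-matches pairs (pseudoknots are outside the
grammar and rejected) and classifies the region between consecutive nested
pairs: $a$ unpaired bases 5′ and $b$ bases 3′ give a 5′ bulge ($a>0, b=0$),
a 3′ bulge ($a=0,b>0$), an internal loop (both), or nothing (stacked);
innermost pairs close hairpins. Strand polarity is positional: the
lower-index strand of a pair is 5′. The bulge signature counts 1-nt bulges
per strand within an optional position window (no fixed helix coordinates
exist, so the window is user input): exactly one 1-nt 3′ bulge and nothing
else is the eukaryote-typical helix-17 state, two such bulges the derived
double-bulge state produced by one extra 3′-strand nucleotide, anything else
"other".

Structure states evolve along the phylogeny; `fitch_transitions()` computes
the minimal number of state changes with a unit-cost small-parsimony dynamic
program. States are opaque symbols, so whole loop-pattern strings
("bulge–2bp–bulge") work directly. The bottom-up pass is exact for
multifurcations (plain Fitch set operations are not), the count is invariant
to rooting, and the top-down pass returns one optimal internal labeling with
ties broken towards the parent state, then lexicographically.

# The synthetic world

The generator emulates the situation the pipeline is built for: several
strategies of trees over a shared taxon set, each a cloud around a possibly
rearranged backbone.

* **Topology.** A base random binary tree with monophyletic groups (default
  4 groups × 4 taxa = 16 taxa — large enough for a non-trivial backbone,
  small enough for hundreds of replicates in seconds). Each strategy's
  backbone applies its configured number of NNI moves to the focal edge,
  chosen deterministically as the lowest canonical group-respecting split so
  backbone variants are comparable across seeds. Per tree, each internal
  edge independently triggers a random NNI with the strategy's jitter
  probability.
* **Supports.** Beta noise with mean $\mu$ and concentration $\kappa$,
  rounded to integer percent. Within-group edges use
  $\mu_\text{stable} = 0.95$ (groups are recovered by all analyses),
  backbone edges $\mu_\text{var} = 0.75$ (the contested relationships).
  These were fixed once as field-realistic values and are not tuned.
* **Branch lengths.** Exponential with mean 0.1 substitutions/site.
* **Alignments.** Uniform A/C/G/T residues, independent per-cell gaps at
  per-column probabilities, per-column confidence scores from Beta(4, 1)
  (mostly-confident columns, as empirical score distributions are), and
  rate categories from a shape-0.5 gamma binned into $C = 8$
  equal-probability classes.

Randomness derives from one root seed through deterministic per-stage
sub-seeds, so adding trees to a config never perturbs the alignment stream.

What a green test does **not** establish: the synthetic trees have no
sequence-level evolution (no substitution-model simulation), no alignment
uncertainty feeding back into topology, no correlation between gap patterns
and rate categories, and jitter NNIs are uniform over edges rather than
concentrated on short ones. The synthetic recovery results validate the
*statistical machinery* (a denser generative cloud is reported as denser),
not any claim about real alignments.

# Numerical choices and degenerate inputs

* Covariance denominator $n-1$; eigenvalues clipped at 0; all-equal rows
  yield all-zero eigenvalues and (under standardization) an explicit error,
  since no column survives scaling.
* Dispersion of a single-tree strategy is 0 by definition.
* Conflicting supports on the two edges merged at a suppressed degree-2
  root are a hard error; `conflict = "max"` is the documented override.
  Non-numeric internal labels warn and are ignored.
* Polytomies are accepted everywhere and simply contribute fewer splits.
* Column ordering of the support matrix is fixed (split size, then
  lexicographic membership mask) and number formatting goes through a
  single `%.15g` path, so all outputs are byte-stable.
* Internal coordinates are 1-based (the R convention) while on-disk tables
  are 1-based as documented; the gap/block worked example keeps the same
  three physical columns either way.
* The canonical Newick writer orders children by the smallest contained
  taxon index. Its basal arrangement reflects the (deterministic) unrooting
  of the input, so two differently rooted renderings of one topology may
  print with different basal rotations while carrying identical split sets;
  round-trips are exact.

# Known limitations

* The reduction criterion is a parameterized surrogate; a published
  reduction can generally not be reproduced without its exact rule.
* Dispersion differences come without a significance test (out of scope).
* The CLI reads whole files into memory; collections of thousands of large
  trees would need streaming.
* GUIDANCE2 scores and per-site rates are consumed, never computed: the
  upstream inference tools remain external by design.
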