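# splitscape

Phylogenetic trees inferred from the same loci can disagree depending on how
the sequences were aligned and which columns were masked before inference.
`splitscape` quantifies that disagreement. It is aimed at molecular
systematists who run the same dataset through several alignment/masking
strategies (manual masking, structure-aware alignment plus automatic
trimming, confidence-score filtering, fast-site stripping) and want to know
*which strategy gives the most stable trees* and *which clades drive the
differences*.

## The method

Each tree with branch supports (ultrafast-bootstrap percentages or Bayesian
posterior probabilities) is represented as a vector over bipartitions
(splits): for tree *t* and split *b*,

```
X[t, b] = support of b in t   (0 when b is absent from t)
```

with columns the union of splits over all trees, each split stored in
canonical orientation (the side not containing the first taxon). The matrix
is optionally reduced to **backbone splits** — splits in which every
predefined taxon group lies wholly on one side, so that only the
interrelationships of the groups remain — and filtered by a support/presence
rule (support ≥ 50 in ≥ 50 % of trees by default). A standardized PCA of
`X` then gives:

* per-tree scores (a "tree space" where each point is one analysis),
* per-split contributions `100 · loading²` to each component (which
  relationships differ between strategies),
* a per-strategy **dispersion** — the mean pairwise Euclidean distance of a
  strategy's scores in the first K = 2 components. Denser cloud = more
  stable strategy.

The package also ships the alignment-thinning generators that produce such
tree series (gap-threshold 0.5 / minimum-block 3 masking; the
0.715–0.990 confidence-score threshold series; stepwise removal of the
fastest of 8 rate categories), an RNA helix analyzer (dot-bracket loop
classification, 3′-strand bulge signatures of the helix-17 type, Fitch
parsimony transition counts for structure states on a tree), and a
synthetic-data module so the entire pipeline is testable without any
external data.

## Worked example

```r
library(splitscape)

# a synthetic world: 16 taxa in 4 groups; three strategies whose backbones
# differ by 0/1/2 NNI moves, with increasing topological jitter and
# increasingly noisy supports
cfg <- synth_config(
  group_sizes = c(4, 4, 4, 4),
  strategies  = data.frame(
    label  = c("manual", "structural", "guidance"),
    n_trees = 12L, nni = c(0L, 1L, 2L),
    jitter = c(0, 0.1, 0.3), kappa = c(200, 50, 10)),
  seed = 1)
sim <- generate_treeset(cfg)

m   <- build_support_matrix(sim$treeset)      # 36 trees x 48 splits
red <- reduce_matrix(m, sim$scheme)           # 4 backbone splits kept
p   <- run_pca(red)
group_dispersion(p, K = 2)
```

```
<stability_report> K = 2 (rank 1 = most stable)
   strategy  n dispersion rank
     manual 12  0.2085342    1
 structural 12  1.4772084    2
   guidance 12  2.7490441    3
```

The manual strategy's trees form the densest cloud (dispersion 0.21), the
noisy "guidance" strategy the loosest (2.75) — the stability ranking
recovers the generative noise order. `variable_contributions(p, 1)` lists
the backbone splits driving PC1.

The same pipeline runs from the command line on real files:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/splitscape", package="splitscape"))')
Rscript $CLI simulate  --out demo --seed 1
Rscript $CLI stability --manifest demo/manifest.tsv --scheme demo/scheme.tsv \
                       --outdir demo_out
Rscript $CLI mask-gaps --fasta demo/alignment.fasta --outdir demo_masked
```

`stability` writes `scores.csv`, `loadings.csv`, `contributions.csv`,
`stability.csv`, `reduction_report.tsv` and a `run_log.txt`; reruns are
byte-identical for the same config and seed.

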