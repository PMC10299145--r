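# coexreg

Prioritising candidate regulatory genes from developmental RNA-seq data by
combining a weighted gene co-expression network with overlapping graph
clustering of an interaction network.

## The problem

Insect development (moulting, metamorphosis) is driven by hormone pathways
— ecdysone and juvenile hormone — whose timing is controlled by a small set
of regulatory genes: nuclear receptors, transcription cofactors and their
kin. Given

- a gene-by-sample read-count matrix across developmental stages,
- a gene interaction network (e.g. a protein–protein interaction network of
  hub genes), and
- a list of genes already annotated as regulatory,

the pipeline identifies which regulatory genes sit inside densely connected,
stage-associated network neighbourhoods, and ranks them as candidates for
follow-up work such as RNAi target validation.

## The method

1. **Preprocessing** — genes with fewer than ten reads in total are removed;
   counts are normalised by median-of-ratios size factors and a shifted log2
   transform; the most variable genes (top 5% by default, the q95 rule) feed
   network construction.
2. **Signed WGCNA** — adjacency `a_ij = ((1 + cor_ij)/2)^β` with β chosen as
   the smallest power whose connectivity distribution reaches a scale-free
   fit R² ≥ 0.80; topological overlap
   `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`; average-linkage
   clustering of `1 − TOM` with eigengene merging (cut height 0.25) and kME
   refinement; module eigengenes correlated with stage indicators; hub genes
   are module members with kME ≥ 0.80.
3. **Overlapping clustering (DPClusO-style)** — greedy seeded growth on the
   interaction network under a density floor `d_k ≥ d_min` (swept over
   0.5–0.9) and cluster-property floor `cp_nk = E_nk/(d_k·N_k) ≥ 0.5`;
   emitted members stay in the graph so clusters may overlap.
4. **Prioritisation** — each cluster's regulatory-gene content is tested
   with the one-sided hypergeometric upper tail (Fisher's exact test for
   over-representation); each gene scores
   `SScore = −log10(min p over containing clusters)`; a ROC threshold sweep
   (predict regulatory when SScore ≥ th) gives TPR/FPR and a trapezoidal
   AUC per density; the best density's significant clusters (p < 0.05)
   supply the ranked candidate list.
5. **Gene-set enrichment** — hypergeometric over-representation with
   Bonferroni correction (overlap ≥ 3, enrichment factor > 1.5) of the
   candidates against any GMT collection.

Because the transcriptomes this procedure was designed around are not
publicly deposited, the package ships a synthetic-data generator that plants
stage-associated co-expression modules in negative-binomial counts and dense
regulatory clusters in an interaction network (338 nodes / 30 regulatory by
default), so every stage is testable end to end against known truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package functions;
running it end to end,

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_network_modules.R
Rscript analysis/04_cluster_prioritize.R
Rscript analysis/05_enrichment.R
```

prints (abridged):

```
simulated 250 genes x 9 samples; network: 338 nodes, 1183 edges, 30 regulatory
filter: 250 of 250 genes pass (>= 10 reads total; 0 removed)
variance selection: 200 genes kept
Module-trait Pearson correlations (n = 9 samples)
             egg larva3   pupa  adult
turquoise -0.549 -0.157 -0.134  0.861
blue       0.421  0.049 -0.043 -0.434
brown     -0.327  0.798 -0.557 -0.021
yellow     0.106 -0.370  0.704 -0.390
modules positively associated with the larval stage: brown
hub genes per module: turquoise=50, blue=41, brown=38, yellow=32
AUC by density: 0.5=0.859, 0.6=0.877, 0.7=0.905, 0.8=0.905, 0.9=0.906
best density: 0.9
5 significant clusters (p < 0.05); 20 candidate regulatory genes
planted in-cluster regulatory genes recovered: 20 / 20
5 of 5 planted-cluster sets enriched among the 20 candidates
```

Reading this: the four planted modules are recovered and each correlates
with its planted stage (the `brown` module is the larva-associated one);
the density sweep's best cluster set contains five significant clusters —
the five planted regulatory-gene clusters — and all 20 planted in-cluster
regulatory genes are recovered as candidates, each traced to its best
cluster in `results/candidates.tsv`.

Key single calls:

```r
library(coexreg)

# enrichment of a 15-gene cluster containing 9 of 30 regulatory genes,
# against a 338-gene network background
bg  <- sprintf("g%03d", 1:338)
reg <- bg[1:30]
cl  <- c(reg[1:9], bg[31:36])
cluster_enrichment(cl, reg, bg)$p_value
#> [1] 3.516458e-07

# density selection from an AUC-by-density map
select_best_density(c("0.5" = 0.913, "0.6" = 0.950, "0.7" = 0.824,
                      "0.8" = 0.947, "0.9" = 0.934))
#> [1] 0.6
```

## Layout

```
R/                 package code: synthetic data, preprocessing, WGCNA core,
                   overlapping clustering, prioritisation, gene sets, pipeline
analysis/          numbered workflow drivers (thin wrappers over R/)
scripts/           acceptance.R
tests/testthat/    unit, property and recovery suites
vignettes/         methods vignette: models, parameters, design decisions
```

The methods vignette (`vignettes/regulatory-gene-prioritisation.Rmd`)
documents the statistical model of the generator, every tunable parameter
with its default and rationale, numerical edge cases, and known
limitations.
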