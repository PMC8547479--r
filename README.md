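# ecoassembly

Null-model inference of microbial community assembly processes from 16S
rRNA count tables, a phylogeny and sample metadata.

## The problem

Microbial communities assemble through a mixture of deterministic
selection (environmental filtering) and stochastic processes (dispersal
and ecological drift). For time series of communities — for example
groundwater wells sampled repeatedly across a chemical gradient — a
pair of null models can partition every pairwise community comparison
among these processes:

1. **βNTI** (beta nearest taxon index). For samples *A* and *B* the
   abundance-weighted between-sample mean nearest taxon distance is

   βMNTD(A,B) = ½ [ Σᵢ∈A pᵢ minⱼ∈B d(i,j) + Σⱼ∈B pⱼ minᵢ∈A d(i,j) ],

   with *d* the patristic (cophenetic) distance and *p* relative
   abundance. Shuffling taxon labels across the tip distance matrix
   generates a null distribution; the standardized deviation

   βNTI = (βMNTD_obs − mean βMNTD_null) / sd βMNTD_null

   flags deterministic turnover: βNTI > 2 means communities are more
   phylogenetically divergent than chance (**variable selection**),
   βNTI < −2 less divergent (**homogeneous selection**).

2. **RCbray** (abundance-weighted Raup-Crick on Bray-Curtis). For pairs
   with |βNTI| ≤ 2, each sample is re-assembled from the regional
   metacommunity profile — observed richness drawn by occurrence
   frequency, observed depth filled by mean relative abundance — and
   the observed Bray-Curtis dissimilarity is ranked within the null:
   RCbray = 2·rank − 1 ∈ [−1, 1]. RCbray > 0.95 indicates **dispersal
   limitation** (with drift), RCbray < −0.95 **homogenizing
   dispersal**, and anything else **undominated** assembly.

The package implements both nulls, the five-way classification with
process-fraction summaries over sample groupings (all pairs,
within-well, between-well, pH categories), the supporting statistics
(per-sample NTI, Bray-Curtis, richness, Pielou evenness, Mantel tests
against environmental distances, a Mantel correlogram testing the
phylogenetic-signal precondition, PERMANOVA), and a metacommunity
simulator whose five scenario presets carry known ground truth so every
inference stage can be verified end to end.

## Worked example

```r
library(ecoassembly)

# a dispersal-limited metacommunity with known ground truth
ds <- generateDataset("dispersal_limitation", seed = 1)
ct <- countTable(ds)
D  <- copheneticDistances(phyloTree(ds))

bnti <- betaNTIMatrix(ct, D, reps = 199, seed = 2)
rcb  <- rcBrayMatrix(ct, reps = 199, seed = 3)

g  <- buildGroupings(sampleData(ds), "between_well")[[1]]
processFractions(bnti, rcb, g)
```

```
ProcessFractions [between_well]: 60 pairs (0 excluded)
    variable_selection  homogeneous_selection   dispersal_limitation
                   3.3                    0.0                   93.3
homogenizing_dispersal            undominated
                   0.0                    3.3
```

93% of the between-site pairs are classified as dispersal limitation —
the process that generated the data. The same pipeline runs from files
(`readCountTable()`, `readNewick()`, `readMetadata()`, then
`alignInputs()`), or in one call from a YAML config via `runPipeline()`,
which writes the βNTI/RCbray matrices in the deposited square-CSV
layout, per-pair calls, fraction tables, per-sample diversity and a
reproducibility manifest.

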