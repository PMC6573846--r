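# ecoassembly

Null-model inference of the ecological processes that assemble microbial
communities, from an OTU count table, a rooted phylogeny, and sample group
metadata.

Microbiome surveys routinely ask not just *how* communities differ between
habitats or seasons, but *why*: how much of the turnover is driven by
deterministic environmental selection, and how much by stochastic dispersal
and drift? `ecoassembly` implements the null-model-based statistical
framework that answers this at the level of sample pairs, for anyone
analysing amplicon-style community data (soil, aquatic, host-associated)
with replicated groups.

## The statistics at its core

For every unordered pair of samples the package computes:

* **βMNTD / βNTI** — phylogenetic turnover. βMNTD is the abundance-weighted
  mean distance from each taxon in one community to its nearest relative in
  the other, averaged over both directions; βNTI standardizes it against a
  null built by shuffling taxon labels across the tips of the pooled
  phylogeny:

  βNTI = (βMNTD_obs − mean_null) / sd_null

  βNTI < −2 indicates **homogeneous selection**, βNTI > +2 **heterogeneous
  selection**.
* **RCbray** — taxonomic turnover for the remaining pairs. The observed
  Bray–Curtis dissimilarity is placed within a null distribution of
  dissimilarities between communities probabilistically reassembled from
  the regional pool (preserving each sample's richness and total
  abundance); RC = 2·quantile − 1. RC > +0.95 indicates **dispersal
  limitation**, RC < −0.95 **homogenizing dispersal**, and |RC| ≤ 0.95 the
  **undominated** bin (drift and weak processes).

Pair labels are aggregated into process fractions overall, within each
group, and between groups. Supporting statistics: rarefaction, Chao1
(S_obs + F1²/2F2), Shannon/Simpson/Pielou indices, within-sample MNTD/NTI,
Bray–Curtis matrices, and ANOSIM. A synthetic-data module generates
two-group OTU tables with *known* ground-truth assembly processes
(selection, dispersal limitation, homogenizing dispersal, drift) so the
whole inference chain is testable without any sequencing data.

## Worked example

Simulate a dispersal-limited two-group design (20 samples, 200 taxa,
depth 2,000) and run the full pipeline:

```r
library(ecoassembly)

sim <- simulate_communities(assembly_scenario("dispersal_limited", seed = 42))
res <- run_pipeline(sim$otu, sim$tree, sim$metadata, depth = 2000,
                    out_dir = "results_run",
                    config = null_model_config(n_null = 299), seed = 42)

res$anosim$r_statistic
#> [1] -0.03944444
head(res$pairs[, c("sample_a", "sample_b", "beta_nti", "rc", "process")], 4)
#>   sample_a sample_b beta_nti rc              process
#> 1    SG_01    SG_02   -0.404  1 dispersal_limitation
#> 2    SG_01    SG_03    0.086  1 dispersal_limitation
#> 3    SG_01    SG_04   -0.903  1 dispersal_limitation
#> 4    SG_01    SG_05   -1.092  1 dispersal_limitation
subset(res$summary, scope == "all" & n_pairs > 0)
#>  scope                 process n_pairs fraction
#>    all   homogeneous_selection       2   0.0105
#>    all heterogeneous_selection       4   0.0211
#>    all    dispersal_limitation     155   0.8158
#>    all             undominated      29   0.1526
```

Reading the output: |βNTI| < 2 for most pairs rules out selection, and
RC ≈ +1 says the observed Bray–Curtis turnover exceeds essentially every
stochastic reassembly of the shared taxon pool — the signature of
dispersal limitation, which the generator built in. 82% of the 190 sample
pairs are classified accordingly. The near-zero ANOSIM R is expected here:
both groups are assembled by the same process, so there is no *group*
separation, only high turnover everywhere. Per-sample diversity sits in
`res$alpha` (e.g., sample SG_01: 44 observed OTUs, Chao1 48.0, Shannon
2.84, Pielou 0.75), and every table is also written under `results_run/`
together with a JSON manifest recording all parameters and per-stage
seeds; rerunning with the same seed reproduces the outputs bit for bit.

Real data enter the same way, as file paths:

```r
run_pipeline("otu_table.tsv", "tree.nwk", "metadata.tsv",
             depth = 11000, out_dir = "results_run", seed = 1)
```

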