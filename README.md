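# ecoassembly

Downstream community ecology for eukaryotic-plankton (and other
microbial) metabarcoding surveys of coastal waters.  Starting from an
OTU-by-sample count table, a rooted phylogeny over the OTUs, and sample
metadata along environmental gradients, the package computes:

* **data I/O and filters** — validated TSV/Newick/CSV readers, the
  strict 90%-identity / 90%-coverage taxonomy confidence filter,
  relative-proportion transform, dominant-taxon (>1%) summaries, and a
  hypoxia flag (DO < 2 mg/L);
* **diversity** — Shannon index (nats) with layer-wise ANOVA and
  Spearman environment correlations, Welch t tests between layers,
  Bray–Curtis dissimilarity, and NMDS minimising Kruskal stress-1 with
  monotone (pool-adjacent-violators) regression;
* **spatial** — haversine distance matrices and distance-decay of
  community similarity with a Mantel-style label-permutation test;
* **assembly** — the two-stage phylogenetic null model: abundance-weighted
  βMNTD → βNTI by taxa-shuffle z-scores, then Raup–Crick on Bray–Curtis
  (RCbray) by probabilistic community reassembly, with per-pair
  classification

  | βNTI | RCbray | process |
  |---|---|---|
  | > 2 | — | heterogeneous selection |
  | < −2 | — | homogeneous selection |
  | \|βNTI\| ≤ 2 | > 0.95 | dispersal limitation |
  | \|βNTI\| ≤ 2 | < −0.95 | homogenizing dispersal |
  | \|βNTI\| ≤ 2 | otherwise | undominated |

  and per-stratum (surface / bottom / all) process fractions;
* **synthetic data** — a seeded metacommunity generator (birth–death
  phylogeny, Brownian niche evolution, estuarine salinity gradient
  1.82–32.17‰ across 17 two-layer sites, four assembly regimes) so the
  whole pipeline is testable without sequencing data.

See `vignettes/community-assembly.Rmd` for the models, parameter
defaults, calibration properties, and known limitations.

## Worked example

```r
library(ecoassembly)

sc  <- simulate_scenario("dispersal_limitation",
                         scenario_config(n_taxa = 150, seed = 7))
dir <- tempfile(); write_scenario(sc, dir)
res <- run_pipeline(file.path(dir, "table.tsv"), file.path(dir, "tree.nwk"),
                    file.path(dir, "meta.csv"), file.path(dir, "out"),
                    reps = 199, seed = 42)
```

`out/summary.txt` then reads:

```
samples: 34   taxa: 150
Shannon range: 2.491 - 3.474
layer ANOVA: F = 0.002, p = 0.9631
NMDS stress: 0.0232
distance-decay [surface]: rho = -0.989, p = 0.001
distance-decay [bottom]: rho = -0.988, p = 0.001
distance-decay [all]: rho = -0.990, p = 0.001
modal assembly process (all pairs): dispersal_limitation
```

Reading: alpha diversity is similar between layers (ANOVA p ≈ 0.96, as
expected — the generator drew both layers from the same regime), the
ordination embeds the dissimilarities almost perfectly (stress 0.023),
similarity decays strongly with distance (Spearman ρ ≈ −0.99,
permutation p = 0.001 at 999 permutations), and the null model
recovers the generating regime: 81% of within-layer pairs classify as
dispersal limitation, 12.5% undominated, 6% heterogeneous selection
(`out/process_summary.tsv`).  Per-pair βNTI/RC values are in
`out/assembly_pairs.tsv`; `out/manifest.json` records parameters, seed,
and input checksums so the run can be reproduced byte-for-byte.

A command-line wrapper with the same capabilities is installed at
`inst/cli/ecoassembly.R` (`simulate` and `run` modes).

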