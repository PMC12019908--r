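# secretome

Analysis pipeline for the **extracellular metaproteome of granular
biofilms** — microbial aggregates such as the *Ca.* Accumulibacter
enrichments used in biological wastewater treatment, whose matrix is held
together in part by secreted, aggregate-forming proteins.

The package is written for proteomics bioinformaticians who have already
run peptide identification and annotation predictors and need the
downstream, reproducible part of the analysis:

* **In-silico digestion** for four protease regimes (trypsin,
  chymotrypsin, LysC, LysC/trypsin), specific and semi-specific, with
  missed-cleavage accounting — and **iBAQ conversion**,
  `iBAQ = intensity / N_theoretical`, where the theoretical peptide count
  is the number of fully specific, zero-missed peptides of 7–30 residues
  under the protease regime of each sample.
* **Experiment-wide protein grouping**: proteins share a group iff they
  share an approach-specific group in ≥ 1 approach and never belong to
  different groups within any approach; conflicts are resolved
  deterministically in canonical order and logged.
* **Property screen**: GRAVY, aromaticity, Henderson–Hasselbalch net
  charge (EMBOSS pKa), cysteine fraction, length, plus beta-sheet
  fraction, mean RSA and mean disorder aggregated from per-residue
  structure predictions; all converted to average-rank percentiles.
  A protein is nominated as a candidate aggregate-forming protein when
  (i) some property is in the top 10% (hydrophobicity, beta-sheet,
  cysteines, aromaticity, length, |charge|) or bottom 10% (RSA,
  disorder), (ii) its abundance is top-50% in ≥ 1 approach, and (iii) it
  is predicted secreted or extracellular. Candidates are clustered with
  Euclidean distance and complete linkage (k = 9 by default).
* **Biomass accounting** by SP/TM evidence, subcellular location,
  taxonomy and COG category (multi-category proteins allocated fully to
  each category), and cumulative secreted-biomass coverage.
* A **seeded synthetic-metaproteome generator** with planted ground truth
  (true candidates and decoys), so the whole pipeline is testable without
  raw MS data.

## Worked example

```r
library(secretome)
library(dplyr)

sim <- simulate_metaproteome(sim_config(seed = 42))   # 500 proteins
res <- run_pipeline(sim$dataset)

res$biomass_shares %>%
  filter(key_type == "secreted", key == "secreted_or_extracellular")
#>   approach    key_type key                       share
#> 1 shaved      secreted secreted_or_extracellular 0.978
#> 2 supernatant secreted secreted_or_extracellular 0.988
#> 3 whole       secreted secreted_or_extracellular 0.654

res$coverage
#>   approach    threshold n_proteins
#> 1 shaved           0.5           6
#> 2 shaved           0.75         11
#> 3 supernatant      0.5           6
#> 4 supernatant      0.75         11
#> 5 whole            0.5           6
#> 6 whole            0.75         12

nrow(res$candidates)        # 68 candidate aggregate-forming proteins
table(res$clusters$cluster_id)
#>  1  2  3  4  5  6  7  8  9
#> 15 12  8  7  6  5  5  5  5
```

Reading the output: the two surface-targeting approaches (shaved,
supernatant) are strongly enriched for secreted biomass relative to
whole-granule lysis, a handful of proteins carries most of the secreted
biomass (6 proteins cover 50% of it in the shaved samples), and the
screen nominates 68 candidates which fall into 9 property clusters. On
this synthetic world every one of the 25 planted true candidates is
recovered and no decoy is selected — that is the generator's built-in
regression oracle.

Real datasets enter through `read_dataset(fasta, quant, annot, struct)`
(schemas documented in `?read_fasta`, `?read_quant`, `?read_annotations`,
`?read_structure`); all thresholds live in `default_config()` /
`read_config()`. A small CLI wrapper is installed under
`system.file("scripts", "secretome", package = "secretome")`.

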