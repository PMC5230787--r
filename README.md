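# ksgtome

Analysis of how the translation-initiation inhibitor Kasugamycin reshapes
the *Escherichia coli* translatome, for researchers working with
polysome-fractionation (translatome) expression data.

Kasugamycin blocks initiation on canonical transcripts whose 5'-UTR carries
a Shine-Dalgarno (SD) motif but spares leaderless transcripts. Starting from
per-replicate intensities for two RNA fractions (free and polysomal mRNA) in
untreated and treated cultures, the package

1. computes per-replicate **translational efficiencies**
   TE = polysomal / free;
2. applies replicate QC: conditions with a coefficient of variation
   (sd/mean) ≥ 60% get a deterministic leave-one-out outlier exclusion, and
   genes must retain ≥ 3 of 5 replicates in both conditions;
3. computes the **Kasugamycin effect value** per gene,
   KEV = mean TE(treated) / mean TE(untreated), median-normalized in log2
   space so KEV = 1 is the average drug effect; genes with KEV ≤ 0.5 are
   *sensitive*, ≥ 2.0 *resistant*, with per-gene Welch t-tests on log2 TEs;
4. analyses start regions: 77-nt windows around the start codon (40 nt
   upstream + first 37 nt of ORF, codon removed), SD detection against the
   consensus TAAGGAGG (present at ≥ 5 position-wise matches or a run of
   ≥ 4), SD–AUG distances, and leaderless classification (5'-UTR ≤ 4 nt
   strict, ≤ 7 nt relaxed);
5. builds **relative-entropy structure logos** per gene group (information
   `Σ q log2(q/p)` in bits against the set's own base composition, upright
   letters over-represented, inverted under-represented);
6. compares annotation features between groups (distal position in operons,
   intergenic distance < 15 nt, 5'-UTR lengths) with Fisher exact tests.

A synthetic-data module (`simulate_translatome()`,
`simulate_start_regions()`, `assemble_genome()`, `simulate_annotation()`)
generates all inputs with known ground truth, so the full pipeline runs and
validates without any external download. The tables of printed worked
examples (22 experimentally mapped 5' ends; group-level feature counts)
ship with the package (`mapped_5p_ends()`, `group_feature_counts()`).

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(`01_simulate_data.R` … `06_printed_tables.R`); run them in order from the
repository root. Stage 1 writes the simulated experiment under
`scratch/simulated/`, later stages write result tables under `results/`.
Stage 2 on the default synthetic experiment (2801 genes, 5 replicates,
seed 1) prints:

```
1817 of 2801 genes passed the >=3-replicates filter (64.9%)
classified: average=1483, resistant=184, sensitive=150
median log2 KEV after normalization: 0
most resistant / most sensitive KEV ratio: 522-fold
log2 KEV RMSE vs truth: 0.563; recall sensitive 0.91, resistant 0.90
```

i.e. about 65% of genes survive the replicate filter (the missingness model
is calibrated to that rate), the normalization centres the log2 KEV
distribution exactly, and the planted sensitive/resistant genes are
recovered with ~0.9 recall at the default noise level. Stage 6 re-derives
the published worked examples from the packaged tables:

```
published yes/no labels reproduced: TRUE
sensitive: 5 of 10 SD-positive, mean SD-AUG distance 5.8 nt
sensitive 5'-UTR lengths: 22-193 nt
resistant: 5 of 9 SD-positive, mean SD-AUG distance 5.8 nt
resistant 5'-UTR lengths: 20-173 nt
sensitive group-level: distal 12/73 (16%), intergenic<15 13/102 (13%)
resistant group-level: distal 46/105 (44%), intergenic<15 39/137 (28%)
```

— the SD detection rule reproduces all 19 published yes/no calls, both
groups have the same mean SD–AUG spacing (5.8 nt), and the resistant group
is strongly enriched for distal operon positions and short intergenic
distances, the signature of translational coupling.

Programmatic use mirrors the drivers:

```r
library(ksgtome)
sim <- simulate_translatome(simulation_config(seed = 1))
res <- kev_analysis(sim$measurements)
table(res$class[res$pass])
```

`run_pipeline()` executes all stages against measurement/genome/annotation
files or objects and writes every stage table plus a YAML run summary.

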