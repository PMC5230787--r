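---
title: "Methods: translatome analysis of Kasugamycin action"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translatome analysis of Kasugamycin action}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Polysome fractionation separates, for each culture, the mRNA that was being
translated at harvest (polysomal fraction) from the mRNA that was not (free
fraction). Competitive hybridisation gives one intensity per (gene,
condition, fraction, replicate). The per-replicate **translational
efficiency** is

\[ \mathrm{TE} = \frac{\text{polysomal signal}}{\text{free signal}}, \]

and the per-gene drug effect — the **Kasugamycin effect value (KEV)** — is
the ratio of the mean TE in treated cultures over the mean TE in untreated
cultures. Two-channel intensities carry arbitrary global scales, so the
absolute degree of translation inhibition is not identifiable; only effects
*relative to the average gene* are. We therefore median-centre the log2
treated/untreated TE ratios across all analysed genes, which makes a KEV of
1 the average drug effect by construction. Genes with KEV at or below 0.5
are called *sensitive* (at least twofold stronger inhibition than average),
genes at or above 2.0 *resistant*; both boundaries inclusive.

The KEV is a ratio of condition means of TE, not a mean of per-replicate
ratios: biological replicates are independent cultures and are not paired
across conditions. For the same reason per-gene significance uses a
two-sided Welch (unequal-variance) two-sample t-test on the log2 TEs of the
retained replicates. The log scale is the natural one for strictly positive
ratio measurements, and Welch avoids assuming equal replicate variance in
treated and untreated cultures. p-values are reported raw; the analysis
makes few planned contrasts and no genome-wide discovery claim, so no
multiplicity adjustment is applied.

## Replicate quality control

With five biological replicates, a single aberrant measurement can dominate
a gene's coefficient of variation (CV = sd/mean of replicate TEs). The
original screening procedure inspected all genes with CV of 60% or more by
eye and removed obvious outliers; we formalise that as a deterministic
rule. If a condition has at least four usable TEs and its CV is at or above
`cv_threshold` (0.60), the single value whose removal most reduces the CV
is excluded, provided it deviates from the mean of the remaining values by
more than `outlier_k` (2) times their standard deviation. The rule is
applied at most once per gene and condition and never below two retained
values (the standard deviation must stay defined); a gene whose CV remains
high is kept but flagged. The rule is checked against a brute-force
leave-one-out oracle in the test suite.

Genes are analysed only if they retain at least `min_replicates` (3) of the
`total_replicates` (5) replicates in **both** conditions, counted after
outlier exclusion; all other genes are carried through to the final table
with an explicit exclusion reason, so no gene is silently dropped. A
missing or non-positive intensity makes that replicate's TE missing — never
zero.

## Start regions, SD motifs, leaderless calls

For every analysed gene we extract the 40 nt upstream of the start codon
and the first 40 nt of the reading frame, remove the 3-nt codon, and store
the resulting 77-nt window 5'→3' on the coding strand (reverse-strand genes
are extracted from mirrored coordinates and reverse-complemented; windows
that run off a sequence end are N-padded and flagged). Reports use 1-based
inclusive forward-strand coordinates; positions within windows are labelled
−40..−1 and +4..+40.

The Shine-Dalgarno detector compares candidate 8-mers position-wise
(ungapped) against the consensus TAAGGAGG and calls a site present if it
has **at least 5 matches or a run of at least 4 consecutive matches**. This
rule is not stated in any reference; it is the simplest rule we found that
reproduces all 19 published yes/no calls of the worked-example table, and
both cut-offs are configurable. When scanning a sequence the candidate's 3'
end may lie 2–12 nt upstream of the start codon — the published SD–AUG
distances span 3–7 nt, and the scan range is widened symmetrically so real
sites are never clipped; the best candidate is chosen by total matches,
then longest run, then smallest distance. `N` never counts as a match.

A transcript is *leaderless* in the strict sense with a 5'-UTR of at most 4
nt and in the relaxed sense at most 7 nt. Two mapped 5' ends within 3 nt of
each other are treated as the same transcription start (`end_tolerance`),
absorbing mapping uncertainty of the 5'-end chemistry.

## Relative-entropy structure logos

For a gene set, the background `p` is the pooled base composition over all
positions of all windows of that set. Per position, with observed
frequencies `q`, the information content is the relative entropy
\(\sum_b q_b \log_2 (q_b / p_b)\) (bits), and each base is drawn with
signed height \(\mathrm{sign}(q_b - p_b)\, q_b \cdot I\): upright letters
are over-represented relative to the set's own composition, inverted ones
under-represented. This height convention makes the absolute heights at a
position sum exactly to its information content, and with a uniform
background it reduces to the familiar Shannon logo height \(2 - H(q)\).
The original web tool's exact height convention is not documented; an
alternative proportional to \(|q_b - p_b|\) could be substituted without
touching the information computation. A pseudocount of 0.5 per base (per
column, and on the pooled background) keeps logarithms finite on small gene
sets of around a hundred sequences; `N` bases are excluded from both
numerator and background counts.

## Feature comparisons

Group summaries count, per sensitivity class: distal-in-operon genes (only
genes listed in the feature annotation enter the denominator), genes whose
intergenic distance to the upstream gene is below 15 nt (all genes in the
denominator; distances are annotated-start minus upstream-annotated-end
minus 1 in 1-based coordinates, so overlapping genes are negative and count
as below threshold — overlap being the strongest evidence of translational
coupling), leaderless genes at both thresholds, and the mean 5'-UTR length
(genes with two mapped ends contribute the mean of both; leaderless calls
use the shorter end). Percentages are rounded half-up to integers, which
reproduces every published percentage from its printed counts. Group
contrasts are tested with a two-sided Fisher exact test; the reported odds
ratio is the sample odds ratio with a 0.5 continuity correction when a cell
is zero. The published comparison reports fractions without a formal test;
the test is added here so the contrast is assertable on synthetic data.

## The synthetic-data generator

The generator exists so the whole pipeline can be exercised, with known
ground truth, in the absence of deposited raw data. It emulates the study
design: 2801 analysable genes, two conditions × two fractions × five
biological replicates with dye-swap metadata on two of them (carried but
never used — no dye-specific correction is modelled), log-normally
distributed baseline abundances and TEs, and per-gene true effects.

True log2 KEVs are normal(0, `log2_kev_sd`) for average genes, shifted by
±`effect_log2` (default 2) for sensitive/resistant genes planted at the
observed group rates (102/2801 and 137/2801). The drawn effects are then
median-centred and the *centred* values stored as truth: a KEV is defined
relative to the median gene, so the centred effect is the estimand the
pipeline can recover, and truth class labels derived from it are consistent
with the thresholds by construction. At zero noise the pipeline recovers
these true log2 KEVs to machine precision — a test anchoring the whole
estimator chain.

Free parameters the source experiment does not constrain, chosen once as
plausible for two-channel translatome data and not revisited:
`noise_cv = 0.3` (multiplicative log-normal noise per intensity; replicate
TE CVs then frequently approach the 60% inspection trigger, as the QC
design anticipates), `missing_prob = 0.18` (chosen so roughly 64% of genes
pass the 3-of-5 rule, mirroring 2801 of 4382 probes), `outlier_prob = 0.01`
with factor 8 (gross outliers that the CV rule must catch), and
`log2_kev_sd = 0.35`, which keeps the bulk of average genes inside the
twofold thresholds so the planted classes dominate the tails, as in the
real distribution. Start regions draw from base composition
A/C/G/T = 0.29/0.22/0.23/0.26 (midpoints of the reported per-set ranges);
SD sites (consensus with 0–2 mismatches) are planted in 65% of genes — the
canonical-transcript fraction reported for this organism — with spacers of
3–7 nt. Annotation tables plant distal-in-operon fractions of 16%/30%/44%
for sensitive/average/resistant genes, matching the observed group
contrast, with short (sometimes negative) intergenic distances for distal
genes and a 1.7% leaderless fraction.

What the generator deliberately does not model: probe-level microarray
artefacts (cross-hybridisation, spatial effects, background), dye bias,
correlated noise between fractions of the same gradient, operon-level
correlation of expression, and any sequence–KEV dependence beyond the
planted features. Passing recovery tests therefore show the estimators are
correct under the stated noise model, not that the model captures every
failure mode of real arrays.

## Numerical and degenerate-input conventions

* Median-centring makes the median log2 KEV zero to machine precision
  (bit-exact for odd gene counts).
* KEVs are invariant under global rescaling of either condition's
  intensities; this is tested directly.
* Histogram bins (width 0.25 log2 units; the published figure's binning is
  unstated) are centred on multiples of the width so a symmetric
  distribution bins symmetrically around 0.
* Welch tests require two retained replicates per condition and return `NA`
  for constant data; genes keep their records either way.
* Ties in the SD scan resolve toward more matches, longer runs, then
  smaller distances; ties in the logo peak report resolve to the most
  upstream position.
* The analysis is deterministic: a fixed generator seed reproduces every
  output byte for byte.

## Problem sizes used in the checks

The packaged checks run the full pipeline at the study scale (2801 genes)
and calibration properties at 10 000 genes (null Welch type-I error within
the 99% binomial interval of 0.05); sequence-composition recoveries use
10 000 windows; oracle agreements (leave-one-out outlier rule, exhaustive
hypergeometric Fisher enumeration) run on hundreds of small random
instances. The worked-example table of 22 mapped 5' ends and the published
group count table ship with the package and take well under a second.

## Known limitations

* The genome-wide headline counts of the source study (102 sensitive, 137
  resistant of 2801; 100-fold KEV span; logo peaks of 0.46/0.27 bits)
  derive from its supplementary microarray data and the real genome, which
  are not distributed with this package; the pipeline reproduces the
  worked-example tables exactly and the genome-wide quantities in
  distribution on synthetic data.
* The SD rule is a reverse-engineered surrogate with two tunable cut-offs;
  on other consensus registers (the published table implies its register
  by typography) it may need re-tuning.
* The outlier rule is a deterministic stand-in for expert visual
  inspection; it removes at most one replicate and will not catch two
  coordinated outliers in the same condition.
* Normalisation assumes most genes respond averagely; if a treatment
  shifted the majority of the translatome in one direction, median-centring
  would absorb that global shift into the definition of "average effect".
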