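---
title: "Methods: batch filtering, annotation and lipid–cytokine integration"
author: "lipicyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batch filtering, annotation and lipid-cytokine integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipicyte)
```

## The problem

Untargeted lipidomics of brain tissue after mild traumatic injury produces a
feature table — tens of thousands of aligned chromatographic peaks, each with
an m/z, a retention time and per-animal peak areas — alongside a targeted
multiplex cytokine panel on the same animals. Three obstacles stand between
that table and a biological statement: cohorts run far apart show batch
structure that dominates any ordination; only a small fraction of features can
be named; and relating a high-dimensional semi-quantitative lipidome to a
15-analyte cytokine panel needs a screening rule that is explicit about both
effect size and correlation strength. This package implements that pipeline
end to end, and — because the real study's counts depend on deposited data —
ships a generator that plants every effect it is later asked to recover.

## Statistical model, stage by stage

**Retention-time filter.** Features eluting with the solvent front are
unreliable (ion suppression); everything with RT strictly below `min_rt`
(default 0.75 min) is dropped. "Below" is read strictly: RT = 0.75 survives.

**Sham-anchored Welch filter.** For feature $i$ with log2 intensities $x$ in
sham batch 1 and $y$ in sham batch 2, the Welch statistic

$$t_i = \frac{\bar x - \bar y}{\sqrt{s_x^2/n_x + s_y^2/n_y}}$$

with Welch–Satterthwaite degrees of freedom gives a two-sided $p_i$; the
feature is removed when $p_i < \alpha$ (default 0.05). Three choices matter:

* *Sham anchoring.* Only sham animals enter the test, so injury effects —
  however large — cannot influence removal. The suite verifies this by
  perturbing injured samples arbitrarily and checking the removal set is
  byte-identical.
* *No multiplicity correction.* For a removal filter, removing more features
  is conservative; raw $p < \alpha$ matches the filter's intent. The cost is a
  known ~$\alpha$ type-I removal rate among null features (measured 4.4% at
  5 sham/batch — slightly under the nominal 5% because the Satterthwaite
  approximation is mildly conservative at these group sizes).
* *Degenerate features.* Zero variance in both groups with equal means gives
  $p := 1$ (kept); with unequal means $p := 0$ (removed). The statistic is
  undefined there and the convention follows what the filter is for.

The all-sample variant (batch 1 vs 2 over everyone) is provided for
comparison. A caution discovered by simulation: batch-balanced group effects
inflate the within-batch variance, so the all-sample test is *conservative*
on injury-affected features rather than aggressive; its real liability is any
chance confounding of injury with batch, which the sham-anchored filter is
immune to by construction.

**PCA diagnostics.** Samples are observations, features are centred
variables; unit-variance scaling is off by default because log2 peak areas
are already comparable. Residual batch structure is quantified per component
as the absolute standardized mean difference (pooled-SD Cohen's d) of scores
between batches, replacing by-eye reading of score plots.

**Exact-mass annotation.** Each feature's m/z is compared with every
dictionary entry × allowed adduct of its ion mode; a candidate matches when
$|10^6 (m/z_\mathrm{obs} - m/z_\mathrm{theo}) / m/z_\mathrm{theo}| \le$ 5 ppm
(precursor) — tolerances standard for an Orbitrap platform at 30,000/15,000
resolution, configurable in the dictionary object. Candidates are ranked by
absolute ppm error; exact ties break by matched fragment count, then
lexicographic name, making annotation deterministic. Identification
confidence: level 2 requires ≥ 1 diagnostic MS2 fragment within 10 ppm;
precursor-only matches are level 3 and flagged. The shipped dictionary (91
species across 18 subclasses, from acylcarnitines to sulfoglycolipids) builds
every formula from backbone + acyl-chain composition, so each entry's
monoisotopic mass is consistent with its name by construction; compositions
indistinguishable by exact mass within one ion mode (e.g. an O-40:5 ether
and a P-40:4 plasmalogen) are carried as a single record.

**Sibling summation.** Isotopologues and same-species adduct features are
summed per sample *on the raw scale* — sums of logs are meaningless — into
one species-level feature; the representative m/z and RT come from the most
intense member. The pipeline enforces raw-before-log ordering and total
intensity per sample is conserved exactly.

**Volcano analysis.** Per species, a one-way fixed-effects ANOVA across
sham/1X/3X on log2 data, with Tukey HSD (studentized range, Tukey–Kramer for
unbalanced groups) pairwise p-values. The classification p is the
Tukey-adjusted p of the plotted contrast extracted from the three-group
model — not a two-group t-test — and the fold change is the ratio of
raw-scale arithmetic group means (a geometric-mean variant is available;
the arithmetic ratio is the default because peak-area summaries are
conventionally reported that way). "Up" requires FC ≥ 1.25 and p < 0.05;
"down" FC ≤ 1/1.25 and p < 0.05. 1.25-fold is ≈ 0.32 log2 units. No FDR
control is applied across features, deliberately matching the screening
character of the analysis; subclass direction tallies count FC > 1 vs FC < 1
regardless of significance, with FC exactly 1 excluded and reported.

**Cytokine injury effects.** The assay's out-of-linear-range analytes carry a
flag and are excluded wholesale. With one observation per animal there is no
repeated-measures structure, so the "mixed-effect" phrasing common in prism
workflows is interpreted explicitly as a fixed-effects linear model
`concentration ~ injury (+ batch)`, batch entering additively whenever both
batches are present (switchable). Pairwise injury contrasts are
Tukey-adjusted via `emmeans`; with the batch term disabled and complete data
this reduces exactly to the ANOVA+Tukey routine, which the suite checks.
Missing animals are handled per analyte by complete-case analysis.

**Integration.** Spearman's ρ (average ranks for ties; pairwise-complete
animals; undefined for constant vectors and reported missing) is computed
between every annotated lipid and every in-range cytokine over a group
restriction. The restriction pairs an injury group with its sham reference
(sham + 3X by default) so that the correlation and the fold-change criterion
describe the same animals; a pure-injury-group restriction is available by
passing a single group. The dual filter keeps lipids with |FC| beyond 1.25
*and* max |ρ| ≥ 0.4, then cytokines with at least one passing partner; it is
provably monotone in both thresholds (tested). Note the filter screens by
correlation magnitude only — no significance test on ρ — so at ~19–35 shared
animals, null lipids that slip past the FC criterion have an appreciable
chance of a |ρ| ≥ 0.4 somewhere in a 15-cytokine panel; this is a property
of the screening rule itself, visible in the synthetic false-positive rates.

## The synthetic-data generator

`synth_config()` fixes the study conditions; `generate_bundle()` emits a
feature table, MS2 spectra, a cytokine panel, and the ground truth.

* **Design.** 2 batches × {sham, 1X, 3X} × `n_per_cell` animals, sexes
  alternating within a cell. The default of 5 per cell (30 animals) is a
  cost-reduced approximation of the real design; validation runs that need
  study-scale power use 9 per cell (54 animals, the study's size).
* **Intensities.** Log-normal baselines: per-feature mean log2 intensity
  uniform on [10, 20], residual SD `noise_sd` = 0.5 log2 units — the
  multiplicative error structure typical of peak areas.
* **Batch effects.** A `frac_batch` = 10% subset is shifted in batch 2 by
  ±`batch_shift` (default 1.5 log2 units = 3·`noise_sd`, where the Welch
  filter at 5 sham/batch has ~97% power). Dictionary-derived lipid features
  are excluded from the batch-affected set so the planted biology survives to
  the integration stage.
* **Injury effects.** 2% of features are shifted in 3X (1% in 1X) by
  |`injury_log_fc`| = 1 log2 unit; 90% of affected 3X features decrease
  (`frac_decrease_3x`), 1X splits evenly — mirroring the decrease-dominated
  repeat-injury lipidome the pipeline is designed around.
* **Masses.** Planted lipids take a dictionary adduct m/z perturbed by
  Gaussian `ppm_noise` (2 ppm); decoys are uniform on 150–2000 Da. At a 5 ppm
  tolerance this is a 2.5σ window, so ~1% of planted lipids are expected to
  fall outside — annotation recall ≥ 95% is the designed margin, not 100%.
  A fraction of planted lipids receive +1 isotopologue sibling rows at
  proportional intensity.
* **Cytokines.** 27 analytes matching a rodent bead panel roster, 12 flagged
  out of linear range. Concentrations are Gaussian on the assay scale
  (per-analyte baseline mean, 15% CV) so a planted effect of
  `cytokine_effect_sd` = 1.5 is exactly 1.5 within-analyte SDs on the scale
  the injury model analyses. Four pro-inflammatory analytes (IL-1beta, IP-10,
  TNF-alpha, RANTES) receive that decrease in 3X animals. One animal is
  dropped from the panel by default, emulating a lost assay sample.
* **Couplings.** Planted lipid–cytokine pairs are realized through a Gaussian
  rank copula: the cytokine's latent normal is correlated at
  $r = 2\sin(\pi \rho / 6)$ with the standardized lipid log-intensity, which
  makes the realized *Spearman* correlation equal the target ρ regardless of
  either variable's marginal scale. When several lipids couple to one
  cytokine, the latent is tied to the standardized mean of the partners'
  z-scores; per-pair realized |ρ| is then somewhat below the target but well
  above the 0.4 screen at the default ρ = 0.8. Coupled analytes inherit the
  lipids' injury decrease through the copula and receive no additional direct
  effect.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: chromatographic drift and peak-shape artefacts,
correlated missingness, heavy-tailed intensity error, intensity-dependent
mass error, co-eluting isomers, and any real biological covariance structure
among lipids beyond the planted group effects. Recovery rates here are upper
bounds for well-behaved data, not predictions for any particular instrument.

## Numerical choices and edge cases

* Welch, ANOVA and Tukey p-values are computed by vectorised matrix routines
  (thousands of features per call); `stats::t.test`, `stats::aov` +
  `TukeyHSD` serve as independent oracles in the test suite, which also
  checks agreement with enumeration/permutation references on small samples.
* Degenerate conventions: all-identical ANOVA groups give p = 1; zero
  within-group variance with differing means gives p = 0; a constant vector
  has no rank correlation and yields a missing matrix cell.
* Fold changes require strictly positive group means; FC exactly 1 is
  excluded from direction tallies and counted separately.
* The log transform records base and pseudocount in the table's provenance,
  and fold changes always invert it back to the raw scale; re-logging a
  logged table is an error rather than a silent double transform.
* Seeds: every generator consumes `seed` (feature table), `seed + 1` (MS2),
  `seed + 2` (cytokines), so bundles are bit-reproducible and the components
  are individually reproducible.

## Validation design and problem sizes

The test suite validates calibration and recovery at desk scale, chosen to
keep the full run under ~2 minutes while leaving clear statistical margins:
null calibration of the sham filter over 200 replicates of 1,000 features at
5 sham/batch; batch-recovery and volcano power on single 500–1,000-feature
tables; annotation recall on 60 planted lipids at 2 ppm noise; end-to-end
selection recovery over 20 seeds of 1,000 features at the 54-animal design;
and cytokine direction recovery over 20 seeds. For the cytokine check the
suite requires each planted analyte to be flagged as significantly decreased
in ≥ 90% of seeds and the exact planted set to be the modal outcome; with
eleven null analytes tested at a within-analyte family-wise α of 0.05, an
occasional spurious flag is the correct behaviour of the procedure, so
demanding a perfectly clean set in ~every seed would test the α convention,
not the implementation.

## Known limitations

* Batch handling is subtractive (feature removal), not corrective; model
  based correction (ComBat-style location/scale adjustment) is out of scope.
* Annotation stops at species-level exact-mass + fragment evidence
  (identification level 2); sn-positions, double-bond locations and
  spectral-library cosine scoring are not attempted.
* The correlation screen is magnitude-only by design; users wanting error
  control over the ρ matrix should treat the selection as a shortlist, not
  an inference.
* The cytokine model assumes one observation per animal; true repeated
  measures designs need a genuinely mixed model and are not supported.
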