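# lipicyte

Integrative analysis of untargeted LC-MS lipidomics feature tables and
multiplex cytokine panels for two-batch, three-group (sham / single-impact
"1X" / repeat-impact "3X") rodent brain-injury designs — with a synthetic-data
generator that plants known batch effects, injury effects and lipid–cytokine
couplings so that every stage of the pipeline can be validated against a
recoverable ground truth.

## Who this is for

Mass-spectrometry and neurotrauma labs that receive a post-quantification
feature table (one row per aligned chromatographic peak with m/z, retention
time and per-sample peak areas) plus a Luminex-style cytokine panel, and need
the downstream statistics: batch-effect feature removal, exact-mass lipid
annotation, differential analysis, and multi-omics correlation screening.
Peak detection, alignment, gap filling and drift correction are assumed done
upstream by vendor software and are out of scope.

## The method

The pipeline runs in a fixed order, each stage a plain function over tibbles:

1. **Retention-time filter.** Features with RT < 0.75 min (solvent front, ion
   suppression) are removed; the boundary is kept.
2. **Sham-anchored batch filter.** For each feature, Welch's unequal-variance
   t-test compares the *sham controls* of batch 1 vs batch 2 on
   log2 intensities; features with p < 0.05 are removed. Anchoring on shams
   means genuine injury signal — which lives in the injured groups — cannot be
   mistaken for a batch effect. An all-sample variant and PCA diagnostics
   (per-component batch-separation scores, a standardized mean difference of
   PC scores) are provided for comparison.
3. **Exact-mass annotation.** Features are matched against a lipid dictionary
   over an adduct table ([M+H]+, [M+NH4]+, [M+Na]+ / [M−H]−, [M+HCOO]−) at a
   5 ppm precursor tolerance, where ppm error = 10⁶·(observed −
   theoretical)/theoretical. A candidate reaches identification level 2 when
   ≥ 1 diagnostic MS2 fragment (e.g. the phosphocholine head-group cation at
   184.0733 Da) matches within 10 ppm; otherwise it stays at level 3.
4. **Sibling summation.** Isotopologues and same-species features are summed
   per sample on the raw scale into species-level features.
5. **Volcano differential analysis.** Per species, a one-way ANOVA across
   sham/1X/3X on log2 data with Tukey HSD post-hoc; the Tukey-adjusted p for
   the plotted contrast is combined with the raw-scale mean-ratio fold change.
   A species is "up" when FC ≥ 1.25 and p < 0.05, "down" when FC ≤ 1/1.25 and
   p < 0.05.
6. **Cytokine injury effects.** Out-of-linear-range analytes are dropped by
   flag; each remaining analyte is modelled as `concentration ~ injury
   (+ batch)` with Tukey-adjusted pairwise contrasts (emmeans), complete-case
   per analyte.
7. **Integration.** Spearman rank correlation of each annotated lipid with
   each cytokine over the shared animals of an injury group plus its sham
   reference; the dual filter keeps lipids with |FC| beyond 1.25 **and** at
   least one |ρ| ≥ 0.4, and cytokines with ≥ 1 passing partner. A PCA over
   the selected lipid panel visualizes the injury effect.

## Worked example

Generate a study-scale synthetic experiment (2 batches × 3 injury groups ×
9 animals, 1,000 features, 12 injury-affected lipids copula-coupled to three
cytokines at Spearman 0.8) and run the whole pipeline:

```r
library(lipicyte)

cfg    <- synth_config(n_features = 1000, n_per_cell = 9, seed = 42)
bundle <- generate_bundle(cfg)
report <- run_pipeline(bundle$table, bundle$panel,
                       bundle$dictionary, bundle$spectra)
report
#> <run_report>
#>   n_detected               1006
#>   n_after_rt               956
#>   n_after_batch            808
#>   n_batch_removed          148
#>   n_annotated_features     60
#>   n_species                55
#>   n_volcano_up             0
#>   n_volcano_down           12
#>   n_analytes_in_range      15
#>   n_selected_lipids        12
#>   n_selected_cytokines     7
```

Reading the funnel: of 1,006 generated features (1,000 base + 6 isotopologue
siblings), 50 eluted before 0.75 min and were dropped; the sham-anchored
Welch filter removed 148 (the 100 planted batch-shifted features plus ~5%
type-I error); 60 features matched the dictionary and collapsed to 55
species; the volcano found exactly the 12 planted decreases in the 3X group
and nothing spurious; and the dual filter recovered all 12 planted lipids.

```r
report$selection
#> <integration_selection> 12 lipids, 7 cytokines (|FC| >= 1.25, |rho| >= 0.4)

head(tidy(report$selection), 5)
#> # A tibble: 5 × 4
#>   lipid     cytokine    rho fold_change
#>   <chr>     <chr>     <dbl>       <dbl>
#> 1 Car(18:1) Eotaxin   0.567       0.506
#> 2 Car(18:1) IP-10     0.627       0.506
#> 3 Car(18:1) LIX       0.418       0.506
#> 4 Car(18:1) RANTES    0.515       0.506
#> 5 Car(18:1) TNF-alpha 0.531       0.506
```

`Car(18:1)` halved in the injured group (FC 0.51) and tracks the coupled
cytokines with moderate positive rank correlations. The extra selected
cytokines are not artefacts: every analyte that decreases with injury
(directly planted or coupled through a lipid) rank-correlates with the
injury-affected lipids over sham + 3X animals.

```r
td <- tidy(report$cytokine_effects)
td[td$contrast == "3X vs sham" & td$significant, ]
#> # A tibble: 6 × 4
#>   analyte   estimate       p_adj direction
#> 1 Eotaxin      -80.2 0.0000134   decreased
#> 2 IL-1beta     -23.7 0.00727     decreased
#> 3 IP-10        -25.8 0.000000264 decreased
#> 4 LIX          -28.5 0.0405      decreased
#> 5 RANTES       -52.4 0.000113    decreased
#> 6 TNF-alpha    -58.6 0.000000796 decreased
```

The four directly planted pro-inflammatory decreases (IL-1beta, IP-10,
TNF-alpha, RANTES) are all flagged; Eotaxin decreases through its planted
lipid coupling; LIX is this seed's single Tukey false positive.

Plots: `autoplot(report$diff)` (volcano), `autoplot(report$correlation)`
(Spearman heatmap), `plot_subclass_tally(report$subclass_tally)`,
`plot_cytokine_heatmap()`, and `autoplot()` on any PCA result.

Real data enter through `read_feature_table()` (CSV:
`feature_id,mz,rt,<sample_id>…` + metadata `sample_id,batch,injury,sex`),
`read_cytokine_panel()` (`analyte,in_linear_range,<animal_id>…`) and
`read_lipid_dictionary()` (see `inst/extdata/lipid_dictionary.csv` for the
dialect).

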