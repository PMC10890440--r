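# metabshift

Longitudinal metabolomic association scans and differential network
analysis for multi-arm weight-loss intervention cohorts.

## The problem

Patients with severe obesity respond heterogeneously to weight-loss
interventions: Roux-en-Y gastric bypass (RYGB) usually yields better
glycemic outcomes than adjustable gastric banding (BAND) or intensive
medical intervention (IMI), and the improvement is not fully explained
by weight loss itself. Given fasting plasma metabolomes measured at
baseline and one year after intervention, `metabshift` asks, for every
metabolite, whether its baseline level or its longitudinal change is
associated with the percent change in a glycemic index — fasting
plasma glucose (FPG) or HbA1c — *differently across intervention
arms*, independent of sex, age, BMI and weight loss; and whether the
metabolite *co-regulation network* itself is rewired by the
intervention.

## What it computes

**Interaction scan.** For outcome
$y = (x_{\text{year1}} - x_{\text{base}})/x_{\text{base}}$ and
standardized metabolite exposure $m$, one pooled OLS fit per
metabolite:

$$ y = \alpha + \beta m + \gamma_g + \delta_g m + \mathbf{c}^\top\theta
 + \varepsilon $$

gives within-group slopes $\beta^*_g = \beta + \delta_g$ and pairwise
interaction contrasts
$\beta^\dagger_{g_2\,\text{vs}\,g_1} = \delta_{g_2} - \delta_{g_1}$
(RYGB vs IMI, RYGB vs BAND, BAND vs IMI — all from the same fit, so
they are consistent by subtraction), with SEs by the
linear-combination rule and Storey q-values per outcome-by-contrast
family.

**Differential networks.** After residualizing clinical covariates,
per-arm unsigned weighted networks $a_{ij} = |r_{ij}|^\beta$ are
clustered on topological-overlap dissimilarity (static tree cut) into
modules; modular differential connectivity
$T = \sum_{i<j\in M}(a^A_{ij} - a^B_{ij})$ between two arms is tested
by label permutation (add-one p, 1000 permutations), calling gain
(GOC) or loss (LOC) of connectivity.

**Pathway enrichment.** One-sided Fisher's exact test of module hits
against the known-metabolite background, plus a pathway impact score:
the share of normalized betweenness-centrality importance carried by
the hits.

**Synthetic cohorts.** `generate_cohort()` emulates the study design
(75 participants, 25/arm, 150 samples, 364 metabolites of which 153
known, arm-dependent weight loss, planted interaction effects and
arm-specific correlation modules) and returns the ground truth, so
every stage has recovery tests.

## Worked example

```r
library(metabshift)

sim  <- generate_cohort(synth_config(seed = 1))
ct   <- build_change_table(presence_filter(sum_normalize(sim$matrix)),
                           sim$cohort)
scan <- run_scan(ct, outcome = "fpg", exposure = "baseline")
scan
#> Interaction scan: %change FPG ~ baseline metabolite exposure (n = 75, 364 metabolites)
#>   RYGB_vs_IMI: 21 metabolites at q < 0.05
#>   RYGB_vs_BAND: 18 metabolites at q < 0.05
#>   BAND_vs_IMI: 0 metabolites at q < 0.05

head(volcano_table(scan, "RYGB_vs_IMI"), 3)
#>    metabolite known estimate        se            p            q
#> 1   known_001  TRUE 1.713968 0.1734632 1.431929e-14 5.212220e-12
#> 11  known_011  TRUE 1.617541 0.2097204 9.448934e-11 1.719706e-08
#> 6   known_006  TRUE 1.625263 0.2205269 3.839595e-10 4.658708e-08
```

The generator planted a slope of 1.8 on `known_001` in the RYGB arm
versus 0.1 in IMI, i.e. a true contrast of 1.7; the scan estimates
1.71 (SE 0.17) and ranks it first. The other small-q metabolites are
members of the correlated module planted around it. No BAND-vs-IMI
contrast was planted, and none is found.

```r
net <- run_network(presence_filter(sum_normalize(sim$matrix)),
                   sim$cohort, n_perm = 1000, seed = 1)
subset(net$mdc, call != "none")
#>      module group_a group_b size statistic      ratio      perm_p call
#> 2 turquoise    RYGB     IMI   12 24.024226 127.131165 0.000999001  GOC
#> 4 turquoise    RYGB    BAND   12 23.883035  73.010364 0.000999001  GOC
#> 5      blue    BAND     IMI    8  5.721748   2.229107 0.024975025  GOC
```

The module planted with correlation 0.85 in RYGB versus 0.3 elsewhere
is recovered (`turquoise`, 12 members) and called GOC against both
comparators at the permutation floor p = 1/1001.

The whole chain — simulate/load, normalize, filter, four scans, three
per-arm networks, three pairwise MDC comparisons, optional enrichment
— runs from one call:

```r
man <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

writing fixed-format TSVs plus a `manifest.json` with dimensions,
parameters, significant-hit counts, module/MDC summaries and MD5
checksums; identical config and seed reproduce every checksum
bit-exactly.

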