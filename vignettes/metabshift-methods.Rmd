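---
title: "Methods: interaction scans and differential metabolite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction scans and differential metabolite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scientific setting

Patients with severe obesity respond very differently to different
weight-loss interventions: Roux-en-Y gastric bypass (RYGB) typically
produces better glycemic outcomes than adjustable gastric banding
(BAND) or intensive medical intervention (IMI), for reasons that are
only partly explained by the amount of weight lost. One way to probe
the molecular side of this heterogeneity is to profile the fasting
plasma metabolome at baseline and one year after intervention and ask,
for every metabolite, whether its baseline level — or its longitudinal
change — is associated with the change in a glycemic index
(fasting plasma glucose, FPG, or HbA1c) *differently across
intervention arms*, after adjusting for clinical covariates including
weight loss itself.

`metabshift` implements that analysis chain as a reusable, testable
pipeline: preprocessing of untargeted abundances, per-metabolite
interaction-regression scans with Storey q-value control, weighted
correlation network modules with permutation-tested modular
differential connectivity, and pathway over-representation with a
topology-based impact score. Because cohorts of this design are rarely
public, the package also ships a synthetic cohort generator that
emulates the data structure and provides ground truth for recovery
tests.

## Outcomes and preprocessing

All glycemic outcomes are percent changes,
$(x_{\text{year1}} - x_{\text{baseline}}) / x_{\text{baseline}}$,
so negative values mean improvement. Metabolite peak heights are

1. **sum-normalized**: each sample's abundances are divided by that
   sample's total intensity over *known* (annotated) metabolites,
   the conventional normalization for GC-MS peak heights — after it,
   the known features of every sample sum to one, making the
   operation idempotent;
2. **presence-filtered**: a metabolite is kept only if present
   (non-missing, positive) in at least 50% of samples *in every
   intervention group* (threshold configurable);
3. for scans, converted to an exposure: either the baseline level or
   the per-participant percent change, **standardized** to zero mean
   and unit variance across participants.

Order of operations: normalize, filter, compute percent change on the
(positive) normalized abundances, and standardize the exposure *last*
— percent change of an already mean-centred variable would be
ill-defined. Missing values surviving the filter are imputed at half
the metabolite's minimum observed value (the usual limit-of-detection
convention), which keeps percent changes defined. "Weight loss" is
coded as the fractional change in body weight (negative under loss),
matching the percent-change convention of the outcomes; this coding is
recorded in the run manifest.

## The interaction scan

For one outcome $y$ (percent change in FPG or HbA1c) and one
metabolite exposure $m$, the scan fits a single pooled OLS model

$$ y = \alpha + \beta m + \sum_g \gamma_g \mathbb{1}[G=g]
   + \sum_g \delta_g\, m\,\mathbb{1}[G=g] + \mathbf{c}^\top \theta
   + \varepsilon, $$

with IMI the reference arm and covariates
$\mathbf{c} = $ (sex, baseline age, baseline BMI, weight loss). The
quantities of interest are the within-group slopes
$\beta^*_g = \beta + \delta_g$ and the pairwise contrasts
$\beta^\dagger_{g_2 \text{ vs } g_1} = \delta_{g_2} - \delta_{g_1}$,
whose standard errors come from the coefficient covariance matrix by
the linear-combination rule; *all three* contrasts (RYGB vs IMI,
RYGB vs BAND, BAND vs IMI) are derived from the same fit, never from a
refit, which is why they are mutually consistent by subtraction —
the identity $\beta^\dagger = \beta^*_{g_2} - \beta^*_{g_1}$ holds to
numerical precision and is enforced in the tests. Two-sided t-tests
use the pooled model's residual degrees of freedom.
`fit_interaction()` returns a classed object with
`print`/`summary`/`coef`/`vcov`/`predict`/`residuals` methods;
`run_scan()` maps it over the metabolome and flags (rather than drops)
metabolites whose fit fails.

An optional binary covariate slot supports sensitivity models such as
additionally adjusting for hypoglycemic-medication use: pass it in the
`covariates` data.frame.

### Multiple testing

Storey q-values are computed within each outcome-by-contrast family
across metabolites. The null proportion $\pi_0$ is estimated on the
grid $\lambda \in \{0.05, 0.10, \ldots, 0.95\}$ as
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$, smoothed by
a cubic smoothing spline (3 df) and evaluated at the largest
$\lambda$, clamped to $(0, 1]$. For families smaller than 100 the
spline is unstable and $\pi_0$ falls back to 1, which makes the
q-values exactly Benjamini–Hochberg adjusted p-values — that identity
(for any p-vector, given $\pi_0 = 1$) is one of the package's
invariant tests. Q-values are monotone in p and never smaller than
$\hat\pi_0$ times the BH value.

## Differential metabolite networks

To study co-regulation rather than single-metabolite effects, the
clinical covariates (age, sex, BMI, weight loss) are first regressed
out of every log-abundance column; the residuals — orthogonal to each
covariate, idempotent under re-residualization — feed the network
stage. Within each intervention arm (pooling both timepoints of that
arm's samples, the default; configurable) the package builds an
unsigned weighted network

$$ a_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta}, $$

computes the topological overlap matrix

$$ \mathrm{TOM}_{ij} =
   \frac{\sum_{u \neq i,j} a_{iu} a_{uj} + a_{ij}}
        {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
   k_i = \sum_{u \neq i} a_{iu}, $$

and clusters $1 - \mathrm{TOM}$ by average-linkage hierarchical
clustering with a **static** tree cut (default height 0.75, minimum
module size 5). A static cut was chosen over the dynamic hybrid cut
because it is deterministic and fully specifiable, and is adequate at
a few hundred features; both the height and the size floor are
configuration knobs. Clusters below the size floor are labelled
`grey` (unassigned). Module labels are size-ranked colour names
(`turquoise`, `blue`, ...) purely as a reporting convention. Each
module's **hub** is the member with maximal intramodular connectivity,
ties broken lexicographically.

### Choosing the soft power

`choose_soft_power()` returns the smallest power in 1..20 whose
scale-free topology fit reaches $R^2 \ge 0.8$ (signed against the
slope of the log–log regression of connectivity-bin frequency on mean
connectivity), falling back to 6 — the conventional unsigned-network
default — with a warning when no power qualifies. Planted
equicorrelated blocks are deliberately *not* scale-free, so on
synthetic cohorts the fallback usually engages. Note an interaction
worth knowing: at power 6 the static cut height of 0.75 corresponds to
TOM $\approx r^6 \approx 0.26$ for large equicorrelated blocks, i.e. a
within-module correlation around 0.8 sits exactly at the detection
boundary. For small panels with strong planted correlations a low
power (2) gives robust module recovery, and the recovery tests use it;
the pipeline default remains `"auto"` with the fallback above.

### Modular differential connectivity

For a module $M$ and two arms $A, B$, the MDC statistic is the signed
sum of pairwise adjacency differences

$$ T = \sum_{i < j \in M} \left( a^A_{ij} - a^B_{ij} \right), $$

computed within each arm's samples at the shared power. $T$ is zero
when the arms are identical and antisymmetric under swapping them —
sign semantics that support both gain (GOC, $T > 0$) and loss (LOC,
$T < 0$) of connectivity. The connectivity *ratio*
$\sum a^A / \sum a^B$ is reported as a secondary column; the signed
sum is the primary statistic because a pure ratio cannot be negative
and so cannot carry the GOC/LOC sign. Significance comes from
permuting arm labels over the pooled samples (group sizes preserved,
default 1000 permutations) with the add-one estimator
$p = (1 + \#\{|T_{\text{perm}}| \ge |T_{\text{obs}}|\})/(n_{\text{perm}}+1)$,
so $p = 0$ is impossible and the floor with 1000 permutations is
$1/1001 \approx 0.001$. GOC/LOC is called at $\alpha = 0.05$. In the
pipeline, each pairwise comparison (RYGB vs IMI, RYGB vs BAND,
BAND vs IMI) tests the modules detected in the first arm of the pair.

## Pathway enrichment and impact

Hits (by default, the known members of the largest RYGB module) are
tested for over-representation in each pathway by a one-sided Fisher's
exact test — the upper hypergeometric tail on the 2×2 table restricted
to the known-metabolite background; unknown features have no pathway
identity and are excluded from the universe. Pathway topology enters
through an impact score: node importance is betweenness centrality
(shortest-path count form, per connected component) normalized to sum
to one within the pathway, with a uniform fallback when all
centralities vanish (two-node pathways, complete graphs, edge-free
graphs); the impact of a hit list is the share of total importance its
members carry, in $[0, 1]$. Raw p-values are reported (an optional BH
column is available); pathway membership ships as GMT plus a
per-pathway edge-list TSV, and a small fully synthetic fixture
(`inst/extdata/synthetic_pathways.gmt`, clearly labelled synthetic) is
bundled for examples and tests — no online database is contacted.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a three-arm
weight-loss cohort: 25 participants per arm, two timepoints
(150 samples), 364 metabolite features of which 153 are flagged known.
Its defaults are fixed study conditions, not tuning dials:

* **Covariates.** Age ~ Normal(51, 8) truncated to [21, 70]; sex
  Bernoulli(0.84 female); baseline BMI ~ Normal(43.3/45.7/48.5 by arm,
  SD 6) truncated at the eligibility floor 33; baseline weight ~
  Normal(120/123/133 kg, SD 20).
* **Weight loss.** Fractional loss ~ Normal(0.12/0.19/0.35 by arm,
  SD 0.05), entering the outcome equation as the (negative) fractional
  weight change with a common coefficient 0.5 — so "independent of
  weight loss" adjustment is genuinely testable, since weight loss is
  confounded with arm by construction.
* **Abundances.** Log-normal (exp of Gaussian), so all peak heights
  are positive and sum-normalization is well defined. Planted modules
  are equicorrelated Gaussian blocks with an arm-specific correlation;
  the default structure plants one module with a strong gain of
  connectivity in RYGB (rho 0.85 vs 0.3), one tight module shared by
  all arms, and one that loses connectivity in RYGB.
* **Outcomes.** Percent changes are generated directly from the
  linear predictor: arm intercept (from the arms' median FPG/HbA1c
  changes: −0.051/−0.107/−0.220 for FPG, −0.070/−0.085/−0.236 for
  HbA1c) + planted slopes × standardized exposure + weight-loss term +
  Gaussian noise (SD 0.1). Crucially the exposures are computed from
  *sum-normalized* abundances exactly as the scan computes them, so
  the fitted model is the generating model and recovery tests are
  exact rather than attenuated. Baseline FPG/HbA1c are log-normal
  around the arm medians; follow-up values are back-computed from the
  percent change.
* **Determinism.** One RNG stream seeded once; permutation streams
  derive sub-seeds deterministically per comparison. Identical seeds
  give bit-identical outputs — the pipeline manifest's MD5 checksums
  are reproducible end to end.
* An optional missing-at-random rate (default 0) supports testing the
  imputation path; real missingness mechanisms in untargeted
  metabolomics are usually abundance-dependent and are *not*
  emulated.

What passing tests on this generator do **not** show: robustness to
batch effects (the generator is single-batch by design; QC-based
batch correction is out of scope), to non-Gaussian tails, to
abundance-dependent missingness, or to assortment of participants into
arms by clinical severity (arm assignment is random here, while real
cohorts of this design are not randomized).

## Numerical choices and problem sizes

Tolerances: TOM and betweenness oracles agree to 1e-12; the contrast
subtraction identity and equivariance hold to 1e-10; residualization
orthogonality to 1e-8. Degenerate inputs error early and name the
offending sample/column (zero known-sums, constant exposures,
rank-deficient designs, self-loops). Tie-breaks are deterministic:
hubs lexicographic, module-size ties by smallest member id.

The test and acceptance workloads use deliberately modest sizes chosen
to make Monte-Carlo bands tight enough to be informative: 1000 null
simulations for the type-I error of the contrast test (binomial 99%
band ≈ ±0.018 around 0.05), 100 generator seeds at 200
participants/arm for planted-contrast recovery, 200 exchangeable-null
and 20 power simulations for the MDC permutation test (1000
permutations in the power arm), and 50 seeds for end-to-end module
recovery at 80 features.

## Limitations

* The MDC literature does not pin a single formula; this package
  defines the signed-sum statistic above (plus the ratio as a
  secondary descriptor) and makes no claim to reproduce any
  particular published MDC value.
* Q-value estimation of $\pi_0$ is unstable for small families; the
  BH fallback is conservative.
* Static tree cutting trades sensitivity for determinism; modules
  whose TOM sits near the cut height (see the power-6 note above) can
  drop out at small sample sizes.
* Mixed-effects/GEE longitudinal models, mediation of weight loss,
  eigengene summaries and module-preservation statistics are out of
  scope.
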