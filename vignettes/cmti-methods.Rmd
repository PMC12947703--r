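---
title: "Multi-trait water-use-efficiency analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait water-use-efficiency analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricewue)
```

## The problem

Rice phenotyping experiments that contrast ponded-water (PW) irrigation
with a moderate limited-water (LW) regime produce many traits per plant:
stomatal conductance (`gs`), stomatal density (`SD`), cuticular and
epicuticular wax (`CEW`, semi-quantified from ATR-FTIR spectra),
chlorophyll-fluorescence parameters (`PhiPSII`, `FvFm`, `PhiNPQ`, `NPQt`),
leaf temperature, relative chlorophyll, and leaf carbon-isotope composition
(`delta13C`), which integrates intrinsic water-use efficiency over the
leaf's lifetime. The analytical questions this package answers are:

1. Which traits respond most strongly to water limitation (effect-size
   screening)?
2. Which traits best track `delta13C`, and hence intrinsic WUE (PLS-VIP)?
3. How do genotypes distribute between two water-use strategies —
   *inherently stable* performance versus *adaptive plasticity* — when
   their selected traits are combined into a single Composite Multi-Trait
   Index (CMTI)?

## The Composite Multi-Trait Index

For genotype $i$ and selected traits $j = 1, \dots, n$:

$$\mathrm{CMTI}_i = \frac{1}{n} \sum_{j=1}^{n} \mathrm{Trait}^{\mathrm{norm}}_{i,j}$$

where $\mathrm{Trait}^{\mathrm{norm}}_{i,j} \in [0, 1]$ is the 0–1
normalized, directionally adjusted value of trait $j$. Traits are weighted
equally, exactly as the index is defined; no weighting option is offered.

**Directional adjustment.** Every trait carries a registered expected
direction of change under LW (`default_registry()`): wax, flavonols,
quenching, leaf temperature, contact angle, `delta13C` and `%N` are
expected to rise; `gs`, `SD`, chlorophyll, PSII yields and the C:N ratio to
fall. `%C` and `PhiNO` have no documented expectation, are registered
neutral, and are excluded from the index unless re-registered — a neutral
trait has no defined "adaptive" direction to score.

**Normalization modes.** The published index description leaves open
whether normalization happens on treatment contrasts or within treatment
levels; both readings are implemented:

* `plasticity` (default): the raw score is the signed relative change
  $(\bar{x}_{LW} - \bar{x}_{PW}) / |\bar{x}_{PW}|$ multiplied by $+1$ if
  the change direction matches the registry expectation and $-1$
  otherwise, then min–max scaled to $[0,1]$ across genotypes per trait.
  High CMTI then literally means "strong adaptive adjustment in the
  expected direction", which is how the index is interpreted; this is why
  it is the default.
* `treatment_level`: per-treatment genotype means are min–max scaled per
  trait within each treatment, decrease-under-LW traits are reflected
  ($1 - $ scaled), and the PW and LW matrices are averaged (both are kept
  as an attribute). This mode supports displays of the index "under PW and
  LW" separately.

Min–max scaling (not z-scores) is used because the index is defined on a
0–1 scale. A consequence worth knowing: `plasticity` mode is invariant to
*rescaling* a trait's units (any positive multiplicative factor) but not to
additive offsets, because relative change has the PW level in its
denominator — a trait measured in kelvin rather than celsius would change
the index. `treatment_level` mode, being purely rank/min–max based, is
invariant to any strictly increasing affine transformation. Traits on
interval scales with arbitrary zero points should therefore either be
expressed relative to a meaningful reference before entering `plasticity`
mode or be analysed in `treatment_level` mode.

**Trait prioritisation.** Three modes: `cohens_d` selects traits with
$|d| \ge$ `d_threshold` (default 0.8, the conventional "large effect"
benchmark — the original cutoff is not documented, so the default is
configurable); `pls_vip` selects traits with VIP $>$ 1; `explicit` takes a
user list. Selection by both effect size and VIP, with agreement between
the two, is the intended workflow (`run_cmti()` supports each).

**Classification.** Genotypes are split into the two strategy classes by a
deterministic one-dimensional two-class clustering: all $G-1$ contiguous
split points of the CMTI-sorted genotypes are scored by total within-class
sum of squares and the minimizer is taken, with exact ties broken toward
balanced classes. Because an optimal two-class partition of 1-D data is
always contiguous in sorted order, this equals the global optimum over all
bipartitions (verified against exhaustive enumeration in the tests) and,
unlike seeded k-means, is exactly reproducible. The lower-CMTI class is
labelled `stable`, the higher `plastic`. If every index is identical there
is no signal to split on and a single-class result is returned with a
warning.

## Effect-size screening

Cohen's d uses the pooled standard deviation,

$$d = \frac{\bar{x}_{LW} - \bar{x}_{PW}}{s_p}, \qquad
s_p^2 = \frac{(n_{LW}-1)s_{LW}^2 + (n_{PW}-1)s_{PW}^2}{n_{LW}+n_{PW}-2},$$

signed LW $-$ PW so that positive $d$ means the trait rose under limited
water, consistent with the CMTI's directional adjustment. The Hedges
small-sample correction $g = d\,(1 - 3/(4N - 9))$ is always reported
alongside. The default aggregation level is one value per genotype per
treatment (`genotype_mean`), which avoids treating replicates of the same
genotype as independent; replicate-level screening is available by flag
because the original aggregation level is not documented. Note the two
levels answer slightly different questions (population-level vs
within-genotype responsiveness) and genotype-mean effect sizes are
typically larger because averaging shrinks the within-group spread.

Welch's unequal-variance t-test (`welch_t()`, delegated to
`stats::t.test`) is used for the `delta13C` and carbon–nitrogen contrasts;
the fractional Welch–Satterthwaite df is the give-away form reported for
such contrasts. The balanced fixed-effects two-way ANOVA
(`anova_two_way_balanced()`, via `stats::aov`) serves the single-trial
balanced traits; genuinely hierarchical multi-trial data belong to linear
mixed models, which established packages (`lme4`, `emmeans`) already fit —
the function refuses unbalanced designs rather than silently approximating
them.

## PLS regression and VIP scores

`fit_pls1()` is a from-scratch single-response NIPALS implementation: X
and y are autoscaled, then per component $k$ the weight
$w_k \propto X^\top y$ (unit norm), score $t_k = X w_k$, loadings
$p_k = X^\top t_k / t_k^\top t_k$, $q_k = y^\top t_k / t_k^\top t_k$, with
deflation of both blocks. Initialization is deterministic, so fitting has
no random component. For one response NIPALS and SIMPLS coincide; the test
suite verifies equality of predictions and scores against an independent
implementation (`mixOmics`).

Variable importance in projection:

$$\mathrm{VIP}_j = \sqrt{\,p \cdot
  \frac{\sum_k \mathrm{SSY}_k \, w_{jk}^2}{\sum_k \mathrm{SSY}_k}\,}$$

with $\mathrm{SSY}_k = q_k^2\, t_k^\top t_k$ the response sum of squares
captured by component $k$ and $p$ the predictor count. Squared VIPs
average to one, which motivates the conventional VIP $> 1$ selection
threshold (the default). The identity $\sum_j \mathrm{VIP}_j^2 = p$ is an
exact consequence of the unit-norm weights and is asserted to $10^{-8}$ on
every fitted model in the tests.

The default component count is 2, matching the two-dimensional structure
(treatment axis + genotype axis) that dominates these datasets;
`choose_components()` offers K-fold cross-validated RMSEP minimization
(ties toward fewer components, fold assignment seeded) when the choice
should be data-driven. Strict RMSEP minimization is used deliberately —
note that when a latent factor loads unequally on predictors, additional
components genuinely improve prediction by reweighting, so selecting more
than one component there is correct behaviour, not overfitting.

PLS is fit by default on genotype × treatment means
(`trait_means_matrix()`); `plant_trait_matrix()` provides replicate-level
fitting where within-genotype variation is the target.

## The synthetic generator

`generate_dataset()` draws every replicate value as

$$x = \mathrm{baseline} + \mathrm{genotype\ offset} +
  \mathrm{trial\ shift} + \mathrm{treatment\ shift} + \varepsilon,$$

with the LW treatment shift parameterized directly in Cohen's-d units
(shift $= d \times$ residual sd, signed along the registry direction) so
planted and estimated effects are commensurable. Defaults reproduce the
targeted study design: 21 genotypes (2 *indica*), 2 treatments, 2 trials,
8 replicates; 10 genotypes planted `stable` ($|d| = 0.2$) and 11 `plastic`
($|d| = 1.5$) on the seven responsive traits, with leaf temperature and
relative chlorophyll weakly responsive ($|d| = 0.3$) in both classes.
Trial shifts are additive and genotype-independent (emulating slightly
different glasshouse conditions between trials) with no planted treatment
× trial interaction; genotype baseline offsets (sd $= 0.5$ residual sd)
give stable genotype rankings across treatments.

Per-plant `delta13C` is `intercept + sum(coef_j * z_j) + noise` over the
informative traits (`gs`, `CEW`, `SD`, `PhiPSII`; coefficient magnitudes
0.8/0.6/0.5/0.4, each signed along the trait's LW direction so simulated
`delta13C` is less negative under LW, as observed). The default noise sd
(0.78) sets the linear signal at roughly 70 % of `delta13C` variance, and
the intercept (−28.9 ‰) and trait baselines/sds are centred on values
typical of temperate rice under these regimes. Random streams are derived
per trait and per operation from the master seed, so adding a trait never
perturbs the draws of existing ones.

What the generator does *not* emulate: genotype × treatment × trial
interactions, non-Gaussian trait distributions, heteroscedasticity across
genotypes, spatial/block effects, and any mechanistic gas-exchange
coupling between traits beyond the linear `delta13C` link. Passing
recovery tests on this generator therefore demonstrates that the
statistical machinery is correct and well-calibrated, not that real
experiments will be as clean; with planted class separation of
$|d| = 0.2$ vs $1.5$ and 32 plants per genotype, classification recovery
is essentially perfect, and real data with weaker separation will sit on a
continuum the index is explicitly described as summarizing.

Problem sizes used in the validation suite — 50 generator seeds for
classification recovery, 100 for VIP recovery, 500 simulated 8 + 8
contrasts for effect-size calibration — were chosen to estimate the
checked proportions to within a few percent while keeping the whole suite
quick to run on a laptop.

## Derived traits and spectra

The arithmetic modules implement the standard phenotyping formulas:
densities from counts in a 600 µm × 450 µm microscope field; percent
weight retained/lost for detached-leaf assays (the conventional formula
computes percent *retained*; both quantities are returned under
unambiguous names rather than silently renaming one); filled-grain
percentage, harvest index and thousand-grain weight (generalized to any
counted sample, default 1000); brown/milled/head rice yields, all as
percentages of the initial *paddy* mass (head-rice recovery against milled
mass is the other convention in use — the paddy-mass definition is
followed and documented); and the dry-down field-capacity target as the
midpoint between initial moisture and the wilting-point moisture.

FTIR band indices integrate baseline-corrected absorbance over the wax
band (2800–3000 cm⁻¹) and the five flavonol fingerprint bands (1125–1140,
1205–1225, 1270–1310, 1435–1475, 1605–1620 cm⁻¹). The default baseline is
the local straight line through the band's endpoint absorbances —
the minimal reproducible choice when no baseline method is documented —
with negative residuals clipped to zero before trapezoidal integration,
since the indices are semi-quantitative abundances. Integrated area was
chosen over peak height because it is robust to the 4 cm⁻¹ acquisition
resolution; the index changes by well under 1 % when the grid is refined,
and it is exactly invariant to adding any global linear baseline.

## Numerical and degenerate-input policy

* Zero pooled variance, constant predictors/responses, unbalanced ANOVA
  designs, bands outside the spectral range, and mass-ordering violations
  all raise immediate, named errors rather than propagating `NaN`.
* Constant traits are dropped (with a warning) from correlation
  strong-pair lists and CMTI normalization; a constant trait carries no
  ranking information.
* PCA loading columns are sign-fixed so the largest-magnitude entry is
  positive; eigenvalues are clipped at zero against round-off.
* All tie-breaks are deterministic: CMTI ranks by first occurrence,
  classification toward balanced classes, component selection toward fewer
  components.

## Worked example

```{r example, eval = FALSE}
sim <- generate_dataset(simulation_config(seed = 1))
res <- run_cmti(sim$table, cmti_config("cohens_d", d_threshold = 0.8))
head(res[order(res$rank), ])
mean(res$class == sim$truth$class_assignment[res$genotype])

# full pipeline with provenance-stamped outputs
out <- run_pipeline(seed = 1, output_dir = tempfile("wue"))
out
```

## Known limitations

* No mixed-effects modelling, estimated marginal means, or post-hoc letter
  displays; unbalanced multi-trial inference should go through `lme4` /
  `emmeans` directly.
* No multi-response PLS2, orthogonal-PLS, or permutation p-values for VIP.
* No spectral peak deconvolution or derivative spectroscopy; band indices
  are semi-quantitative by design.
* The stable/plastic split assumes exactly two strategy classes; data
  falling on a smooth continuum will still be split, and the
  within-class sums of squares should be inspected before interpreting the
  two groups as discrete.
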