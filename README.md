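# ricewue

Multi-trait water-use-efficiency (WUE) analysis for rice phenotyping
experiments that contrast ponded-water (PW) irrigation with a moderate
limited-water (LW) regime held at a fraction of field capacity.

Such experiments produce many traits per plant — stomatal conductance
(g_s), stomatal density (SD), cuticular/epicuticular wax (CEW, from
ATR-FTIR spectra), chlorophyll-fluorescence parameters (ΦPSII, Fv/Fm,
ΦNPQ, NPQt), and leaf carbon-isotope composition (δ¹³C), the integrative
proxy for intrinsic WUE in C₃ plants. `ricewue` turns them into a genotype
ranking: it screens traits by treatment effect size, ranks them by their
contribution to δ¹³C variation, folds the selected traits into a single
index per genotype, and splits genotypes into *inherently stable* versus
*adaptively plastic* water-use strategies.

## The core statistic

The **Composite Multi-Trait Index** for genotype *i* over *n* selected
traits:

```
CMTI_i = (1/n) Σ_j Trait_norm(i, j)
```

where `Trait_norm` is the 0–1 normalized, directionally adjusted trait
value (traits expected to fall under LW — g_s, SD, ΦPSII, Fv/Fm — count
positively when they fall; traits expected to rise — CEW, ΦNPQ, NPQt —
when they rise). High CMTI = strong adaptive adjustment under water
limitation; low CMTI = constitutive stability. Genotypes are split into
the two classes by a deterministic optimal two-class 1-D clustering of the
index.

Traits enter the index via Cohen's *d* screening (|d| ≥ 0.8 by default) or
via Variable-Importance-in-Projection scores (VIP > 1) from a from-scratch
single-response NIPALS PLS regression of δ¹³C on the trait matrix.

Around the core: Welch t contrasts, balanced two-way ANOVA, trait
correlation structure, correlation-matrix PCA, FTIR band indices (wax and
flavonol regions), phenotyping arithmetic (stomatal/papillae densities,
detached-leaf water loss, dry-down field-capacity targets, yield and
milling metrics), and a synthetic genotype × treatment generator with
planted effect sizes so every stage can be validated against known ground
truth.

## Worked example

Simulate a study-scale dataset (21 genotypes, 2 treatments, 2 trials,
8 replicates, planted stable/plastic classes), then run the analysis:

```r
library(ricewue)

sim <- generate_dataset(simulation_config(seed = 1))
eff <- effect_sizes_by_trait(sim$table)
eff[order(-abs(eff$d)), c("trait", "mean_pw", "mean_lw", "d", "hedges_g")]
#>     trait mean_pw mean_lw      d hedges_g
#>    PhiNPQ   0.232   0.280  1.494    1.466
#>   PhiPSII   0.603   0.555 -1.373   -1.347
#>  delta13C -29.674 -28.097  1.360    1.335
#>        gs 426.268 370.266 -1.239   -1.216
#>      NPQt   1.588   1.864  1.172    1.150
#>      FvFm   0.791   0.764 -1.148   -1.127
#>       CEW  19.440  21.913  1.106    1.085
#>        SD 445.885 420.331 -1.046   -1.027
#>       RCh  39.799  38.530 -0.645   -0.633
#>        LT  27.927  28.193  0.380    0.373
```

The signs read as LW − PW: stomatal conductance and PSII efficiency fall
under limited water while quenching, wax and δ¹³C (less negative = higher
intrinsic WUE) rise; leaf temperature and chlorophyll barely respond.
Traits with |d| ≥ 0.8 feed the index:

```r
res <- run_cmti(sim$table, cmti_config("cohens_d", d_threshold = 0.8))
head(res[order(res$rank), ], 5)
#>  genotype  cmti rank   class
#>       G21 0.840    1 plastic
#>       G11 0.829    2 plastic
#>       G14 0.808    3 plastic
#>       G20 0.805    4 plastic
#>       G16 0.792    5 plastic

mean(res$class == sim$truth$class_assignment[res$genotype])
#> [1] 1
```

The top-ranked genotypes adjust their traits most strongly under LW
(plastic strategy); the bottom of the ranking barely moves (stable
strategy). On this planted dataset the recovered classes match the ground
truth exactly. The full pipeline — effects, PLS-VIP, PCA, CMTI — runs as
one call and writes provenance-stamped outputs:

```r
run_pipeline(seed = 1, output_dir = "out")
#> <wue_pipeline> seed 1 config 134f473f
#>   observations: 6720
#>   CMTI traits: CEW, delta13C, FvFm, gs, NPQt, PhiNPQ, PhiPSII, SD
#>   VIP > threshold: CEW, gs, PhiNPQ, PhiPSII, SD
#>   PC1 51.4%, PC2 15.3% of variance
#>   planted-class recovery: 100.0%
```

See `vignettes/cmti-methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.

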