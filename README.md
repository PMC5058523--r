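# invasim

Invasion-risk analysis for range-expanding species: presence-background
habitat suitability modeling, habitat-overlap statistics, a three-component
invasion-risk score, and a dispersal-constrained cellular-automaton
projection — with a synthetic-landscape generator providing ground truth
for every stage.

## Who this is for

Spatial ecologists and conservation planners facing an endemic species
expanding into a crop's cultivation areas (the motivating system is a
forest snail invading cardamom plantations in a tropical biodiversity
hotspot). The package answers, on any co-registered raster landscape:
where is habitat suitable for the invader and the crop, how much do those
areas overlap, which cultivated cells face the highest invasion pressure,
and how far can a poor disperser realistically spread as the environment
changes?

## The core model

Suitability is a maximum-entropy (Gibbs) distribution over a background
sample of landscape cells,

    q(x) = exp(lambda . f(x)) / Z,

with linear, quadratic, and product features of the predictors,
standardized over the background. Weights minimize the convex L1-penalized
presence log-loss `-mean_presence(lambda . f) + log Z +
(beta/sqrt(m)) * sum |lambda|` by coordinate descent; the logistic output
`q e^H / (1 + q e^H)` (H = entropy of the fitted background distribution)
gives a bounded suitability index. Maps are thresholded at the maximum
sensitivity-plus-specificity (MTSS) point; model quality is reported as
rank-based AUC and the true skill statistic (TSS) over replicate
train/test splits. Invasion risk on crop-suitable cells adds three bounded
components — the invader's categorical suitability, a binary land-cover
transformation map, and inverted rescaled distance to the nearest invader
record — and rescales the sum to [0, 1]. Future occupancy is projected
with a MIGCLIM-style cellular automaton (colonization threshold on a
0–1000 suitability scale, distance-indexed kernel, maturity ages, optional
long-distance dispersal, strong barriers) under unlimited / none /
constrained dispersal scenarios.

See `vignettes/invasion-risk-methods.Rmd` for the full model account,
parameter meanings, and design conventions.

## Worked example

```r
library(invasim)

# a synthetic landscape with a known, sharply delimited niche
spec    <- landscape_spec(nrows = 60, ncols = 60, n_vars = 5,
                          smoothing_radius = 3, seed = 7)
stack   <- gen_env_stack(spec)
truth   <- truth_model(c(env1 = 4, env2 = -3), intercept = -7)
surface <- true_suitability(stack, truth)
occ     <- sample_occurrences(surface, 200, seed = 11)
bg      <- sample_background(stack, 2000, seed = 12)

model <- fit_maxent(occ, bg, stack)
model
#> <suitability_model> 20 features over 5 predictors; 9 active (nonzero)
#>   reg_beta 1, objective 6.18524, entropy H 6.1856, converged: TRUE

pred <- predict(model, stack)
cor(as.numeric(pred$values), as.numeric(surface$values), method = "spearman")
#> [1] 0.994

replicate_evaluate(occ, stack, n_replicates = 5, n_background = 2000,
                   seed = 13)
#> <replicate_evaluation> 5 replicates
#>   auc_train       0.941 (0.002)
#>   auc_test        0.941 (0.007)
#>   tss             0.800 (0.031)
#>   mtss_threshold  0.276 (0.039)

percent_contribution(model)
#>   variable    percent
#> 1     env1 64.0186212
#> 2     env2 35.5484976
#> 4     env4  0.2529149
#> 5     env5  0.1799663
#> 3     env3  0.0000000
```

The fitted surface rank-correlates 0.994 with the generating truth; test
AUC 0.94 and TSS 0.80 reflect the niche's sharp delimitation (about 8% of
the landscape is suitable); and the two planted active predictors (`env1`,
`env2`) absorb >99% of the model's gain while the three inactive layers
stay near zero.

The full chain — simulate, screen, fit, evaluate, project, overlap, risk,
disperse, demography, report — runs from one configuration:

```r
manifest <- run_pipeline(default_config(seed = 1, out_dir = "run1"))
```

Every artifact is an ASCII grid or delimited text file; the returned
manifest lists each with its MD5 hash, and a rerun with the same seed is
bit-identical. A thin CLI wrapper lives at `inst/scripts/invasim.R`.

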