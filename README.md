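# tradescape

Morpho-functional trade-off landscapes for 3D landmark shape data.

When one anatomical structure serves two competing functions — the classic
example being a jaw that can bite either hard or fast, but not both — each
species strikes a compromise. `tradescape` quantifies that compromise and
its macroevolutionary footprint. It is aimed at evolutionary
morphologists working with landmark-based geometric morphometrics,
per-shape functional performance metrics (typically finite-element
summaries), and a time-calibrated phylogeny.

## The model

Shapes are Procrustes-aligned, projected to tangent space, and summarised
by their scores on the first two principal components. Two functional
metrics, min–max scaled to [0, 1], are modelled as *performance surfaces*
F₁(z), F₂(z) over the (PC1, PC2) plane — polynomial, thin-plate spline or
kriging fits selected by 10-fold cross-validated RMSE. The surfaces
combine into a functional landscape

    W(z; w) = w · F₁(z) + (1 − w) · F₂(z),      w ∈ [0, 1]

and the log-fitness of a shape at position z̄ under weight w is

    ln [ w F₁(z̄) + (1 − w) F₂(z̄) ] / max_grid [ w F₁ + (1 − w) F₂ ]

the log of its height relative to the landscape's highest point, the
maximum being recomputed for every w over a theoretical grid of shapes
(an 8 × 8 grid over the PC range extended by 10%). The *trade-off
weight* of a species is the w maximising this quantity: w → 1 means the
shape is explicable as optimising F₁, w → 0 as optimising F₂.

Downstream, the package relates the weight to morphological diversity: a
40 × 40 weight surface gives the "w volume" (how many theoretical shapes
support each weight interval), a sliding-window analysis compares that
theoretical volume to the observed disparity (trace of the shape
covariance, summed over mclust position clusters) of species in the same
weight interval, two-block PLS with major-axis prediction tests whether a
form–function mapping fitted on one clade transfers to another, and a
comparative layer (BM/OU/EB fits with AICc, PGLS with permutation tests,
independent contrasts, Mantel tests, phylogenetic PCA, rate-table
associations) handles the phylogenetic questions. A seeded synthetic-study
generator with a brute-force weight oracle makes every stage testable
against known truth.

## Worked example

A complete run on a synthetic study with known ground truth:

```r
library(tradescape)

study <- gen_study(synthetic_config(seed = 1))
study
#> synthetic_study: 132 species (35 landmarks), seed 1
#> true w: min 0.000, median 0.472, max 0.731

study$morphospace
#> morphospace_model: 132 specimens, 98 components
#> PC1 21.27%, PC2 11.55% (PC1+PC2 32.82%) of total variance

# select and fit the two performance surfaces
cv1 <- crossvalidate_surfaces(study$grid, study$traits$f1$value, k = 10, seed = 1)
cv1
#> cv_report: 10-fold CV, seed 1
#>      family order n_params       rmse failed
#>  polynomial     1        3 0.22499884  FALSE
#>  polynomial     2        6 0.14652933  FALSE
#>  polynomial     3       10 0.12150392  FALSE
#>  polynomial     4       15 0.12577923  FALSE
#>  polynomial     5       21 0.09969669  FALSE
#>         tps     2       67 0.03229211  FALSE
#>         tps     3       70 0.01898066  FALSE
#>         tps     4       74 0.02089607  FALSE
#>     kriging     0       67 0.04510756  FALSE
#> best: tps order 3 (RMSE 0.01898)
f1 <- fit_surface(study$grid, study$traits$f1$value, cv1$best$family, cv1$best$order)
cv2 <- crossvalidate_surfaces(study$grid, study$traits$f2$value, k = 10, seed = 1)
f2 <- fit_surface(study$grid, study$traits$f2$value, cv2$best$family, cv2$best$order)

# species trade-off weights
sw <- species_w(study$species_positions, f1, f2, study$grid, floor_eps = 1e-9)
head(sw[c("species", "pc1", "pc2", "w", "log_fitness", "tied")], 4)
#>   species     pc1      pc2     w log_fitness  tied
#> 1      t1 -0.0496  0.00570 0.484      -0.231 FALSE
#> 2      t2  0.0835  0.01626 0.699      -1.013 FALSE
#> 3      t3  0.0351 -0.00193 0.484      -0.145 FALSE
#> 4      t4 -0.0777  0.03983 0.358      -0.918 FALSE
median(abs(sw$w - study$true_w))   # against the brute-force oracle truth
#> [1] 0.0308

# theoretical weight volume vs observed disparity
ws <- w_surface(f1, f2, study$grid, n = 40, floor_eps = 1e-9)
ws
#> w_surface: 1600 cells (40 per axis), w in [0.000, 1.000]
c(high = sum(ws$w > 0.6), low = sum(ws$w < 0.4))
#>  high  low
#>   357  613
wins <- make_windows(min(ws$w), max(ws$w), step = 0.0002, size = 0.011)
shapes <- t(apply(study$alignment$aligned, 3, as.vector))
wd <- windowed_disparity(sw$w, sw[c("pc1", "pc2")], shapes, wins, ws$w, seed = 1)
association(wd$volume, wd$disparity, seed = 1)
#>          estimate p_value
#> pearson    0.9221       0
#> spearman   0.5437       0
#> xi         0.9721       0
```

Reading the output: the surfaces are recovered with cross-validated RMSE
under 2% of the metric range; species weights land within ~0.03 of the
planted truth (the weight search runs at resolution 0.001); far fewer
theoretical shapes support force-dominated weights (w > 0.6) than
velocity-dominated ones (w < 0.4); and across the 175 populated sliding
windows the theoretically available volume at a weight strongly predicts
the disparity real (here: simulated) species show at that weight. A single
study's profile correlation is variable across simulation seeds (the
species weights concentrate on a few modes); the acceptance script pools
windows over replicate studies for a stable estimate.

`run_pipeline(pipeline_config(...))` chains all stages from files on disk
(TPS/CSV landmarks, trait CSVs, newick tree) and writes every artifact as
CSV/JSON with a provenance record; `inst/scripts/tradescape.R` is a thin
command-line front end over `gen_study()`/`run_pipeline()`.

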