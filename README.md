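# grassID

Vision-based discrimination of wheat, annual ryegrass and brome grass
seedlings from top-view colour images.

Annual ryegrass and brome grass are the dominant grass weeds of southern
Australian wheat fields. At the 1–4 leaf stage all three species are
narrow-leaf grasses that even experts struggle to tell apart, yet that is
exactly when site-specific weed control is cheapest. `grassID` implements
an image-analysis pipeline that quantifies the subtle colour, shape and
texture cues an expert uses and turns them into per-species decision
thresholds:

1. **Segmentation** — the plant region is isolated by HSV hue
   thresholding: low-saturation pixels are zeroed, and foliage is kept
   where hue ∈ [54°, 154°].
2. **Feature extraction** — eleven features per plant (Table-style
   notation): normalized colour factors
   `r_i = R/I, g_i = G/I, b_i = B/I` with grayscale intensity
   `I = 0.2989 R + 0.5870 G + 0.1140 B`; the contrast indices
   `RBI = (r_i − b_i)/(r_i + b_i)`, `ERI = (r_i − g_i)(r_i − b_i)`,
   `EGI = (g_i − r_i)(g_i − b_i)`, `EBI = (b_i − g_i)(b_i − r_i)`;
   the erosion width `W = 2 ×` (number of 3×3 erosions until the region
   vanishes); the **Waddle Disk Ratio** `WDR = W / (2√(A/π))` (erosion
   width over the diameter of the equal-area disk); and the histogram
   texture statistics uniformity `U_t = Σ p(z)²` and entropy
   `E_t = −Σ p(z) log₂ p(z)` over the 256 gray levels of the region.
3. **Feature selection** — a greedy correlation filter keeps one
   representative of every feature group with pairwise |r| ≥ 0.7.
4. **Component model** — PCA of the correlation matrix of the selected
   features, Kaiser-criterion retention (with a small tolerance for
   borderline eigenvalues), Varimax rotation with Kaiser
   row-normalization, and SPSS-convention regression score coefficients
   (`B = R⁻¹ L`), so fitted component scores are standardized.
5. **Discrimination** — one-way ANOVA and Bonferroni post-hoc tests on
   the scores, 95% confidence intervals per species, a threshold at the
   midpoint of the CI gap for each species pair, and pairwise
   classification of held-out plants against those thresholds.

Because the original greenhouse images are not publicly deposited, the
package ships a **synthetic seedling generator** (`drawPlant`,
`makeDataset`) that renders labelled plants with ground-truth masks and
controllable species contrasts, so the entire pipeline is testable and
reproducible end to end.

## Worked example

```r
library(grassID)

# a labelled synthetic dataset with the class balance of the original
# study: 118 wheat, 122 brome, 46 ryegrass
ds  <- makeDataset(nPerSpecies = c(118L, 122L, 46L), seed = 1)
tab <- extractFeatureTable(ds$plants)

res <- runPipeline(tab, "out", pipelineConfig(seed = 1))
#> [grassID] using supplied feature table (286 plants)
#> [grassID] correlation filter kept 4/11 features: r_i, RBI, W, U_t
#> [grassID] split: 229 training / 57 holdout plants
#> [grassID] model: 2 retained components, 80.9% variance explained
#> [grassID] holdout ryegrass vs brome on PC1: 100.0% (32/32)
#> [grassID] holdout wheat vs brome on PC1: 97.8% (44/45)
#> [grassID] holdout ryegrass vs wheat on PC2: 100.0% (37/37)
```

The log reads: the correlation filter reduced the eleven features to four
low-redundancy survivors; the Varimax-rotated model retained two
components explaining 80.9% of the standardized variance; CI-midpoint
thresholds then separated each species pair in the 57-plant holdout with
97.8–100% accuracy (44 of 45 wheat/brome plants correct, all others
correct). All stage artifacts (feature table, correlation
matrix, selection report, model JSON, scores, ANOVA/post-hoc/descriptive
tables, thresholds, per-plant predictions) are written under `out/`.

Scoring single plants against the bundled calibration of the original
greenhouse study:

```r
B <- referenceScoreCoefficients()   # 6 features x 3 components
z <- c(r_i = 1, RBI = 0, EBI = 0, W = 0, WDR = 0, U_t = 0)  # standardized
drop(z %*% B)
#>    PC1    PC2    PC3
#>  0.482  0.127 -0.081
```

A thin command-line front end is installed under
`inst/scripts/grassid.R` with subcommands `simulate`, `segment`,
`extract`, `select`, `fit`, `score`, `thresholds`, `classify`,
`evaluate` and `pipeline`, each a wrapper over the exported functions.

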