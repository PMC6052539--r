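# shaperates

Comparative tests of **multivariate body-shape evolution rates** on
time-calibrated phylogenies, for geometric morphometricians and
phylogenetic comparative biologists. The motivating question is the
classic sister-clade contrast: does a species-rich clade (e.g. the
viviparous goodeid fishes of the Mexican Mesa Central, ~40 species)
evolve body shape faster than its depauperate sister clade (the Great
Basin spring-dwellers, 4 species), and is any rate difference
concentrated in the trophic (head) or the locomotor (trunk) module?

## The statistic

Species mean shapes come from 2-D landmark configurations (TPS files)
superimposed by generalized Procrustes analysis (GPA): translation,
unit-centroid-size scaling, and optimal rotation (no reflections),
leaving pure shape. Given a chronogram with phylogenetic covariance
matrix `C` (`C[i,j]` = shared root-to-MRCA path length in Myr), the net
multivariate Brownian-motion rate for a group of species is

    sigma2_mult = sum_i || C^(-1/2) (y_i - a) ||^2 / (N * p)

where `a` is the GLS phylogenetic mean, `p` the trait dimension, and
the sum runs over the group's whitened rows — the mean squared
phylogenetically-whitened distance per trait per Myr. Tests report:

* `sigma2_R` — clade rate ratio (larger/smaller, orientation labeled),
* `R_mult` — module rate ratio (head vs. trunk; head = landmarks 1–8,
  15–18, trunk = 9–14 in the 18-landmark scheme),
* simulation p-values: `nsim` datasets simulated under a single shared
  rate on the same tree (trait correlations preserved via a shrunk
  empirical rate matrix), each re-analyzed identically, with
  `p = (1 + #{sim >= obs}) / (1 + nsim)`.

A phylomorphospace (PCA of mean shapes + Brownian ancestral states of
the scores, tree edges drawn in PC1–PC2) summarizes morphospace
occupancy.

## Worked example (synthetic study at the motivating scale)

Everything below is generated; no external data are needed. The truth:
44 species (40 + 4 split 18.02 Myr ago), Goodeinae evolving at twice
the Empetrichthyinae rate, 38 specimens per species with digitizing
noise and nuisance rotation/translation/scaling.

```r
library(shaperates)

gc  <- generate_chronogram(seed = 8)                  # 44-tip chronogram + clade map
st  <- simulate_study(gc$tree, gc$groups, truth_record(seed = 9))
fit <- align_gpa(st$configs)                          # GPA on 1672 specimens
Y   <- species_means(fit, st$species_map)             # 44 x 36 shape matrix

rate_ratio_test(Y, gc$tree, gc$groups, nsim = 999, seed = 10)
#> <rate_test_result>
#>   sigma2[Empetrichthyinae] = 8.52e-05  (n = 4)
#>   sigma2[Goodeinae] = 0.0001511  (n = 40)
#>   ratio (Goodeinae / Empetrichthyinae) = 1.773, p = 0.001  [nsim = 999, p = 36 traits]

modularity_rate_test(Y, gc$tree, default_partition(), nsim = 999, seed = 11)
#> <modularity_result>
#>   sigma2[head] = 0.0001498  (24 traits)
#>   sigma2[trunk] = 0.0001356  (12 traits)
#>   R_mult (head / trunk) = 1.105, p = 0.204  [nsim = 999]

phylomorphospace(gc$tree, Y, gc$groups)
#> <morphospace> 44 tips, 43 internal nodes; PC1 20.7%, PC2 15.0% of variance
```

Reading: the clade test recovers the simulated 2x rate contrast
(estimate 1.77, p = 0.001 — the 4-species denominator makes the ratio
noisy, which the package warns about); the modularity test correctly
finds no module contrast (none was simulated, p = 0.204).
Per-trait rates are attenuated ~11% relative to the generating value
because shape space has `2k - 4` free dimensions (see the methods
vignette).

The same analysis runs from files via `run_pipeline()` (JSON config
pointing at newick/TPS/CSV inputs; writes `report.json` and CSV
tables) or the CLI at `inst/cli/shaperates.R` with verbs `simulate`,
`validate`, `run`, `report`.

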