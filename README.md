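# conemosaics

Quantitative analysis of cone photoreceptor mosaics and visual-pigment
spectra in the teleost retina, built around the transformations the
flatfish retina undergoes at metamorphosis: the larval honeycomb of single
cones gives way to a square mosaic of double cones around centre singles,
with a region of randomly arranged single, double and triple cones.
`conemosaics` provides the full analysis chain used to characterise such
mosaics from digitized centroid fields, plus the spectral decomposition
used to identify co-expressed visual pigments in microspectrophotometric
records — together with synthetic-data generators so every stage can be
exercised and validated without micrograph data.

It is intended for visual ecologists and retinal anatomists who work with
cone centroid coordinates (from tangential sections or wholemounts) and/or
single-cell absorbance spectra.

## What it computes

**Mosaic spatial statistics** (per cone class, homotypic):

- Delaunay neighbour graphs, nearest-neighbour distances (NND), Voronoi
  domain areas clipped to the sampling window, and border-cell exclusion
  (cells whose Voronoi polygon touches the window edge are excluded from
  summaries).
- Regularity index RI = mean/SD of the NND or Voronoi-area distribution;
  lattice-like mosaics give high RI.
- Spatial autocorrelogram and density recovery profile (DRP): density of
  same-class cells in annuli around each cell. The central dip is
  summarised by the effective radius (exclusion zone) via the
  equivalent-volume estimator
  ER = sqrt(V / (pi * D)), where V is the density deficit below the first
  annulus that reaches the mean density D.
- Comparison of any observed statistic against an ensemble of 20 random
  fields matched for density and constrained by soma size
  (single 2.2 µm, double 3.0 µm, triple 4.1 µm), via z-score or empirical
  rank; ANOVA with Tukey HSD compact-letter grouping for regional density
  comparisons.

**Theoretical visual acuity** from cone density and lens geometry:

    f_N = (pi * PND / 360) * sqrt(2 * D / sqrt(3))

with PND = 2.55 × lens radius (Matthiessen's ratio), D the cone cell
density in cells/mm² (each double counts 2 cells, each triple 3), minimum
resolvable angle θ = 1/f_N, and the distance at which a 0.5 mm target
subtends θ.

**Visual-pigment mixture spectra**: A1 nomogram templates A(λ)
parameterised by λ_max (α plus β band, valid 330–620 nm), Fourier low-pass
filtering, λ_max and half-maximum bandwidth estimation, and decomposition
of co-expression spectra with the mixture response

    R(λ) = [ Σ_i k_i · A_i(λ)^p ]^(1/p)

fitted by Nelder–Mead (Simplex) least squares; candidate pigment sets are
ranked by least sum of squares (SS).

## Worked example

```r
library(conemosaics)

## a post-metamorphic square mosaic: 4 double cones around each single
f <- gen_square_mosaic(6, jitter_sd = 0.3, seed = 7)
mosaic_summary(f, "double")
#> Mosaic statistics for double cones: 119 interior of 162 cells
#>   NND:     mean 3.751  SD 0.296  min 2.947  max 4.430 um  RI 12.683
#>   Voronoi: mean 17.971  SD 1.213  min 15.126  max 21.055 um^2  RI 14.813

## is the double-cone lattice more regular than a soma-constrained
## random field of the same density?
ne  <- simulate_null_ensemble(f, "double", n_replicates = 20, seed = 1,
                              drp_max_radius = 10)
obs <- field_scalar_stats(f, "double", drp_max_radius = 10)
compare_to_null(obs[["nnd_ri"]], ne, "nnd_ri")
#> nnd_ri: observed 12.68 vs null 10.04 +/- 1.303  (z = 2.029, p = 0.0424) SIGNIFICANT

## a random mixed mosaic with triple cones is NOT distinguishable from
## its matched random null
m  <- gen_mixed_triple_field(seed = 5)   # 15 single / 30 double / 28 triple
nm <- simulate_null_ensemble(m, "triple", n_replicates = 20, seed = 2,
                             drp_max_radius = 10)
om <- field_scalar_stats(m, "triple", drp_max_radius = 10)
compare_to_null(om[["nnd_ri"]], nm, "nnd_ri")
#> nnd_ri: observed 3.17 vs null 4.513 +/- 1.452  (z = -0.925, p = 0.3550) n.s.

## theoretical acuity of a field at measured post-metamorphic density
acuity(gen_square_mosaic(14, jitter_sd = 0.84, seed = 2),
       lens_radius = 0.32)
#> Theoretical acuity:
#>   cone cell density     29585.8 cells/mm^2
#>   PND                    0.8160 mm
#>   Nyquist frequency      1.3162 cycles/degree
#>   min. angle             0.7598 degrees
#>   detection distance       37.7 mm (0.5 mm target)

## decompose a co-expression spectrum into a pigment pair
obs2 <- gen_spectrum(c(431, 500), k = c(1.398, 0.061), p = 5.523,
                     noise_sd = 0.01, seed = 5)
fit_mixture(obs2, list(431, c(431, 457), c(431, 500), c(431, 514),
                       c(431, 527)))
#> Ranked pigment-mixture fits (best first):
#>  1. {431, 500} nm: SS = 0.01956
#>  2. {431, 514} nm: SS = 0.3518
#>  3. {431, 527} nm: SS = 1.008
#>  4. {431, 457} nm: SS = 3.693
#>  5. {431} nm: SS = 7.588
```

The interpretation: the double cones of a lightly jittered square lattice
are significantly more regular than any random packing of the same
density, whereas the triple cones of the mixed mosaic behave exactly like
a soma-constrained random field — the two signatures that distinguish
lattice from random mosaic regions. The spectral fit recovers the
generating pigment pair (431 + 500 nm) as the lowest-SS combination, with
the co-expression "hump" captured by a small k for the 500 nm pigment.

`run_mosaic_pipeline()` and `run_spectra_pipeline()` chain these stages
and write per-class CSV/JSON reports plus a manifest; `read_cone_field()`
/ `read_spectrum()` ingest plain CSV centroid and spectrum files.

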