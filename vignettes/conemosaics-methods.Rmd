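---
title: "Models and methods behind conemosaics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind conemosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conemosaics)
```

`conemosaics` analyses the planar organisation of cone photoreceptors and
the pigment composition of their absorbance spectra. This vignette
explains the models implemented, the defaults and why they were chosen,
what the synthetic-data generators do and do not emulate, and the
numerical choices made where the underlying methods leave them open.

## The data model

A `cone_field` is a marked planar point pattern: continuous Cartesian
centroid coordinates in micrometres inside a rectangular sampling window
(default 52 × 52 µm², the size of one tangential micrograph field), with
one label per point from {single, double, triple}. A fused double or
triple cone is a single sampling unit and therefore a single centroid;
when cone *cells* are needed (for density and acuity), doubles count as
two cells and triples as three. All spatial statistics are homotypic —
computed within one class — because the biological questions (is the
double-cone lattice regular? are triple cones randomly placed?) concern
each class's own mosaic. A Delaunay graph over all classes together is
available for mosaic-unit queries such as counting the double cones
flanking a single cone.

## Spatial statistics

**Delaunay / Voronoi.** Tessellations are computed with the `deldir`
library (Lee–Schachter algorithm), with Voronoi polygons clipped to the
sampling window so that domain areas always sum exactly to the window
area. Nearest-neighbour distances are read off the Delaunay graph (the
nearest neighbour of a point is always a Delaunay neighbour). The test
suite verifies both against hand-written brute-force references:
all-pairs minima for NND, and Voronoi cells built by half-plane clipping
for areas and adjacency, with near-degenerate adjacency disputes settled
by the empty-circumcircle definition.

**Border exclusion.** Cells whose within-class Voronoi polygon touches
the window boundary have truncated domains and possibly censored nearest
neighbours, so they are excluded from every summary statistic (they still
serve as neighbours for interior cells). This makes the "uncertain border
cell" criterion deterministic and has a useful monotonicity: shrinking
the window can only remove interior cells, never add them.

**Regularity index.** RI = mean / SD, with the sample (n − 1) SD. A
perfectly regular lattice has SD 0 and RI = Inf, which is reported as
such rather than clamped. Jittered lattices give RI ≈ 1/CV of the jitter
(tens and above); Poisson points give ≈ 1.9 for NND.

**Autocorrelogram and density recovery profile.** For every reference
cell at least `max_radius` from each window edge (a guard zone, which
removes edge bias without area-weighting corrections — cheap and unbiased
at the default 10–15 µm radius in ≥ 52 µm windows), the displacements to
all other same-class cells within `max_radius` are accumulated. Binning
displacement magnitudes into annuli of width Δ (default 1 µm; 0.25 µm
when resolving soma-scale structure) and dividing by reference count and
annulus area gives the DRP in cells/mm²; the mean density is estimated
from the whole field. The exclusion zone is summarised by the
equivalent-volume (Rodieck-style) effective radius: with D the mean
density, r\* the inner edge of the first annulus whose density reaches D,
and V the summed density deficit below r\*,

$$ER = \sqrt{V / (\pi D)}.$$

For an ideal step profile this returns the hard-core radius exactly, and
on simulated soma-constrained random fields it recovers the constraint to
within the bin resolution (median 2.25 µm over 20 fields for a 2.2 µm
constraint at Δ = 0.25 µm). Two caveats are documented deliberately:
the estimator is bounded above by the first-recovery radius, so for a
jittered lattice (which has no hard core) it lands slightly *below* the
lattice spacing; and annulus counts are paired (each unordered pair
enters twice), so the count variance is twice Poisson — the flatness
tests use a 3-SE envelope with that factor.

## The random-null comparison

Observed statistics are compared with ensembles of random fields "matched
for density and constrained by soma size": random sequential placement
with rejection, where a candidate is accepted only if its distance to
every placed point is at least the hard-core distance. The soma sizes are
the measured class means — 2.2 µm (single diameter), 3.0 µm (double short
axis), 4.1 µm (triple median) — and the cross-class constraint is the
larger of the two classes' sizes (the conservative symmetric choice;
only the single-class constraint matters for the homotypic nulls).
Classes are placed in decreasing soma order, which improves feasibility
near jamming without changing the distribution class. Requests beyond an
area bound, or that stall for `max_attempts` consecutive rejections, fail
with the offending class named.

The ensemble default is 20 replicates, matching the standard protocol.
With so few replicates an empirical two-sided p-value cannot fall below
2/21, so the default test is a z-score of the observed statistic against
the replicate mean and SD with normal critical values (|z| > 1.96 at
α = 0.05); an empirical-rank alternative is available via
`method = "rank"`. Referencing a z-score to a 20-replicate estimate of
the null SD inflates the type-I rate slightly above nominal (about 6–7%
rather than 5%, the t-vs-normal effect); the calibration test allows for
this with a binomial envelope around that rate. At near-jamming densities
the RSA null is itself quite regular, so detecting lattice order against
it is a genuinely hard test — a 5% jitter square lattice is still
detected essentially always.

Regional density comparisons use one-way ANOVA with Tukey HSD at
α = 0.05 and a compact-letter display built by insert-and-absorb, so
regions sharing a letter are statistically indistinct. The
Student–Newman–Keuls variant is deliberately omitted as redundant with
Tukey HSD.

## Visual acuity

The retina is modelled as a hexagonal sampling array of cone cells of
density D (cells/mm², doubles ×2, triples ×3) behind a lens of posterior
nodal distance PND = 2.55 × lens radius (Matthiessen's ratio for teleost
eyes). The Nyquist frequency in cycles/degree is

$$f_N = \frac{\pi \cdot PND}{360} \sqrt{\frac{2D}{\sqrt{3}}},$$

the minimum resolvable angle is θ = 1/f_N degrees, and the distance at
which a target of size s (default 0.5 mm, a food-pellet/copepod scale) is
just resolved uses the exact subtense d = (s/2)/tan(θ/2); at the
sub-degree angles involved this differs from the small-angle form s/θ by
under 0.01%, but the exact form degrades gracefully for coarse arrays.

## Pigment templates and mixture decomposition

Templates are the standard Govardovskii-type vitamin-A1 nomogram — the
log-normal-like α band plus the Gaussian β band, parameterised solely by
λ_max and renormalised to exactly 1 at λ_max — valid for λ_max in
330–620 nm. The β band matters because short-wavelength absorbance is
often missing from single-cell records. The template interface is
pluggable (`template_fun`), so an alternative polynomial template can be
substituted without touching the fitting code. The implemented nomogram
reproduces the A1 signature used for chromophore identification: the
half-maximum bandwidth of a 491 nm template is ≈ 4270 cm⁻¹, inside the
measured 4170 ± 234 cm⁻¹ band for rod pigments.

Co-expression spectra are modelled by

$$R(\lambda) = \Big[\sum_i k_i A_i(\lambda)^p\Big]^{1/p},$$

where the k_i are non-negative coupling constants and the single exponent
p > 0 keeps the fitted absorbance differentiable at the origin. With one
pigment and k = 1 the response is the template itself; with p = 1 it is a
weighted sum; large p approaches the upper envelope of the scaled
templates, producing the characteristic "hump" of a minor long-wavelength
pigment riding on a short-wavelength one.

Fitting minimises SS = Σ(R − A_obs)² by Nelder–Mead over (log k_i,
log p) — the log parameterisation enforces positivity without
constraints — from multiple starts (p₀ ∈ {1, 2, 4}, k₀ matched to the
observed absorbance at each pigment's peak raised to p₀), followed by a
polish from the best start; convergence tolerance 1e-12 relative on SS,
5000 iterations per start. Candidate pigment sets are fitted
independently and ranked by SS, so model selection is "least SS wins",
and each fit's SS is recomputed from its returned parameters in the test
suite to guard against reporting drift. Noiseless two-pigment spectra are
recovered to machine precision; with a single pigment only k^(1/p) is
identified and the converged (k, p) pair is reported as such. Spectra are
fitted as given by default; `normalize = TRUE` rescales to unit peak
first for records on arbitrary scales.

**Fourier filtering** is a plain circular DFT low-pass: components with
period shorter than the cutoff (default 40 nm along the wavelength axis)
are zeroed, the DC term is kept, so the mean is preserved and a stop-band
sinusoid commensurate with the record is annihilated exactly. The cost of
the circular convention is Gibbs ringing from the mismatch between the
two record ends, which bounds the noise reduction at the default cutoff
to about a factor of two for noisy templates; the grid default (350–750
nm in 2 nm steps) matches standard microspectrophotometric records.

**λ_max estimation** fits a single template with a linear least-squares
scale over a 1 nm grid of candidate peaks and refines the best candidate
by golden-section search; under 0.02 absorbance-unit noise the mean
absolute error is well under the 6–11 nm between-cell spread of measured
pigments. Bandwidth estimation converts to wavenumber (ν = 10⁷/λ) and
interpolates the two half-maximum crossings nearest the peak, failing
loudly (with the flank named) if a flank never crosses half maximum.

## Synthetic generators: what they emulate, and what not

The generators provide fields with the statistical structure the analyses
assume, at the study's scales:

- `gen_honeycomb`: triangular lattice of single cones (six neighbours
  each), Gaussian jitter, default spacing such that cones sit nearly side
  by side.
- `gen_square_mosaic`: square lattice of centre single cones with double
  cones at the two edge-midpoint positions per unit cell (double:single
  = 2); corner positions are left empty, matching post-metamorphic
  mosaics where corner cones are absent or rare. Interior singles
  therefore have exactly four double-cone Delaunay neighbours.
- `gen_hardcore_random` / `gen_mixed_triple_field`: the soma-constrained
  random fields described above; the mixed default (15/30/28) reproduces
  a double:triple ratio near 1.07, at the low end of the measured 0.96 to
  1.3 range for mixed regions.
- `gen_spectrum`: the analytic mixture response plus i.i.d. Gaussian
  noise.

Jitter defaults to 6% of the lattice spacing — real mosaics do not come
with a published jitter figure, so this is a configurable package choice
that leaves the lattice structure clearly detectable while avoiding the
co-circular degeneracies of an exact lattice. The generators make no
attempt to emulate micrograph rendering, double-cone member orientation,
partition membranes, outer-segment properties, retinal curvature, or
density gradients across a field; passing tests therefore demonstrate
correctness of the *statistics* on fields with known structure, not that
real retinas behave like the generators.

All generators (and both pipelines) are deterministic given their `seed`
argument, restore the caller's RNG state, and produce bit-identical
coordinates across runs; pipeline stages derive per-stage seeds from the
master seed by fixed offsets.

## Numerical choices and degenerate inputs

- Tessellations of < 3 points, collinear sets, or classes with < 2
  interior cells raise errors naming the problem; NND falls back to
  all-pairs distances for collinear-but-distinct points.
- Co-circular lattice points (zero jitter) rely on the tessellation
  library's internal tie-breaking; tests use ≥ 1% jitter where adjacency
  counts matter, and zero-jitter fields are only asserted to satisfy the
  container invariants.
- Voronoi areas are kept at full double precision (no rounding), so
  tessellation conservation holds to 1e-8 absolute.
- The DRP guard zone must be non-empty, otherwise the autocorrelogram
  errors with a suggestion to reduce the radius; pipelines record such
  per-class failures in the manifest instead of aborting.
- A null ensemble with zero SD and a deviating observation is flagged
  significant with an infinite z marker rather than dividing by zero.

## Problem sizes used in the checks

The shipped verification uses study-scale problems chosen to give the
statistical power the properties need while staying desk-sized: 52 µm
(occasionally ~100 µm) windows with tens to a few hundred cells per
class, 20-replicate null ensembles, 50 meta-repeats for calibration
rates, 20 seeds for recovery medians, 100 random fields (n ≤ 60) for the
brute-force equivalence, and 30–50 noisy replicates for spectral model
selection at the 201-point default grid.

## Known limitations

- Homotypic analyses only; no cross-correlograms between classes and no
  anisotropy decomposition of the autocorrelogram.
- The guard-zone edge correction discards reference cells near the
  window edge; for max_radius approaching half the window size an
  area-weighted correction would be preferable.
- The RSA null is one specific hard-core process; at densities near its
  jamming limit it is intrinsically regular, which makes "more regular
  than random" a conservative comparison there.
- A1 chromophore templates only (no A2), additive Gaussian noise only,
  and the effective radius is reported at bin resolution.
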