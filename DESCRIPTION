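Package: conemosaics
Title: Spatial Statistics of Cone Photoreceptor Mosaics, Visual Acuity,
    and Visual-Pigment Mixture Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cone photoreceptor mosaics in the
    teleost retina and of microspectrophotometric absorbance spectra.
    Provides per-class spatial statistics of digitized cone centroid
    fields (nearest-neighbour distances, Voronoi domain areas, border
    exclusion, regularity indices), spatial autocorrelograms with density
    recovery profiles and effective (exclusion-zone) radii, comparison of
    observed mosaics against ensembles of soma-size-constrained random
    fields, ANOVA with Tukey HSD grouping of regional cone densities,
    theoretical visual acuity (Nyquist frequency, minimum resolvable
    angle, target detection distance) from cone density and lens
    geometry, and decomposition of absorbance spectra into visual-pigment
    mixtures using A1 nomogram templates and Nelder-Mead least squares.
    Includes generators for synthetic honeycomb, square-lattice, and
    hard-core random mosaics and for noisy mixture spectra, so the whole
    analysis chain is exercisable without micrograph data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
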