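# Theoretical visual acuity from cone density and lens geometry.
#
# The retina is treated as a hexagonal sampling array of cone cells of
# density D (cells/mm^2) behind a lens whose posterior nodal distance PND
# follows Matthiessen's ratio (PND = 2.55 x lens radius for teleosts). The
# Nyquist frequency of the array, in cycles per degree, is
#
#   f_N = (pi * PND / 360) * sqrt(2 * D / sqrt(3))
#
# and its inverse is the minimum resolvable angle in degrees of arc, from
# which the distance at which a target of given size is just resolved
# follows by plane trigonometry.

#' Cone cell density of a field
#'
#' Converts a centroid field to a cell density in cells per mm^2, with
#' each double cone contributing two cells and each triple cone three.
#'
#' @param field A [cone_field()].
#' @return Density in cells/mm^2.
#' @examples
#' f <- gen_square_mosaic(6, jitter_sd = 0.3, seed = 1)
#' cone_cell_density(f)
#' @export
cone_cell_density <- function(field) {
  stopifnot(inherits(field, "cone_field"))
  tab <- table(field$label)
  cells <- tab[["single"]] + 2 * tab[["double"]] + 3 * tab[["triple"]]
  area_mm2 <- prod(field$window) / 1e6
  as.numeric(cells) / area_mm2
}

#' Posterior nodal distance from lens radius
#'
#' @param lens_radius Lens radius in mm (> 0).
#' @param matthiessen Matthiessen's ratio; 2.55 is the teleost mean.
#' @return PND in mm.
#' @export
posterior_nodal_distance <- function(lens_radius, matthiessen = 2.55) {
  if (!is.finite(lens_radius) || lens_radius <= 0)
    stop("`lens_radius` must be > 0")
  if (!is.finite(matthiessen) || matthiessen <= 0)
    stop("`matthiessen` must be > 0")
  lens_radius * matthiessen
}

#' Nyquist frequency of a retinal sampling array
#'
#' @param D Cone cell density in cells/mm^2 (> 0).
#' @param PND Posterior nodal distance in mm (> 0).
#' @return Nyquist frequency in cycles per degree.
#' @examples
#' nyquist_frequency(8660.254, 1)  # ~ 0.8727 cycles/degree
#' @export
nyquist_frequency <- function(D, PND) {
  if (!is.finite(D) || D <= 0) stop("`D` must be > 0")
  if (!is.finite(PND) || PND <= 0) stop("`PND` must be > 0")
  (pi * PND / 360) * sqrt(2 * D / sqrt(3))
}

#' Minimum resolvable angle
#'
#' @param f_N Nyquist frequency in cycles per degree (> 0).
#' @return Angle in degrees of arc.
#' @export
min_resolvable_angle <- function(f_N) {
  if (!is.finite(f_N) || f_N <= 0) stop("`f_N` must be > 0")
  1 / f_N
}

#' Distance at which a target of given size is just resolvable
#'
#' Returns the distance at which a target of size `target_size` subtends
#' exactly the minimum resolvable angle: d = (s/2) / tan(theta/2). For the
#' sub-degree angles typical of fish eyes this is indistinguishable from
#' the small-angle form s/theta.
#'
#' @param theta Minimum resolvable angle in degrees (0 < theta < 180).
#' @param target_size Target diameter in mm (default 0.5, a food pellet or
#'   copepod-scale prey item).
#' @return Detection distance in mm.
#' @examples
#' detection_distance(1.1459)  # ~ 25 mm for a 0.5 mm target
#' @export
detection_distance <- function(theta, target_size = 0.5) {
  if (!is.finite(theta) || theta <= 0 || theta >= 180)
    stop("`theta` must be in (0, 180) degrees")
  if (target_size <= 0) stop("`target_size` must be > 0")
  (target_size / 2) / tan(theta / 2 * pi / 180)
}

#' Full acuity computation from density and lens size
#'
#' Composes [posterior_nodal_distance()], [nyquist_frequency()],
#' [min_resolvable_angle()] and [detection_distance()].
#'
#' @param D Cone cell density in cells/mm^2, or a [cone_field()] whose
#'   density is computed with [cone_cell_density()].
#' @param lens_radius Lens radius in mm.
#' @param matthiessen Matthiessen's ratio (default 2.55).
#' @param target_size Target size in mm (default 0.5).
#' @return Object of class `acuity_result`: list with `density_mm2`,
#'   `PND_mm`, `nyquist_cpd`, `min_angle_deg`, `detection_distance_mm`.
#' @examples
#' acuity(25000, lens_radius = 0.32)
#' @export
acuity <- function(D, lens_radius, matthiessen = 2.55, target_size = 0.5) {
  if (inherits(D, "cone_field")) D <- cone_cell_density(D)
  PND <- posterior_nodal_distance(lens_radius, matthiessen)
  fN <- nyquist_frequency(D, PND)
  theta <- min_resolvable_angle(fN)
  structure(
    list(density_mm2 = D, PND_mm = PND, nyquist_cpd = fN,
         min_angle_deg = theta,
         detection_distance_mm = detection_distance(theta, target_size),
         target_size_mm = target_size),
    class = "acuity_result")
}

#' @export
print.acuity_result <- function(x, ...) {
  cat(sprintf(
    paste0("Theoretical acuity:\n",
           "  cone cell density  %10.1f cells/mm^2\n",
           "  PND                %10.4f mm\n",
           "  Nyquist frequency  %10.4f cycles/degree\n",
           "  min. angle         %10.4f degrees\n",
           "  detection distance %10.1f mm (%.2g mm target)\n"),
    x$density_mm2, x$PND_mm, x$nyquist_cpd, x$min_angle_deg,
    x$detection_distance_mm, x$target_size_mm))
  invisible(x)
}
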