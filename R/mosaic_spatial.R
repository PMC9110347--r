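# Per-class spatial statistics of a cone field: Delaunay adjacency,
# nearest-neighbour distances, Voronoi domain areas clipped to the sampling
# window, border-cell exclusion, and the regularity index (mean/SD).
#
# All statistics are homotypic: points of the selected class are tessellated
# on their own. Delaunay over "all" classes is available for mosaic-unit
# queries such as counting the double cones around a single cone.

# Shared tessellation with degeneracy checks; z holds original field indices.
tessellate <- function(field, cone_class) {
  idx <- class_index(field, cone_class)
  if (length(idx) < 3L)
    stop("tessellation undefined: fewer than 3 points of class '",
         cone_class, "'")
  x <- field$x[idx]; y <- field$y[idx]
  # collinearity: all points on one line leaves the triangulation undefined
  cx <- x - mean(x); cy <- y - mean(y)
  cross <- abs(cx * cy[1] - cy * cx[1])
  if (all(cross < 1e-9 * max(1, max(abs(cx)), max(abs(cy)))))
    stop("tessellation undefined: points of class '", cone_class,
         "' are collinear")
  dd <- deldir::deldir(x, y, rw = c(0, field$window[1], 0, field$window[2]),
                       round = FALSE, suppressMsge = TRUE)
  list(dd = dd, idx = idx)
}

#' Delaunay neighbour graph of a cone class
#'
#' Undirected adjacency from the Delaunay triangulation of the selected
#' points. In a honeycomb mosaic interior points have modal degree six; in
#' a square mosaic each interior single cone is flanked by four double
#' cones.
#'
#' @param field A [cone_field()].
#' @param cone_class `"single"`, `"double"`, `"triple"`, or `"all"`.
#' @return A list with `neighbours` (list of integer vectors, positions
#'   into the selected-point set), `index` (original field indices of the
#'   selected points), and `edges` (two-column matrix of adjacent pairs,
#'   positions into the selected-point set).
#' @examples
#' f <- gen_honeycomb(5, jitter_sd = 0.05, seed = 1)
#' g <- delaunay_neighbours(f, "single")
#' table(lengths(g$neighbours))
#' @export
delaunay_neighbours <- function(field, cone_class = "all") {
  tt <- tessellate(field, cone_class)
  m <- length(tt$idx)
  e <- as.matrix(tt$dd$delsgs[, c("ind1", "ind2")])
  nb <- vector("list", m)
  for (i in seq_len(m)) nb[[i]] <- integer(0)
  for (r in seq_len(nrow(e))) {
    a <- e[r, 1]; b <- e[r, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  nb <- lapply(nb, function(v) sort(unique(v)))
  list(neighbours = nb, index = tt$idx, edges = unname(e))
}

#' Nearest-neighbour distances within a cone class
#'
#' Euclidean distance from each cell of the class to its closest same-class
#' cell, determined from the Delaunay triangulation (the nearest neighbour
#' of a point is always one of its Delaunay neighbours).
#'
#' @inheritParams delaunay_neighbours
#' @param cone_class A single cone class.
#' @return Numeric vector of distances (um), one per point of the class,
#'   in field order.
#' @export
nearest_neighbour_distances <- function(field, cone_class) {
  idx <- class_index(field, cone_class)
  if (length(idx) < 2L)
    stop("need at least 2 points of class '", cone_class, "'")
  x <- field$x[idx]; y <- field$y[idx]
  if (length(idx) < 3L) {
    d <- sqrt((x[1] - x[2])^2 + (y[1] - y[2])^2)
    return(rep(d, 2))
  }
  g <- tryCatch(delaunay_neighbours(field, cone_class), error = identity)
  if (inherits(g, "error")) {
    # collinear but distinct points still have well-defined NNDs
    d2 <- as.matrix(stats::dist(cbind(x, y)))
    diag(d2) <- Inf
    return(unname(apply(d2, 1, min)))
  }
  vapply(seq_along(idx), function(i) {
    nb <- g$neighbours[[i]]
    min(sqrt((x[nb] - x[i])^2 + (y[nb] - y[i])^2))
  }, numeric(1))
}

#' Voronoi domain areas within a cone class
#'
#' Area of the territory closer to each cell than to any other cell of the
#' same class, clipped to the sampling window, so the areas always sum to
#' the window area.
#'
#' @inheritParams nearest_neighbour_distances
#' @return Numeric vector of polygon areas (um^2), one per point of the
#'   class, in field order.
#' @export
voronoi_domains <- function(field, cone_class) {
  tt <- tessellate(field, cone_class)
  if (length(tt$idx) < 4L)
    stop("need at least 4 points of class '", cone_class,
         "' for Voronoi domain statistics")
  tt$dd$summary$dir.area
}

#' Interior (non-border) cells of a cone class
#'
#' Border cells are those whose within-class Voronoi polygon touches the
#' window boundary: their true domain (and possibly their nearest
#' neighbour) extends beyond the sampled field, so their statistics are
#' uncertain and they are excluded from all summaries.
#'
#' @inheritParams nearest_neighbour_distances
#' @return Integer vector of positions (into the class's point set, field
#'   order) of interior cells; possibly empty.
#' @export
exclude_border_cells <- function(field, cone_class) {
  idx <- class_index(field, cone_class)
  if (length(idx) < 3L) return(integer(0))
  tt <- tryCatch(tessellate(field, cone_class), error = identity)
  if (inherits(tt, "error")) return(integer(0))
  which(tt$dd$summary$nbpt == 0)
}

#' Regularity index: mean divided by sample standard deviation
#'
#' High values indicate lattice-like order; a perfectly regular set of
#' values has zero SD and the index is reported as `Inf`.
#'
#' @param values Numeric vector (length >= 2) of positive spacing or area
#'   values.
#' @return A single number, `Inf` when the SD is zero.
#' @examples
#' regularity_index(c(8, 10, 12))  # mean 10, SD 2 -> 5
#' @export
regularity_index <- function(values) {
  if (length(values) < 2L)
    stop("regularity index needs at least 2 values")
  s <- stats::sd(values)
  if (s == 0) return(Inf)
  mean(values) / s
}

summarise_values <- function(v) {
  list(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v),
       regularity_index = regularity_index(v))
}

#' Per-class mosaic statistics over interior cells
#'
#' Assembles the nearest-neighbour-distance and Voronoi-domain summaries
#' (mean, SD, min, max, regularity index) for one cone class, computed over
#' interior cells only; border cells contribute as potential neighbours but
#' not as sample points.
#'
#' @inheritParams nearest_neighbour_distances
#' @return An object of class `mosaic_stats`: list with `cone_class`,
#'   `n_total`, `n_interior`, `nnd` and `voronoi` summary lists, and the
#'   per-interior-cell vectors `nnd_values` and `vd_values`.
#' @examples
#' f <- gen_square_mosaic(6, jitter_sd = 0.3, seed = 7)
#' mosaic_summary(f, "double")
#' @export
mosaic_summary <- function(field, cone_class) {
  idx <- class_index(field, cone_class)
  if (length(idx) < 4L)
    stop("mosaic summary needs at least 4 points of class '",
         cone_class, "'")
  interior <- exclude_border_cells(field, cone_class)
  if (length(interior) < 2L)
    stop("fewer than 2 interior cells of class '", cone_class,
         "'; field too sparse relative to its window")
  nnd_all <- nearest_neighbour_distances(field, cone_class)
  vd_all <- voronoi_domains(field, cone_class)
  nnd <- nnd_all[interior]
  vd <- vd_all[interior]
  structure(
    list(cone_class = cone_class,
         n_total = length(idx),
         n_interior = length(interior),
         interior = interior,
         nnd = summarise_values(nnd),
         voronoi = summarise_values(vd),
         nnd_values = nnd,
         vd_values = vd),
    class = "mosaic_stats")
}

#' @export
print.mosaic_stats <- function(x, ...) {
  fmt <- function(s, unit)
    sprintf("mean %.3f  SD %.3f  min %.3f  max %.3f %s  RI %.3f",
            s$mean, s$sd, s$min, s$max, unit, s$regularity_index)
  cat("Mosaic statistics for", x$cone_class, "cones:",
      x$n_interior, "interior of", x$n_total, "cells\n")
  cat("  NND:    ", fmt(x$nnd, "um"), "\n")
  cat("  Voronoi:", fmt(x$voronoi, "um^2"), "\n")
  invisible(x)
}

#' Per-cell table of spatial statistics
#'
#' @inheritParams nearest_neighbour_distances
#' @return A data.frame with columns `cell_id`, `nnd_um`, `voronoi_um2`,
#'   `interior` for every cell of the class.
#' @export
mosaic_cell_table <- function(field, cone_class) {
  idx <- class_index(field, cone_class)
  interior <- exclude_border_cells(field, cone_class)
  data.frame(cell_id = idx,
             nnd_um = nearest_neighbour_distances(field, cone_class),
             voronoi_um2 = voronoi_domains(field, cone_class),
             interior = seq_along(idx) %in% interior)
}
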