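# Synthetic mosaic generators. These emulate the three arrangements seen in
# metamorphosing flatfish retinas: the larval honeycomb (hexagonal packing of
# single cones), the juvenile square mosaic (four double cones around each
# centre single cone, corner positions empty), and soma-size-constrained
# random fields with mixed single/double/triple cones.

# Gaussian jitter applied to lattice points; displacements that would leave
# the window are redrawn so the window invariant holds exactly.
jitter_points <- function(x, y, sd, window) {
  if (sd <= 0) return(list(x = x, y = y))
  for (i in seq_along(x)) {
    repeat {
      nx <- x[i] + stats::rnorm(1, 0, sd)
      ny <- y[i] + stats::rnorm(1, 0, sd)
      if (nx >= 0 && nx <= window[1] && ny >= 0 && ny <= window[2]) {
        x[i] <- nx; y[i] <- ny
        break
      }
    }
  }
  list(x = x, y = y)
}

#' Generate a jittered honeycomb (hexagonal) mosaic of single cones
#'
#' Points are laid on a triangular lattice of the given spacing (rows
#' `spacing * sqrt(3)/2` apart, alternate rows offset by half a spacing),
#' clipped to the window, then each point is displaced by isotropic Gaussian
#' jitter; displacements leaving the window are redrawn. In the noiseless
#' lattice every interior point has six equidistant Delaunay neighbours, the
#' arrangement described for larval single-cone mosaics.
#'
#' @param spacing Lattice constant in um (> 0).
#' @param window Numeric length-2 window (um); default `c(52, 52)`.
#' @param jitter_sd Isotropic Gaussian jitter SD in um (>= 0).
#' @param seed Integer seed; the output is reproducible given
#'   `(spacing, window, jitter_sd, seed)`.
#' @return A [cone_field()] with all points labelled `"single"`.
#' @examples
#' f <- gen_honeycomb(5, jitter_sd = 0.25, seed = 1)
#' table(f$label)
#' @export
gen_honeycomb <- function(spacing, window = c(52, 52), jitter_sd = 0.06 * spacing,
                          seed = 0) {
  if (!is.finite(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  row_h <- spacing * sqrt(3) / 2
  rows <- floor(window[2] / row_h) + 1L
  cols <- floor(window[1] / spacing) + 1L
  if (rows < 2L || cols < 2L)
    stop("degenerate field: window ", window[1], " x ", window[2],
         " um holds fewer than two lattice rows/columns at spacing ",
         spacing, " um")
  xs <- ys <- numeric(0)
  for (r in seq_len(rows) - 1L) {
    off <- if (r %% 2L == 1L) spacing / 2 else 0
    px <- seq(off, window[1], by = spacing)
    xs <- c(xs, px)
    ys <- c(ys, rep(r * row_h, length(px)))
  }
  keep <- xs <= window[1] & ys <= window[2]
  xs <- xs[keep]; ys <- ys[keep]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  j <- jitter_points(xs, ys, jitter_sd, window)
  cone_field(j$x, j$y, rep("single", length(j$x)), window = window,
             meta = list(generator = "honeycomb", spacing = spacing,
                         jitter_sd = jitter_sd, seed = seed))
}

#' Generate a jittered square mosaic of single and double cones
#'
#' Single cones sit on a square lattice of pitch `unit_spacing`; double
#' cones occupy the two edge-midpoint positions of each unit cell, giving a
#' double:single ratio of 2 in the interior. Corner positions are left
#' empty, as observed in post-metamorphic square mosaics where corner cones
#' are absent or extremely rare, so each interior single cone has exactly
#' four double-cone Delaunay neighbours.
#'
#' @param unit_spacing Square-lattice pitch in um (> 0).
#' @inheritParams gen_honeycomb
#' @return A [cone_field()] with labels `"single"` and `"double"`.
#' @examples
#' f <- gen_square_mosaic(6, jitter_sd = 0.3, seed = 7)
#' table(f$label)
#' @export
gen_square_mosaic <- function(unit_spacing, window = c(52, 52),
                              jitter_sd = 0.06 * unit_spacing, seed = 0) {
  if (!is.finite(unit_spacing) || unit_spacing <= 0)
    stop("`unit_spacing` must be > 0")
  if (jitter_sd < 0) stop("`jitter_sd` must be >= 0")
  a <- unit_spacing
  if (floor(window[1] / a) < 2 || floor(window[2] / a) < 2)
    stop("degenerate field: window too small for unit spacing ", a, " um")
  gx <- seq(0, window[1], by = a)
  gy <- seq(0, window[2], by = a)
  singles <- expand.grid(x = gx, y = gy)
  d1 <- expand.grid(x = gx + a / 2, y = gy)        # horizontal edge midpoints
  d2 <- expand.grid(x = gx, y = gy + a / 2)        # vertical edge midpoints
  doubles <- rbind(d1, d2)
  doubles <- doubles[doubles$x <= window[1] & doubles$y <= window[2], ]
  xs <- c(singles$x, doubles$x)
  ys <- c(singles$y, doubles$y)
  lab <- c(rep("single", nrow(singles)), rep("double", nrow(doubles)))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  j <- jitter_points(xs, ys, jitter_sd, window)
  cone_field(j$x, j$y, lab, window = window,
             meta = list(generator = "square_mosaic", unit_spacing = a,
                         jitter_sd = jitter_sd, seed = seed))
}

#' Generate a hard-core random cone field (random sequential placement)
#'
#' Candidate points are drawn uniformly in the window and accepted only if
#' their distance to every already-placed point is at least the larger of
#' the two soma sizes involved (cross-class rule: max of the two classes'
#' sizes). Classes are placed in decreasing soma-size order, which improves
#' feasibility at high packing without changing the distribution class.
#' This emulates the random mosaics against which observed fields are
#' tested: random in arrangement, but constrained by soma size.
#'
#' Exactly the requested counts are produced or an error is thrown naming
#' the class that could not be placed.
#'
#' @param n Named integer vector of requested counts, names among
#'   `"single"`, `"double"`, `"triple"`; alternatively give `density_mm2`.
#' @param density_mm2 Named numeric vector of densities in cells per mm^2;
#'   converted to counts via the window area (rounded to nearest integer).
#' @param soma A [soma_sizes()] vector of hard-core distances (um).
#' @param window Numeric length-2 window (um).
#' @param seed Integer seed.
#' @param max_attempts Maximum consecutive rejections tolerated per point
#'   before the request is declared infeasible.
#' @return A [cone_field()].
#' @examples
#' f <- gen_hardcore_random(c(single = 30), seed = 3)
#' min(dist(cbind(f$x, f$y))) >= 2.2
#' @export
gen_hardcore_random <- function(n = NULL, density_mm2 = NULL,
                                soma = soma_sizes(), window = c(52, 52),
                                seed = 0, max_attempts = 20000L) {
  if (is.null(n) && is.null(density_mm2))
    stop("give either `n` (counts) or `density_mm2`")
  if (is.null(n)) {
    area_mm2 <- prod(window) / 1e6
    n <- round(density_mm2 * area_mm2)
  }
  if (is.null(names(n)) || !all(names(n) %in% CONE_CLASSES))
    stop("`n` must be named with cone classes")
  if (max_attempts < 1L) stop("`max_attempts` must be >= 1")
  n <- n[n > 0]
  if (!length(n))
    return(cone_field(numeric(0), numeric(0), character(0), window = window,
                      meta = list(generator = "hardcore_random", seed = seed)))
  # quick infeasibility bound: disks of diameter c cover area n*pi*c^2/4;
  # random sequential packing jams well below full coverage
  occupied <- sum(n * pi * (soma[names(n)] / 2)^2)
  if (occupied > 0.7 * prod(window + max(soma)))
    stop("packing infeasible: requested ", sum(n), " cells would occupy ",
         round(occupied), " um^2 in a ", prod(window), " um^2 window")
  ord <- names(n)[order(soma[names(n)], decreasing = TRUE)]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  total <- sum(n)
  px <- py <- numeric(total)
  pc <- numeric(total)          # soma size of each placed point
  plab <- character(total)
  k <- 0L
  for (cls in ord) {
    c_this <- soma[[cls]]
    for (i in seq_len(n[[cls]])) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        cx <- stats::runif(1, 0, window[1])
        cy <- stats::runif(1, 0, window[2])
        ok <- if (k == 0L) TRUE else {
          req <- pmax(pc[seq_len(k)], c_this)
          all((px[seq_len(k)] - cx)^2 + (py[seq_len(k)] - cy)^2 >= req^2)
        }
        if (ok) {
          k <- k + 1L
          px[k] <- cx; py[k] <- cy; pc[k] <- c_this; plab[k] <- cls
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", cls, " cone ", i, " of ", n[[cls]],
             " after ", max_attempts,
             " attempts: requested density too high for soma constraint")
    }
  }
  cone_field(px, py, plab, window = window,
             meta = list(generator = "hardcore_random", seed = seed,
                         soma = as.numeric(soma[CONE_CLASSES])))
}

#' Generate a mixed single/double/triple random field
#'
#' Convenience wrapper over [gen_hardcore_random()] emulating the
#' centrodorsotemporal random mosaic in which all three cone types are
#' randomly arranged subject to soma-size exclusion.
#'
#' @param counts Named integer vector over `"single"`, `"double"`,
#'   `"triple"`; default reproduces a double:triple ratio near 1.07.
#' @inheritParams gen_hardcore_random
#' @return A [cone_field()].
#' @export
gen_mixed_triple_field <- function(counts = c(single = 15, double = 30,
                                              triple = 28),
                                   soma = soma_sizes(), window = c(52, 52),
                                   seed = 0, max_attempts = 20000L) {
  f <- gen_hardcore_random(n = counts, soma = soma, window = window,
                           seed = seed, max_attempts = max_attempts)
  f$meta$generator <- "mixed_triple_field"
  f
}

# Seed handling: generators use the global RNG but save/restore its state so
# a fixed `seed` argument gives bit-reproducible output without clobbering
# the caller's random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
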