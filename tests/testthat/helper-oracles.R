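# Brute-force geometric reference implementations, independent of the
# tessellation library used by the package. Voronoi cells are built by
# Sutherland-Hodgman half-plane clipping against every other point;
# Delaunay adjacency follows from shared Voronoi edges; NND from all-pairs
# distances.

# Clip convex polygon (n x 2 matrix) to half-plane a*x + b*y <= c
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  out <- matrix(numeric(0), 0, 2)
  inside <- a * poly[, 1] + b * poly[, 2] <= c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- poly[i, ]; q <- poly[j, ]
    if (inside[i]) out <- rbind(out, p)
    if (inside[i] != inside[j]) {
      t <- (c - a * p[1] - b * p[2]) /
        (a * (q[1] - p[1]) + b * (q[2] - p[2]))
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

# Voronoi cell of point i clipped to bbox = c(x0, x1, y0, y1)
oracle_voronoi_cell <- function(x, y, i, bbox) {
  poly <- cbind(c(bbox[1], bbox[2], bbox[2], bbox[1]),
                c(bbox[3], bbox[3], bbox[4], bbox[4]))
  for (j in seq_along(x)) {
    if (j == i) next
    a <- 2 * (x[j] - x[i]); b <- 2 * (y[j] - y[i])
    c <- x[j]^2 + y[j]^2 - x[i]^2 - y[i]^2
    poly <- clip_halfplane(poly, a, b, c)
    if (nrow(poly) < 3L) return(poly)
  }
  poly
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# Voronoi areas clipped to the rectangular window (0,w1) x (0,w2)
oracle_voronoi_areas <- function(x, y, window) {
  vapply(seq_along(x), function(i)
    polygon_area(oracle_voronoi_cell(x, y, i, c(0, window[1], 0, window[2]))),
    numeric(1))
}

# Delaunay adjacency via shared Voronoi edges in a huge bounding box:
# an edge of cell i whose midpoint is equidistant (to tolerance) from i
# and some j witnesses the Delaunay edge i-j.
oracle_delaunay_adj <- function(x, y, pad = 1e4) {
  n <- length(x)
  bbox <- c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    poly <- oracle_voronoi_cell(x, y, i, bbox)
    m <- nrow(poly)
    if (m < 2L) next
    nxt <- c(2:m, 1L)
    for (e in seq_len(m)) {
      p <- poly[e, ]; q <- poly[nxt[e], ]
      if (sum((p - q)^2) < 1e-12) next          # zero-length edge
      # the partner j must have BOTH endpoints on the i-j bisector;
      # a midpoint-only test can be fooled by near-cocircular vertices
      d2p <- (x - p[1])^2 + (y - p[2])^2
      d2q <- (x - q[1])^2 + (y - q[2])^2
      errs <- pmax(abs(d2p - d2p[i]), abs(d2q - d2q[i])) /
        pmax(1, d2p[i], d2q[i])
      errs[i] <- Inf
      j <- which.min(errs)
      if (errs[j] < 1e-6) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

# Definition-level test of a single Delaunay edge: (i, j) is a Delaunay
# edge iff some circumdisk through i, j and a third point contains no other
# point. Used to arbitrate pairs where the finite bounding box of the
# clipping oracle misses a far-away Voronoi edge (near-collinear hull
# points).
oracle_delaunay_edge <- function(x, y, i, j) {
  n <- length(x)
  ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]
  for (k in setdiff(seq_len(n), c(i, j))) {
    cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-9) next                    # collinear triple
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    dd <- (x - ux)^2 + (y - uy)^2
    dd[c(i, j, k)] <- Inf
    if (min(dd) >= r2 * (1 - 1e-12)) return(TRUE)
  }
  FALSE
}

# Full reference adjacency: half-plane clipping, with any pair disputed
# against a candidate adjacency settled by the empty-circumcircle
# definition.
oracle_delaunay_reference <- function(x, y, candidate) {
  ref <- oracle_delaunay_adj(x, y)
  disputes <- which(ref != candidate & upper.tri(ref), arr.ind = TRUE)
  for (r in seq_len(nrow(disputes))) {
    i <- disputes[r, 1]; j <- disputes[r, 2]
    ref[i, j] <- ref[j, i] <- oracle_delaunay_edge(x, y, i, j)
  }
  ref
}

# All-pairs nearest-neighbour distances
oracle_nnd <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

# Random test field helper used by several property tests
random_field <- function(n, window = c(52, 52), seed = 1,
                         label = "single") {
  set.seed(seed)
  cone_field(runif(n, 0, window[1]), runif(n, 0, window[2]),
             rep(label, n), window = window)
}
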