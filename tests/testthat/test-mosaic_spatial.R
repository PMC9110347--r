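test_that("Delaunay adjacency matches elementary geometry", {
  # unit-square corners plus centre: centre adjacent to all four corners
  f <- cone_field(c(10, 11, 11, 10, 10.5), c(10, 10, 11, 11, 10.5),
                  rep("single", 5))
  g <- delaunay_neighbours(f, "single")
  expect_setequal(g$neighbours[[5]], 1:4)

  collinear <- cone_field(c(1, 2, 3), c(1, 2, 3), rep("single", 3))
  expect_error(delaunay_neighbours(collinear, "single"), "collinear")
  expect_error(
    delaunay_neighbours(cone_field(1:2, 1:2, rep("single", 2)), "single"),
    "fewer than 3")
})

test_that("NND handles the 3-4-5 line and perfect lattices", {
  f <- cone_field(c(0, 3, 6), c(0, 4, 8), rep("single", 3))
  expect_equal(nearest_neighbour_distances(f, "single"), c(5, 5, 5))

  hc <- gen_honeycomb(5, jitter_sd = 0, seed = 1)
  interior <- exclude_border_cells(hc, "single")
  expect_equal(nearest_neighbour_distances(hc, "single")[interior],
               rep(5, length(interior)), tolerance = 1e-9)

  expect_error(
    nearest_neighbour_distances(cone_field(1, 1, "single"), "single"),
    "at least 2")
})

test_that("NND and adjacency match brute-force references on random fields", {
  for (rep in 1:12) {
    n <- c(10, 15, 20, 30, 45, 60)[(rep - 1) %% 6 + 1]
    f <- random_field(n, seed = 100 + rep)
    expect_equal(nearest_neighbour_distances(f, "single"),
                 oracle_nnd(f$x, f$y), tolerance = 1e-9)
    g <- delaunay_neighbours(f, "single")
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) adj[i, g$neighbours[[i]]] <- TRUE
    expect_identical(adj, oracle_delaunay_reference(f$x, f$y, adj))
  }
})

test_that("Voronoi areas: square grid, hexagonal closed form, conservation", {
  # interior cells of a unit-pitch square grid have unit area
  gx <- seq(0.5, 19.5, by = 1)
  gr <- expand.grid(x = gx, y = gx)
  f <- cone_field(gr$x, gr$y, rep("single", nrow(gr)), window = c(20, 20))
  va <- voronoi_domains(f, "single")
  interior <- exclude_border_cells(f, "single")
  expect_equal(va[interior], rep(1, length(interior)), tolerance = 1e-9)
  expect_equal(sum(va), 400, tolerance = 1e-9)

  # hexagonal tiling: interior areas sqrt(3)/2 * s^2
  hc <- gen_honeycomb(5, jitter_sd = 0, seed = 1)
  vh <- voronoi_domains(hc, "single")
  ih <- exclude_border_cells(hc, "single")
  expect_equal(vh[ih], rep(sqrt(3) / 2 * 25, length(ih)),
               tolerance = 1e-6)
  expect_equal(sum(vh), prod(hc$window), tolerance = 1e-6)

  # conservation and oracle agreement on random fields
  for (rep in 1:5) {
    f <- random_field(25, seed = 200 + rep)
    va <- voronoi_domains(f, "single")
    expect_equal(sum(va), prod(f$window), tolerance = 1e-8)
    expect_equal(va, oracle_voronoi_areas(f$x, f$y, f$window),
                 tolerance = 1e-7)
  }
})

test_that("border exclusion keeps exactly the cells with untruncated domains", {
  gx <- seq(2.6, 49.4, length.out = 10)
  gr <- expand.grid(x = gx, y = gx)
  f <- cone_field(gr$x, gr$y, rep("single", 100))
  interior <- exclude_border_cells(f, "single")
  expect_equal(length(interior), 64)
  # the interior set is exactly the inner 8 x 8 block
  inner <- which(gr$x > gx[1] & gr$x < gx[10] & gr$y > gx[1] &
                 gr$y < gx[10])
  expect_setequal(interior, inner)

  # 2x2 grid filling the window: every polygon touches the boundary
  g4 <- expand.grid(x = c(15, 37), y = c(15, 37))
  f4 <- cone_field(g4$x, g4$y, rep("single", 4))
  expect_length(exclude_border_cells(f4, "single"), 0)

  expect_length(exclude_border_cells(cone_field(5, 5, "single"), "single"),
                0)
})

test_that("shrinking the window never adds interior cells", {
  f <- random_field(50, window = c(60, 60), seed = 11)
  big <- exclude_border_cells(f, "single")
  keep <- f$x <= 50 & f$y <= 50
  small <- cone_field(f$x[keep], f$y[keep],
                      rep("single", sum(keep)), window = c(50, 50))
  small_int <- exclude_border_cells(small, "single")
  # map the smaller field's interior back to original indices: every cell
  # interior after shrinking was already interior before
  orig <- which(keep)[small_int]
  expect_true(all(orig %in% big))
  expect_lte(length(small_int), length(big))
})

test_that("regularity index follows its definition, with Inf at zero SD", {
  expect_equal(regularity_index(c(8, 10, 12)), 5)
  expect_identical(regularity_index(rep(10, 4)), Inf)
  expect_error(regularity_index(7), "at least 2")
  # sample SD (n-1): mean 10, SD 2 for {8,10,12}
  expect_equal(regularity_index(c(8, 10, 12)),
               10 / stats::sd(c(8, 10, 12)))
})

test_that("regularity ordering: lattice > hard-core random > Poisson", {
  ri <- function(vals) stats::median(vals)
  lat <- hc <- po <- numeric(10)
  for (s in 1:10) {
    lat[s] <- mosaic_summary(gen_honeycomb(5, jitter_sd = 0.25,
                                           seed = s),
                             "single")$nnd$regularity_index
    n <- 110
    hcf <- gen_hardcore_random(c(single = n), soma = soma_sizes(),
                               seed = s)
    hc[s] <- mosaic_summary(hcf, "single")$nnd$regularity_index
    po[s] <- mosaic_summary(random_field(n, seed = 300 + s),
                            "single")$nnd$regularity_index
  }
  expect_gt(ri(lat), ri(hc))
  expect_gt(ri(hc), ri(po))
})

test_that("mosaic_summary is internally consistent and uses interior cells", {
  f <- gen_square_mosaic(6, jitter_sd = 0.36, seed = 7)
  ms <- mosaic_summary(f, "double")
  expect_equal(ms$nnd$mean, mean(ms$nnd_values))
  expect_equal(ms$voronoi$sd, stats::sd(ms$vd_values))
  expect_equal(ms$nnd$regularity_index,
               mean(ms$nnd_values) / stats::sd(ms$nnd_values))
  expect_lte(ms$n_interior, ms$n_total)
  expect_true(ms$nnd$min <= ms$nnd$mean && ms$nnd$mean <= ms$nnd$max)

  # silently including border cells must change the result on a field
  # whose border spacing differs from its interior spacing
  all_nnd <- nearest_neighbour_distances(f, "double")
  expect_false(isTRUE(all.equal(mean(all_nnd), ms$nnd$mean)))

  # perfect square grid: zero SD, infinite regularity
  gx <- seq(1, 51, by = 2)
  gr <- expand.grid(x = gx, y = gx)
  pf <- cone_field(gr$x, gr$y, rep("single", nrow(gr)))
  ps <- mosaic_summary(pf, "single")
  expect_equal(ps$nnd$mean, 2)
  expect_identical(ps$nnd$regularity_index, Inf)
})

test_that("hard-core fields never violate the constraint in NND terms", {
  for (s in 1:20) {
    f <- gen_hardcore_random(c(single = 40), seed = 400 + s)
    ms <- mosaic_summary(f, "single")
    expect_gte(ms$nnd$min, 2.2)
  }
})
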