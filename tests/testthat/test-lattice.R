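test_that("regular triangular lattice reconstructs as hexagons of area sqrt(3)/2", {
  p <- hex_patch(8, 8, spacing = 1)
  vc <- voronoi_cells(p)
  int <- vc$is_interior
  expect_gt(sum(int), 20)
  expect_true(all(vc$n_walls[int] == 6L))
  expect_equal(vc$area[int], rep(sqrt(3) / 2, sum(int)), tolerance = 1e-5)
  # area-sum invariant at another spacing
  p2 <- hex_patch(10, 10, spacing = 2)
  vc2 <- voronoi_cells(p2)
  int2 <- vc2$is_interior
  expect_equal(sum(vc2$area[int2]), sum(int2) * 4 * sqrt(3) / 2,
               tolerance = 1e-5)
})

test_that("square grid of centres yields 4-walled interior cells", {
  sq <- as.matrix(expand.grid(x = 0:6, y = 0:6))
  vc <- voronoi_cells(sq)
  expect_true(all(vc$n_walls[vc$is_interior] == 4L))
})

test_that("wall counts and areas match the half-plane oracle cell-by-cell", {
  pj <- jitter_points(hex_patch(9, 9), 0.05, seed = 4)
  vc <- voronoi_cells(pj)
  for (i in which(vc$is_interior)) {
    expect_identical(vc$n_walls[i], oracle_wall_count(pj, i))
    expect_equal(vc$area[i], oracle_cell_area(pj, i), tolerance = 1e-4)
  }
})

test_that("interior polygons are simple, contain their centre, and average 6 walls", {
  pj <- jitter_points(hex_patch(12, 12), 0.04, seed = 9)
  vc <- voronoi_cells(pj)
  polys <- attr(vc, "polygons")
  int <- which(vc$is_interior)
  for (i in int[seq(1, length(int), by = 5)]) {
    ring <- polys[[i]]
    expect_gte(nrow(ring), 3L)
    # convex Voronoi cells contain their generator
    k <- nrow(ring)
    cr <- (ring[c(2:k, 1), 1] - ring[, 1]) * (vc$y[i] - ring[, 2]) -
      (ring[c(2:k, 1), 2] - ring[, 2]) * (vc$x[i] - ring[, 1])
    expect_true(all(cr > 0) || all(cr < 0))
  }
  # defect-free patch: every interior cell hexagonal, so the mean is 6
  expect_equal(mean(vc$n_walls[int]), 6)
})

test_that("validation rejects degenerate point sets", {
  collinear <- cbind(1:10, 2 * (1:10))
  expect_error(voronoi_cells(collinear), "collinear")
  expect_error(delaunay_graph(collinear), "collinear")
  dup <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 0))
  expect_error(voronoi_cells(dup), "duplicate")
  expect_error(voronoi_cells(rbind(c(0, 0), c(1, 0), c(NA, 1), c(1, 1))),
               "finite")
})

test_that("circumcircle test is strict with trivial and boundary cases", {
  a <- c(0, 0); b <- c(1, 0); cc <- c(0.5, sqrt(3) / 2)
  expect_true(circumcircle_contains(a, b, cc, c(0.5, 0.29)))
  expect_false(circumcircle_contains(a, b, cc, c(10, 10)))
  # point exactly on the circle: outside by the strict-interior convention
  centre <- c(0.5, sqrt(3) / 6)
  r <- sqrt(sum((a - centre)^2))
  on_circle <- centre + c(r, 0)
  expect_false(circumcircle_contains(a, b, cc, on_circle))
  expect_error(circumcircle_contains(a, b, c(2, 0), c(0, 0)), "collinear")
})

test_that("delaunay graph matches hand counts and the empty-circumcircle law", {
  g3 <- delaunay_graph(rbind(c(0, 0), c(2, 0), c(1, 1.5)), triangles = TRUE)
  expect_identical(nrow(g3$edges), 3L)
  expect_identical(nrow(g3$triangles), 1L)
  # cocircular square: 4 hull edges plus one tie-broken diagonal
  g4 <- delaunay_graph(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_identical(nrow(g4$edges), 5L)
  # 200 jittered lattice points: no triangle's circumcircle contains another
  pj <- jitter_points(hex_patch(14, 15), 0.05, seed = 2)[1:200, ]
  g <- delaunay_graph(pj, triangles = TRUE)
  for (r in seq_len(nrow(g$triangles))) {
    tri <- g$triangles[r, ]
    a <- pj[tri[1], ]; b <- pj[tri[2], ]; cc <- pj[tri[3], ]
    for (q in setdiff(seq_len(200), tri))
      if (circumcircle_contains(a, b, cc, pj[q, ], tol = 1e-7))
        fail(sprintf("triangle %d contains point %d", r, q))
  }
  succeed()
})

test_that("delaunay adjacency is dual to shared retained Voronoi walls", {
  pj <- jitter_points(hex_patch(10, 10), 0.05, seed = 11)
  vc <- voronoi_cells(pj)
  g <- delaunay_graph(pj)
  adj <- attr(vc, "adjacency")
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  expect_setequal(key(adj$i[adj$retained], adj$j[adj$retained]),
                  key(g$edges$i[g$edges$retained], g$edges$j[g$edges$retained]))
  # geometric duality: retained edges are exactly the pairs whose oracle
  # polygons share a wall of non-negligible length
  int <- which(vc$is_interior)
  some <- int[seq(1, length(int), by = 7)]
  for (i in some) {
    nb <- sort(c(adj$j[adj$retained & adj$i == i],
                 adj$i[adj$retained & adj$j == i]))
    expect_identical(length(nb), as.integer(vc$n_walls[i]))
  }
})
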