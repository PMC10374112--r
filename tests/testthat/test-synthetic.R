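test_that("hex_patch builds the stated lattice", {
  p <- hex_patch(1, 3, 1.0)
  expect_identical(dim(p), c(3L, 2L))
  expect_true(all(p[, 2] == 0))
  expect_equal(diff(p[, 1]), c(1, 1))

  p2 <- hex_patch(3, 3, 1.0)
  d <- as.matrix(dist(p2))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(1, 9), tolerance = 1e-12)

  vc <- voronoi_cells(hex_patch(10, 10, 2.0))
  expect_equal(vc$area[vc$is_interior],
               rep(4 * sqrt(3) / 2, sum(vc$is_interior)), tolerance = 1e-5)
  expect_error(hex_patch(3, 3, 0), "positive")
  expect_error(hex_patch(0, 3), ">= 1")
})

test_that("jitter is reproducible, scale-aware and identity at sigma 0", {
  p <- hex_patch(6, 6)
  expect_identical(jitter_points(p, 0, seed = 1), p)
  j1 <- jitter_points(p, 0.05, seed = 7)
  j2 <- jitter_points(p, 0.05, seed = 7)
  expect_identical(j1, j2)
  expect_false(identical(j1, jitter_points(p, 0.05, seed = 8)))
  # displacement sd scales with local spacing
  big <- jitter_points(p, 0.05, seed = 7, local_spacing = 10)
  expect_equal((big - p) / 10, j1 - p, tolerance = 1e-12)
  expect_error(jitter_points(p, -0.1), ">= 0")
})

test_that("small jitter leaves near-hexagonal lattices hexagonal", {
  p <- hex_patch(32, 32)
  for (sd in 1:10) {
    vc <- voronoi_cells(jitter_points(p, 0.03, seed = sd))
    expect_gte(mean(vc$n_walls[vc$is_interior] == 6L), 0.99)
  }
})

test_that("monomorphic one-step merge is a defect-free lattice", {
  cb <- one_step_merge(L = 8, alpha = 1, jitter_sigma = 0)
  cl <- analyze_comb(cb)$cells
  expect_identical(sum(cl$is_interior & cl$n_walls != 6L), 0L)
})

test_that("one-step merges produce the bookkept dislocations", {
  # alpha = 2, L = 7: floor((1 - 1/2) * 7) = 3 pairs on the line
  cb <- one_step_merge(L = 7, alpha = 2, jitter_sigma = 0)
  expect_identical(pairs_on_window(cb), 3L)
  # short low-dimorphism line stays defect-free (L < alpha/(alpha-1))
  cb2 <- one_step_merge(L = 4, alpha = 1.2, jitter_sigma = 0)
  cl2 <- analyze_comb(cb2)$cells
  w <- cb2$metadata$window
  expect_identical(sum(cl2$is_interior & cl2$n_walls != 6L &
                         cl2$x >= w[1] & cl2$x < w[2]), 0L)
  expect_error(one_step_merge(L = 1, alpha = 1.5), "L must be")
  expect_error(one_step_merge(L = 8, alpha = 0.9), "alpha")
})

test_that("generator-analyzer closure holds on an (alpha, L) grid", {
  for (al in alpha_grid(1.1, 1.9, by = 0.2)) {
    for (L in c(4, 9, 15)) {
      cb <- one_step_merge(L = L, alpha = al, jitter_sigma = 0)
      expect_lte(abs(pairs_on_window(cb) - expected_pairs(al, L)), 1)
    }
  }
})

test_that("every non-hexagonal cell on a noiseless line is a worker-side 5 with a reproductive 7", {
  for (al in c(1.35, 1.7)) {
    cb <- one_step_merge(L = 12, alpha = al, jitter_sigma = 0)
    a <- analyze_comb(cb)
    det <- detect_57_pairs(a)
    cl <- a$cells
    w <- cb$metadata$window
    inw <- cl$is_interior & cl$n_walls != 6L & cl$x >= w[1] & cl$x < w[2]
    expect_true(all(cl$cell_id[inw] %in%
                      c(det$pairs$five_id, det$pairs$seven_id)))
    expect_true(all(det$pairs$five_label == "worker"))
    expect_true(all(det$pairs$seven_label == "reproductive"))
  }
})

test_that("layered merges with the required layer count are defect-free", {
  for (al in c(1.15, 1.3, 1.6432, 1.95)) {
    L <- 10
    cb <- layered_merge(L = L, alpha = al, T = layers_required(al, L),
                        jitter_sigma = 0)
    cl <- analyze_comb(cb)$cells
    expect_identical(sum(cl$is_interior & cl$n_walls != 6L), 0L)
  }
})

test_that("layering never increases, and complete layering removes, dislocations", {
  al <- 1.3; L <- 10
  sudden <- pairs_on_window(one_step_merge(L, al, jitter_sigma = 0,
                                           margin = 0, phase_nudge = 0))
  partial <- pairs_on_window(layered_merge(L, al, T = 1, jitter_sigma = 0))
  complete <- pairs_on_window(layered_merge(L, al, T = layers_required(al, L),
                                            jitter_sigma = 0))
  expect_lte(partial, sudden)
  expect_identical(complete, 0L)
  expect_lt(complete, sudden)
})

test_that("layered merge geometry follows the generating conventions", {
  # T layers step the spacing geometrically, layer T at reproductive pitch
  cb <- layered_merge(L = 8, alpha = 1.44, T = 2, jitter_sigma = 0)
  for (t in 1:2) {
    row <- cb$centers[cb$labels == paste0("transition_", t), , drop = FALSE]
    expect_equal(unique(round(diff(sort(row[, 1])), 9)), 1.44^(t / 2))
  }
  # alpha = 1: all layers at worker spacing
  cb1 <- layered_merge(L = 8, alpha = 1, T = 3, jitter_sigma = 0)
  for (t in 1:3) {
    row <- cb1$centers[cb1$labels == paste0("transition_", t), , drop = FALSE]
    expect_equal(unique(round(diff(sort(row[, 1])), 9)), 1)
  }
  # T = 0 delegates to the one-step generator
  cb0 <- layered_merge(L = 8, alpha = 1.3, T = 0)
  expect_identical(cb0$metadata$generator, "one_step_merge")
})
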