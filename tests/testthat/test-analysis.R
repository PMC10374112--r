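test_that("normalized areas map the worker median to zero", {
  cb <- one_step_merge(L = 8, alpha = 1, jitter_sigma = 0)
  na <- normalized_areas(cb)
  a <- analyze_comb(cb)
  expect_equal(stats::median(na[a$cells$is_interior], na.rm = TRUE), 0,
               tolerance = 1e-9)
  # alpha = 1.2: reproductive cells cluster near alpha^2 - 1 = 0.44
  cb2 <- one_step_merge(L = 10, alpha = 1.2, jitter_sigma = 0)
  a2 <- analyze_comb(cb2)
  na2 <- normalized_areas(a2)
  rep_far <- a2$cells$is_interior & a2$cells$label == "reproductive" &
    a2$cells$n_walls == 6L & a2$cells$y > 2
  expect_equal(stats::median(na2[rep_far]), 0.44, tolerance = 0.02)
})

test_that("dimorphism score recovers the generating ratio and handles absence", {
  cb <- one_step_merge(L = 10, alpha = sqrt(2.70), jitter_sigma = 0)
  expect_equal(dimorphism_score(cb), 1.70, tolerance = 0.02)
  cb1 <- one_step_merge(L = 10, alpha = 1, jitter_sigma = 0)
  expect_equal(dimorphism_score(cb1), 0, tolerance = 0.02)
  # missing a label class: absent value, not zero
  mono <- comb(hex_patch(6, 6), labels = "worker")
  expect_true(is.na(dimorphism_score(mono)))
  expect_error(normalized_areas(comb(hex_patch(6, 6), labels = "reproductive")),
               "worker")
})

test_that("transition line is recovered, label-symmetric and rotation-equivariant", {
  cb <- one_step_merge(L = 12, alpha = 1.5, jitter_sigma = 0.02, seed = 3)
  ln <- fit_transition_line(cb)
  truth <- cb$metadata$line
  expect_lt(abs(ln$point[2] - truth$point[2]), 0.1)
  ang <- abs(atan2(ln$direction[2], ln$direction[1])) %% pi
  expect_lt(min(ang, pi - ang), 2 * pi / 180)
  # swapping the two classes leaves the line unchanged
  swapped <- cb
  swapped$labels <- ifelse(cb$labels == "worker", "reproductive", "worker")
  ln2 <- fit_transition_line(swapped)
  expect_equal(ln2$point, ln$point, tolerance = 1e-9)
  expect_equal(abs(sum(ln2$direction * ln$direction)), 1, tolerance = 1e-9)
  # rotating the comb rotates the fitted line with it
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- comb(cb$centers %*% t(R), cb$labels,
              growth_direction = as.numeric(R %*% cb$growth_direction))
  ln3 <- fit_transition_line(rot)
  expect_equal(abs(sum(ln3$direction * (R %*% ln$direction))), 1,
               tolerance = 1e-6)
})

test_that("four-parameter fit recovers noiseless profiles to numerical precision", {
  set.seed(1)
  d <- stats::runif(400, -6, 6)
  y <- 1 + pmin(pmax((d + 1) / 3, 0), 1)
  f <- fit_transition(distances = d, areas = y)
  expect_equal(f$A_worker, 1, tolerance = 1e-6)
  expect_equal(f$A_rep, 2, tolerance = 1e-6)
  expect_equal(f$O_worker, -1, tolerance = 1e-5)
  expect_equal(f$O_rep, 2, tolerance = 1e-5)
  expect_lt(f$rss, 1e-10)
  expect_error(fit_transition(distances = 1:3, areas = 1:3), "fewer")
})

test_that("monomorphic combs fit a degenerate transition with no layers", {
  cb <- one_step_merge(L = 8, alpha = 1, jitter_sigma = 0.02, seed = 5)
  a <- analyze_comb(cb)
  f <- fit_transition(a)
  expect_equal(f$A_rep / f$A_worker, 1, tolerance = 0.05)
  expect_equal(observed_layers(f), 0)
  # zero-width ramp means no layers regardless of alpha
  f0 <- f; f0$depth <- 0; f0$O_rep <- f0$O_worker
  expect_identical(observed_layers(f0, alpha = 1.4, L = 10), 0)
})

test_that("observed layers recover the generated layering and obey the 50% rule", {
  cb <- layered_merge(L = 10, alpha = 1.3, T = 3, jitter_sigma = 0)
  f <- fit_transition(cb)
  expect_equal(observed_layers(f, alpha = 1.3), 3, tolerance = 0.5)
  # dense defects force T_obs to zero through the hexagonal-fraction rule
  cb2 <- one_step_merge(L = 10, alpha = 1.9, jitter_sigma = 0.02, seed = 2)
  f2 <- fit_transition(cb2)
  expect_lt(f2$hex_fraction_in_transition, 0.5)
  expect_identical(observed_layers(f2, alpha = 1.9), 0)
})

test_that("5-7 pair detection pairs, orients and summarises correctly", {
  # defect-free lattice: nothing to detect
  cb0 <- one_step_merge(L = 8, alpha = 1, jitter_sigma = 0)
  det0 <- detect_57_pairs(cb0)
  expect_identical(nrow(det0$pairs), 0L)
  expect_true(all(det0$summary$n_by_class == 0))

  cb <- one_step_merge(L = 7, alpha = 2, jitter_sigma = 0)
  det <- detect_57_pairs(cb)
  expect_identical(pairs_on_window(cb, det), 3L)
  expect_true(all(det$pairs$oriented_correctly))
  # greedy matching uses each cell at most once
  ids <- c(det$pairs$five_id, det$pairs$seven_id)
  expect_identical(anyDuplicated(ids), 0L)
  # without growth direction pairing still works, orientation is absent
  cb_na <- comb(cb$centers, cb$labels, growth_direction = NULL,
                metadata = cb$metadata)
  det_na <- detect_57_pairs(cb_na)
  expect_identical(nrow(det_na$pairs), nrow(det$pairs))
  expect_true(all(is.na(det_na$pairs$oriented_correctly)))
  # in noiseless one-step merges every 5/7 cell is paired (margin 0 keeps
  # line-end dislocations out of the interior, so none loses its partner)
  cb_p <- one_step_merge(L = 7, alpha = 1.6432, jitter_sigma = 0, margin = 0)
  expect_equal(detect_57_pairs(cb_p)$summary$fraction_paired, 1)
})

test_that("defect-class percentages reproduce the published breakdown", {
  res <- defect_class_percentages(c(`4` = 2, `5` = 291, `7` = 259, `8` = 14))
  expect_identical(res$total, 566)
  expect_equal(round(unname(res$percent), 2), c(0.35, 51.41, 45.76, 2.47))
  expect_equal(round(res$percent_57, 2), 97.17)
  empty <- defect_class_percentages(c(`4` = 0, `5` = 0, `7` = 0, `8` = 0))
  expect_identical(empty$total, 0)
})

test_that("per-comb summary assembles consistent measurements", {
  cb <- one_step_merge(L = 9, alpha = 1.5, jitter_sigma = 0.02, seed = 4)
  s <- comb_summary(cb)
  expect_equal(s$D, 1.25, tolerance = 0.07)
  expect_equal(s$alpha, sqrt(s$D + 1))
  expect_identical(s$n_nonhex, s$n4 + s$n5 + s$n7 + s$n8 +
                     (s$n_interior - s$n4 - s$n5 - s$n6 - s$n7 - s$n8))
  expect_lte(s$alpha_E, s$alpha + 1e-9)
  expect_equal(s$prop_nonhex, s$n_nonhex / s$n_interior)
})
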