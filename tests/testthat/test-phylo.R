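test_that("time trees assemble from dated splits", {
  t2 <- build_timetree("(A,B);", data.frame(tip1 = "A", tip2 = "B", age = 179))
  expect_equal(t2$edge.length, c(179, 179))

  # taxon-count ages {2, 1} rescaled to an 8-My anchor become {8, 4}
  t3 <- build_timetree("((X,(Y,Z)),W);",
                       data.frame(tip1 = "X", tip2 = "W", age = 20),
                       rescale_clade = list(tips = c("X", "Y", "Z"), age = 8))
  bt <- ape::branching.times(t3)
  expect_equal(sort(unname(bt)), c(4, 8, 20))
  expect_true(ape::is.ultrametric(t3))
  # rescaling preserves topology: (Y,Z) still form a cherry inside (X,Y,Z)
  expect_true(all(sort(t3$tip.label) == c("W", "X", "Y", "Z")))
  expect_identical(unname(bt[as.character(ape::getMRCA(t3, c("Y", "Z")))]), 4)
  expect_identical(unname(bt[as.character(ape::getMRCA(t3, c("X", "Y")))]), 8)

  expect_error(build_timetree("((A,B),C);",
                              data.frame(tip1 = "A", tip2 = "B", age = 10),
                              rescale_clade = list(tips = c("A", "Q"), age = 8)),
               "absent")
  # ages must be monotone along the tree
  expect_error(build_timetree("((A,B),C);",
                              data.frame(tip1 = c("A", "A"), tip2 = c("B", "C"),
                                         age = c(30, 10))),
               "monotone")
})

test_that("the bundled example study tree is ultrametric with the stated anchors", {
  tr <- study_timetree()
  expect_identical(ape::Ntip(tr), 10L)
  expect_true(ape::is.ultrametric(tr))
  bt <- ape::branching.times(tr)
  expect_equal(max(bt), 179)
  vesp <- c("V_vulgaris", "V_flavopilosa", "V_maculifrons", "V_shidai")
  expect_equal(unname(bt[as.character(ape::getMRCA(tr, vesp))]), 8)
})

test_that("pgls at lambda 0 equals ordinary least squares", {
  tr <- study_timetree()
  set.seed(11)
  x <- stats::setNames(stats::rnorm(10), tr$tip.label)
  y <- stats::setNames(stats::rnorm(10), tr$tip.label)
  f <- pgls_fit(x, y, tr, lambda = 0)
  o <- stats::lm(y[tr$tip.label] ~ x[tr$tip.label])
  expect_equal(f$slope, unname(stats::coef(o)[2]), tolerance = 1e-10)
  expect_equal(f$intercept, unname(stats::coef(o)[1]), tolerance = 1e-10)
  expect_equal(f$adj_R2, summary(o)$adj.r.squared, tolerance = 1e-10)
  expect_equal(f$F_stat, unname(summary(o)$fstatistic[1]), tolerance = 1e-8)
})

test_that("on a star phylogeny pgls equals ols for any lambda", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(4)
  x <- stats::setNames(stats::rnorm(6), star$tip.label)
  y <- stats::setNames(2 + 0.5 * x + stats::rnorm(6, 0, 0.1), star$tip.label)
  o <- stats::lm(y[star$tip.label] ~ x[star$tip.label])
  for (lam in c(0, 0.4, 1)) {
    f <- pgls_fit(x, y, star, lambda = lam)
    expect_equal(f$slope, unname(stats::coef(o)[2]), tolerance = 1e-10)
  }
})

test_that("pgls agrees with the independent gls implementation at fixed lambda", {
  skip_if_not_installed("nlme")
  tr <- study_timetree()
  set.seed(21)
  x <- sim_brownian(tr)
  y <- 1 + 0.3 * x + sim_brownian(tr, sigma2 = 0.3)
  d <- data.frame(x = x[tr$tip.label], y = y[tr$tip.label],
                  sp = tr$tip.label)
  for (lam in c(0.25, 0.6, 0.95)) {
    f <- pgls_fit(x, y, tr, lambda = lam)
    g <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(lam, tr, form = ~sp,
                                               fixed = TRUE),
                   method = "ML")
    expect_equal(f$slope, unname(stats::coef(g)[2]), tolerance = 1e-8)
    expect_equal(f$intercept, unname(stats::coef(g)[1]), tolerance = 1e-8)
    expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-8)
  }
})

test_that("the likelihood at the estimated lambda dominates a coarse grid", {
  tr <- study_timetree()
  set.seed(33)
  for (r in 1:5) {
    x <- sim_brownian(tr)
    y <- 0.5 * x + sim_brownian(tr, sigma2 = 0.4)
    f <- pgls_fit(x, y, tr)
    for (lam in c(0, 0.5, 1)) {
      fl <- pgls_fit(x, y, tr, lambda = lam)
      expect_gte(f$loglik, fl$loglik - 1e-7)
    }
  }
})

test_that("brownian simulations recover slope and high lambda", {
  tr <- study_timetree()
  set.seed(5)
  sl <- lam <- numeric(60)
  for (r in 1:60) {
    x <- sim_brownian(tr, sigma2 = 1 / 179)
    y <- 1 + 0.3 * x + sim_brownian(tr, sigma2 = 0.25 / 179)
    f <- pgls_fit(x, y, tr)
    sl[r] <- f$slope; lam[r] <- f$lambda
  }
  mc_se <- stats::sd(sl) / sqrt(60)
  expect_lt(abs(mean(sl) - 0.3), 3 * mc_se + 1e-8)
  expect_gte(stats::median(lam), 0.8)
})
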