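# Brute-force Bray-Curtis oracle
oracle_bc <- function(x, y) sum(abs(x - y)) / sum(x + y)

test_that("Bray-Curtis matches hand values and the brute-force oracle", {
  m <- rbind(a = c(2, 1, 0), b = c(1, 1, 1)) / 3
  expect_equal(as.matrix(bray_curtis(rbind(a = c(2, 1, 0), b = c(1, 1, 1))))["a", "b"],
               1 / 3)
  expect_equal(max(as.matrix(bray_curtis(rbind(c(1, 0), c(0, 1))))), 1) # disjoint
  expect_equal(as.matrix(bray_curtis(rbind(c(0.5, 0.5), c(0.5, 0.5))))[1, 2], 0)
  set.seed(9)
  x <- matrix(rgamma(5 * 7, 1), 5, 7)
  d <- as.matrix(bray_curtis(x))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], oracle_bc(x[i, ], x[j, ]))
    expect_equal(d[i, j], d[j, i]) # symmetry
  }
  expect_validation_error(bray_curtis(rbind(c(1, 1), c(0, 0))), "all-zero row")
})

test_that("Bray-Curtis agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(rgamma(60, 1), 6, 10)
  expect_equal(as.matrix(bray_curtis(m)),
               as.matrix(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA recovers geometry of Euclidean configurations", {
  # 1-D points: first axis reproduces all pairwise distances
  d <- dist(c(0, 3, 5))
  ord <- pcoa(d, k = 2)
  ax1 <- ord$coordinates$Axis1
  expect_equal(as.matrix(dist(ax1)), as.matrix(d), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_lt(max(abs(ord$eigenvalues[-1])), 1e-8) # remaining eigenvalues ~ 0
  expect_equal(ord$proportion_explained[1], 1, tolerance = 1e-10)

  # full-rank reconstruction of a random Euclidean cloud
  set.seed(4)
  x <- matrix(rnorm(8 * 3), 8, 3)
  ordx <- pcoa(dist(x), k = 7)
  coords <- as.matrix(ordx$coordinates[-1])
  expect_lt(max(abs(as.matrix(dist(coords)) - as.matrix(dist(x)))), 1e-8)

  # degenerate: all-zero distances -> all-zero coordinates
  z <- pcoa(matrix(0, 4, 4), k = 2)
  expect_true(all(as.matrix(z$coordinates[-1]) == 0))

  expect_validation_error(pcoa(dist(c(0, 1, 2)), k = 3), "k must")
})

test_that("PCoA reports negative eigenvalues for non-Euclidean input", {
  m <- matrix(c(0, 1, 1, 10,
                1, 0, 1, 1,
                1, 1, 0, 1,
                10, 1, 1, 0), 4, 4) # violates the triangle inequality badly
  ord <- pcoa(m, k = 2)
  expect_lt(min(ord$eigenvalues), -1e-8)
})

test_that("PERMANOVA exact enumeration reproduces the 4-point line fixture", {
  res <- permanova(dist(c(0, 1, 10, 11)), c("a", "a", "b", "b"))
  expect_true(res$exact)
  expect_equal(res$statistic, 200)
  expect_equal(res$r_squared, 100 / 101)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$n_permutations, 6)
})

test_that("PERMANOVA validates inputs and handles degenerate data", {
  d <- dist(c(0, 1, 2, 3))
  expect_validation_error(permanova(d, c("a", "a", "a", "a")), "at least 2 groups")
  expect_validation_error(permanova(d, c("a", "a", "a", "b")), "fewer than 2")
  res <- permanova(matrix(0, 4, 4), c("a", "a", "b", "b")) # identical samples
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("PERMANOVA F and R2 agree with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(88)
  m <- matrix(rgamma(20 * 12, 1), 20, 12)
  g <- rep(c("a", "b"), each = 10)
  d <- bray_curtis(m)
  mine <- permanova(d, g, n_perm = 99, seed = 1)
  va <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(mine$statistic, va$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, va$R2[1], tolerance = 1e-10)
})

test_that("exact and Monte-Carlo PERMANOVA p-values agree on a small instance", {
  d <- dist(c(0, 1, 10, 11, 5))
  g <- c("a", "a", "b", "b", "b")
  exact <- permanova(d, g) # 10 assignments, enumerated
  expect_true(exact$exact)
  mc <- permanova(d, g, n_perm = 9999, seed = 2, exact_limit = 1)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 9999)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 2 / 9999)
})

test_that("dispersion test sees equal spread in congruent clouds, unequal in scaled", {
  set.seed(10)
  base <- matrix(rnorm(15 * 2), 15, 2)
  # congruent: same shape, translated apart -> no dispersion difference
  x <- rbind(base, sweep(base, 2, c(20, 0), "+"))
  g <- rep(c("a", "b"), each = 15)
  res <- betadisper_test(dist(x), g, n_perm = 199, seed = 3)
  expect_lt(res$statistic, 1e-6)
  expect_gt(res$p_value, 0.9)
  expect_validation_error(
    betadisper_test(dist(x[c(1:15, 16), ]), rep(c("a", "b"), c(15, 1))),
    "fewer than 2")

  # group B five times as dispersed: power over seeded replicates
  hits <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    a <- matrix(rnorm(10 * 2), 10, 2)
    b <- matrix(rnorm(10 * 2, sd = 5), 10, 2)
    g2 <- rep(c("a", "b"), each = 10)
    betadisper_test(dist(rbind(a, b)), g2, n_perm = 999,
                    seed = i)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("dispersion distances agree with vegan::betadisper (centroid type)", {
  skip_if_not_installed("vegan")
  set.seed(55)
  m <- matrix(rgamma(24 * 10, 1), 24, 10)
  g <- rep(c("a", "b"), each = 12)
  d <- bray_curtis(m)
  mine <- betadisper_test(d, g, n_perm = 99, seed = 1, type = "centroid")
  vb <- vegan::betadisper(d, g, type = "centroid")
  f_vegan <- anova(vb)$`F value`[1]
  expect_equal(mine$statistic, f_vegan, tolerance = 1e-6)
})

test_that("permutation p-values are calibrated under a small null (smoke)", {
  set.seed(303)
  hits <- vapply(1:60, function(i) {
    x <- matrix(rnorm(16 * 3), 16, 3)
    g <- rep(c("a", "b"), each = 8)
    permanova(dist(x), g, n_perm = 199, seed = i,
              exact_limit = 1)$p_value <= 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.15) # loose module-level guard; full calibration elsewhere
})
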