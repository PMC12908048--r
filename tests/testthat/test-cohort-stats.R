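# Hand step-up BH oracle, independent of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

test_that("PLR is the platelet/lymphocyte quotient with guards", {
  expect_equal(plr(300000, 2000), 150)
  expect_equal(plr(250000, 1250), 200)
  expect_equal(plr(c(3e5, 2.5e5), c(2000, 1250)), c(150, 200))
  expect_validation_error(plr(100000, 0), "lymphocytes")
  expect_validation_error(plr(-1, 100), "platelets")
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03) # single p unchanged
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.5, 10)), rep(0.5, 10)) # equal-p fixed point
  expect_validation_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_validation_error(bh_fdr(c(0.5, 0)), "0, 1")
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15)) # adjusted >= raw
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone in sorted order
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm]) # permutation equivariance
  }
})

test_that("categorical comparisons use the chi-square closed form", {
  df <- tibble::tibble(
    infection = rep(c(1, 0), c(33, 47)),
    agegrp = c(rep(c("lt60", "ge60"), c(8, 25)), rep(c("lt60", "ge60"), c(28, 19)))
  )
  res <- compare_groups(df, vars = "agegrp")
  closed_form <- 80 * (8 * 19 - 25 * 28)^2 / (33 * 47 * 36 * 44)
  expect_equal(res$test, "chi_square")
  expect_equal(res$statistic, closed_form, tolerance = 1e-6)
  expect_equal(res$statistic, 9.779, tolerance = 1e-3)

  # balanced table: statistic 0, p 1
  bal <- tibble::tibble(infection = rep(c(1, 0), each = 20),
                        x = rep(c("a", "b"), 20))
  res0 <- compare_groups(bal, vars = "x")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # sparse expected cells route to Fisher
  sparse <- tibble::tibble(infection = rep(c(1, 0), each = 6),
                           x = c(rep("a", 5), "b", "a", rep("b", 5)))
  expect_equal(compare_groups(sparse, vars = "x")$test, "fisher")
})

test_that("chi-square equals the 2x2 closed form on random well-filled tables", {
  set.seed(31)
  for (i in 1:20) {
    tab <- matrix(sample(10:40, 4, replace = TRUE), 2, 2)
    df <- tibble::tibble(
      infection = rep(c(1, 1, 0, 0), times = as.vector(t(tab))),
      x = rep(c("a", "b", "a", "b"), times = as.vector(t(tab)))
    )
    n <- sum(tab)
    cf <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
    res <- compare_groups(df, vars = "x")
    if (res$test == "chi_square") expect_equal(res$statistic, cf)
  }
})

test_that("continuous comparisons pick a test and handle identical samples", {
  set.seed(8)
  df <- tibble::tibble(infection = rep(c(1, 0), each = 20),
                       gauss = rnorm(40), skewed = rlnorm(40, 0, 2))
  res <- compare_groups(df)
  expect_equal(res$test[res$variable == "gauss"], "t")
  expect_equal(res$test[res$variable == "skewed"], "mann_whitney")
  expect_true(all(grepl(";", res$summary_case[res$kind == "continuous"])))

  same <- tibble::tibble(infection = rep(c(1, 0), each = 5),
                         v = rep(c(3, 7, 1, 9, 5), 2))
  expect_equal(compare_groups(same, vars = "v",
                              policy = "mann_whitney")$p_value, 1)
  expect_equal(compare_groups(df, vars = "gauss", policy = "mann_whitney")$test,
               "mann_whitney") # policy override recorded
  expect_validation_error(compare_groups(dplyr::mutate(df, infection = 1)),
                          "two groups")
})

test_that("correlation handles ranks, ties and degenerate input", {
  expect_equal(correlate(1:8, (1:8)^3)$estimate, 1) # monotone -> rho 1
  expect_equal(correlate(1:8, -(1:8)^3)$estimate, -1)
  # mid-ranks under ties: Spearman == Pearson on mid-rank-transformed data
  x <- c(1, 2, 2, 3)
  y <- c(1, 3, 2, 4)
  expect_equal(correlate(x, y)$estimate, cor(rank(x), rank(y)))
  expect_equal(correlate(x, y)$estimate, 1.5 / sqrt(1.5 * 5 / 3)) # hand value
  set.seed(77)
  for (i in 1:15) {
    a <- sample(1:6, 12, replace = TRUE)
    b <- sample(1:6, 12, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(correlate(a, b)$estimate, cor(rank(a), rank(b)))
  }
  expect_validation_error(correlate(rep(1, 5), 1:5), "constant")
  expect_validation_error(correlate(1:3, 1:3), "at least 4")
})

test_that("biomarker association table carries BH-adjusted point correlations", {
  co <- tiny_cohort(seed = 13)
  res <- biomarker_associations(co$metadata)
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  expect_true(all(abs(res$r) <= 1))
  # directions follow the generative shifts
  expect_gt(res$r[res$biomarker == "nmdar"], 0)
  expect_lt(res$r[res$biomarker == "butyrate"], 0)
})

test_that("family-wise any-rejection rate is controlled under the global null", {
  set.seed(1001)
  any_rej <- replicate(300, any(bh_fdr(runif(100)) < 0.05))
  expect_lte(mean(any_rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})
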