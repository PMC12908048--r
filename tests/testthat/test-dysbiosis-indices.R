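panel_ab <- dysbiosis_panel(enriched = "A", depleted = "B")

test_that("MDI matches its defining formula on hand cases", {
  expect_equal(mdi(c(A = 0.1, B = 0.1), panel_ab), 0) # symmetric sums
  expect_equal(mdi(c(A = 9, B = 0), panel_ab), 1) # algebraic identity check
  expect_equal(mdi(c(A = 0.04, B = 0.24), panel_ab), log10(1.04 / 1.24))
  expect_equal(log10(1.04 / 1.24), -0.0764, tolerance = 1e-3)
  # panel taxon absent from sample contributes zero
  expect_equal(mdi(c(A = 0.04, X = 0.5), panel_ab), log10(1.04))
  # bounds on relative abundances
  expect_lte(mdi(c(A = 1, B = 0), panel_ab), log10(2))
  expect_gte(mdi(c(A = 0, B = 1), panel_ab), -log10(2))
})

test_that("SDI reduces to MDI at unit weights and epsilon 1, and applies weights", {
  set.seed(41)
  for (i in 1:20) {
    ab <- setNames(random_proportions(6), c("A", "B", "C", "D", "E", "F"))
    pan <- dysbiosis_panel(enriched = c("A", "C"), depleted = c("B", "D"))
    expect_identical(sdi(ab, pan, epsilon = 1), mdi(ab, pan))
  }
  w <- dysbiosis_panel(enriched = c(A = 2), depleted = c(B = 1))
  got <- sdi(c(A = 0.1, B = 0.05), w, epsilon = 1e-6)
  expect_equal(got, log10(0.200001 / 0.050001))
  expect_equal(got, 0.602052, tolerance = 1e-5)
  # symmetric weighted sums -> 0
  expect_equal(sdi(c(A = 0.05, B = 0.1), w), 0)
  expect_validation_error(sdi(c(A = 0.1, B = 0.1), w, epsilon = 0), "epsilon")
})

test_that("indices are monotone in enriched abundance and zero at empty panels", {
  set.seed(43)
  pan <- dysbiosis_panel(enriched = c("A", "B"), depleted = c("C", "D"))
  for (i in 1:15) {
    ab <- setNames(runif(5, 0, 0.2), c("A", "B", "C", "D", "E"))
    bumped <- ab
    bumped["A"] <- ab["A"] + runif(1, 0, 0.2)
    expect_gte(sdi(bumped, pan), sdi(ab, pan))
    expect_gte(mdi(bumped, pan), mdi(ab, pan))
    zeroed <- ab
    zeroed[c("A", "B", "C", "D")] <- 0
    expect_equal(sdi(zeroed, pan, epsilon = 1), 0)
    expect_equal(mdi(zeroed, pan), 0)
  }
})

test_that("dysbiosis_scores reports coverage and refuses count tables", {
  co <- tiny_cohort(seed = 2)
  sc <- dysbiosis_scores(co$abundance)
  expect_equal(names(sc), c("sample_id", "sdi", "mdi", "panel_coverage"))
  expect_true(all(is.finite(sc$sdi) & is.finite(sc$mdi)))
  expect_equal(unique(sc$panel_coverage), 1)
  expect_validation_error(dysbiosis_scores(co$counts), "relative")
  # panel taxa missing from the table lower the coverage
  pan <- dysbiosis_panel(enriched = c("Klebsiella_pneumoniae", "NotInTable"),
                         depleted = "Faecalibacterium_prausnitzii")
  expect_equal(unique(dysbiosis_scores(co$abundance, pan)$panel_coverage), 2 / 3)
})

test_that("derive_panel finds a strongly shifted taxon and honours alpha", {
  set.seed(19)
  n <- 30
  m <- matrix(rgamma(2 * n * 10, 1), 2 * n, 10,
              dimnames = list(NULL, paste0("t", 1:10)))
  labels <- rep(c(1, 0), each = n)
  m[labels == 1, "t1"] <- m[labels == 1, "t1"] * 10 # planted fold-10 shift
  tbl <- rel_table(m)
  pan <- derive_panel(tbl, labels, alpha = 0.05)
  expect_true("t1" %in% names(pan$enriched))
  expect_equal(unname(pan$enriched["t1"]), 1) # largest shift carries weight 1
  # alpha = 1: every taxon with a nonzero median difference is assigned
  all_pan <- derive_panel(tbl, labels, alpha = 1)
  expect_equal(length(all_pan$enriched) + length(all_pan$depleted), 10)
  expect_validation_error(derive_panel(tbl, rep(c(1, 0), c(2, 58))),
                          "fewer than 3")
})

test_that("derive_panel on null tables raises the empty-panel error", {
  set.seed(23)
  empty_raised <- vapply(1:60, function(i) {
    m <- matrix(rgamma(20 * 15, 1), 20, 15,
                dimnames = list(NULL, paste0("t", 1:15)))
    tryCatch({
      derive_panel(rel_table(m), rep(c(1, 0), each = 10), alpha = 0.05)
      FALSE
    }, strokedysbiosis_validation_error = function(e) {
      grepl("both panel lists empty", conditionMessage(e))
    })
  }, logical(1))
  expect_gte(mean(empty_raised), 0.9)
})

test_that("age-SDI correlation handles monotone, null and two-cluster cases", {
  md <- tibble::tibble(sample_id = sprintf("S%02d", 1:12),
                       age = 40 + (1:12), infection = rep(c(1, 0), 6))
  sc <- tibble::tibble(sample_id = md$sample_id, sdi = (1:12) / 10)
  pooled <- age_sdi_correlation(md, sc, stratify = "pooled")
  expect_equal(pooled$rho, 1)
  expect_equal(pooled$n, 12)

  expect_validation_error(
    age_sdi_correlation(dplyr::mutate(md, age = 50), sc, stratify = "pooled"),
    "constant age")

  # Simpson-style reversal: pooled correlation exceeds both within-group ones
  set.seed(71)
  n <- 20
  md2 <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:(2 * n)),
    infection = rep(c(0, 1), each = n),
    age = c(rnorm(n, 55, 3), rnorm(n, 70, 3))
  )
  sc2 <- tibble::tibble(sample_id = md2$sample_id,
                        sdi = c(rnorm(n, -0.4, 0.15), rnorm(n, 0.4, 0.15)))
  res <- age_sdi_correlation(md2, sc2)
  pooled_rho <- res$rho[res$stratum == "pooled"]
  within <- res$rho[res$stratum != "pooled"]
  expect_gt(pooled_rho, max(abs(within)))
  expect_gt(pooled_rho, 0.5)
})

test_that("independent age and SDI give null-calibrated correlation p-values", {
  set.seed(99)
  ps <- replicate(200, {
    md <- tibble::tibble(sample_id = as.character(1:25), infection = rep(0, 25),
                        age = rnorm(25, 60, 10))
    sc <- tibble::tibble(sample_id = md$sample_id, sdi = rnorm(25))
    age_sdi_correlation(md, sc, stratify = "pooled")$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 2.576 * sqrt(0.05 * 0.95 / 200) + 0.01)
  expect_gt(mean(ps), 0.4) # roughly uniform
})
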