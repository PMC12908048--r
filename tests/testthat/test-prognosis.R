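noise_data <- function(n, p, seed) {
  set.seed(seed)
  df <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(n * p), n, p)),
                                   paste0("x", seq_len(p))))
  df$y <- rbinom(n, 1, 0.45)
  while (length(unique(df$y)) < 2 || sum(df$y) < 10) df$y <- rbinom(n, 1, 0.45)
  df
}

test_that("AUC matches exhaustive pair counting and handles ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  set.seed(5)
  for (i in 1:10) {
    s <- rnorm(20)
    l <- rbinom(20, 1, 0.5)
    if (length(unique(l)) < 2) next
    # exhaustive pair-counting oracle
    pos <- s[l == 1]; neg <- s[l == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(s, l), mean(pairs))
    expect_equal(auc(s, l) + auc(-s, l), 1) # complement identity (tie-free)
  }
  expect_validation_error(auc(1:4, c(1, 1, 1, 1)), "single class")
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(6)
  s <- rnorm(50)
  l <- rbinom(50, 1, 0.4)
  expect_equal(auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("logistic fits reproduce closed-form log odds", {
  # 2x2 layout: among y=1 20 exposed/10 not; among y=0 10 exposed/20 not
  df <- tibble::tibble(y = rep(c(1, 0), each = 30),
                       x = c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20)))
  fit <- fit_logistic(df, "y", "x")
  expect_equal(fit$coefficients$estimate[2], log(4), tolerance = 1e-6)
  expect_false(fit$penalized)

  # intercept-only: logit of prevalence 37/80
  df2 <- tibble::tibble(y = rep(c(1, 0), c(37, 43)))
  fit2 <- fit_logistic(df2, "y", character())
  expect_equal(fit2$coefficients$estimate[1], log(37 / 43), tolerance = 1e-8)

  expect_validation_error(fit_logistic(dplyr::mutate(df, y = y + 1), "y", "x"),
                          "binary")
})

test_that("complete separation triggers the flagged ridge fallback", {
  df <- tibble::tibble(y = rep(c(1, 0), each = 15), x = rep(c(1, 0), each = 15))
  fit <- fit_logistic(df, "y", "x")
  expect_true(fit$penalized)
  expect_true(is.finite(fit$coefficients$estimate[2]))
  expect_gt(fit$coefficients$estimate[2], 0)
  # and the screen still selects the perfect predictor (p flagged to 0)
  df$y2 <- df$y
  sc <- univariate_screen(dplyr::bind_cols(df, noise = rnorm(30)), "y",
                          c("y2", "noise"))
  expect_true(sc$selected[sc$predictor == "y2"])
  expect_equal(sc$note[sc$predictor == "y2"], "complete separation")
})

test_that("screening keeps p < alpha, skips constants, honours boundaries", {
  df <- noise_data(120, 4, seed = 2)
  df$x_const <- 1
  sc <- univariate_screen(df, "y", c(paste0("x", 1:4), "x_const"))
  expect_equal(sc$note[sc$predictor == "x_const"], "zero variance (skipped)")
  expect_false(sc$selected[sc$predictor == "x_const"])
  expect_identical(sc$selected[1:4], sc$p_value[1:4] < 0.10)
  all_in <- univariate_screen(df, "y", paste0("x", 1:4), screen_alpha = 1)
  expect_true(all(all_in$selected))
  expect_validation_error(univariate_screen(df, "y", c("x1", "y")), "outcome")
})

test_that("pure-noise predictors are selected at about the screening rate", {
  sel <- vapply(1:400, function(i) {
    df <- noise_data(200, 1, seed = 5000 + i)
    univariate_screen(df, "y", "x1")$selected
  }, logical(1))
  band <- 2.576 * sqrt(0.10 * 0.90 / 400)
  expect_gt(mean(sel), 0.10 - band - 0.01)
  expect_lt(mean(sel), 0.10 + band + 0.01)
})

test_that("an identity resample gives zero optimism", {
  # find a seed whose first bootstrap draw is the identity permutation
  n <- 3
  seed_id <- NULL
  for (s in 1:2000) {
    ok <- strokedysbiosis:::with_seed(s, identical(sample.int(n, n, replace = TRUE), 1:3))
    if (ok) { seed_id <- s; break }
  }
  skip_if(is.null(seed_id), "no identity-resample seed found in range")
  df <- tibble::tibble(y = c(1, 0, 1), x = c(2, 1, 3))
  res <- bootstrap_optimism(df, "y", "x", n_boot = 1, seed = seed_id)
  expect_equal(res$optimism, 0)
  expect_equal(res$corrected_auc, res$apparent_auc)
})

test_that("bootstrap optimism is deterministic and self-consistent", {
  df <- noise_data(60, 3, seed = 9)
  a <- bootstrap_optimism(df, "y", paste0("x", 1:3), n_boot = 40, seed = 11)
  b <- bootstrap_optimism(df, "y", paste0("x", 1:3), n_boot = 40, seed = 11)
  expect_identical(glance(a), glance(b))
  expect_identical(a$optimism_draws, b$optimism_draws)
  expect_equal(a$corrected_auc, a$apparent_auc - a$optimism, tolerance = 1e-12)
  expect_lte(a$ci_low, a$corrected_auc + 1e-12)
  expect_gte(a$ci_high, a$corrected_auc - 1e-12)
})

test_that("optimism is positive under the null, more so with in-loop screening", {
  df <- noise_data(60, 10, seed = 21)
  cand <- paste0("x", 1:10)
  inside <- bootstrap_optimism(df, "y", cand, n_boot = 120, seed = 4)
  expect_gt(inside$optimism, 0)

  # outside-loop variant (screen once, only refit per resample): computed
  # here with the package's own fit/auc primitives as a comparison arm
  sel <- with(univariate_screen(df, "y", cand), predictor[selected])
  outside_opt <- strokedysbiosis:::with_seed(4, {
    mean(vapply(1:120, function(b) {
      repeat {
        idx <- sample.int(60, 60, replace = TRUE)
        if (length(unique(df$y[idx])) == 2) break
      }
      fit <- fit_logistic(df[idx, ], "y", sel)
      auc(predict(fit, df[idx, ]), df$y[idx]) - auc(predict(fit, df), df$y)
    }, numeric(1)))
  })
  # freezing the selection outside the loop hides selection uncertainty
  expect_gt(inside$optimism, outside_opt)
})
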