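# Cohort statistics: group comparisons (continuous and categorical),
# biomarker-outcome correlations with FDR control, and the
# platelet-to-lymphocyte ratio.

#' Platelet-to-lymphocyte ratio
#'
#' `PLR = platelets / lymphocytes`, both in cells/uL from the baseline
#' complete blood count; a simple systemic-inflammation ratio.
#'
#' @param platelets,lymphocytes Positive counts (vectorised).
#' @return Dimensionless ratio.
#' @examples
#' plr(300000, 2000) # 150
#' @export
plr <- function(platelets, lymphocytes) {
  ok <- !is.na(lymphocytes) & !is.na(platelets)
  assert_that(all(lymphocytes[ok] > 0), "lymphocytes must be > 0")
  assert_that(all(platelets[ok] > 0), "platelets must be > 0")
  platelets / lymphocytes
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input
#' range); adjusted values never exceed 1 and never fall below the raw p.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p_values) {
  assert_that(is.numeric(p_values) && !anyNA(p_values),
              "p-values must be numeric and non-missing")
  assert_that(all(p_values > 0 & p_values <= 1), "p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

summ_continuous <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
  sprintf("%.1f (%.1f); %.1f (%.1f-%.1f)", mean(x, na.rm = TRUE),
          sd(x, na.rm = TRUE), q[2], q[1], q[3])
}

compare_continuous <- function(x, y, policy) {
  normal <- function(v) {
    if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) return(FALSE)
    shapiro.test(v)$p.value >= 0.05
  }
  test <- if (policy == "auto") {
    if (normal(x) && normal(y)) "t" else "mann_whitney"
  } else {
    policy
  }
  if (test == "t") {
    ht <- t.test(x, y)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  }
  list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value)
}

compare_categorical <- function(tab, policy) {
  test <- if (policy == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) "fisher" else "chi_square"
  } else {
    policy
  }
  if (test == "fisher") {
    ht <- fisher.test(tab)
    list(test = test, statistic = NA_real_, p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(test = test, statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}

#' Two-group comparisons for cohort characteristics
#'
#' For each requested variable, compares the two groups defined by `group`
#' (a binary 0/1 column): continuous variables with Student's t-test when a
#' Shapiro-Wilk screen (at 0.05, per group) accepts normality in both groups,
#' otherwise the Mann-Whitney test; categorical variables with the chi-square
#' test (no continuity correction) unless any expected cell is below 5, in
#' which case Fisher's exact test. The policy can be overridden per call, and
#' every record states which test ran.
#'
#' @param data A data frame (e.g., cohort metadata).
#' @param vars Character vector of variable names to compare; defaults to
#'   every column except `group` and `sample_id`.
#' @param group Name of the binary grouping column (default `"infection"`).
#' @param policy `"auto"` (default) or one of `"t"`, `"mann_whitney"`,
#'   `"chi_square"`, `"fisher"` to force a test.
#' @return A tibble with one row per variable: `variable`, `kind`, `test`,
#'   `statistic`, `p_value`, and formatted group summaries (`mean (SD);
#'   median (Q1-Q3)` for continuous, `n (%)` per level for categorical).
#' @export
compare_groups <- function(data, vars = NULL, group = "infection",
                           policy = c("auto", "t", "mann_whitney",
                                      "chi_square", "fisher")) {
  policy <- match.arg(policy)
  data <- as_tibble(data)
  assert_that(group %in% names(data), "grouping column '%s' not found", group)
  g <- data[[group]]
  assert_that(length(unique(na.omit(g))) == 2, "need exactly two groups")
  vars <- vars %||% setdiff(names(data), c(group, "sample_id"))
  lev <- sort(unique(na.omit(g)), decreasing = TRUE) # 1 (case) first
  purrr::map(vars, function(v) {
    x <- data[[v]]
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]
    gg <- g[keep]
    x1 <- x[gg == lev[1]]
    x2 <- x[gg == lev[2]]
    assert_that(length(x1) > 0 && length(x2) > 0, "empty group for '%s'", v)
    if (is.numeric(x) && length(unique(x)) > 2) {
      assert_that(length(x1) >= 3 && length(x2) >= 3,
                  "fewer than 3 observations per group for '%s'", v)
      res <- compare_continuous(x1, x2,
                                if (policy %in% c("auto", "t", "mann_whitney")) policy else "auto")
      tibble(variable = v, kind = "continuous", test = res$test,
             statistic = res$statistic, p_value = res$p_value,
             summary_case = summ_continuous(x1),
             summary_control = summ_continuous(x2))
    } else {
      tab <- table(factor(gg, levels = lev), x)
      assert_that(ncol(tab) >= 2, "variable '%s' has a single level", v)
      res <- compare_categorical(tab,
                                 if (policy %in% c("auto", "chi_square", "fisher")) policy else "auto")
      fmt <- function(row) {
        paste(sprintf("%s: %d (%s%%)", colnames(tab), row,
                      format(percent(row, sum(row)))), collapse = ", ")
      }
      tibble(variable = v, kind = "categorical", test = res$test,
             statistic = res$statistic, p_value = res$p_value,
             summary_case = fmt(tab[1, ]), summary_control = fmt(tab[2, ]))
    }
  }) |> list_rbind()
}

#' Correlation between two variables
#'
#' Spearman (mid-ranks for ties, asymptotic p) or Pearson correlation on
#' pairwise-complete observations. With a binary 0/1 `y` this yields the
#' point-biserial correlation under `method = "pearson"` and its rank-based
#' analogue under `"spearman"`.
#'
#' @param x,y Numeric vectors; at least 4 pairwise-complete pairs.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble: `method`, `estimate`, `p_value`, `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  assert_that(length(x) >= 4, "need at least 4 pairwise-complete observations")
  assert_that(var(x) > 0 && var(y) > 0, "constant input")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(method = method, estimate = unname(ct$estimate),
         p_value = ct$p.value, n = length(x))
}

#' Biomarker-outcome correlation table with FDR control
#'
#' Correlates each biomarker with a binary outcome (0/1), then adjusts the
#' p-values across biomarkers by Benjamini-Hochberg.
#'
#' @param data Metadata tibble.
#' @param biomarkers Character vector of biomarker column names; defaults to
#'   the six serum biomarkers.
#' @param outcome Binary outcome column (default `"infection"`).
#' @param method Correlation method passed to [correlate()].
#' @return Tibble: `biomarker`, `method`, `r`, `p_value`, `p_adjusted`.
#' @export
biomarker_associations <- function(data,
                                   biomarkers = c("nmdar", "butyrate", "tmao",
                                                  "rankl", "ifabp", "lps"),
                                   outcome = "infection",
                                   method = "spearman") {
  data <- as_tibble(data)
  assert_that(all(biomarkers %in% names(data)),
              "biomarker column '%s' not found",
              setdiff(biomarkers, names(data))[1])
  assert_that(outcome %in% names(data), "outcome column '%s' not found", outcome)
  y <- as.numeric(data[[outcome]])
  out <- purrr::map(biomarkers, function(b) {
    cr <- correlate(data[[b]], y, method = method)
    tibble(biomarker = b, method = cr$method, r = cr$estimate,
           p_value = cr$p_value)
  }) |> list_rbind()
  mutate(out, p_adjusted = bh_fdr(pmax(.data$p_value, .Machine$double.xmin)))
}
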