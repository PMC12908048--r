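# Dysbiosis indices: the microbial dysbiosis index (MDI), the weighted
# stroke dysbiosis index (SDI), data-driven panel derivation, and the
# age-SDI correlation analysis.

panel_sums <- function(sample, panel, weighted = FALSE) {
  take <- function(side) {
    w <- panel[[side]]
    present <- names(w)[names(w) %in% names(sample)]
    a <- sample[present]
    if (weighted) sum(w[present] * a) else sum(a)
  }
  c(enriched = take("enriched"), depleted = take("depleted"))
}

#' Microbial dysbiosis index of one sample
#'
#' `MDI = log10((1 + sum of pathogenic/enriched abundances) /
#' (1 + sum of beneficial/depleted abundances))`, unweighted. For relative
#' abundances the value is bounded in `[-log10(2), log10(2)]` and is positive
#' iff the pathogenic sum exceeds the beneficial sum. Panel taxa absent from
#' the sample contribute 0.
#'
#' @param sample Named numeric vector of relative taxon abundances.
#' @param panel A [dysbiosis_panel()].
#' @return MDI scalar.
#' @examples
#' mdi(c(A = 0.04, B = 0.24), dysbiosis_panel("A", "B")) # log10(1.04/1.24)
#' @export
mdi <- function(sample, panel) {
  assert_that(is.numeric(sample) && !is.null(names(sample)),
              "sample must be a named abundance vector")
  assert_that(all(sample >= 0), "negative abundances")
  s <- panel_sums(sample, panel, weighted = FALSE)
  log10((1 + s["enriched"]) / (1 + s["depleted"]))[[1]]
}

#' Stroke dysbiosis index of one sample
#'
#' Weighted log-ratio of stroke-/infection-associated to control-associated
#' taxon abundances:
#' `SDI = log10((eps + sum(w_i * a_i, enriched)) /
#'              (eps + sum(w_j * a_j, depleted)))`.
#' With all weights 1 and `epsilon = 1` this reduces exactly to [mdi()],
#' which anchors the two indices to each other.
#'
#' @inheritParams mdi
#' @param epsilon Positive pseudocount stabilising empty panels (default 1,
#'   the same pseudocount style as the MDI).
#' @return SDI scalar.
#' @export
sdi <- function(sample, panel, epsilon = 1) {
  assert_that(is.numeric(sample) && !is.null(names(sample)),
              "sample must be a named abundance vector")
  assert_that(all(sample >= 0), "negative abundances")
  assert_that(length(epsilon) == 1 && is.finite(epsilon) && epsilon > 0,
              "epsilon must be > 0")
  s <- panel_sums(sample, panel, weighted = TRUE)
  log10((epsilon + s["enriched"]) / (epsilon + s["depleted"]))[[1]]
}

#' Per-sample dysbiosis scores for an abundance table
#'
#' Computes SDI and MDI for every sample plus `panel_coverage`, the fraction
#' of panel taxa present as columns of the table (missing panel taxa are
#' scored as abundance 0). Requires a relative-mode table: convert counts to
#' proportions first — the indices are defined on relative abundances.
#'
#' @param abundance A relative-mode `abundance_tbl`.
#' @param panel A [dysbiosis_panel()]; default [default_panel()].
#' @param epsilon Pseudocount for the SDI (default 1).
#' @return Tibble with columns `sample_id`, `sdi`, `mdi`, `panel_coverage`.
#' @export
dysbiosis_scores <- function(abundance, panel = default_panel(), epsilon = 1) {
  assert_that(ab_mode(abundance) == "relative",
              "dysbiosis indices require relative abundances, not counts")
  m <- abundance_matrix(abundance)
  panel_taxa <- c(names(panel$enriched), names(panel$depleted))
  coverage <- mean(panel_taxa %in% colnames(m))
  tibble(
    sample_id = rownames(m),
    sdi = apply(m, 1, sdi, panel = panel, epsilon = epsilon),
    mdi = apply(m, 1, mdi, panel = panel),
    panel_coverage = coverage
  )
}

#' Derive a dysbiosis panel from a labelled cohort
#'
#' Data-driven panel construction mirroring how dysbiosis indices are built
#' from case/control contrasts: each taxon is tested with a two-sided
#' Mann-Whitney test between groups, p-values are Benjamini-Hochberg
#' adjusted, and taxa with adjusted p below `alpha` are assigned to the
#' enriched or depleted list by the sign of the case-minus-control median
#' difference. Weights are the absolute median differences normalised so the
#' largest is 1.
#'
#' @param abundance An `abundance_tbl`.
#' @param labels Binary vector (1 = case/infected, 0 = control), one per
#'   sample; at least 3 samples per group.
#' @param alpha Adjusted-p threshold for inclusion (default 0.05).
#' @param level Taxonomic level recorded on the returned panel.
#' @return A `dysbiosis_panel`; errors if no taxon passes in either
#'   direction ("both panel lists empty").
#' @export
derive_panel <- function(abundance, labels, alpha = 0.05, level = "species") {
  m <- abundance_matrix(abundance)
  assert_that(length(labels) == nrow(m), "labels length does not match table")
  assert_that(all(labels %in% c(0, 1)), "labels must be coded 0/1")
  assert_that(sum(labels == 1) >= 3 && sum(labels == 0) >= 3,
              "fewer than 3 samples per group")
  assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
  case <- labels == 1
  stats_tbl <- purrr::map(colnames(m), function(tx) {
    x <- m[case, tx]
    y <- m[!case, tx]
    p <- if (var(c(x, y)) == 0) 1 else {
      suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    }
    tibble(taxon = tx, p_value = p, med_diff = median(x) - median(y))
  }) |> list_rbind() |>
    mutate(p_adjusted = bh_fdr(.data$p_value))
  hits <- filter(stats_tbl, .data$p_adjusted < alpha, .data$med_diff != 0)
  assert_that(nrow(hits) > 0 &&
                any(hits$med_diff > 0) && any(hits$med_diff < 0),
              "both panel lists empty (or one-sided): no taxa pass alpha = %g",
              alpha)
  w <- abs(hits$med_diff) / max(abs(hits$med_diff))
  names(w) <- hits$taxon
  dysbiosis_panel(
    enriched = w[hits$med_diff > 0],
    depleted = w[hits$med_diff < 0],
    level = level
  )
}

#' Age-SDI correlation, pooled and by group
#'
#' Spearman correlation between age and the stroke dysbiosis index, computed
#' for the pooled cohort and/or within infection strata. When the two groups
#' differ in both mean age and mean SDI, the pooled correlation can exceed
#' both within-group correlations (a between-group composition effect worth
#' reporting alongside the strata).
#'
#' @param metadata Metadata tibble with `sample_id`, `age`, `infection`.
#' @param scores Output of [dysbiosis_scores()] (needs `sample_id`, `sdi`).
#' @param stratify `"both"` (default), `"pooled"` or `"by_group"`.
#' @return Tibble with columns `stratum`, `n`, `rho`, `p_value`.
#' @export
age_sdi_correlation <- function(metadata, scores,
                                stratify = c("both", "pooled", "by_group")) {
  stratify <- match.arg(stratify)
  df <- inner_join(
    select(as_tibble(metadata), "sample_id", "age", "infection"),
    select(scores, "sample_id", "sdi"),
    by = "sample_id"
  )
  one <- function(sub, name) {
    assert_that(nrow(sub) >= 4, "stratum '%s' has fewer than 4 samples", name)
    assert_that(var(sub$age) > 0, "constant age vector in stratum '%s'", name)
    ct <- suppressWarnings(cor.test(sub$age, sub$sdi, method = "spearman",
                                    exact = FALSE))
    tibble(stratum = name, n = nrow(sub),
           rho = unname(ct$estimate), p_value = ct$p.value)
  }
  out <- list()
  if (stratify %in% c("both", "pooled")) out <- c(out, list(one(df, "pooled")))
  if (stratify %in% c("both", "by_group")) {
    out <- c(out,
             list(one(filter(df, .data$infection == 1), "infected"),
                  one(filter(df, .data$infection == 0), "noninfected")))
  }
  list_rbind(out)
}
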