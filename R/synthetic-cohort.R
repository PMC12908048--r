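# Synthetic cohort generator: seeded infected / non-infected stroke cohorts
# with the compositional and biomarker structure the downstream analysis
# assumes, so the whole pipeline is testable without patient data.

PATHOGENIC_TAXA <- c(
  "Klebsiella_pneumoniae", "Escherichia_coli", "Salmonella_enterica",
  "Streptococcus_anginosus", "Enterobacter_cloacae", "Proteus_mirabilis"
)
BENEFICIAL_TAXA <- c(
  "Faecalibacterium_prausnitzii", "Blautia_wexlerae", "Agathobacter_rectalis",
  "Roseburia_intestinalis", "Ruminococcus_bromii", "Lachnospira_pectinoschiza"
)

#' Default serum biomarker distribution parameters
#'
#' Group medians and quartiles (assay units) of the six serum biomarkers the
#' generator emulates: NMDAR NR2B and iFABP in ng/mL, TMAO in ng/mL, RANKL,
#' LPS in pg/mL, butyrate in ng/mL. Units are carried as opaque labels; each
#' biomarker is drawn log-normally with parameters solved from the printed
#' median and interquartile range per group.
#'
#' @return A tibble with columns `biomarker`, `group`
#'   (`infected`/`noninfected`), `median`, `q1`, `q3`.
#' @export
default_biomarker_params <- function() {
  tribble_rows <- list(
    c("nmdar",    3.99,   3.28,   9.20,   1.23,   0.82,   2.67),
    c("butyrate", 7.59,   4.16,   9.74,  13.22,  11.81,  15.56),
    c("tmao",   636.46, 569.08, 691.52, 396.22, 299.13, 478.63),
    c("rankl",    4.51,   3.92,   5.53,  43.92,   6.40,  83.09),
    c("ifabp",    4.35,   3.43,   5.57,   2.43,   1.79,   3.02),
    c("lps",    190.80,  14.01, 251.93,  83.00,  63.94, 122.00)
  )
  purrr::map(tribble_rows, function(r) {
    tibble(
      biomarker = rep(r[1], 2),
      group = c("infected", "noninfected"),
      median = as.numeric(c(r[2], r[5])),
      q1 = as.numeric(c(r[3], r[6])),
      q3 = as.numeric(c(r[4], r[7]))
    )
  }) |> list_rbind()
}

#' Default dysbiosis panel of infection-associated and commensal taxa
#'
#' Unit-weight species-level panel: enteric pathogens enriched with
#' infection (*Klebsiella pneumoniae*, *Escherichia coli*, *Salmonella
#' enterica*) versus depleted SCFA-producing commensals (*Faecalibacterium
#' prausnitzii*, *Blautia wexlerae*, *Agathobacter rectalis*).
#'
#' @return A `dysbiosis_panel`.
#' @export
default_panel <- function() {
  dysbiosis_panel(
    enriched = PATHOGENIC_TAXA[1:3],
    depleted = BENEFICIAL_TAXA[1:3],
    level = "species"
  )
}

#' Specify a synthetic cohort
#'
#' Defines the generative conditions: group sizes, community size, how many
#' taxa are shifted and by how much, biomarker distribution targets, and age
#' structure. Defaults emulate an 80-patient acute-ischemic-stroke cohort
#' with 37 infected / 43 non-infected members, pathogen enrichment and
#' SCFA-producer depletion in the infected group, and log-scale biomarker
#' shifts matching [default_biomarker_params()].
#'
#' @param n_total Total number of samples.
#' @param n_infected Number of infected samples (must be <= `n_total`).
#' @param n_taxa Number of taxa in the community.
#' @param n_pathogenic,n_beneficial Number of taxa shifted up / down in the
#'   infected group (their sum must be <= `n_taxa`).
#' @param pathogenic_fold_change Infected vs non-infected mean relative
#'   abundance ratio for pathogenic taxa (> 0).
#' @param beneficial_fold_change Same for beneficial taxa (< 1 for depletion).
#' @param biomarker_params Tibble as returned by [default_biomarker_params()].
#' @param age_params Named list with `infected = c(mean, sd)` and
#'   `noninfected = c(mean, sd)` in years.
#' @param sequencing_depth Reads per sample for the multinomial count table.
#' @param total_concentration Total Dirichlet concentration governing
#'   sample-to-sample compositional variability (smaller = noisier).
#' @param seed Integer seed; one global seed drives named substreams (taxa,
#'   biomarkers, labels, ...) so adding a variable does not perturb others.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_total = 80, n_infected = 37, n_taxa = 150,
                        n_pathogenic = 6, n_beneficial = 6,
                        pathogenic_fold_change = 4,
                        beneficial_fold_change = 0.25,
                        biomarker_params = default_biomarker_params(),
                        age_params = list(infected = c(mean = 67.2, sd = 10.4),
                                          noninfected = c(mean = 57.8, sd = 11.6)),
                        sequencing_depth = 10000,
                        total_concentration = 50,
                        seed = 1L) {
  spec <- structure(
    list(n_total = n_total, n_infected = n_infected, n_taxa = n_taxa,
         n_pathogenic = n_pathogenic, n_beneficial = n_beneficial,
         pathogenic_fold_change = pathogenic_fold_change,
         beneficial_fold_change = beneficial_fold_change,
         biomarker_params = as_tibble(biomarker_params),
         age_params = age_params,
         sequencing_depth = sequencing_depth,
         total_concentration = total_concentration,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec`.
#' @export
validate_cohort_spec <- function(spec) {
  count_ok <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x > 0
  for (f in c("n_total", "n_infected", "n_taxa", "n_pathogenic", "n_beneficial")) {
    assert_that(count_ok(spec[[f]]), "%s must be a positive integer", f)
  }
  assert_that(spec$n_infected <= spec$n_total, "n_infected exceeds n_total")
  assert_that(spec$n_pathogenic + spec$n_beneficial <= spec$n_taxa,
              "n_pathogenic + n_beneficial exceeds n_taxa")
  assert_that(spec$pathogenic_fold_change > 0, "pathogenic_fold_change must be > 0")
  assert_that(spec$beneficial_fold_change > 0, "beneficial_fold_change must be > 0")
  assert_that(spec$sequencing_depth >= 100, "sequencing_depth too small")
  assert_that(spec$total_concentration > 0, "total_concentration must be > 0")
  bp <- spec$biomarker_params
  assert_that(all(c("biomarker", "group", "median", "q1", "q3") %in% names(bp)),
              "biomarker_params lacks required columns")
  assert_that(all(bp$q1 > 0 & bp$q1 < bp$median & bp$median < bp$q3),
              "biomarker_params quartiles must satisfy 0 < q1 < median < q3")
  for (g in c("infected", "noninfected")) {
    ap <- spec$age_params[[g]]
    assert_that(!is.null(ap) && length(ap) == 2 && ap[2] > 0,
                "age_params$%s must be c(mean, sd) with sd > 0", g)
  }
  spec
}

#' Log-normal parameters from a printed median and IQR
#'
#' Solves `(mu, sigma)` of a log-normal distribution so that `exp(mu)` equals
#' the median and the model quartiles fit the printed `(q1, q3)` in the
#' least-squares sense on the log scale. With `mu` anchored at the median the
#' least-squares solution is closed-form:
#' `sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))`, which is exact when the
#' printed quartiles are symmetric on the log scale; otherwise a residual
#' quartile misfit remains (the asymmetry is split evenly).
#'
#' @param median,q1,q3 Printed median and quartiles; must satisfy
#'   `0 < q1 < median < q3`.
#' @return Named numeric vector `c(mu, sigma)`.
#' @examples
#' solve_lognormal_from_median_iqr(1, exp(-qnorm(0.75)), exp(qnorm(0.75)))
#' @export
solve_lognormal_from_median_iqr <- function(median, q1, q3) {
  assert_that(is.finite(median) && is.finite(q1) && is.finite(q3) &&
                q1 > 0 && q1 < median && median < q3,
              "quartiles must satisfy 0 < q1 < median < q3")
  c(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

#' Generate a synthetic infected / non-infected cohort
#'
#' Draws, deterministically for a fixed seed:
#' \itemize{
#' \item taxa: per-sample relative abundances from a Dirichlet distribution
#'   whose concentration vector is a log-normal community baseline; in the
#'   infected group pathogenic taxa are multiplied by
#'   `pathogenic_fold_change`, beneficial taxa by `beneficial_fold_change`,
#'   and the remaining bulk is rescaled so the total concentration matches
#'   the control group — making the expected infected/control mean
#'   relative-abundance ratio of every panel taxon exactly its fold change;
#' \item counts: a multinomial read count table at `sequencing_depth`;
#' \item biomarkers: log-normal draws with `(mu, sigma)` solved per group
#'   from the spec's median/IQR targets;
#' \item clinical covariates: age (normal per group), sex, NIHSS, platelet
#'   and lymphocyte counts;
#' \item labels: exactly `n_infected` infected samples, order shuffled under
#'   the seed.
#' }
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `abundance`
#'   (relative-mode `abundance_tbl`), `counts` (count-mode), `metadata`
#'   (tibble) and `truth` (named vector of the per-taxon group-effect
#'   multipliers used in generation).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_total = 20, n_infected = 9, seed = 7))
#' table(cohort$metadata$infection)
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  n <- spec$n_total
  nt <- spec$n_taxa
  taxa <- synthetic_taxa_names(nt, spec$n_pathogenic, spec$n_beneficial)
  pathogenic <- taxa[seq_len(spec$n_pathogenic)]
  beneficial <- taxa[spec$n_pathogenic + seq_len(spec$n_beneficial)]
  sample_ids <- sprintf("S%03d", seq_len(n))

  # infection labels: fixed group sizes, order shuffled under the seed
  infection <- with_seed(derive_seed(spec$seed, "labels"), {
    sample(c(rep(1L, spec$n_infected), rep(0L, n - spec$n_infected)))
  })

  # community baseline and group-specific concentration vectors
  baseline <- with_seed(derive_seed(spec$seed, "taxa_baseline"), {
    b <- rlnorm(nt, meanlog = 0, sdlog = 1)
    b / sum(b) * spec$total_concentration
  })
  mult <- setNames(rep(1, nt), taxa)
  mult[pathogenic] <- spec$pathogenic_fold_change
  mult[beneficial] <- spec$beneficial_fold_change
  bulk <- !(taxa %in% c(pathogenic, beneficial))
  if (any(bulk)) {
    # Cap the panel's post-fold-change concentration load at 80% of the
    # total so the bulk can always absorb the compensation; if the random
    # baseline would exceed it, shrink the panel baselines and hand the
    # freed mass to the bulk. Keeps the infected/control totals equal, so
    # the expected relative-abundance ratio of a panel taxon is exactly its
    # fold change.
    load <- sum((baseline * mult)[!bulk])
    limit <- 0.8 * spec$total_concentration
    if (load > limit) {
      baseline[!bulk] <- baseline[!bulk] * limit / load
      baseline[bulk] <- baseline[bulk] *
        (spec$total_concentration - sum(baseline[!bulk])) / sum(baseline[bulk])
    }
    alpha_inf <- baseline * mult
    need <- spec$total_concentration - sum(alpha_inf[!bulk])
    bulk_scale <- need / sum(baseline[bulk])
    alpha_inf[bulk] <- baseline[bulk] * bulk_scale
    mult[taxa[bulk]] <- bulk_scale # truth records the effective multiplier
  } else {
    alpha_inf <- baseline * mult
  }

  rel <- with_seed(derive_seed(spec$seed, "taxa_samples"), {
    t(vapply(seq_len(n), function(i) {
      a <- if (infection[i] == 1L) alpha_inf else baseline
      g <- rgamma(nt, shape = a, rate = 1)
      if (sum(g) == 0) g[which.max(a)] <- 1 # guard: all-zero gamma draw
      g / sum(g)
    }, numeric(nt)))
  })
  colnames(rel) <- taxa
  rownames(rel) <- sample_ids

  counts <- with_seed(derive_seed(spec$seed, "counts"), {
    t(apply(rel, 1, function(p) rmultinom(1, spec$sequencing_depth, p)[, 1]))
  })
  dimnames(counts) <- dimnames(rel)

  # biomarkers: log-normal per group from median/IQR targets
  bp <- spec$biomarker_params
  biomarkers <- unique(bp$biomarker)
  bm <- matrix(NA_real_, n, length(biomarkers),
               dimnames = list(sample_ids, biomarkers))
  for (b in biomarkers) {
    bm[, b] <- with_seed(derive_seed(spec$seed, paste0("biomarker_", b)), {
      draw_group_lognormal(bp[bp$biomarker == b, ], infection)
    })
  }

  age <- with_seed(derive_seed(spec$seed, "age"), {
    ifelse(infection == 1L,
           rnorm(n, spec$age_params$infected["mean"], spec$age_params$infected["sd"]),
           rnorm(n, spec$age_params$noninfected["mean"], spec$age_params$noninfected["sd"]))
  })
  sex <- with_seed(derive_seed(spec$seed, "sex"), {
    p_female <- ifelse(infection == 1L, 0.541, 0.302)
    ifelse(rbinom(n, 1, p_female) == 1, "female", "male")
  })
  nihss <- with_seed(derive_seed(spec$seed, "nihss"), {
    2L + rnbinom(n, size = 4, mu = ifelse(infection == 1L, 3.5, 2.5))
  })
  platelets <- with_seed(derive_seed(spec$seed, "platelets"), {
    pars <- solve_lognormal_from_median_iqr(275000, 230000, 330000)
    rlnorm(n, pars["mu"], pars["sigma"])
  })
  lymphocytes <- with_seed(derive_seed(spec$seed, "lymphocytes"), {
    pi_ <- solve_lognormal_from_median_iqr(1300, 1000, 1700)
    pn <- solve_lognormal_from_median_iqr(1900, 1500, 2400)
    ifelse(infection == 1L, rlnorm(n, pi_["mu"], pi_["sigma"]),
           rlnorm(n, pn["mu"], pn["sigma"]))
  })

  metadata <- bind_cols(
    tibble(sample_id = sample_ids, infection = infection,
           age = age, sex = sex, nihss = as.integer(nihss),
           platelets = platelets, lymphocytes = lymphocytes),
    as_tibble(bm)
  )

  structure(
    list(
      abundance = abundance_table(rel, mode = "relative"),
      counts = abundance_table(counts, mode = "count"),
      metadata = validate_metadata(metadata),
      truth = mult,
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

draw_group_lognormal <- function(params2, infection) {
  gi <- params2[params2$group == "infected", ]
  gn <- params2[params2$group == "noninfected", ]
  pi_ <- solve_lognormal_from_median_iqr(gi$median, gi$q1, gi$q3)
  pn <- solve_lognormal_from_median_iqr(gn$median, gn$q1, gn$q3)
  n <- length(infection)
  ifelse(infection == 1L, rlnorm(n, pi_["mu"], pi_["sigma"]),
         rlnorm(n, pn["mu"], pn["sigma"]))
}

synthetic_taxa_names <- function(n_taxa, n_pathogenic, n_beneficial) {
  path <- c(PATHOGENIC_TAXA, sprintf("Pathogen_sp%02d", seq_len(max(0, n_pathogenic - length(PATHOGENIC_TAXA)))))[seq_len(n_pathogenic)]
  ben <- c(BENEFICIAL_TAXA, sprintf("Commensal_sp%02d", seq_len(max(0, n_beneficial - length(BENEFICIAL_TAXA)))))[seq_len(n_beneficial)]
  rest <- sprintf("Taxon_%03d", seq_len(n_taxa - n_pathogenic - n_beneficial))
  c(path, ben, rest)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$spec$n_total, "samples (",
      sum(x$metadata$infection == 1), "infected ),", x$spec$n_taxa, "taxa\n")
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_total, "samples (", x$n_infected, "infected ),",
      x$n_taxa, "taxa; fold changes", x$pathogenic_fold_change, "/",
      x$beneficial_fold_change, "; seed", x$seed, "\n")
  invisible(x)
}
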