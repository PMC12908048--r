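# End-to-end orchestration: one seeded configuration drives synthetic
# generation (or file input) through diversity, dysbiosis scoring, cohort
# statistics, prognosis and network stages to a reproducible output bundle.

PIPELINE_STAGES <- c("alpha", "beta", "indices", "stats", "prognosis", "network")

#' Pipeline run configuration
#'
#' Exactly one of `input` (paths to an abundance TSV + metadata CSV, with
#' optional count TSV and panel JSON) or `synthetic` (arguments for
#' [cohort_spec()]) must be given. Thresholds default to the analysis
#' conventions: univariate screen at p < 0.10, BH-FDR at 0.05, 999
#' permutations, 1000 bootstrap resamples. One global seed drives per-stage
#' substreams (derived by stage name), so toggling a stage does not perturb
#' another stage's draws.
#'
#' @param input Optional list with elements `abundance`, `metadata` and
#'   optionally `counts`, `panel` (file paths).
#' @param synthetic Optional list of [cohort_spec()] arguments.
#' @param stages Character subset of
#'   `c("alpha", "beta", "indices", "stats", "prognosis", "network")`.
#' @param screen_alpha,fdr_alpha,n_perm,n_boot Analysis thresholds.
#' @param seed Global integer seed.
#' @param out_dir Output directory (created if missing).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       stages = PIPELINE_STAGES,
                       screen_alpha = 0.10, fdr_alpha = 0.05,
                       n_perm = 999, n_boot = 1000,
                       seed = 1L, out_dir = tempfile("strokedysbiosis_run_")) {
  assert_that(xor(is.null(input), is.null(synthetic)),
              "exactly one of 'input' and 'synthetic' must be given")
  if (!is.null(input)) {
    assert_that(all(c("abundance", "metadata") %in% names(input)),
                "input must name 'abundance' and 'metadata' paths")
  }
  assert_that(all(stages %in% PIPELINE_STAGES), "unknown stage '%s'",
              setdiff(stages, PIPELINE_STAGES)[1])
  assert_that(screen_alpha > 0 && screen_alpha <= 1, "screen_alpha out of range")
  assert_that(fdr_alpha > 0 && fdr_alpha <= 1, "fdr_alpha out of range")
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  assert_that(n_boot >= 1, "n_boot must be >= 1")
  structure(
    list(input = input, synthetic = synthetic, stages = stages,
         screen_alpha = screen_alpha, fdr_alpha = fdr_alpha,
         n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path Path to a YAML file whose top-level keys are `run_config()`
#'   arguments.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  clean <- config[setdiff(names(config), "out_dir")]
  yaml::write_yaml(clean, tmp)
  unname(tools::md5sum(tmp))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

stage_error <- function(stage, e) {
  abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
        class = "strokedysbiosis_stage_error", parent = e)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (alpha diversity, beta diversity,
#' dysbiosis indices, cohort statistics, prognosis, co-occurrence networks),
#' writing per-stage plain-text outputs plus a `manifest.json` recording the
#' package version, a configuration hash, the seed and every output file.
#' Re-running the same configuration reproduces byte-identical numeric
#' outputs. Any stage validation error aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `manifest` (as written), `results`
#'   (per-stage in-memory results) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- if (!is.null(config$synthetic)) {
    spec <- do.call(cohort_spec, modifyList(list(seed = config$seed),
                                            config$synthetic))
    generate_cohort(spec)
  } else {
    list(
      abundance = read_abundance(config$input$abundance, mode = "relative"),
      counts = if (!is.null(config$input$counts)) {
        read_abundance(config$input$counts, mode = "count")
      },
      metadata = read_metadata(config$input$metadata),
      panel = if (!is.null(config$input$panel)) read_panel(config$input$panel)
    )
  }
  panel <- cohort$panel %||% default_panel()
  md <- cohort$metadata
  infection <- md$infection
  results <- list()
  manifest_files <- list()
  out <- function(name) file.path(config$out_dir, name)
  log_line <- function(...) {
    cat(sprintf("stage=%s %s\n", ...), file = out("run.log"), append = TRUE)
  }

  for (stage in PIPELINE_STAGES) {
    if (!(stage %in% config$stages)) next
    sseed <- derive_seed(config$seed, paste0("stage_", stage))
    files <- tryCatch(
      switch(stage,
        alpha = {
          tbl <- alpha_diversity(cohort$counts %||% cohort$abundance)
          readr::write_csv(tbl, out("alpha_diversity.csv"), progress = FALSE)
          tests <- compare_groups(
            inner_join(tbl, select(md, "sample_id", "infection"), by = "sample_id"),
            vars = setdiff(names(tbl), "sample_id")
          )
          write_json_out(tests, out("alpha_tests.json"))
          results$alpha <- list(indices = tbl, tests = tests)
          c("alpha_diversity.csv", "alpha_tests.json")
        },
        beta = {
          d <- bray_curtis(cohort$abundance)
          write_distance(d, out("bray_curtis.tsv"))
          ord <- pcoa(d, k = 2)
          readr::write_csv(ord$coordinates, out("pcoa.csv"), progress = FALSE)
          pmv <- permanova(d, infection, n_perm = config$n_perm, seed = sseed)
          bdp <- betadisper_test(d, infection, n_perm = config$n_perm,
                                 seed = derive_seed(sseed, "betadisper"))
          write_json_out(list(permanova = tidy(pmv), betadisper = tidy(bdp)),
                         out("beta_tests.json"))
          results$beta <- list(distance = d, ordination = ord,
                                permanova = pmv, betadisper = bdp)
          c("bray_curtis.tsv", "pcoa.csv", "beta_tests.json")
        },
        indices = {
          scores <- dysbiosis_scores(cohort$abundance, panel)
          readr::write_csv(scores, out("dysbiosis_indices.csv"), progress = FALSE)
          contrast <- compare_groups(
            inner_join(scores, select(md, "sample_id", "infection"), by = "sample_id"),
            vars = c("sdi", "mdi")
          )
          age_cor <- if ("age" %in% names(md)) {
            age_sdi_correlation(md, scores)
          }
          write_json_out(list(group_contrast = contrast, age_sdi = age_cor),
                         out("index_tests.json"))
          results$indices <- list(scores = scores, contrast = contrast,
                                   age_sdi = age_cor)
          c("dysbiosis_indices.csv", "index_tests.json")
        },
        stats = {
          md_plr <- mutate(md, plr = plr(.data$platelets, .data$lymphocytes))
          clin <- intersect(c("age", "sex", "nihss", "plr", "nmdar", "butyrate",
                              "tmao", "rankl", "ifabp", "lps"), names(md_plr))
          comp <- compare_groups(md_plr, vars = clin)
          readr::write_csv(comp, out("group_comparisons.csv"), progress = FALSE)
          assoc <- biomarker_associations(md_plr)
          readr::write_csv(assoc, out("biomarker_correlations.csv"), progress = FALSE)
          results$stats <- list(comparisons = comp, associations = assoc,
                                 metadata = md_plr)
          c("group_comparisons.csv", "biomarker_correlations.csv")
        },
        prognosis = {
          df <- mutate(md, plr = plr(.data$platelets, .data$lymphocytes))
          if (!is.null(results$indices)) {
            df <- inner_join(df, results$indices$scores[c("sample_id", "sdi", "mdi")],
                             by = "sample_id")
          }
          candidates <- intersect(c("nmdar", "butyrate", "tmao", "rankl",
                                    "ifabp", "lps", "plr", "nihss", "age",
                                    "sdi", "mdi"), names(df))
          pr <- bootstrap_optimism(df, "infection", candidates,
                                   screen_alpha = config$screen_alpha,
                                   n_boot = config$n_boot, seed = sseed)
          write_json_out(list(summary = glance(pr), selected = pr$selected,
                              coefficients = pr$coefficients),
                         out("prognosis.json"))
          readr::write_csv(pr$roc, out("roc_points.csv"), progress = FALSE)
          results$prognosis <- pr
          c("prognosis.json", "roc_points.csv")
        },
        network = {
          nets <- list(
            infected = build_network(cohort$abundance, infection == 1,
                                     fdr_alpha = config$fdr_alpha),
            noninfected = build_network(cohort$abundance, infection == 0,
                                        fdr_alpha = config$fdr_alpha)
          )
          for (gname in names(nets)) {
            readr::write_tsv(nets[[gname]]$edges,
                             out(sprintf("network_edges_%s.tsv", gname)),
                             progress = FALSE)
          }
          summaries <- purrr::map(nets, network_summary) |>
            list_rbind(names_to = "group")
          write_json_out(summaries, out("network_summary.json"))
          results$network <- list(networks = nets, summaries = summaries)
          c("network_edges_infected.tsv", "network_edges_noninfected.tsv",
            "network_summary.json")
        }
      ),
      error = function(e) stage_error(stage, e)
    )
    manifest_files[[stage]] <- files
    log_line(stage, sprintf("seed=%d files=%d", sseed, length(files)))
  }

  manifest <- list(
    package = "strokedysbiosis",
    version = as.character(packageVersion("strokedysbiosis")),
    config_hash = config_hash(config),
    seed = config$seed,
    stages = manifest_files
  )
  write_json_out(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(list(manifest = manifest, results = results,
                 out_dir = config$out_dir))
}
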