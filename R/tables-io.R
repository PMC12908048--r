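# Tabular artifacts: abundance tables, cohort metadata, dysbiosis panels,
# distance matrices — constructors, schema validation and plain-text IO.
#
# Orientation is fixed throughout: samples in rows, taxa in columns.

#' Construct a validated abundance table
#'
#' An abundance table is a tibble whose first column is `sample_id` and whose
#' remaining columns are numeric taxon abundances, tagged with a `mode`:
#' `"relative"` (rows sum to 1) or `"count"` (non-negative integers).
#'
#' @param x A data frame with a `sample_id` column (or a numeric matrix with
#'   rownames taken as sample ids).
#' @param mode `"relative"` or `"count"`.
#' @param renorm_tol Relative-mode rows whose sum deviates from 1 by at most
#'   this tolerance are renormalized; larger deviations are an error. Default
#'   1e-3, absorbing rounding in exported tables.
#' @return A tibble of class `abundance_tbl` with attribute `ab_mode`.
#' @examples
#' abundance_table(
#'   tibble::tibble(sample_id = c("a", "b"), t1 = c(0.6, 0.5), t2 = c(0.4, 0.5)),
#'   mode = "relative"
#' )
#' @export
abundance_table <- function(x, mode = c("relative", "count"), renorm_tol = 1e-3) {
  mode <- match.arg(mode)
  if (is.matrix(x)) {
    ids <- rownames(x) %||% sprintf("S%03d", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- sprintf("Taxon_%03d", seq_len(ncol(x)))
    x <- bind_cols(tibble(sample_id = ids), as_tibble(x))
  }
  x <- as_tibble(x, .name_repair = "minimal")
  assert_that(nrow(x) > 0 && ncol(x) > 1, "abundance table is empty")
  assert_that(identical(names(x)[1], "sample_id"), "first column must be sample_id")
  taxa <- names(x)[-1]
  assert_that(!anyDuplicated(taxa), "duplicate taxon ids")
  x <- as_tibble(x)
  x$sample_id <- as.character(x$sample_id)
  assert_that(!anyDuplicated(x$sample_id), "duplicate sample ids")
  m <- as.matrix(x[taxa])
  assert_that(is.numeric(m) && !anyNA(m), "non-numeric or missing abundance cells")
  assert_that(all(m >= 0), "negative abundance values")
  if (mode == "relative") {
    rs <- rowSums(m)
    assert_that(
      all(abs(rs - 1) <= renorm_tol),
      "row sum out of tolerance: sample '%s' sums to %.6g",
      x$sample_id[which.max(abs(rs - 1))], rs[which.max(abs(rs - 1))]
    )
    m <- m / rs
    x[taxa] <- as_tibble(m)
  } else {
    assert_that(
      all(abs(m - round(m)) < 1e-8),
      "non-integer count for taxon '%s'",
      taxa[which(colSums(abs(m - round(m)) >= 1e-8) > 0)[1]]
    )
    x[taxa] <- as_tibble(round(m))
  }
  structure(x, ab_mode = mode, class = c("abundance_tbl", class(x)))
}

#' @rdname abundance_table
#' @export
ab_mode <- function(x) attr(x, "ab_mode") %||% "relative"

#' Extract the numeric sample-by-taxon matrix of an abundance table
#'
#' @param x An `abundance_tbl`.
#' @return Numeric matrix with sample ids as rownames.
#' @export
abundance_matrix <- function(x) {
  taxa <- setdiff(names(x), "sample_id")
  m <- as.matrix(x[taxa])
  rownames(m) <- x$sample_id
  m
}

#' Read / write an abundance table (TSV)
#'
#' The on-disk format is UTF-8 tab-separated text with a header row: the first
#' column holds sample ids, remaining columns one taxon each.
#'
#' @param path File path.
#' @param mode `"relative"` or `"count"`.
#' @inheritParams abundance_table
#' @return `read_abundance()` returns an `abundance_tbl`; `write_abundance()`
#'   returns `path` invisibly.
#' @export
read_abundance <- function(path, mode = c("relative", "count"), renorm_tol = 1e-3) {
  mode <- match.arg(mode)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(nrow(raw) > 0 && ncol(raw) > 1, "empty abundance table: %s", path)
  names(raw)[1] <- "sample_id"
  vals <- raw[-1]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  assert_that(length(bad) == 0, "non-numeric cells in column '%s'", bad[1])
  abundance_table(raw, mode = mode, renorm_tol = renorm_tol)
}

#' @rdname read_abundance
#' @param x An `abundance_tbl`.
#' @export
write_abundance <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(path)
}

#' Read / write cohort metadata (CSV)
#'
#' Metadata holds one row per sample with a mandatory binary `infection`
#' column (0/1); conventional columns are `age`, `sex` (`male`/`female`),
#' `nihss`, `platelets`, `lymphocytes` (cells/uL) and the serum biomarkers
#' (`nmdar`, `butyrate`, `tmao`, `rankl`, `ifabp`, `lps`). Unknown columns are
#' preserved as extras; missing biomarker values are allowed and propagate as
#' `NA` (handled pairwise-complete downstream).
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_metadata <- function(path) {
  md <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param md A metadata data frame.
#' @export
write_metadata <- function(md, path) {
  readr::write_csv(md, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_metadata
#' @export
validate_metadata <- function(md) {
  md <- as_tibble(md)
  assert_that("infection" %in% names(md), "metadata lacks an 'infection' column")
  assert_that(!anyNA(md$infection), "missing infection label")
  assert_that(all(md$infection %in% c(0, 1)), "infection must be coded 0/1")
  if ("sample_id" %in% names(md)) {
    md$sample_id <- as.character(md$sample_id)
    assert_that(!anyDuplicated(md$sample_id), "duplicate sample ids in metadata")
  }
  for (col in c("platelets", "lymphocytes")) {
    if (col %in% names(md)) {
      v <- md[[col]]
      assert_that(all(v[!is.na(v)] > 0), "%s must be > 0 when present", col)
    }
  }
  if ("sex" %in% names(md)) {
    v <- md$sex
    assert_that(all(v[!is.na(v)] %in% c("male", "female")),
                "sex must be 'male' or 'female'")
  }
  md
}

#' Construct a dysbiosis panel
#'
#' A panel names the taxa used by the dysbiosis indices: `enriched` taxa
#' (stroke-/infection-associated, positively weighted) and `depleted` taxa
#' (control-associated SCFA producers and other commensals, negatively
#' weighted). Weights default to 1 and must be positive; the two lists must
#' be disjoint and non-empty.
#'
#' @param enriched,depleted Either a character vector of taxon ids (weights
#'   default to 1) or a named numeric vector of positive weights.
#' @param level Taxonomic level the ids refer to, `"species"` or `"genus"`
#'   (taxa are matched by exact id; no taxonomy-aware collapsing).
#' @return A list of class `dysbiosis_panel`.
#' @examples
#' dysbiosis_panel(
#'   enriched = c("Klebsiella_pneumoniae", "Escherichia_coli"),
#'   depleted = c(Faecalibacterium_prausnitzii = 1)
#' )
#' @export
dysbiosis_panel <- function(enriched, depleted, level = c("species", "genus")) {
  level <- match.arg(level)
  as_weights <- function(x, side) {
    if (is.character(x)) x <- setNames(rep(1, length(x)), x)
    assert_that(is.numeric(x) && !is.null(names(x)) && all(nzchar(names(x))),
                "%s panel must be taxon ids or a named weight vector", side)
    assert_that(length(x) > 0, "%s panel list is empty", side)
    assert_that(all(x > 0), "%s panel weights must be positive", side)
    assert_that(!anyDuplicated(names(x)), "duplicate taxon in %s panel", side)
    x
  }
  enriched <- as_weights(enriched, "enriched")
  depleted <- as_weights(depleted, "depleted")
  overlap <- intersect(names(enriched), names(depleted))
  assert_that(length(overlap) == 0, "overlapping panel: taxon '%s' in both lists",
              overlap[1])
  structure(list(enriched = enriched, depleted = depleted, level = level),
            class = "dysbiosis_panel")
}

#' Read / write a dysbiosis panel (JSON)
#'
#' Format: `{"level": "species", "enriched": {taxon: weight, ...},
#' "depleted": {...}}`. Either list may instead be a plain array of taxon
#' ids, in which case weights default to 1.
#'
#' @param path File path.
#' @return `read_panel()` returns a `dysbiosis_panel`.
#' @export
read_panel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(all(c("enriched", "depleted") %in% names(raw)),
              "panel JSON must contain 'enriched' and 'depleted'")
  as_side <- function(x) {
    if (is.list(x)) x <- unlist(x)
    if (is.character(x) && is.null(names(x))) return(x)
    x
  }
  dysbiosis_panel(as_side(raw$enriched), as_side(raw$depleted),
                  level = raw$level %||% "species")
}

#' @rdname read_panel
#' @param panel A `dysbiosis_panel`.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(
    list(level = panel$level,
         enriched = as.list(panel$enriched),
         depleted = as.list(panel$depleted)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
print.dysbiosis_panel <- function(x, ...) {
  cat("<dysbiosis_panel> level:", x$level, "\n")
  cat("  enriched:", paste(names(x$enriched), collapse = ", "), "\n")
  cat("  depleted:", paste(names(x$depleted), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a distance matrix (square TSV)
#'
#' Square tab-separated layout with sample ids both as header row and first
#' column.
#'
#' @param path File path.
#' @return `read_distance()` returns a [stats::dist] with sample-id labels.
#' @export
read_distance <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[-1])
  rownames(m) <- ids
  assert_that(identical(colnames(m), ids), "distance matrix ids do not match")
  assert_that(all(is.finite(m)), "non-finite distances")
  assert_that(max(abs(m - t(m))) < 1e-12, "distance matrix is not symmetric")
  assert_that(all(diag(m) == 0), "distance matrix diagonal must be zero")
  stats::as.dist(m)
}

#' @rdname read_distance
#' @param d A `dist` or symmetric matrix with labels.
#' @export
write_distance <- function(d, path) {
  m <- as.matrix(d)
  out <- bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
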