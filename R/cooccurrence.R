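# Microbial co-occurrence networks: pairwise taxon correlations within a
# sample group, FDR-controlled edge selection and graph summaries.

#' Build a co-occurrence network for a sample group
#'
#' Keeps taxa present (abundance > 0) in at least `prevalence_min` of the
#' group's samples, computes all pairwise correlations (Spearman by default,
#' asymptotic t p-values), adjusts p across pairs by Benjamini-Hochberg, and
#' draws an edge where `|r| >= r_min` and adjusted p < `fdr_alpha`. Taxa with
#' no surviving edge are dropped from the node set by default (set
#' `keep_isolated = TRUE` to retain them).
#'
#' @param abundance An `abundance_tbl`.
#' @param samples Optional character vector of sample ids (or logical mask)
#'   selecting the group; default all samples.
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @param prevalence_min Minimum within-group prevalence for a taxon to be
#'   tested (default 0.2).
#' @param r_min Absolute-correlation threshold for an edge, in \[0, 1\]
#'   (default 0.6).
#' @param fdr_alpha BH-adjusted significance threshold for an edge
#'   (default 0.05).
#' @param keep_isolated Keep prevalence-passing taxa without edges as nodes.
#' @return Object of class `co_network`: `nodes` (character), `edges`
#'   (tibble `taxon_a`, `taxon_b`, `r`, `p_value`, `p_adjusted`), `params`,
#'   `n_samples`, `n_tested_pairs`.
#' @export
build_network <- function(abundance, samples = NULL,
                          method = c("spearman", "pearson"),
                          prevalence_min = 0.2, r_min = 0.6,
                          fdr_alpha = 0.05, keep_isolated = FALSE) {
  method <- match.arg(method)
  assert_that(r_min >= 0 && r_min <= 1, "r_min must lie in [0, 1]")
  assert_that(prevalence_min >= 0 && prevalence_min <= 1,
              "prevalence_min must lie in [0, 1]")
  assert_that(fdr_alpha > 0 && fdr_alpha <= 1, "fdr_alpha must lie in (0, 1]")
  m <- if (is.matrix(abundance)) abundance else abundance_matrix(abundance)
  if (is.null(colnames(m))) colnames(m) <- sprintf("T%03d", seq_len(ncol(m)))
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  n <- nrow(m)
  assert_that(n >= 5, "group too small: need at least 5 samples")
  prev <- colMeans(m > 0)
  keep <- names(prev)[prev >= prevalence_min]
  params <- list(method = method, prevalence_min = prevalence_min,
                 r_min = r_min, fdr_alpha = fdr_alpha)
  empty <- tibble(taxon_a = character(), taxon_b = character(),
                  r = numeric(), p_value = numeric(), p_adjusted = numeric())
  if (length(keep) < 2) {
    return(structure(list(nodes = if (keep_isolated) keep else character(),
                          edges = empty, params = params, n_samples = n,
                          n_tested_pairs = 0L),
                     class = "co_network"))
  }
  sub <- m[, keep, drop = FALSE]
  cm <- suppressWarnings(cor(sub, method = method))
  cm[!is.finite(cm)] <- 0 # constant taxa correlate with nothing
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  # asymptotic t approximation (mid-ranks for Spearman ties), |r| = 1 -> p = 0
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(abs(r) >= 1, 0, 2 * pt(tt, df = n - 2, lower.tail = FALSE))
  p_adj <- p.adjust(p, method = "BH")
  sel <- abs(r) >= r_min & p_adj < fdr_alpha
  edges <- tibble(
    taxon_a = keep[ut[sel, 1]], taxon_b = keep[ut[sel, 2]],
    r = r[sel], p_value = p[sel], p_adjusted = p_adj[sel]
  ) |>
    mutate(swap = .data$taxon_a > .data$taxon_b,
           a = ifelse(.data$swap, .data$taxon_b, .data$taxon_a),
           b = ifelse(.data$swap, .data$taxon_a, .data$taxon_b)) |>
    transmute(taxon_a = .data$a, taxon_b = .data$b, r = .data$r,
              p_value = .data$p_value, p_adjusted = .data$p_adjusted) |>
    arrange(.data$taxon_a, .data$taxon_b)
  nodes <- if (keep_isolated) keep else sort(unique(c(edges$taxon_a, edges$taxon_b)))
  structure(list(nodes = nodes, edges = edges, params = params,
                 n_samples = n, n_tested_pairs = length(r)),
            class = "co_network")
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[c("taxon_a", "taxon_b")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}

#' Summarise a co-occurrence network
#'
#' @param net A `co_network` from [build_network()].
#' @return One-row tibble: `n_nodes`, `n_edges`, `mean_degree`, `density`,
#'   `n_components` (all zero for an empty network).
#' @export
network_summary <- function(net) {
  if (length(net$nodes) == 0) {
    return(tibble(n_nodes = 0L, n_edges = 0L, mean_degree = 0,
                  density = 0, n_components = 0L))
  }
  g <- as_igraph(net)
  tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    mean_degree = mean(igraph::degree(g)),
    density = igraph::edge_density(g),
    n_components = igraph::components(g)$no
  )
}

#' @export
print.co_network <- function(x, ...) {
  cat("<co_network>", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(%s, prevalence >= %.2g, |r| >= %.2g, FDR < %.2g; n = %d)\n",
              x$params$method, x$params$prevalence_min, x$params$r_min,
              x$params$fdr_alpha, x$n_samples))
  invisible(x)
}

#' @export
tidy.co_network <- function(x, ...) x$edges

#' @export
glance.co_network <- function(x, ...) network_summary(x)
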