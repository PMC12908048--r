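# Beta diversity: Bray-Curtis dissimilarity, principal-coordinates analysis,
# PERMANOVA group-separation test and a BETADISPER-style test for
# homogeneity of multivariate dispersions.

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `BC(x, y) = sum(|x - y|) / sum(x + y)`; for relative abundances the value
#' lies in \[0, 1\], 0 iff the profiles are identical and 1 iff their
#' supports are disjoint.
#'
#' @param abundance An `abundance_tbl` or non-negative numeric matrix
#'   (samples in rows); every row must have at least one positive entry.
#' @return A [stats::dist] with sample-id labels.
#' @export
bray_curtis <- function(abundance) {
  m <- if (is.matrix(abundance)) abundance else abundance_matrix(abundance)
  assert_that(all(m >= 0), "negative abundances")
  rs <- rowSums(m)
  assert_that(all(rs > 0), "all-zero row: sample '%s'",
              (rownames(m) %||% seq_len(nrow(m)))[which(rs == 0)[1]])
  num <- as.matrix(dist(m, method = "manhattan"))
  den <- outer(rs, rs, "+")
  stats::as.dist(num / den)
}

# Gower-centred matrix B = -0.5 * J D^2 J underlying PCoA.
gower_center <- function(d) {
  m <- as.matrix(d)
  a <- -0.5 * m^2
  rm_ <- rowMeans(a)
  a - outer(rm_, rep(1, ncol(a))) - outer(rep(1, nrow(a)), colMeans(a)) + mean(a)
}

#' Principal-coordinates analysis (PCoA)
#'
#' Eigendecomposition of the double-centred squared-distance (Gower) matrix.
#' All eigenvalues are reported, including negative ones arising from
#' non-Euclidean dissimilarities (they are never silently dropped);
#' coordinates are returned for the leading `k` positive axes, scaled by the
#' square root of their eigenvalues so that full-rank Euclidean input is
#' reproduced exactly.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param k Number of axes to return (`1 <= k < n`).
#' @return A list of class `pcoa_ordination`: `coordinates` (tibble with
#'   `sample_id` and `Axis1..Axisk`), `eigenvalues` (all, descending),
#'   `proportion_explained` (per returned axis, relative to the positive
#'   eigenvalue total).
#' @export
pcoa <- function(d, k = 2) {
  m <- as.matrix(d)
  n <- nrow(m)
  assert_that(k >= 1 && k < n, "k must satisfy 1 <= k < n")
  eg <- eigen(gower_center(m), symmetric = TRUE)
  values <- eg$values
  tol <- max(abs(values), 0) * 1e-10
  coords <- matrix(0, n, k)
  pos <- which(values > tol)
  use <- head(pos, k)
  if (length(use) > 0) {
    coords[, seq_along(use)] <-
      eg$vectors[, use, drop = FALSE] %*% diag(sqrt(values[use]), length(use))
  }
  colnames(coords) <- paste0("Axis", seq_len(k))
  pos_total <- sum(values[values > tol])
  prop <- if (pos_total > 0) {
    vapply(seq_len(k), function(j) {
      if (j <= length(use)) values[use[j]] / pos_total else 0
    }, numeric(1))
  } else {
    rep(0, k)
  }
  ids <- rownames(m) %||% sprintf("S%03d", seq_len(n))
  structure(
    list(
      coordinates = bind_cols(tibble(sample_id = ids), as_tibble(coords)),
      eigenvalues = values,
      proportion_explained = prop
    ),
    class = "pcoa_ordination"
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  k <- ncol(x$coordinates) - 1
  cat("<pcoa_ordination>", nrow(x$coordinates), "samples,", k, "axes;",
      "first-axis variance", sprintf("%.1f%%", 100 * x$proportion_explained[1]), "\n")
  if (any(x$eigenvalues < 0)) {
    cat("  (negative eigenvalues present: min", format(min(x$eigenvalues)), ")\n")
  }
  invisible(x)
}

# ---- permutation-test machinery ------------------------------------------

check_perm_groups <- function(labels, n, min_size = 2) {
  assert_that(length(labels) == n, "labels length does not match distance matrix")
  labels <- as.factor(labels)
  assert_that(nlevels(labels) >= 2, "need at least 2 groups (labels constant)")
  sizes <- table(labels)
  assert_that(all(sizes >= min_size), "group '%s' has fewer than %d samples",
              names(sizes)[which(sizes < min_size)[1]], min_size)
  labels
}

# distance-based pseudo-F decomposition for one grouping
permanova_stats <- function(D2, labels) {
  n <- nrow(D2)
  lev <- levels(labels)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (l in lev) {
    idx <- which(labels == l)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  k <- length(lev)
  f <- if (ss_total <= 0) {
    0
  } else if (ss_within <= 0) {
    Inf
  } else {
    (ss_between / (k - 1)) / (ss_within / (n - k))
  }
  list(f = f, r2 = if (ss_total > 0) ss_between / ss_total else 0)
}

# all distinct label assignments preserving group sizes (groups labelled)
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  lev <- names(sizes)
  rec <- function(remaining, sizes_left) {
    if (length(sizes_left) == 1) {
      return(list(setNames(list(remaining), NULL)))
    }
    out <- list()
    first <- remaining[1] # fix the first remaining index to kill nothing: keep all labelled assignments
    picks <- combn(remaining, sizes_left[1], simplify = FALSE)
    for (p in picks) {
      rest <- rec(setdiff(remaining, p), sizes_left[-1])
      out <- c(out, lapply(rest, function(r) c(list(p), r)))
    }
    out
  }
  parts <- rec(seq_len(n), as.integer(sizes))
  lapply(parts, function(groups) {
    lab <- character(n)
    for (i in seq_along(groups)) lab[groups[[i]]] <- lev[i]
    factor(lab, levels = lev)
  })
}

n_distinct_assignments <- function(sizes) {
  exp(lfactorial(sum(sizes)) - sum(lfactorial(sizes)))
}

perm_test_result <- function(method, statistic, r_squared, p_value,
                             n_permutations, seed, exact, extra = list()) {
  structure(
    c(list(method = method, statistic = statistic, r_squared = r_squared,
           p_value = p_value, n_permutations = n_permutations,
           seed = seed, exact = exact), extra),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test>", x$method, "\n")
  cat(sprintf("  statistic = %.4g, R2 = %.4g, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$r_squared, x$p_value,
              if (x$exact) "exact enumeration" else "Monte Carlo",
              x$n_permutations))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, r_squared = x$r_squared,
         p_value = x$p_value, n_permutations = x$n_permutations,
         exact = x$exact)
}

#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' PERMANOVA: one-factor permutational multivariate ANOVA on a distance matrix
#'
#' Pseudo-F from distance sums of squares: with
#' `SS_total = sum(d_ij^2)/n` over pairs and
#' `SS_within = sum_g sum(d_ij^2 in g)/n_g`,
#' `F = (SS_between/(k-1)) / (SS_within/(n-k))` and
#' `R^2 = SS_between / SS_total`. Significance is assessed by permuting group
#' labels (unrestricted, one factor). When the number of distinct label
#' assignments is at most `exact_limit` the full enumeration is used and the
#' p-value is exact; otherwise `n_perm` Monte-Carlo permutations with the
#' add-one convention `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` (ties
#' count toward p, and p is never 0).
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param labels Group labels, one per sample; at least 2 groups of size >= 2.
#' @param n_perm Number of Monte-Carlo permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @param exact_limit Enumerate exhaustively when the distinct assignments
#'   are no more than this (default 10000).
#' @return A `perm_test` with fields `statistic` (pseudo-F), `r_squared`,
#'   `p_value`, `n_permutations`, `exact`.
#' @examples
#' d <- dist(c(0, 1, 10, 11))
#' permanova(d, c("a", "a", "b", "b")) # exact: F = 200, p = 1/3
#' @export
permanova <- function(d, labels, n_perm = 999, seed = NULL, exact_limit = 10000) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  labels <- check_perm_groups(labels, n)
  obs <- permanova_stats(D2, labels)
  sizes <- table(labels)
  if (all(D2 == 0)) { # degenerate: all samples identical
    return(perm_test_result("PERMANOVA", 0, 0, 1, 0L, seed, TRUE))
  }
  f_tol <- 1e-10 * max(1, abs(obs$f[is.finite(obs$f)]), na.rm = TRUE)
  if (n_distinct_assignments(sizes) <= exact_limit) {
    perms <- enumerate_assignments(sizes)
    f_all <- vapply(perms, function(l) permanova_stats(D2, l)$f, numeric(1))
    p <- mean(f_all >= obs$f - f_tol)
    return(perm_test_result("PERMANOVA", obs$f, obs$r2, p,
                            length(perms), seed, TRUE))
  }
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      permanova_stats(D2, sample(labels))$f
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= obs$f - f_tol)) / (1 + n_perm)
  perm_test_result("PERMANOVA", obs$f, obs$r2, p, n_perm, seed, FALSE)
}

# ---- dispersion homogeneity ----------------------------------------------

# geometric (spatial) median by Weiszfeld iteration; rs2 = rowSums(X^2)
# precomputed so per-iteration distances reduce to one BLAS product
spatial_median <- function(X, rs2 = rowSums(X^2), tol = 1e-7, max_iter = 100) {
  if (nrow(X) == 1) return(X[1, ])
  m <- colMeans(X)
  for (i in seq_len(max_iter)) {
    dd <- sqrt(pmax(rs2 - 2 * drop(X %*% m) + sum(m * m), 0))
    w <- 1 / pmax(dd, 1e-12)
    m_new <- drop(crossprod(X, w)) / sum(w)
    if (sum((m_new - m)^2) <= tol^2) {
      return(m_new)
    }
    m <- m_new
  }
  m
}

# per-sample distances to group centre in a PCoA embedding with the standard
# negative-eigenvalue correction (squared real-part distance minus squared
# imaginary-part distance, floored at 0)
dispersion_distances <- function(xpos, xneg, labels, type,
                                 rs2p = rowSums(xpos^2),
                                 rs2n = rowSums(xneg^2)) {
  z2 <- numeric(nrow(xpos))
  has_neg <- ncol(xneg) > 0
  for (l in levels(labels)) {
    idx <- which(labels == l)
    Xg <- xpos[idx, , drop = FALSE]
    cpos <- if (type == "median") spatial_median(Xg, rs2p[idx]) else colMeans(Xg)
    dp <- rs2p[idx] - 2 * drop(Xg %*% cpos) + sum(cpos * cpos)
    dn <- 0
    if (has_neg) {
      Ng <- xneg[idx, , drop = FALSE]
      cneg <- if (type == "median") spatial_median(Ng, rs2n[idx]) else colMeans(Ng)
      dn <- rs2n[idx] - 2 * drop(Ng %*% cneg) + sum(cneg * cneg)
    }
    z2[idx] <- pmax(dp - dn, 0)
  }
  sqrt(z2)
}

anova_f <- function(z, labels) {
  n <- length(z)
  k <- nlevels(labels)
  gm <- mean(z)
  codes <- as.integer(labels)
  sizes <- tabulate(codes, k)
  gsums <- vapply(seq_len(k), function(j) sum(z[codes == j]), numeric(1))
  means <- gsums / sizes
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((z - means[codes])^2)
  if (ssw <= 0) {
    if (ssb <= 0) 0 else Inf
  } else {
    (ssb / (k - 1)) / (ssw / (n - k))
  }
}

#' Homogeneity of multivariate dispersions (BETADISPER-style)
#'
#' Embeds the dissimilarity matrix by PCoA (negative eigenvalues handled by
#' the standard correction: squared distances in the imaginary axes are
#' subtracted from those in the real axes, floored at zero), computes each
#' sample's distance to its group centre — the spatial median by default, the
#' mean centroid with `type = "centroid"` — and tests the one-way ANOVA F of
#' those distances by permuting group labels and recomputing centres and
#' distances. A significant result means groups differ in dispersion, which
#' can masquerade as a location effect in PERMANOVA.
#'
#' @inheritParams permanova
#' @param type Group centre: `"median"` (spatial median, robust, default) or
#'   `"centroid"` (mean).
#' @return A `perm_test` with the dispersion F, `r_squared` (eta-squared of
#'   the dispersion ANOVA) and the add-one permutation p-value.
#' @export
betadisper_test <- function(d, labels, n_perm = 999, seed = NULL,
                            type = c("median", "centroid")) {
  type <- match.arg(type)
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- check_perm_groups(labels, n)
  eg <- eigen(gower_center(m), symmetric = TRUE)
  tol <- max(abs(eg$values), 0) * 1e-10
  pos <- which(eg$values > tol)
  neg <- which(eg$values < -tol)
  xpos <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]), length(pos))
  xneg <- eg$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eg$values[neg]), length(neg))
  rs2p <- rowSums(xpos^2)
  rs2n <- rowSums(xneg^2)
  z <- dispersion_distances(xpos, xneg, labels, type, rs2p, rs2n)
  f_obs <- anova_f(z, labels)
  # eta-squared of the dispersion ANOVA, for the result record
  gm <- mean(z)
  r2 <- if (sum((z - gm)^2) > 0) {
    means <- tapply(z, labels, mean)
    sum(tabulate(labels) * (means - gm)^2) / sum((z - gm)^2)
  } else {
    0
  }
  f_tol <- 1e-10 * max(1, if (is.finite(f_obs)) abs(f_obs) else 1)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      lp <- sample(labels)
      anova_f(dispersion_distances(xpos, xneg, lp, type, rs2p, rs2n), lp)
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs - f_tol)) / (1 + n_perm)
  perm_test_result("BETADISPER", f_obs, r2, p, n_perm, seed, FALSE,
                   extra = list(type = type))
}
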