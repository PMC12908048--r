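# Per-sample alpha diversity: Shannon entropy, Pielou evenness, Gini-Simpson
# and the Chao1 richness estimator.

check_proportions <- function(p, tol = 1e-6) {
  assert_that(is.numeric(p) && length(p) > 0 && !anyNA(p), "invalid proportion vector")
  assert_that(all(p >= 0), "negative entries in proportion vector")
  assert_that(abs(sum(p) - 1) <= tol, "proportions must sum to 1 (got %.8g)", sum(p))
  p / sum(p)
}

#' Shannon diversity of a proportion vector
#'
#' `H = -sum(p_i * log(p_i))` over positive entries, in nats by default.
#'
#' @param p Non-negative proportions summing to 1 (within 1e-6).
#' @param base Logarithm base; default `exp(1)` (nats), use 2 for bits.
#' @return Non-negative scalar; zeros contribute nothing.
#' @examples
#' shannon(rep(0.25, 4)) # log(4)
#' @export
shannon <- function(p, base = exp(1)) {
  p <- check_proportions(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Pielou evenness
#'
#' `J = H / log(S)` where `S` is the number of taxa with positive abundance;
#' requires at least two present taxa (evenness of a single taxon is
#' undefined).
#'
#' @inheritParams shannon
#' @return Value in (0, 1]; 1 for a uniform community.
#' @export
pielou <- function(p, base = exp(1)) {
  p <- check_proportions(p)
  s <- sum(p > 0)
  assert_that(s >= 2, "evenness undefined: fewer than 2 taxa present")
  shannon(p, base = base) / log(s, base = base)
}

#' Gini-Simpson diversity
#'
#' `1 - sum(p_i^2)`, the probability that two random reads come from
#' different taxa.
#'
#' @inheritParams shannon
#' @return Value in `[0, 1 - 1/S]`.
#' @export
simpson <- function(p) {
  p <- check_proportions(p)
  1 - sum(p^2)
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1*(F1-1) / (2*(F2+1))` from singleton (`F1`)
#' and doubleton (`F2`) counts; the classic form `S_obs + F1^2/(2*F2)` is
#' available with `bias_corrected = FALSE` (infinite when `F2 = 0`). Requires
#' count data: richness cannot be estimated from relative abundances.
#'
#' @param counts Non-negative integer vector of per-taxon read counts.
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness, always `>= S_obs`.
#' @examples
#' chao1(c(1, 1, 2, 3)) # 4.5
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  assert_that(is.numeric(counts) && !anyNA(counts) && all(counts >= 0),
              "counts must be non-negative")
  assert_that(all(abs(counts - round(counts)) < 1e-8),
              "non-integer count: Chao1 requires count data")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f1 == 0) {
    s_obs
  } else {
    s_obs + f1^2 / (2 * f2) # Inf when F2 = 0 and F1 > 0
  }
}

#' Alpha diversity indices for every sample of an abundance table
#'
#' Computes Shannon, Pielou and Gini-Simpson per sample; for count-mode
#' tables, Chao1 as well (proportions for the other indices are then taken
#' as counts / depth). Chao1 is never computed from relative abundances.
#'
#' @param abundance An `abundance_tbl` (either mode).
#' @param base Logarithm base for Shannon/Pielou.
#' @return A tibble with columns `sample_id`, `shannon`, `pielou`, `simpson`
#'   and, for count input, `chao1`.
#' @export
alpha_diversity <- function(abundance, base = exp(1)) {
  m <- abundance_matrix(abundance)
  counts <- ab_mode(abundance) == "count"
  props <- if (counts) m / rowSums(m) else m
  out <- tibble(
    sample_id = rownames(m),
    shannon = unname(apply(props, 1, shannon, base = base)),
    pielou = unname(apply(props, 1, pielou, base = base)),
    simpson = unname(apply(props, 1, simpson))
  )
  if (counts) out$chao1 <- unname(apply(m, 1, chao1))
  out
}
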