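# Shared fixtures, built in code at test time.

# random strictly-positive proportion vector of length s
random_proportions <- function(s) {
  x <- rgamma(s, shape = 1) + 1e-6
  x / sum(x)
}

# small abundance_tbl from a raw matrix, rows renormalized
rel_table <- function(m, ids = sprintf("S%03d", seq_len(nrow(m)))) {
  rownames(m) <- ids
  abundance_table(m / rowSums(m), mode = "relative")
}

# tiny deterministic cohort used across tests
tiny_cohort <- function(seed = 42, ...) {
  generate_cohort(cohort_spec(n_total = 30, n_infected = 14, n_taxa = 40,
                              sequencing_depth = 2000, seed = seed, ...))
}

# biomarker parameter table with identical distributions in both groups
null_biomarker_params <- function() {
  bp <- default_biomarker_params()
  for (b in unique(bp$biomarker)) {
    ref <- bp[bp$biomarker == b & bp$group == "noninfected", ]
    bp[bp$biomarker == b, c("median", "q1", "q3")] <-
      ref[rep(1, 2), c("median", "q1", "q3")]
  }
  bp
}

expect_validation_error <- function(expr, pattern = NULL) {
  expect_error(expr, regexp = pattern,
               class = "strokedysbiosis_validation_error")
}
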