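# Shared fixtures: a 2x2 worked example (two populations of two, one SNP
# with frequencies 0.2 / 0.8) with closed-form block elements, and random
# valid panel generators used by the property tests.

toy_structure <- function() pop_structure(c(2L, 2L), c("A", "B"))

toy_freqs <- function() {
  freq_table(rbind(0.2, 0.8), snp_ids = "rs1", pop_labels = c("A", "B"))
}

toy_summary <- function(mode = "mixture") {
  ps <- toy_structure()
  ft <- toy_freqs()
  egrm_elements(ps, ft, genotype_moments(ps, ft, mode))
}

# A random consistent (structure, frequency table) pair. Frequencies are
# kept away from 0/1 so every SNP is polymorphic in the total population.
random_panel_case <- function(seed, K = NULL, max_pop = 50L, M = NULL,
                              f_range = c(0.05, 0.95)) {
  set.seed(seed)
  if (is.null(K)) K <- sample(1:5, 1)
  sizes <- sample(seq_len(max_pop), K, replace = TRUE)
  if (is.null(M)) M <- sample(1:5, 1)
  f <- matrix(stats::runif(K * M, f_range[1], f_range[2]), K, M)
  list(structure = pop_structure(sizes), freqs = freq_table(f))
}

# Independent oracle for the mixture genotype variance: exact enumeration
# of P(X = g), g in {0, 1, 2}, for the binomial mixture with weights w and
# per-component frequencies f.
mixture_variance_oracle <- function(w, f) {
  p <- vapply(0:2, function(g) sum(w * stats::dbinom(g, 2L, f)), numeric(1))
  mu <- sum((0:2) * p)
  sum(((0:2) - mu)^2 * p)
}

# Multiset comparison of two eigenvalue collections within a tolerance.
expect_multiset_equal <- function(a, b, tol = 1e-8) {
  expect_equal(length(a), length(b))
  expect_lt(max(abs(sort(a) - sort(b))), tol)
}
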