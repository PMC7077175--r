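#' Inter- and intra-population variance components
#'
#' The `K` structural eigenvalues of an EGRM sum to
#' `sigma_B^2 + sigma_W^2`, where `sigma_B^2 = sum_k N_k z^kk` is the
#' inter-population component (within-population covariance factors in as
#' between-population variance after eigen-decomposition) and
#' `sigma_W^2 = sum_k (z^k - z^kk)` the intra-population component.
#'
#' @param summary a theoretical [block_summary()].
#' @param structure the matching [pop_structure()].
#' @return Named numeric `c(sigma_B2, sigma_W2)`.
#' @export
variance_components <- function(summary, structure) {
  if (!inherits(summary, "block_summary")) {
    stop("summary must be a block_summary", call. = FALSE)
  }
  if (summary$n_pops != structure$n_pops) {
    stop("summary and structure have different numbers of populations",
         call. = FALSE)
  }
  c(sigma_B2 = sum(structure$sizes * summary$zkk),
    sigma_W2 = sum(summary$zk - summary$zkk))
}

#' Population-divergence ratios over the K informative PCs
#'
#' `F_PC = sigma_B^2 / sigma_W^2` and its normalized version
#' `F_PC* = sigma_B^2 / (sigma_B^2 + sigma_W^2)`, a fraction in `[0, 1)`.
#' The larger either is, the more divergent the populations. Note that
#' with multiple SNPs F_PC is aggregated through the pooled variance
#' components, not by averaging per-SNP ratios, and its value depends on
#' the `sigma_m` convention used to build the EGRM (it is
#' convention-invariant only for a single SNP, where `sigma_m` cancels).
#'
#' @param sigma_B2 inter-population variance component.
#' @param sigma_W2 intra-population variance component, strictly positive.
#' @return `fpc()` the ratio; `fpc_star()` the fraction.
#' @export
fpc <- function(sigma_B2, sigma_W2) {
  if (!is.finite(sigma_W2) || sigma_W2 <= 0) {
    stop("intra-population variance component must be positive",
         call. = FALSE)
  }
  unname(sigma_B2 / sigma_W2)
}

#' @rdname fpc
#' @export
fpc_star <- function(sigma_B2, sigma_W2) {
  tot <- sigma_B2 + sigma_W2
  if (!is.finite(tot) || tot <= 0) {
    stop("total variance must be positive", call. = FALSE)
  }
  unname(sigma_B2 / tot)
}

#' Single-SNP F_PC
#'
#' For one SNP the divergence ratio reduces to the closed form
#' `F_PC = 2 sum_k N_k (f_k - f)^2 / sum_k f_k (1 - f_k)`, with `f` the
#' size-weighted total frequency. The `sigma_m` convention cancels, so this
#' matches the EGRM route for any normalization mode.
#'
#' @param structure a [pop_structure()].
#' @param f length-`K` per-population coded-allele frequencies of one SNP;
#'   at least one must be strictly inside `(0, 1)`.
#' @return The single-SNP F_PC value.
#' @export
single_snp_fpc <- function(structure, f) {
  f <- as.numeric(f)
  if (length(f) != structure$n_pops) {
    stop("f must hold one frequency per population", call. = FALSE)
  }
  if (any(f < 0) || any(f > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  den <- sum(f * (1 - f))
  if (den <= 0) {
    stop("all per-population frequencies are fixed (0 or 1); F_PC undefined",
         call. = FALSE)
  }
  ftot <- sum(structure$sizes * f) / structure$n_total
  2 * sum(structure$sizes * (f - ftot)^2) / den
}

#' Wright's fixation index for a single SNP
#'
#' Solves `F_ST / (1 - F_ST) = sum_k N_k (f_k - f)^2 /
#' sum_k N_k f_k (1 - f_k)` for `F_ST`. The related N-PC variance ratio
#' identity `sigma_B^2 / sum_k N_k (z^k - z^kk) = 2 F_ST / (1 - F_ST)`
#' holds per SNP regardless of the normalization convention.
#'
#' @param structure a [pop_structure()].
#' @param f length-`K` per-population frequencies of one SNP.
#' @return The F_ST value in `[0, 1)`.
#' @export
fst <- function(structure, f) {
  f <- as.numeric(f)
  if (length(f) != structure$n_pops) {
    stop("f must hold one frequency per population", call. = FALSE)
  }
  if (any(f < 0) || any(f > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  den <- sum(structure$sizes * f * (1 - f))
  if (den <= 0) {
    stop("all per-population frequencies are fixed (0 or 1); F_ST undefined",
         call. = FALSE)
  }
  ftot <- sum(structure$sizes * f) / structure$n_total
  r <- sum(structure$sizes * (f - ftot)^2) / den
  r / (1 + r)
}

#' Sum of squared distances among populations in scaled PC space
#'
#' With eigenvectors scaled by the square roots of their eigenvalues,
#' every member of a population sits at its representative point. The sum
#' over samples of squared deviations from the grand center across the
#' `K` structural dimensions reduces to
#' `d^2 = sum_k lambda_k - (1/N) sum_k N_k (z^k - z^kk)`,
#' the structural eigenvalue sum minus the average intra-population
#' variance.
#'
#' @param structural_eigenvalues the `K` structural eigenvalues (e.g. from
#'   [structural_spectrum()]).
#' @param summary the matching theoretical [block_summary()].
#' @param structure the matching [pop_structure()].
#' @return The population distance `d^2`.
#' @export
pop_distance_d2 <- function(structural_eigenvalues, summary, structure) {
  if (length(structural_eigenvalues) != structure$n_pops) {
    stop("need exactly K structural eigenvalues", call. = FALSE)
  }
  if (summary$n_pops != structure$n_pops) {
    stop("summary and structure have different numbers of populations",
         call. = FALSE)
  }
  sum(structural_eigenvalues) -
    sum(structure$sizes * (summary$zk - summary$zkk)) / structure$n_total
}

#' Full divergence report from a frequency panel
#'
#' End-to-end pipeline: genotypic moments, EGRM block elements, structural
#' eigenvalues, variance components and the divergence statistics F_PC,
#' F_PC* and d^2.
#'
#' @param structure a [pop_structure()].
#' @param freqs a [freq_table()].
#' @param mode moment convention passed to [genotype_moments()].
#' @return Object of class `divergence_report` with fields `sigma_B2`,
#'   `sigma_W2`, `f_pc`, `f_pc_star`, `d2`, `k_pcs`, `n_snps`, `mode`.
#' @examples
#' ps <- pop_structure(c(2, 2))
#' ft <- freq_table(rbind(0.2, 0.8))
#' divergence_report(ps, ft) # F_PC = 2.25
#' @export
divergence_report <- function(structure, freqs,
                              mode = c("mixture", "total_binomial",
                                       "eigensoft", "gcta")) {
  mode <- match.arg(mode)
  norm <- genotype_moments(structure, freqs, mode)
  summary <- egrm_elements(structure, freqs, norm)
  spec <- structural_spectrum(summary, structure)
  vc <- variance_components(summary, structure)
  base::structure(
    list(sigma_B2 = unname(vc["sigma_B2"]),
         sigma_W2 = unname(vc["sigma_W2"]),
         f_pc = fpc(vc["sigma_B2"], vc["sigma_W2"]),
         f_pc_star = fpc_star(vc["sigma_B2"], vc["sigma_W2"]),
         d2 = pop_distance_d2(spec$values, summary, structure),
         k_pcs = structure$n_pops,
         n_snps = freqs$n_snps,
         mode = mode),
    class = "divergence_report"
  )
}

#' @export
print.divergence_report <- function(x, digits = 5, ...) {
  cat(sprintf(
    "Divergence over %d PCs (%d SNPs, %s moments): F_PC = %s, F_PC* = %s, d2 = %s\n",
    x$k_pcs, x$n_snps, x$mode,
    signif(x$f_pc, digits), signif(x$f_pc_star, digits),
    signif(x$d2, digits)))
  invisible(x)
}
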