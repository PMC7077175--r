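#' Block elements of the expected genetic relationship matrix
#'
#' The EGRM — the expectation of the GRM under Hardy-Weinberg sampling
#' within each population — is fully determined by three families of
#' numbers, each averaged over the `M` SNPs:
#'
#' * `z^k  = (1/M) sum_m [2 f_km (1 - f_km) + (2 f_km - mu_m)^2] / sigma_m^2`,
#'   the genotypic variance of individuals from population `k`;
#' * `z^kk = (1/M) sum_m (2 f_km - mu_m)^2 / sigma_m^2`, the covariance
#'   between two individuals from population `k`;
#' * `z^kl = (1/M) sum_m (2 f_km - mu_m)(2 f_lm - mu_m) / sigma_m^2`, the
#'   covariance between one individual from population `k` and one from `l`.
#'
#' @param structure a [pop_structure()].
#' @param freqs a [freq_table()].
#' @param norm a [norm_params()] with one `(mu, sigma)` pair per SNP, e.g.
#'   from [genotype_moments()].
#' @return A theoretical [block_summary()].
#' @examples
#' ps <- pop_structure(c(2, 2))
#' ft <- freq_table(rbind(0.2, 0.8))
#' nm <- genotype_moments(ps, ft, "mixture")
#' egrm_elements(ps, ft, nm) # z^k = 1, z^kk = 9/17, z^12 = -9/17
#' @export
egrm_elements <- function(structure, freqs, norm) {
  check_pair(structure, freqs)
  if (!inherits(norm, "norm_params")) {
    stop("norm must be a norm_params", call. = FALSE)
  }
  f <- freqs$freqs
  M <- ncol(f)
  if (length(norm$mu) != M) {
    stop("normalization parameters do not match the number of SNPs",
         call. = FALSE)
  }
  # centered population means scaled by sigma; D[k, m] = (2 f_km - mu_m)/sigma_m
  D <- sweep(2 * f, 2L, norm$mu, "-")
  D <- sweep(D, 2L, norm$sigma, "/")
  het <- sweep(2 * f * (1 - f), 2L, norm$sigma^2, "/")
  zkl <- tcrossprod(D) / M
  zkk <- diag(zkl)
  zk <- zkk + rowSums(het) / M
  block_summary(zk, zkk, zkl,
                labels = structure$labels, sizes = structure$sizes,
                source = "theoretical")
}

#' Assemble the dense EGRM from its block summary
#'
#' Materializes the `N x N` expected relationship matrix: diagonal entries
#' `z^k`, off-diagonal entries within population `k` equal to `z^kk`, and
#' all entries of the `(k, l)` cross block equal to `z^kl`. Most analyses
#' never need the dense form — the eigen-structure is computed from the
#' `K x K` reduced matrix (see [structural_spectrum()]) — but it is useful
#' for export and for validation against empirical GRMs.
#'
#' @param structure a [pop_structure()].
#' @param summary a theoretical [block_summary()] with matching `K`.
#' @return A [relationship_matrix()] of kind `"theoretical-EGRM"`.
#' @export
assemble_egrm <- function(structure, summary) {
  if (!inherits(summary, "block_summary")) {
    stop("summary must be a block_summary", call. = FALSE)
  }
  if (summary$n_pops != structure$n_pops) {
    stop("summary and structure have different numbers of populations",
         call. = FALSE)
  }
  if (anyNA(summary$zkk) || anyNA(summary$zkl)) {
    stop("cannot assemble a matrix from a summary with missing elements",
         call. = FALSE)
  }
  memb <- structure$membership
  # expand the K x K covariance pattern, then overwrite the diagonal
  values <- summary$zkl[memb, memb, drop = FALSE]
  diag(values) <- summary$zk[memb]
  relationship_matrix(values, kind = "theoretical-EGRM",
                      structure = structure)
}

#' Block-average an observed relationship matrix
#'
#' The empirical analogue of [egrm_elements()]: `z^k` is the mean diagonal
#' entry of population `k`'s block, `z^kk` the mean of its
#' `N_k (N_k - 1) / 2` off-diagonal entries, and `z^kl` the mean of the
#' `N_k N_l` entries of the cross block. A population of size 1 has no
#' within-population pairs; its `z^kk` is reported as `NA`.
#'
#' @param matrix a [relationship_matrix()] (empirical or theoretical).
#' @param structure a [pop_structure()] with `N` matching the matrix.
#' @return A [block_summary()] with `source = "empirical"`.
#' @export
block_summaries <- function(matrix, structure) {
  if (!inherits(matrix, "relationship_matrix")) {
    stop("matrix must be a relationship_matrix", call. = FALSE)
  }
  if (structure$n_total != matrix$n) {
    stop("structure size does not match matrix dimension", call. = FALSE)
  }
  V <- matrix$values
  blocks <- pop_blocks(structure)
  K <- structure$n_pops
  zk <- zkk <- numeric(K)
  zkl <- base::matrix(0, K, K)
  for (k in seq_len(K)) {
    bk <- blocks[[k]]
    nk <- length(bk)
    dk <- diag(V)[bk]
    zk[k] <- mean(dk)
    zkk[k] <- if (nk < 2L) NA_real_ else {
      (sum(V[bk, bk]) - sum(dk)) / (nk * (nk - 1))
    }
    zkl[k, k] <- zkk[k]
    if (k < K) {
      for (l in seq.int(k + 1L, K)) {
        bl <- blocks[[l]]
        zkl[k, l] <- zkl[l, k] <- mean(V[bk, bl])
      }
    }
  }
  block_summary(zk, zkk, zkl,
                labels = structure$labels, sizes = structure$sizes,
                source = "empirical")
}
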