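# Deterministic sign convention: within each eigenvector, the entry of
# largest magnitude (lowest index on ties) is made positive. Ties are
# resolved with a small relative tolerance so that entries equal up to
# floating-point noise count as tied.
fix_signs <- function(vectors, tol = 1e-9) {
  for (j in seq_len(ncol(vectors))) {
    a <- abs(vectors[, j])
    i <- which(a >= max(a) * (1 - tol))[1]
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  vectors
}

#' Full eigen-decomposition of a relationship matrix
#'
#' Standard symmetric eigen-decomposition with eigenvalues sorted in
#' descending order, a deterministic eigenvector sign convention (the
#' largest-magnitude entry of each vector is positive, ties broken by
#' lowest index), and per-eigenvalue variance-explained fractions
#' `lambda_i / sum(lambda)`.
#'
#' @param matrix a [relationship_matrix()].
#' @return Object of class `eigen_result` with fields `values`, `vectors`,
#'   `variance_explained`, `kind`, `sample_ids`.
#' @export
full_spectrum <- function(matrix) {
  if (!inherits(matrix, "relationship_matrix")) {
    stop("matrix must be a relationship_matrix", call. = FALSE)
  }
  e <- eigen(matrix$values, symmetric = TRUE)
  vectors <- fix_signs(e$vectors)
  dimnames(vectors) <- list(matrix$sample_ids,
                            sprintf("PC%d", seq_len(ncol(vectors))))
  structure(
    list(values = e$values, vectors = vectors,
         variance_explained = e$values / sum(e$values),
         kind = matrix$kind, sample_ids = matrix$sample_ids),
    class = "eigen_result"
  )
}

#' @export
print.eigen_result <- function(x, ...) {
  cat(sprintf("Eigen-decomposition of a %s (N = %d)\n", x$kind,
              length(x$values)))
  cat("Leading eigenvalues:",
      paste(signif(utils::head(x$values, 5L), 5), collapse = ", "), "\n")
  invisible(x)
}

#' Exact eigen-structure of an EGRM from its block summary
#'
#' An EGRM has two kinds of eigenvalues. For each population `k` there are
#' `N_k - 1` eigenvalues equal to the intra-population variance
#' `z^k - z^kk`, with eigenvectors contrasting individuals inside the
#' block. The remaining `K` "structural" eigenpairs carry all
#' inter-population variance and are obtained exactly from the `K x K`
#' reduced matrix `B` with `B_kk = (z^k - z^kk) + N_k z^kk` and
#' `B_kl = sqrt(N_k N_l) z^kl`; its eigenvectors map back to block-constant
#' length-`N` vectors with value `u_k / sqrt(N_k)` inside block `k`.
#' Working on `B` separates the structural eigenvalues exactly even when
#' they are numerically degenerate with intra eigenvalues, which
#' magnitude-sorting of the full spectrum cannot do.
#'
#' @param summary a theoretical [block_summary()].
#' @param structure a [pop_structure()] with matching `K`.
#' @return Object of class `structural_spectrum`: `values` (the `K`
#'   structural eigenvalues, descending), `vectors` (`N x K` block-constant
#'   orthonormal columns, sign-fixed), `intra_values` (`z^k - z^kk` per
#'   population), `intra_multiplicities` (`N_k - 1`), `reduced_matrix`
#'   (`B`), plus labels and sizes.
#' @export
structural_spectrum <- function(summary, structure) {
  if (!inherits(summary, "block_summary")) {
    stop("summary must be a block_summary", call. = FALSE)
  }
  if (summary$n_pops != structure$n_pops) {
    stop("summary and structure have different numbers of populations",
         call. = FALSE)
  }
  if (anyNA(summary$zkk) || anyNA(summary$zkl)) {
    stop("summary contains missing elements", call. = FALSE)
  }
  K <- structure$n_pops
  Ns <- structure$sizes
  intra <- summary$zk - summary$zkk
  B <- sqrt(Ns) %o% sqrt(Ns) * summary$zkl
  diag(B) <- intra + Ns * summary$zkk
  e <- eigen(B, symmetric = TRUE)
  U <- matrix(e$vectors, K, K)
  # block-constant expansion: value u_k / sqrt(N_k) within block k
  blockvals <- U / sqrt(Ns)
  vectors <- fix_signs(blockvals[structure$membership, , drop = FALSE])
  dimnames(vectors) <- list(default_sample_ids(structure),
                            sprintf("PC%d", seq_len(K)))
  base::structure(
    list(values = e$values, vectors = vectors,
         intra_values = intra, intra_multiplicities = Ns - 1L,
         reduced_matrix = B,
         labels = structure$labels, sizes = Ns),
    class = "structural_spectrum"
  )
}

#' @export
print.structural_spectrum <- function(x, ...) {
  cat(sprintf("Structural spectrum: K = %d\n", length(x$values)))
  cat("Structural eigenvalues:",
      paste(signif(x$values, 5), collapse = ", "), "\n")
  cat("Intra eigenvalues z^k - z^kk (multiplicity N_k - 1):\n")
  for (k in seq_along(x$intra_values)) {
    cat(sprintf("  %s: %.5g (x%d)\n", x$labels[k], x$intra_values[k],
                x$intra_multiplicities[k]))
  }
  invisible(x)
}

#' Closed-form eigenvalues for a two-population EGRM
#'
#' For `K = 2` the two structural eigenvalues have the closed form
#' `lambda_{1,2} = [N_1 z^11 + N_2 z^22 + (z^1 - z^11) + (z^2 - z^22)
#' +/- sqrt(a)] / 2` with
#' `a = [(z^1 - z^11) - (z^2 - z^22) + N_1 z^11 - N_2 z^22]^2 +
#' 4 N_1 N_2 (z^12)^2`. When the intra-population variances of the two
#' populations are equal this degenerates to
#' `lambda_1 = N_1 z^11 + N_2 z^22 + sigma_W^2 / 2`,
#' `lambda_2 = sigma_W^2 / 2`.
#'
#' @param summary a theoretical [block_summary()] with `K = 2`.
#' @param structure a [pop_structure()] with two populations.
#' @return Numeric `c(lambda1, lambda2)`, descending.
#' @export
two_pop_eigenvalues <- function(summary, structure) {
  if (structure$n_pops != 2L || summary$n_pops != 2L) {
    stop("closed-form eigenvalues require exactly two populations",
         call. = FALSE)
  }
  N1 <- structure$sizes[1]; N2 <- structure$sizes[2]
  w1 <- summary$zk[1] - summary$zkk[1]
  w2 <- summary$zk[2] - summary$zkk[2]
  s <- N1 * summary$zkk[1] + N2 * summary$zkk[2] + w1 + w2
  a <- (w1 - w2 + N1 * summary$zkk[1] - N2 * summary$zkk[2])^2 +
    4 * N1 * N2 * summary$zkl[1, 2]^2
  c(lambda1 = (s + sqrt(a)) / 2, lambda2 = (s - sqrt(a)) / 2)
}

#' Fraction of variance explained by the top-k PCs
#'
#' @param result an `eigen_result` from [full_spectrum()].
#' @param k number of leading eigenvalues, `1 <= k <= N`.
#' @return Fraction of the trace carried by the `k` largest eigenvalues.
#' @export
variance_explained_topk <- function(result, k) {
  if (!inherits(result, "eigen_result")) {
    stop("result must be an eigen_result", call. = FALSE)
  }
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(result$values)) {
    stop("k must be between 1 and the number of eigenvalues", call. = FALSE)
  }
  sum(result$values[seq_len(k)]) / sum(result$values)
}

#' Representative points of the populations in PC space
#'
#' In the `K` structural dimensions each individual of population `k` sits
#' at the same point: coordinate `sqrt(lambda_j)` times the block-constant
#' eigenvector entry of block `k`. These common points are the
#' representative points (centers) of the populations; the grand center is
#' `sqrt(lambda_j) x_j' 1_N / N` per dimension. Exact block-constancy only
#' holds for theoretical EGRMs, so this function takes a
#' [structural_spectrum()]; for observed GRMs use
#' [representative_points_empirical()], which averages within-population
#' coordinates and is approximate.
#'
#' @param spectrum a [structural_spectrum()].
#' @param structure the matching [pop_structure()].
#' @return List with `centers` (`K x K` matrix, populations x dimensions),
#'   `grand_center` (length-`K`), `eigenvalues`.
#' @export
representative_points <- function(spectrum, structure) {
  if (inherits(spectrum, "relationship_matrix") &&
      spectrum$kind == "empirical-GRM") {
    stop(paste("representative points are exact only for theoretical EGRMs;",
               "use representative_points_empirical() for observed GRMs"),
         call. = FALSE)
  }
  if (!inherits(spectrum, "structural_spectrum")) {
    stop("spectrum must be a structural_spectrum", call. = FALSE)
  }
  if (length(spectrum$values) != structure$n_pops) {
    stop("spectrum and structure have different numbers of populations",
         call. = FALSE)
  }
  sq <- sqrt(pmax(spectrum$values, 0))
  block_start <- cumsum(c(1L, structure$sizes))[seq_len(structure$n_pops)]
  blockvals <- spectrum$vectors[block_start, , drop = FALSE]
  centers <- sweep(blockvals, 2L, sq, "*")
  dimnames(centers) <- list(structure$labels,
                            sprintf("dim%d", seq_along(sq)))
  grand <- sq * colMeans(spectrum$vectors)
  list(centers = centers, grand_center = grand,
       eigenvalues = spectrum$values)
}

#' Approximate population centers from an observed GRM
#'
#' Averages the square-root-of-eigenvalue-scaled coordinates of each
#' population's members over the top `k` PCs of an empirical GRM. Unlike
#' [representative_points()], members of a population do not share exact
#' coordinates, so these centers are approximate and labelled as such.
#'
#' @param result an `eigen_result` from [full_spectrum()] of an empirical
#'   GRM.
#' @param structure a [pop_structure()].
#' @param k number of leading PCs to use (default `K`).
#' @return List with `centers` (`K x k`), `grand_center`, and
#'   `approximate = TRUE`.
#' @export
representative_points_empirical <- function(result, structure,
                                            k = structure$n_pops) {
  if (!inherits(result, "eigen_result")) {
    stop("result must be an eigen_result", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L || k > length(result$values)) {
    stop("k out of range", call. = FALSE)
  }
  sq <- sqrt(pmax(result$values[seq_len(k)], 0))
  coords <- sweep(result$vectors[, seq_len(k), drop = FALSE], 2L, sq, "*")
  centers <- do.call(rbind, lapply(pop_blocks(structure), function(idx) {
    colMeans(coords[idx, , drop = FALSE])
  }))
  dimnames(centers) <- list(structure$labels, sprintf("dim%d", seq_len(k)))
  list(centers = centers, grand_center = colMeans(coords),
       approximate = TRUE)
}
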