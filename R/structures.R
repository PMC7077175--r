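#' Define a multi-population sample structure
#'
#' A population structure records `K` populations with sizes `N_k` and the
#' sample-to-population membership. Samples are ordered by population, each
#' population occupying a contiguous block of rows; all block computations in
#' the package (EGRM assembly, block averaging, structural eigenvectors)
#' index through this object.
#'
#' @param sizes integer vector of `K` positive population sizes `N_k`.
#' @param labels character vector of `K` unique population names; defaults to
#'   `pop1`, `pop2`, ...
#' @return An object of class `pop_structure` with fields `labels`, `sizes`,
#'   `membership` (length-`N` integer vector of population indices),
#'   `n_pops` and `n_total`.
#' @examples
#' ps <- pop_structure(c(2, 2), c("EUR", "EAS"))
#' ps$membership
#' @export
pop_structure <- function(sizes, labels = sprintf("pop%d", seq_along(sizes))) {
  if (length(sizes) < 1L) {
    stop("at least one population is required", call. = FALSE)
  }
  sizes_int <- as.integer(sizes)
  if (any(is.na(sizes_int)) || any(sizes_int < 1L) ||
      any(abs(sizes - sizes_int) > 0)) {
    stop("population sizes must be positive integers", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != length(sizes_int) || anyDuplicated(labels)) {
    stop("labels must be unique and match the number of populations",
         call. = FALSE)
  }
  structure(
    list(
      labels = labels,
      sizes = sizes_int,
      membership = rep.int(seq_along(sizes_int), sizes_int),
      n_pops = length(sizes_int),
      n_total = sum(sizes_int)
    ),
    class = "pop_structure"
  )
}

#' @export
print.pop_structure <- function(x, ...) {
  cat(sprintf("Population structure: K = %d, N = %d\n", x$n_pops, x$n_total))
  cat(paste(sprintf("  %s (N = %d)", x$labels, x$sizes), collapse = "\n"),
      "\n", sep = "")
  invisible(x)
}

# indices of the samples belonging to each population block
pop_blocks <- function(structure) {
  split(seq_len(structure$n_total), structure$membership)
}

default_sample_ids <- function(structure) {
  unlist(lapply(seq_len(structure$n_pops), function(k) {
    sprintf("%s_%d", structure$labels[k], seq_len(structure$sizes[k]))
  }), use.names = FALSE)
}

#' Per-population coded-allele frequency table
#'
#' Holds the `K x M` matrix of coded-allele frequencies `f_km`, one row per
#' population and one column per SNP.
#'
#' @param freqs numeric `K x M` matrix (or vector for `M = 1`) with all
#'   entries in `[0, 1]`.
#' @param snp_ids character vector of `M` unique SNP identifiers; defaults to
#'   `snp1`, `snp2`, ...
#' @param pop_labels optional character vector of `K` population names used
#'   for row names.
#' @return Object of class `freq_table` with fields `freqs` (matrix),
#'   `snp_ids`, `pop_labels`, `n_pops`, `n_snps`.
#' @examples
#' freq_table(rbind(c(0.2, 0.5), c(0.8, 0.5)), c("rs1", "rs2"))
#' @export
freq_table <- function(freqs, snp_ids = NULL, pop_labels = NULL) {
  if (!is.matrix(freqs)) freqs <- matrix(freqs, nrow = length(freqs))
  storage.mode(freqs) <- "double"
  if (ncol(freqs) < 1L) stop("at least one SNP is required", call. = FALSE)
  if (anyNA(freqs) || any(freqs < 0) || any(freqs > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(ncol(freqs)))
  snp_ids <- as.character(snp_ids)
  if (length(snp_ids) != ncol(freqs) || anyDuplicated(snp_ids)) {
    stop("snp_ids must be unique, one per SNP", call. = FALSE)
  }
  if (!is.null(pop_labels)) {
    if (length(pop_labels) != nrow(freqs)) {
      stop("pop_labels must have one entry per population", call. = FALSE)
    }
    rownames(freqs) <- pop_labels
  }
  colnames(freqs) <- snp_ids
  structure(
    list(freqs = freqs, snp_ids = snp_ids,
         pop_labels = rownames(freqs),
         n_pops = nrow(freqs), n_snps = ncol(freqs)),
    class = "freq_table"
  )
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("Allele frequency table: %d populations x %d SNPs\n",
              x$n_pops, x$n_snps))
  print(utils::head(t(x$freqs), 6L))
  invisible(x)
}

#' Genotype matrix of coded-allele counts
#'
#' @param values integer `N x M` matrix of coded-allele counts, each entry in
#'   `{0, 1, 2}`. Missing values are rejected: the relationship-matrix model
#'   assumes complete data.
#' @param sample_ids,snp_ids optional identifier vectors (defaults generated).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, sample_ids = NULL, snp_ids = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (anyNA(values)) {
    stop("missing genotypes are not allowed", call. = FALSE)
  }
  if (!all(values %in% c(0, 1, 2))) {
    stop("genotype values must be coded-allele counts in {0, 1, 2}",
         call. = FALSE)
  }
  storage.mode(values) <- "integer"
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%d", seq_len(nrow(values)))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(ncol(values)))
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique, one per row", call. = FALSE)
  }
  if (length(snp_ids) != ncol(values) || anyDuplicated(snp_ids)) {
    stop("snp_ids must be unique, one per column", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         snp_ids = as.character(snp_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d SNPs\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Genotype normalization parameters
#'
#' Per-SNP genotypic means and standard deviations used to standardize
#' coded-allele counts, `Y = (X - mu) / sigma`. The `mode` records which
#' moment convention produced them: `mixture` (exact moments of the
#' multi-population binomial mixture), `total_binomial` (binomial moments at
#' the pooled frequency), `eigensoft` (`sigma = sqrt(f(1-f))`), `gcta`
#' (`sigma = sqrt(2f(1-f))`) or `sample` (observed column moments).
#'
#' @param mu length-`M` genotypic means, each in `[0, 2]`.
#' @param sigma length-`M` genotypic standard deviations, strictly positive.
#' @param mode character, one of `"mixture"`, `"total_binomial"`,
#'   `"eigensoft"`, `"gcta"`, `"sample"`.
#' @return Object of class `norm_params`.
#' @export
norm_params <- function(mu, sigma,
                        mode = c("mixture", "total_binomial", "eigensoft",
                                 "gcta", "sample")) {
  mode <- match.arg(mode)
  mu <- as.numeric(mu)
  sigma <- as.numeric(sigma)
  if (length(mu) != length(sigma)) {
    stop("mu and sigma must have the same length", call. = FALSE)
  }
  if (any(mu < 0) || any(mu > 2)) {
    stop("genotypic means must lie in [0, 2]", call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("genotypic standard deviations must be strictly positive",
         call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, mode = mode), class = "norm_params")
}

#' Per-population block summary of a relationship matrix
#'
#' The complete description of a (expected) relationship matrix's block
#' structure: per-population genotypic variances `z^k`, within-population
#' covariances `z^kk` and cross-population covariances `z^kl`. A theoretical
#' EGRM is fully determined by these `2K + K(K-1)/2` numbers.
#'
#' @param zk length-`K` per-population variances.
#' @param zkk length-`K` within-population covariances (may contain `NA` for
#'   populations of size 1 in empirical summaries).
#' @param zkl symmetric `K x K` matrix of cross-population covariances; the
#'   diagonal is set to `zkk`.
#' @param labels population labels.
#' @param sizes population sizes `N_k`.
#' @param source `"theoretical"` or `"empirical"`.
#' @return Object of class `block_summary`.
#' @export
block_summary <- function(zk, zkk, zkl, labels = NULL, sizes = NULL,
                          source = c("theoretical", "empirical")) {
  source <- match.arg(source)
  K <- length(zk)
  if (length(zkk) != K) stop("zkk must have length K", call. = FALSE)
  if (K == 1L && length(zkl) == 1L) zkl <- matrix(zkl, 1L, 1L)
  if (!is.matrix(zkl) || nrow(zkl) != K || ncol(zkl) != K) {
    stop("zkl must be a K x K matrix", call. = FALSE)
  }
  asym <- suppressWarnings(max(abs(zkl - t(zkl)), 0, na.rm = TRUE))
  if (is.finite(asym) && asym > 1e-8) {
    stop("zkl must be symmetric", call. = FALSE)
  }
  diag(zkl) <- zkk
  if (is.null(labels)) labels <- sprintf("pop%d", seq_len(K))
  structure(
    list(zk = as.numeric(zk), zkk = as.numeric(zkk), zkl = zkl,
         labels = as.character(labels),
         sizes = if (is.null(sizes)) NULL else as.integer(sizes),
         n_pops = K, source = source),
    class = "block_summary"
  )
}

#' @export
print.block_summary <- function(x, digits = 5, ...) {
  cat(sprintf("Block summary (%s), K = %d\n", x$source, x$n_pops))
  df <- data.frame(population = x$labels,
                   zk = signif(x$zk, digits),
                   zkk = signif(x$zkk, digits))
  print(df, row.names = FALSE)
  if (x$n_pops > 1L) {
    cat("Cross-population covariances z^kl:\n")
    print(signif(x$zkl, digits))
  }
  invisible(x)
}

#' An N x N genetic relationship matrix
#'
#' Wraps a symmetric `N x N` matrix and tags it as either an empirical GRM
#' (computed from observed genotypes) or a theoretical EGRM (the
#' expectation under the population model). Downstream operations that are
#' only exact on block-structured expectations refuse empirical input.
#'
#' @param values symmetric numeric matrix.
#' @param kind `"empirical-GRM"` or `"theoretical-EGRM"`.
#' @param structure optional [pop_structure()] the rows follow.
#' @param sample_ids optional row/column identifiers.
#' @param sym_tol symmetry tolerance.
#' @return Object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values,
                                kind = c("empirical-GRM", "theoretical-EGRM"),
                                structure = NULL, sample_ids = NULL,
                                sym_tol = 1e-8) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("values must be a square matrix", call. = FALSE)
  }
  scale <- max(1, max(abs(values)))
  if (max(abs(values - t(values))) > sym_tol * scale) {
    stop("relationship matrix is not symmetric within tolerance",
         call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (!is.null(structure) && structure$n_total != nrow(values)) {
    stop("structure size does not match matrix dimension", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(structure)) default_sample_ids(structure)
                  else sprintf("sample%d", seq_len(nrow(values)))
  }
  dimnames(values) <- list(sample_ids, sample_ids)
  base::structure(
    list(values = values, kind = kind, structure = structure,
         sample_ids = as.character(sample_ids), n = nrow(values)),
    class = "relationship_matrix"
  )
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s: %d x %d\n", x$kind, x$n, x$n))
  invisible(x)
}

# shared consistency check between a structure and a frequency table
check_pair <- function(structure, freqs) {
  if (!inherits(structure, "pop_structure")) {
    stop("structure must be a pop_structure", call. = FALSE)
  }
  if (!inherits(freqs, "freq_table")) {
    stop("freqs must be a freq_table", call. = FALSE)
  }
  if (freqs$n_pops != structure$n_pops) {
    stop(sprintf(
      "frequency table has %d populations but structure has %d",
      freqs$n_pops, structure$n_pops), call. = FALSE)
  }
  invisible(TRUE)
}
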