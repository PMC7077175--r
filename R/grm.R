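#' Standardize coded genotypes
#'
#' Applies the per-SNP standardization `Y(n, m) = (X(n, m) - mu_m) / sigma_m`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param norm a [norm_params()] with one `(mu, sigma)` pair per SNP.
#' @return Numeric `N x M` matrix of standardized genotypes, dimnames
#'   preserved.
#' @export
normalize_genotypes <- function(genotypes, norm) {
  if (!inherits(genotypes, "genotype_matrix")) {
    stop("genotypes must be a genotype_matrix", call. = FALSE)
  }
  if (!inherits(norm, "norm_params")) {
    stop("norm must be a norm_params", call. = FALSE)
  }
  X <- genotypes$values
  if (length(norm$mu) != ncol(X)) {
    stop("normalization parameters do not match the number of SNPs",
         call. = FALSE)
  }
  Y <- sweep(X, 2L, norm$mu, "-")
  sweep(Y, 2L, norm$sigma, "/")
}

#' Genetic relationship matrix from standardized genotypes
#'
#' `Z = (1/M) Y Y'`: diagonal entries are per-individual genotypic
#' variances, off-diagonal entries pairwise genotypic covariances, averaged
#' over SNPs.
#'
#' @param normalized numeric `N x M` matrix from [normalize_genotypes()].
#' @param structure optional [pop_structure()] to attach.
#' @return A [relationship_matrix()] of kind `"empirical-GRM"`.
#' @export
compute_grm <- function(normalized, structure = NULL) {
  if (!is.matrix(normalized) || ncol(normalized) < 1L) {
    stop("normalized must be a matrix with at least one SNP column",
         call. = FALSE)
  }
  Z <- tcrossprod(normalized) / ncol(normalized)
  relationship_matrix(Z, kind = "empirical-GRM", structure = structure,
                      sample_ids = rownames(normalized))
}

#' Estimate normalization parameters from observed genotypes
#'
#' Sample-based analogue of [genotype_moments()]: the coded-allele frequency
#' is estimated as `f_hat = column mean / 2` and `mu_hat = 2 f_hat`; the
#' standard deviation follows the chosen convention (`eigensoft`:
#' `sqrt(f_hat (1 - f_hat))`; `gcta`: `sqrt(2 f_hat (1 - f_hat))`;
#' `sample`: the observed column standard deviation).
#'
#' @param genotypes a [genotype_matrix()].
#' @param mode `"eigensoft"`, `"gcta"` or `"sample"`.
#' @param on_monomorphic `"error"` (default) raises on columns with zero
#'   estimated standard deviation; `"drop"` removes them with a warning and
#'   records the kept column indices in the `"kept"` attribute of the
#'   result.
#' @return A [norm_params()]; in drop mode, covering the kept columns only.
#' @export
estimate_norm_params <- function(genotypes,
                                 mode = c("gcta", "eigensoft", "sample"),
                                 on_monomorphic = c("error", "drop")) {
  mode <- match.arg(mode)
  on_monomorphic <- match.arg(on_monomorphic)
  if (!inherits(genotypes, "genotype_matrix")) {
    stop("genotypes must be a genotype_matrix", call. = FALSE)
  }
  X <- genotypes$values
  fhat <- colMeans(X) / 2
  mu <- 2 * fhat
  sigma2 <- switch(mode,
    eigensoft = fhat * (1 - fhat),
    gcta = 2 * fhat * (1 - fhat),
    sample = apply(X, 2L, stats::var)
  )
  bad <- which(!is.finite(sigma2) | sigma2 <= 0)
  if (length(bad)) {
    if (on_monomorphic == "error") {
      stop(sprintf("monomorphic SNP column(s): %s",
                   paste(genotypes$snp_ids[utils::head(bad, 5L)],
                         collapse = ", ")),
           call. = FALSE)
    }
    warning(sprintf("dropping %d monomorphic SNP column(s)", length(bad)),
            call. = FALSE)
    keep <- setdiff(seq_len(ncol(X)), bad)
    if (!length(keep)) {
      stop("all SNP columns are monomorphic", call. = FALSE)
    }
    out <- norm_params(mu[keep], sqrt(sigma2[keep]), mode)
    attr(out, "kept") <- keep
    return(out)
  }
  out <- norm_params(mu, sqrt(sigma2), mode)
  attr(out, "kept") <- seq_len(ncol(X))
  out
}

#' One-call empirical GRM from genotypes
#'
#' Convenience pipeline: estimate (or accept) normalization parameters,
#' standardize, and form `Z = (1/M) Y Y'`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param norm either a [norm_params()] (known-moment route) or a mode
#'   string passed to [estimate_norm_params()].
#' @param structure optional [pop_structure()].
#' @param on_monomorphic passed to [estimate_norm_params()] when `norm` is
#'   a mode string.
#' @return A [relationship_matrix()] of kind `"empirical-GRM"`.
#' @export
grm_from_genotypes <- function(genotypes, norm = "gcta", structure = NULL,
                               on_monomorphic = c("error", "drop")) {
  if (is.character(norm)) {
    norm <- estimate_norm_params(genotypes, norm, on_monomorphic)
    keep <- attr(norm, "kept")
    if (length(keep) != ncol(genotypes$values)) {
      genotypes <- genotype_matrix(
        genotypes$values[, keep, drop = FALSE],
        sample_ids = genotypes$sample_ids,
        snp_ids = genotypes$snp_ids[keep])
    }
  }
  compute_grm(normalize_genotypes(genotypes, norm), structure = structure)
}
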