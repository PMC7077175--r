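#' Pooled (total-population) coded-allele frequencies
#'
#' The coded-allele frequency of each SNP in the total population is the
#' size-weighted mean of the per-population frequencies,
#' `f_m = sum_k N_k f_km / N`.
#'
#' @param structure a [pop_structure()].
#' @param freqs a [freq_table()] with matching `K`.
#' @return Numeric length-`M` vector of total frequencies, each in `[0, 1]`.
#' @examples
#' ps <- pop_structure(c(3, 1))
#' ft <- freq_table(rbind(0.2, 0.8))
#' total_allele_frequency(ps, ft) # 0.35
#' @export
total_allele_frequency <- function(structure, freqs) {
  check_pair(structure, freqs)
  w <- structure$sizes / structure$n_total
  as.vector(crossprod(w, freqs$freqs))
}

#' Genotypic moments of each SNP in the total population
#'
#' Computes the per-SNP genotypic mean `mu_m` and standard deviation
#' `sigma_m` under one of several conventions:
#'
#' * `mixture`: exact moments of the genotype distribution, a mixture of
#'   `Binomial(2, f_km)` components weighted by `N_k / N`. The variance is
#'   `2 sum_k (N_k/N) f_km (1 - f_km) + 4 sum_{k<l} (N_k N_l / N^2)
#'   (f_km - f_lm)^2`, the within-population binomial term plus a
#'   between-population dispersion term over unordered population pairs.
#' * `total_binomial`: binomial moments at the pooled frequency,
#'   `mu = 2 f_m`, `sigma^2 = 2 f_m (1 - f_m)`.
#' * `eigensoft`: `mu = 2 f_m`, `sigma = sqrt(f_m (1 - f_m))` (the
#'   smartpca convention).
#' * `gcta`: `mu = 2 f_m`, `sigma = sqrt(2 f_m (1 - f_m))`.
#'
#' SNPs monomorphic in the total population have `sigma_m = 0` and cannot be
#' standardized; they raise an error naming the offending SNP. Callers that
#' prefer to drop them should filter beforehand (see
#' [estimate_norm_params()] for the sample-based analogue).
#'
#' @param structure a [pop_structure()].
#' @param freqs a [freq_table()].
#' @param mode moment convention, see Details.
#' @return A [norm_params()] object.
#' @examples
#' ps <- pop_structure(c(1, 1))
#' ft <- freq_table(rbind(0.2, 0.8))
#' genotype_moments(ps, ft, "mixture") # mu = 1, sigma^2 = 0.68
#' @export
genotype_moments <- function(structure, freqs,
                             mode = c("mixture", "total_binomial",
                                      "eigensoft", "gcta")) {
  mode <- match.arg(mode)
  check_pair(structure, freqs)
  f <- freqs$freqs
  K <- nrow(f)
  w <- structure$sizes / structure$n_total
  fm <- as.vector(crossprod(w, f))
  mu <- 2 * fm
  sigma2 <- switch(mode,
    mixture = {
      within <- 2 * as.vector(crossprod(w, f * (1 - f)))
      between <- numeric(ncol(f))
      if (K > 1L) {
        for (k in seq_len(K - 1L)) {
          for (l in seq.int(k + 1L, K)) {
            between <- between + w[k] * w[l] * (f[k, ] - f[l, ])^2
          }
        }
      }
      within + 4 * between
    },
    total_binomial = 2 * fm * (1 - fm),
    gcta = 2 * fm * (1 - fm),
    eigensoft = fm * (1 - fm)
  )
  bad <- which(sigma2 <= 0)
  if (length(bad)) {
    stop(sprintf(
      "SNP(s) monomorphic in the total population: %s",
      paste(freqs$snp_ids[utils::head(bad, 5L)], collapse = ", ")),
      call. = FALSE)
  }
  norm_params(mu, sqrt(sigma2), mode)
}

# half-open MAF bin boundaries, from rare to common
.maf_breaks <- c(0.0001, 0.01, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Assign SNPs to minor-allele-frequency bins
#'
#' The minor allele frequency is `min(f, 1 - f)` in the total population.
#' Six half-open bins are used, numbered from common to rare:
#' bin 1 = (0.4, 0.5], bin 2 = (0.3, 0.4], bin 3 = (0.2, 0.3],
#' bin 4 = (0.1, 0.2], bin 5 = (0.01, 0.1], bin 6 = (0.0001, 0.01].
#' SNPs with MAF at or below 0.0001 fall outside all bins and return `NA`.
#'
#' @param f_total numeric vector of total-population coded-allele
#'   frequencies in `[0, 1]`.
#' @return Integer vector of bin numbers 1-6, `NA` where the MAF is at or
#'   below 0.0001.
#' @examples
#' assign_maf_bin(c(0.45, 0.4, 0.99995)) # 1, 2, NA
#' @export
assign_maf_bin <- function(f_total) {
  f_total <- as.numeric(f_total)
  if (anyNA(f_total) || any(f_total < 0) || any(f_total > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  maf <- pmin(f_total, 1 - f_total)
  idx <- as.integer(cut(maf, breaks = .maf_breaks, right = TRUE))
  7L - idx
}

#' Boundaries of a MAF bin
#'
#' @param bin integer bin number in 1-6 (1 = most common, 6 = rare).
#' @return Numeric `c(lower, upper)`; the interval is half-open,
#'   `(lower, upper]`.
#' @export
maf_bin_range <- function(bin) {
  bin <- as.integer(bin)
  if (length(bin) != 1L || is.na(bin) || bin < 1L || bin > 6L) {
    stop("bin must be a single integer in 1..6", call. = FALSE)
  }
  i <- 7L - bin
  c(.maf_breaks[i], .maf_breaks[i + 1L])
}
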