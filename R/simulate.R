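# Run expr with a local RNG state seeded at `seed`, restoring the caller's
# stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a replicate sub-seed from a master seed
#'
#' Deterministic counter scheme: replicate `i` of master seed `s` uses
#' `(s + i * 1000003) mod (2^31 - 1)`. Experiments that loop over
#' replicates draw each replicate from its own substream, so results are
#' reproducible replicate-by-replicate and independent of loop order.
#'
#' @param master integer master seed.
#' @param i replicate counter (non-negative integer).
#' @return An integer seed.
#' @export
substream_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 + as.double(i) * 1000003) %%
               2147483647)
}

#' Simulate genotypes under within-population Hardy-Weinberg equilibrium
#'
#' Each genotype `X(n, m)` is an independent `Binomial(2, f_km)` draw,
#' where `k` is individual `n`'s population. Sites are independent (no
#' linkage disequilibrium) and individuals unrelated, matching the model
#' under which the EGRM is the exact expectation of the GRM.
#'
#' @param structure a [pop_structure()].
#' @param freqs a [freq_table()].
#' @param seed integer seed; the same seed always yields the same matrix.
#' @return A [genotype_matrix()] with samples ordered by population block.
#' @export
simulate_genotypes <- function(structure, freqs, seed) {
  check_pair(structure, freqs)
  f <- freqs$freqs
  M <- ncol(f)
  with_seed(seed, {
    rows <- lapply(seq_len(structure$n_pops), function(k) {
      nk <- structure$sizes[k]
      matrix(stats::rbinom(nk * M, size = 2L, prob = rep(f[k, ], each = nk)),
             nrow = nk, ncol = M)
    })
    genotype_matrix(do.call(rbind, rows),
                    sample_ids = default_sample_ids(structure),
                    snp_ids = freqs$snp_ids)
  })
}

#' Draw a synthetic per-population allele-frequency panel
#'
#' Stand-in for sampling real SNPs by MAF bin. For each SNP a
#' total-population frequency is drawn uniformly within the requested MAF
#' bin (or explicit range), then per-population frequencies are drawn from
#' the Balding-Nichols model, `f_k ~ Beta(f (1-F)/F, (1-f)(1-F)/F)`, whose
#' mean is `f` and variance `F f (1-f)`; the `divergence` parameter is the
#' Beta-model `F` and calibrates directly against single-SNP F_ST levels
#' (continental human populations are typically `F ~ 0.05-0.15`). With
#' `divergence = 0` all populations share the total frequency. Draws are
#' accepted only if the realized size-weighted total MAF lies in the
#' requested interval and the SNP is polymorphic in the total population.
#'
#' @param structure a [pop_structure()]; sizes weight the total frequency.
#' @param n_snps number of SNPs to draw.
#' @param bin MAF bin 1-6 (see [assign_maf_bin()]); alternative to
#'   `freq_range`.
#' @param freq_range explicit `c(lower, upper]` MAF interval.
#' @param divergence Beta-model `F >= 0` controlling between-population
#'   frequency spread.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap per SNP.
#' @return A [freq_table()].
#' @export
draw_frequency_panel <- function(structure, n_snps, bin = NULL,
                                 freq_range = NULL, divergence = 0.1,
                                 seed = 1L, max_attempts = 10000L) {
  if (is.null(freq_range)) {
    if (is.null(bin)) stop("provide either bin or freq_range", call. = FALSE)
    freq_range <- maf_bin_range(bin)
  }
  lo <- freq_range[1]; hi <- freq_range[2]
  if (!(lo >= 0 && hi <= 0.5 && lo < hi)) {
    stop("freq_range must be a non-empty sub-interval of [0, 0.5]",
         call. = FALSE)
  }
  if (divergence < 0) stop("divergence must be non-negative", call. = FALSE)
  K <- structure$n_pops
  w <- structure$sizes / structure$n_total
  with_seed(seed, {
    f <- matrix(NA_real_, K, n_snps)
    for (m in seq_len(n_snps)) {
      for (attempt in seq_len(max_attempts)) {
        ftot <- stats::runif(1, lo, hi)
        fk <- if (divergence == 0) {
          rep(ftot, K)
        } else {
          shape <- (1 - divergence) / divergence
          stats::rbeta(K, ftot * shape, (1 - ftot) * shape)
        }
        tot <- sum(w * fk)
        if (tot > 0 && tot < 1 &&
            min(tot, 1 - tot) > lo && min(tot, 1 - tot) <= hi) {
          f[, m] <- fk
          break
        }
      }
      if (anyNA(f[, m])) {
        stop(sprintf(
          "could not draw a SNP with total MAF in (%g, %g] after %d attempts",
          lo, hi, max_attempts), call. = FALSE)
      }
    }
    freq_table(f, pop_labels = structure$labels)
  })
}

#' Replicate convergence of empirical block summaries to theory
#'
#' Simulates `reps` genotype cohorts under the population model, computes
#' a GRM for each — standardizing either with the known theoretical
#' moments (`mode = "known"`, exact-mixture `mu_m`, `sigma_m`) or with
#' per-replicate sample estimates (`mode = "estimated"`, observed column
#' mean and standard deviation) — block-averages each GRM, and compares
#' the replicate means of `z^k` and `z^kk` to their theoretical values
#' with Monte-Carlo standard errors. In estimated mode, SNPs monomorphic
#' within a replicate are dropped from that replicate and counted.
#'
#' @param structure a [pop_structure()].
#' @param freqs a [freq_table()].
#' @param reps number of replicates, at least 2.
#' @param mode `"known"` or `"estimated"` moments.
#' @param seed master seed; replicate `r` uses [substream_seed()]`(seed, r)`.
#' @return Object of class `convergence_experiment`: a data frame `table`
#'   with columns `population`, `stat` (`zk`/`zkk`), `theoretical`,
#'   `mean`, `se`, plus fields `reps`, `mode`, `dropped_snps` (total
#'   column drops over replicates) and `skipped_reps`.
#' @export
convergence_experiment <- function(structure, freqs, reps,
                                   mode = c("known", "estimated"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  reps <- as.integer(reps)
  if (reps < 2L) stop("reps must be at least 2", call. = FALSE)
  check_pair(structure, freqs)
  norm_known <- genotype_moments(structure, freqs, "mixture")
  theory <- egrm_elements(structure, freqs, norm_known)
  K <- structure$n_pops
  zk_reps <- matrix(NA_real_, K, reps)
  zkk_reps <- matrix(NA_real_, K, reps)
  dropped <- 0L
  skipped <- 0L
  for (r in seq_len(reps)) {
    X <- simulate_genotypes(structure, freqs, substream_seed(seed, r))
    if (mode == "known") {
      Y <- normalize_genotypes(X, norm_known)
    } else {
      est <- withCallingHandlers(
        estimate_norm_params(X, mode = "sample", on_monomorphic = "drop"),
        warning = function(w) invokeRestart("muffleWarning"))
      keep <- attr(est, "kept")
      dropped <- dropped + (ncol(X$values) - length(keep))
      if (!length(keep)) {
        skipped <- skipped + 1L
        next
      }
      Xk <- genotype_matrix(X$values[, keep, drop = FALSE],
                            sample_ids = X$sample_ids,
                            snp_ids = X$snp_ids[keep])
      Y <- normalize_genotypes(Xk, est)
    }
    bs <- block_summaries(compute_grm(Y, structure = structure), structure)
    zk_reps[, r] <- bs$zk
    zkk_reps[, r] <- bs$zkk
  }
  used <- colSums(!is.na(zk_reps)) > 0
  mc_stats <- function(m) {
    list(mean = rowMeans(m, na.rm = TRUE),
         se = apply(m, 1L, function(x) {
           x <- x[!is.na(x)]
           stats::sd(x) / sqrt(length(x))
         }))
  }
  zk_s <- mc_stats(zk_reps)
  zkk_s <- mc_stats(zkk_reps)
  tab <- data.frame(
    population = rep(structure$labels, 2L),
    stat = rep(c("zk", "zkk"), each = K),
    theoretical = c(theory$zk, theory$zkk),
    mean = c(zk_s$mean, zkk_s$mean),
    se = c(zk_s$se, zkk_s$se),
    stringsAsFactors = FALSE
  )
  base::structure(
    list(table = tab, reps = sum(used), mode = mode,
         dropped_snps = dropped, skipped_reps = skipped, seed = seed),
    class = "convergence_experiment"
  )
}

#' @export
print.convergence_experiment <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Convergence experiment: %d replicates, %s moments, %d dropped SNP column(s)\n",
    x$reps, x$mode, x$dropped_snps))
  tab <- x$table
  tab$theoretical <- signif(tab$theoretical, digits)
  tab$mean <- signif(tab$mean, digits)
  tab$se <- signif(tab$se, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
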