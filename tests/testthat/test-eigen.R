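test_that("full spectrum of the worked example matches closed forms", {
  egrm <- assemble_egrm(toy_structure(), toy_summary())
  fs <- full_spectrum(egrm)
  expect_equal(fs$values, c(44 / 17, 8 / 17, 8 / 17, 8 / 17))
  expect_equal(sum(fs$values), 4)          # trace conservation
  expect_equal(sum(fs$variance_explained), 1)
  # orthonormality of the eigenvector basis
  expect_lt(max(abs(crossprod(fs$vectors) - diag(4))), 1e-8)

  id3 <- relationship_matrix(diag(3), "theoretical-EGRM")
  fs3 <- full_spectrum(id3)
  expect_equal(fs3$values, c(1, 1, 1))
  expect_equal(fs3$variance_explained, rep(1 / 3, 3))
})

test_that("structural spectrum comes from the K x K reduced matrix", {
  ps <- toy_structure()
  ss <- structural_spectrum(toy_summary(), ps)
  expect_equal(unname(ss$reduced_matrix),
               matrix(c(26, -18, -18, 26) / 17, 2L, 2L))
  expect_equal(ss$values, c(44 / 17, 8 / 17))
  expect_equal(ss$intra_values, c(8 / 17, 8 / 17))
  expect_identical(ss$intra_multiplicities, c(1L, 1L))

  # K = 1: single structural eigenvalue (z1 - z11) + N1 z11
  ps1 <- pop_structure(5L)
  bs1 <- block_summary(1.2, 0.1, matrix(0.1, 1, 1), sizes = 5L)
  ss1 <- structural_spectrum(bs1, ps1)
  expect_equal(ss1$values, (1.2 - 0.1) + 5 * 0.1)

  # no structure: B is diagonal, structural eigenvalues are the z^k
  bs0 <- block_summary(c(1.3, 1.1), c(0, 0), matrix(0, 2, 2),
                       sizes = c(3L, 4L))
  ss0 <- structural_spectrum(bs0, pop_structure(c(3L, 4L)))
  expect_equal(ss0$values, c(1.3, 1.1))
})

test_that("structural plus intra eigenvalues recover the full spectrum", {
  for (seed in 1:20) {
    case <- random_panel_case(seed)
    bs <- egrm_elements(case$structure, case$freqs,
                        genotype_moments(case$structure, case$freqs,
                                         "mixture"))
    ss <- structural_spectrum(bs, case$structure)
    analytic <- c(ss$values,
                  rep(ss$intra_values, times = ss$intra_multiplicities))
    fs <- full_spectrum(assemble_egrm(case$structure, bs))
    expect_multiset_equal(analytic, fs$values, tol = 1e-8)
    # every population contributes N_k - 1 copies of z^k - z^kk
    for (k in seq_len(case$structure$n_pops)) {
      hits <- sum(abs(fs$values - ss$intra_values[k]) < 1e-8)
      expect_gte(hits, case$structure$sizes[k] - 1L)
    }
  }
})

test_that("two-population closed-form eigenvalues match numeric decomposition", {
  # equal intra variance: lambda1 = N1 z11 + N2 z22 + sigma_W^2/2
  bs <- toy_summary()
  lam <- two_pop_eigenvalues(bs, toy_structure())
  expect_equal(unname(lam), c(44 / 17, 8 / 17), tolerance = 1e-12)
  sW2 <- sum(bs$zk - bs$zkk)
  expect_equal(unname(lam[1]), 2 * (9 / 17) + 2 * (9 / 17) + sW2 / 2)
  expect_equal(unname(lam[2]), sW2 / 2)

  # uncorrelated, zero-covariance case
  bs0 <- block_summary(c(1.3, 1.1), c(0, 0), matrix(0, 2, 2))
  lam0 <- two_pop_eigenvalues(bs0, pop_structure(c(3L, 4L)))
  expect_equal(unname(lam0), c(1.3, 1.1))

  # asymmetric case against the numeric oracle
  ps <- pop_structure(c(3L, 1L))
  zkl <- matrix(c(0.3, -0.25, -0.25, 0.2), 2L, 2L)
  bsA <- block_summary(c(1.2, 1.1), c(0.3, 0.2), zkl, sizes = c(3L, 1L))
  lamA <- two_pop_eigenvalues(bsA, ps)
  full <- eigen(assemble_egrm(ps, bsA)$values, symmetric = TRUE,
                only.values = TRUE)$values
  ssA <- structural_spectrum(bsA, ps)
  expect_equal(unname(lamA), ssA$values, tolerance = 1e-10)
  # the full numeric spectrum is the closed-form pair plus the intra values
  analytic <- c(lamA, rep(ssA$intra_values, ssA$intra_multiplicities))
  expect_multiset_equal(analytic, full, tol = 1e-10)

  expect_error(two_pop_eigenvalues(bsA, pop_structure(c(1L, 1L, 1L))),
               "two populations")
})

test_that("variance explained by the top k eigenvalues", {
  fs <- full_spectrum(assemble_egrm(toy_structure(), toy_summary()))
  expect_equal(variance_explained_topk(fs, 1L), 11 / 17)
  expect_equal(variance_explained_topk(fs, 4L), 1)
  fsI <- full_spectrum(relationship_matrix(diag(4), "theoretical-EGRM"))
  expect_equal(variance_explained_topk(fsI, 2L), 0.5)
  expect_error(variance_explained_topk(fs, 5L), "between 1 and")
  expect_error(variance_explained_topk(fs, 0L), "between 1 and")
})

test_that("representative points sit at the scaled block coordinates", {
  ps <- toy_structure()
  ss <- structural_spectrum(toy_summary(), ps)
  rp <- representative_points(ss, ps)
  expect_equal(unname(rp$centers[, 1]),
               c(sqrt(44 / 17) / 2, -sqrt(44 / 17) / 2))
  expect_equal(unname(rp$centers[, 2]), rep(sqrt(8 / 17) / 2, 2))
  expect_equal(unname(rp$grand_center), c(0, sqrt(8 / 17) / 2),
               tolerance = 1e-12)

  # K = 1: the population center is the grand center
  ps1 <- pop_structure(4L)
  ft1 <- freq_table(rbind(0.3))
  bs1 <- egrm_elements(ps1, ft1, genotype_moments(ps1, ft1, "mixture"))
  rp1 <- representative_points(structural_spectrum(bs1, ps1), ps1)
  expect_equal(unname(rp1$centers[1, ]), unname(rp1$grand_center))

  # refuses observed GRMs (block constancy does not hold exactly)
  grm <- relationship_matrix(diag(4), "empirical-GRM", structure = ps)
  expect_error(representative_points(grm, ps), "empirical")
  fs <- full_spectrum(grm)
  approx <- representative_points_empirical(fs, ps)
  expect_true(isTRUE(approx$approximate))
})

test_that("scaled structural coordinates reproduce the population distance", {
  for (seed in 41:60) {
    case <- random_panel_case(seed)
    bs <- egrm_elements(case$structure, case$freqs,
                        genotype_moments(case$structure, case$freqs,
                                         "mixture"))
    ss <- structural_spectrum(bs, case$structure)
    coords <- sweep(ss$vectors, 2L, sqrt(pmax(ss$values, 0)), "*")
    centered <- sweep(coords, 2L, colMeans(coords), "-")
    d2_coord <- sum(centered^2)
    d2 <- pop_distance_d2(ss$values, bs, case$structure)
    expect_equal(d2_coord, d2, tolerance = 1e-8)
  }
})

test_that("eigenvector signs are deterministic across repeated runs", {
  case <- random_panel_case(123)
  bs <- egrm_elements(case$structure, case$freqs,
                      genotype_moments(case$structure, case$freqs,
                                       "mixture"))
  eg <- assemble_egrm(case$structure, bs)
  fs1 <- full_spectrum(eg)
  fs2 <- full_spectrum(eg)
  expect_identical(fs1$vectors, fs2$vectors)
  ss1 <- structural_spectrum(bs, case$structure)
  ss2 <- structural_spectrum(bs, case$structure)
  expect_identical(ss1$vectors, ss2$vectors)
  # the convention itself: largest-magnitude entry is positive
  for (j in seq_len(ncol(fs1$vectors))) {
    expect_gte(fs1$vectors[which.max(abs(fs1$vectors[, j])), j], 0)
  }
})
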