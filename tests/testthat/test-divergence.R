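test_that("variance components and divergence ratios match the worked example", {
  ps <- toy_structure()
  bs <- toy_summary()
  vc <- variance_components(bs, ps)
  expect_equal(unname(vc["sigma_B2"]), 36 / 17)
  expect_equal(unname(vc["sigma_W2"]), 16 / 17)
  expect_equal(fpc(vc["sigma_B2"], vc["sigma_W2"]), 2.25)
  expect_equal(fpc_star(vc["sigma_B2"], vc["sigma_W2"]), 9 / 13)

  # conservation: components sum to the structural eigenvalue sum
  ss <- structural_spectrum(bs, ps)
  expect_equal(sum(vc), sum(ss$values), tolerance = 1e-12)
  expect_equal(sum(vc), 52 / 17)

  # single population has no inter-population component under mixture moments
  ps1 <- pop_structure(10L)
  ft1 <- freq_table(rbind(0.25))
  bs1 <- egrm_elements(ps1, ft1, genotype_moments(ps1, ft1, "mixture"))
  vc1 <- variance_components(bs1, ps1)
  expect_equal(unname(vc1["sigma_B2"]), 0)
  expect_equal(unname(vc1["sigma_W2"]), 1)

  expect_equal(fpc(0, 1), 0)
  expect_equal(fpc_star(0, 1), 0)
  expect_error(fpc(1, 0), "positive")
})

test_that("F_PC* = F_PC / (1 + F_PC) on random inputs", {
  set.seed(11)
  for (i in 1:25) {
    b <- runif(1, 0, 10)
    w <- runif(1, 0.1, 5)
    f <- fpc(b, w)
    expect_equal(fpc_star(b, w), f / (1 + f), tolerance = 1e-12)
    expect_gte(fpc_star(b, w), 0)
    expect_lt(fpc_star(b, w), 1)
  }
})

test_that("single-SNP F_PC matches the frequency closed form and the EGRM route", {
  ps <- toy_structure()
  expect_equal(single_snp_fpc(ps, c(0.2, 0.8)), 2.25)
  expect_equal(single_snp_fpc(ps, c(0.4, 0.4)), 0)
  expect_error(single_snp_fpc(ps, c(0, 1)), "undefined")

  # the sigma convention cancels for a single SNP
  for (mode in c("mixture", "total_binomial", "eigensoft", "gcta")) {
    for (seed in 1:10) {
      case <- random_panel_case(seed + 500, M = 1L)
      bs <- egrm_elements(case$structure, case$freqs,
                          genotype_moments(case$structure, case$freqs, mode))
      vc <- variance_components(bs, case$structure)
      expect_equal(single_snp_fpc(case$structure, case$freqs$freqs[, 1]),
                   fpc(vc["sigma_B2"], vc["sigma_W2"]),
                   tolerance = 1e-10)
    }
  }

  # f = (2c, c) with N = (1, 1): F_PC = c / (3 - 5c), decreasing as c -> 0
  ps11 <- pop_structure(c(1L, 1L))
  cs <- c(0.25, 0.1, 0.05, 0.01)
  vals <- vapply(cs, function(cc) single_snp_fpc(ps11, c(2 * cc, cc)),
                 numeric(1))
  expect_equal(vals, cs / (3 - 5 * cs), tolerance = 1e-12)
  expect_true(all(diff(vals) < 0))
})

test_that("F_ST solves the printed odds ratio and links to the N-PC variance ratio", {
  ps <- toy_structure()
  expect_equal(fst(ps, c(0.2, 0.8)), 0.36)
  expect_equal(fst(ps, c(0.3, 0.3)), 0)
  expect_error(fst(ps, c(0, 0)), "undefined")

  # sigma_B^2 / sum N_k (z^k - z^kk) = 2 F_ST / (1 - F_ST), any convention
  bs <- toy_summary()
  vc <- variance_components(bs, ps)
  npc_ratio <- unname(vc["sigma_B2"]) /
    sum(ps$sizes * (bs$zk - bs$zkk))
  expect_equal(npc_ratio, 1.125)
  f <- fst(ps, c(0.2, 0.8))
  expect_equal(npc_ratio, 2 * f / (1 - f), tolerance = 1e-12)
})

test_that("population distance d^2 matches the eigenvalue formula", {
  ps <- toy_structure()
  bs <- toy_summary()
  ss <- structural_spectrum(bs, ps)
  expect_equal(pop_distance_d2(ss$values, bs, ps), 44 / 17)

  # identical populations: the EGRM degenerates to z^k I, every structural
  # eigenvalue equals z^k (= 1 under mixture moments), and the distance
  # formula gives (K - 1) z^k; the coordinate-space oracle agrees.
  ps_eq <- pop_structure(c(5L, 5L, 5L))
  ft_eq <- freq_table(rbind(0.3, 0.3, 0.3))
  bs_eq <- egrm_elements(ps_eq, ft_eq,
                         genotype_moments(ps_eq, ft_eq, "mixture"))
  ss_eq <- structural_spectrum(bs_eq, ps_eq)
  expect_equal(pop_distance_d2(ss_eq$values, bs_eq, ps_eq), 2,
               tolerance = 1e-12)
  coords_eq <- sweep(ss_eq$vectors, 2L, sqrt(pmax(ss_eq$values, 0)), "*")
  dev_eq <- sweep(coords_eq, 2L, colMeans(coords_eq), "-")
  expect_equal(sum(dev_eq^2), 2, tolerance = 1e-10)

  # identical populations of unequal size: same K - 1 value
  ps_un <- pop_structure(c(2L, 7L))
  ft_un <- freq_table(rbind(0.3, 0.3))
  bs_un <- egrm_elements(ps_un, ft_un,
                         genotype_moments(ps_un, ft_un, "mixture"))
  ss_un <- structural_spectrum(bs_un, ps_un)
  expect_equal(pop_distance_d2(ss_un$values, bs_un, ps_un), 1,
               tolerance = 1e-12)

  expect_error(pop_distance_d2(c(1, 2, 3), bs, ps), "K structural")
})

test_that("d^2 shrinks as the coded-allele frequencies shrink proportionally", {
  ps <- pop_structure(c(100L, 100L))
  cs <- c(0.25, 0.1, 0.05, 0.01)
  d2s <- vapply(cs, function(cc) {
    ft <- freq_table(matrix(rep(c(2 * cc, cc), 100L), nrow = 2L))
    rep <- divergence_report(ps, ft, "mixture")
    rep$d2
  }, numeric(1))
  expect_true(all(diff(d2s) < 0))
})

test_that("F_PC and d^2 are non-increasing under proportional frequency shrinkage", {
  shrink <- c(1, 0.5, 0.25, 0.1, 0.05)
  for (seed in 1:25) {
    case <- random_panel_case(seed + 900, f_range = c(0.05, 0.45))
    vals <- vapply(shrink, function(cc) {
      ft <- freq_table(case$freqs$freqs * cc)
      rep <- divergence_report(case$structure, ft, "mixture")
      c(rep$f_pc, rep$d2)
    }, numeric(2))
    expect_true(all(diff(vals[1, ]) <= 1e-10))
    expect_true(all(diff(vals[2, ]) <= 1e-10))
  }
})

test_that("the pipeline report agrees with its parts", {
  ps <- toy_structure()
  rep <- divergence_report(ps, toy_freqs(), "mixture")
  expect_equal(rep$f_pc, 2.25)
  expect_equal(rep$f_pc_star, 9 / 13)
  expect_equal(rep$d2, 44 / 17)
  expect_identical(rep$k_pcs, 2L)
})
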