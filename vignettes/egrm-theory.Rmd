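---
title: "Expected GRMs, their eigen-structure, and divergence statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected GRMs, their eigen-structure, and divergence statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egrmpca)
```

## The model

Population-stratification PCA eigen-decomposes the genetic relationship
matrix (GRM)

$$\mathbf{Z} = \frac{1}{M}\,\mathbf{Y}\mathbf{Y}^\top,\qquad
\mathbf{Y}(n,m) = \frac{\mathbf{X}(n,m) - \mu_m}{\sigma_m},$$

where $\mathbf{X}$ is the $N \times M$ matrix of coded-allele counts and
$\mu_m$, $\sigma_m$ are the genotypic mean and standard deviation of SNP
$m$ in the total sample. Suppose the $N$ samples come from $K$
populations of sizes $N_1,\dots,N_K$, each SNP is in Hardy–Weinberg
equilibrium within each population with coded-allele frequency $f_{km}$,
sites are independent, and individuals are unrelated. Then each genotype
is a two-trial binomial draw and the expectation of the GRM — the
**EGRM** — is exactly block-structured: ordering samples by population,
its diagonal entries are the per-population genotypic variances

$$z^k = \frac{1}{M}\sum_m
  \frac{2f_{km}(1-f_{km}) + (2f_{km}-\mu_m)^2}{\sigma_m^2},$$

within-population off-diagonal entries are

$$z^{kk} = \frac{1}{M}\sum_m \frac{(2f_{km}-\mu_m)^2}{\sigma_m^2},$$

and every entry of the $(k,l)$ cross block is

$$z^{kl} = \frac{1}{M}\sum_m
  \frac{(2f_{km}-\mu_m)(2f_{lm}-\mu_m)}{\sigma_m^2}.$$

These $2K + K(K-1)/2$ numbers (`block_summary`) carry all information in
the EGRM; `egrm_elements()` computes them and `assemble_egrm()`
materializes the dense matrix only when needed.

### Moment conventions

The standardization moments are a modelling choice, exposed as explicit
modes rather than a hidden default:

* **mixture** — the exact moments of the genotype distribution, a
  binomial mixture over populations: $\mu_m = 2f_m$ with
  $f_m = \sum_k N_k f_{km}/N$, and
  $$\sigma_m^2 = 2\sum_k \tfrac{N_k}{N} f_{km}(1-f_{km})
    + 4\sum_{k<l}\tfrac{N_kN_l}{N^2}(f_{km}-f_{lm})^2.$$
  The between-population term runs over *unordered* pairs: only then does
  the expression equal the exact mixture variance by the law of total
  variance, which the test suite verifies against brute-force enumeration
  of the mixture distribution. Under this convention $z^k$ need not be 1,
  but the population-size-weighted average of the blocks centres exactly
  (row sums equal $z^k - z^{kk}$).
* **total_binomial** — $\sigma_m^2 = 2f_m(1-f_m)$, the binomial variance
  at the pooled frequency. This ignores the between-population
  dispersion, so $z^k \ge 1$ in stratified samples; with a single
  population the EGRM is exactly the identity.
* **eigensoft** / **gcta** — $\sigma_m = \sqrt{f_m(1-f_m)}$ and
  $\sqrt{2f_m(1-f_m)}$, the conventions of the two standard PCA tools.
  With the eigensoft convention diagonals sit near 2 rather than 1; we
  expose the mode as-is and leave any rescaling to the caller, since no
  canonical choice exists that reproduces unit diagonals under it.

SNPs monomorphic in the total population have $\sigma_m = 0$ and are
indivisible from the model: the core functions raise an error naming the
SNP, and pipeline-level callers (`estimate_norm_params()`,
`grm_from_genotypes()`, the replicate experiment) may instead drop such
columns with a warning and a count. Missing genotypes are rejected
outright — mean-imputation would silently change the GRM definition.

## Eigen-structure

For each population the EGRM has $N_k - 1$ eigenvalues equal to the
intra-population variance $z^k - z^{kk}$. The remaining $K$
"structural" eigenpairs carry *all* inter-population variance and are
computed exactly from the $K\times K$ reduced matrix
$B_{kk} = (z^k - z^{kk}) + N_k z^{kk}$,
$B_{kl} = \sqrt{N_kN_l}\,z^{kl}$, whose eigenvectors map back to
block-constant vectors (value $u_k/\sqrt{N_k}$ inside block $k$).
`structural_spectrum()` implements this; working on $B$ instead of
thresholding the full spectrum separates structural from intra
eigenvalues even when they are numerically degenerate (in the worked
example below, $\lambda_2$ equals the intra eigenvalue exactly, so
magnitude sorting could not tell them apart). For $K = 2$,
`two_pop_eigenvalues()` evaluates the closed form
$\lambda_{1,2} = \tfrac12\bigl[N_1z^{11}+N_2z^{22}+(z^1-z^{11})+(z^2-z^{22})
\pm\sqrt{a}\bigr]$ with
$a = [(z^1-z^{11})-(z^2-z^{22})+N_1z^{11}-N_2z^{22}]^2+4N_1N_2(z^{12})^2$.

Eigenvector signs are fixed deterministically: the largest-magnitude
entry of each vector is made positive, ties broken by lowest index, with
ties detected at a relative tolerance of $10^{-9}$ so that entries equal
up to floating-point noise count as tied. Within a numerically repeated
eigenvalue the basis is whatever LAPACK returns after sign fixing; tests
compare invariant subspaces (or eigenvalue multisets), never individual
vectors of a degenerate space.

## Divergence statistics

The structural eigenvalues sum to $\sigma_B^2 + \sigma_W^2$ with
$\sigma_B^2 = \sum_k N_k z^{kk}$ (inter-population) and
$\sigma_W^2 = \sum_k (z^k - z^{kk})$ (intra-population). Divergence over
the $K$ population-informative PCs is measured by

$$\mathrm{F}_{PC} = \sigma_B^2/\sigma_W^2, \qquad
  \mathrm{F}_{PC}^{*} = \sigma_B^2/(\sigma_B^2+\sigma_W^2),$$

and by the population distance

$$d^2 = \sum_k \lambda_k - \frac{1}{N}\sum_k N_k (z^k - z^{kk}),$$

the sum over samples of squared deviations from the grand centre in
$\sqrt{\lambda}$-scaled structural coordinates. Multi-SNP
$\mathrm{F}_{PC}$ aggregates through the pooled variance components, not
by averaging per-SNP ratios — that is what the definition above states
on a panel. $\mathrm{F}_{PC}$ depends on the $\sigma_m$ convention for
$M > 1$; for a single SNP the convention cancels and the closed form
$\mathrm{F}_{PC} = 2\sum_k N_k(f_k-f)^2 / \sum_k f_k(1-f_k)$ applies
(`single_snp_fpc()`), alongside Wright's fixation index solved from
$\mathrm{F}_{ST}/(1-\mathrm{F}_{ST}) =
\sum_k N_k(f_k-f)^2/\sum_k N_kf_k(1-f_k)$ (`fst()`). Had
$\mathrm{F}_{PC}$ been defined over all $N$ PCs instead of the $K$
informative ones, it would equal $2\mathrm{F}_{ST}/(1-\mathrm{F}_{ST})$;
the suite checks this identity per SNP at $10^{-10}$.

A worked example used throughout the tests: two populations of two
individuals and one SNP with frequencies 0.2 / 0.8. Mixture moments give
$\mu = 1$, $\sigma^2 = 0.68$, hence $z^1 = z^2 = 1$,
$z^{11} = z^{22} = 9/17$, $z^{12} = -9/17$; structural eigenvalues
$44/17$ and $8/17$; $\mathrm{F}_{PC} = 2.25$,
$\mathrm{F}_{PC}^{*} = 9/13$, $d^2 = 44/17$.

```{r toy}
ps <- pop_structure(c(2, 2), c("A", "B"))
ft <- freq_table(rbind(0.2, 0.8), snp_ids = "rs1", pop_labels = ps$labels)
divergence_report(ps, ft, "mixture")
structural_spectrum(egrm_elements(ps, ft, genotype_moments(ps, ft)), ps)
```

### Degenerate cases

Two degenerate behaviours are worth stating explicitly. First, when all
populations share identical frequencies the EGRM collapses to $z^k\,I$
and every structural eigenvalue equals $z^k$; the distance formula then
yields $d^2 = (K-1)\,z^k$, *not* zero. The structural eigenvectors are an
arbitrary basis of a fully degenerate space, so $d^2$ here reflects the
block-constant parametrization rather than genuine separation — a reason
to read $d^2$ alongside $\mathrm{F}_{PC}$ (which is 0 in this case), not
in isolation. Second, representative points
(`representative_points()`) are exact only for theoretical EGRMs, whose
members share block-constant coordinates; for observed GRMs the
within-population average of scaled coordinates is provided as an
explicitly approximate variant.

## The synthetic-data generator

`simulate_genotypes()` draws each genotype independently as
$\mathrm{Binomial}(2, f_{km})$ — exactly the model under which the EGRM
is the expectation of the GRM. It emulates within-population
Hardy–Weinberg equilibrium, site independence and unrelated individuals;
it does **not** emulate linkage disequilibrium, inbreeding, relatedness,
genotyping error or missingness. Tests passing under this generator
validate the mathematics of the EGRM theory, not robustness of PCA to
those real-data features (by linearity of expectation the EGRM formulas
themselves survive LD, but convergence of the GRM to the EGRM slows).

`draw_frequency_panel()` stands in for sampling real SNPs by MAF bin.
Per SNP it draws a total-population frequency uniformly within the
requested half-open MAF bin — the six bins (0.4,0.5], (0.3,0.4],
(0.2,0.3], (0.1,0.2], (0.01,0.1], (0.0001,0.01] are numbered 1–6 from
common to rare — then draws per-population frequencies from the
Balding–Nichols model
$f_k \sim \mathrm{Beta}\bigl(f\tfrac{1-F}{F},\,(1-f)\tfrac{1-F}{F}\bigr)$,
with mean $f$ and variance $F f(1-f)$. The `divergence` parameter is the
Beta-model $F$: it calibrates directly against single-SNP
$\mathrm{F}_{ST}$, so `divergence = 0.1` produces continental-scale
differentiation (realized mean $\mathrm{F}_{ST} \approx 0.08$ on common
panels); human within-continent structure is nearer 0.01–0.05.
Draws are rejection-sampled until the realized size-weighted total MAF
falls inside the requested bin and the SNP is polymorphic overall.
Bin boundaries are compared exactly as given — no rounding.

All randomness flows from one integer master seed. Replicated
experiments derive per-replicate substreams by a counter scheme,
`substream_seed(master, i) = (master + i * 1000003) mod (2^31 - 1)`, so
replicate $r$ is reproducible in isolation and results do not depend on
loop order. Generators save and restore the caller's RNG state.

## The replicate convergence experiment

`convergence_experiment()` contrasts the two normalization routes the
theory distinguishes: *known* moments (the exact mixture $\mu_m$,
$\sigma_m$, as assumed in the derivations) versus *estimated* moments
(per-replicate sample mean and standard deviation, as practice forces).
For each replicate it simulates a cohort, computes the GRM,
block-averages it, and reports replicate means with Monte-Carlo standard
errors next to the theoretical $z^k$, $z^{kk}$. With common SNPs the two
routes agree; with a rare SNP (f ≈ 0.005) the estimated route acquires a
systematic negative bias in the covariance elements $z^{kk}$ of order
$1/N$ — small in absolute terms but comparable to the rare-SNP $z^{kk}$
itself, while the known route stays unbiased. The acceptance suite runs
this at 5 populations × 500 individuals and 100 replicates, asserting
3-standard-error agreement for the common SNP and the known-vs-estimated
ordering on the rare SNP's covariance elements.

## Numerical choices and problem sizes

* Eigen-decompositions use LAPACK's symmetric solver
  (`eigen(symmetric = TRUE)`); matrices are symmetrized
  (`(Z + Z')/2`) after an asymmetry check at relative $10^{-8}$.
* Structural eigenvalue identities are asserted at $10^{-10}$ (exact
  algebra), spectrum multiset equalities at $10^{-8}$ (accumulated
  round-off over $N$ up to 250), Monte-Carlo comparisons at 3 standard
  errors.
* The randomized property tests run 200 EGRM instances with
  $K \in 1..5$, $N_k \in 1..50$; the GRM-to-EGRM convergence check uses
  $N = 400$ with $M \in \{10^3, 10^4, 10^5\}$ and verifies the
  $1/\sqrt{M}$ error rate by a log–log slope in $(-0.75, -0.25)$; the
  replicate experiment uses 2500 individuals. These sizes make the full
  suite complete in a few minutes on one core while leaving Monte-Carlo
  noise well below the asserted tolerances.
* `fpc()` refuses $\sigma_W^2 \le 0$; `single_snp_fpc()` and `fst()`
  refuse SNPs fixed in every population; populations of size one report
  their empirical $z^{kk}$ as missing rather than zero.

## Known limitations

* The theory treats allele frequencies as known constants; frequency
  estimation error enters only through the explicit `estimated` mode of
  the convergence experiment.
* No LD-aware convergence rates, no relatedness, no missing-data
  handling, no Tracy–Widom significance testing of eigenvalues, and no
  outlier-removal step as in EIGENSOFT's pipeline.
* The dense EGRM is materialized in memory when asked for; block
  summaries and the reduced matrix cover biobank-scale $N$, but
  `assemble_egrm()`/`full_spectrum()` do not.
* The Balding–Nichols panel generator draws sites independently; it is a
  calibration device, not a demographic model.
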