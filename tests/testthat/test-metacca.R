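test_that("beta normalization: arithmetic, domain errors, clamping", {
  expect_equal(normalize_beta(0, 0.3, 50), 0)
  expect_equal(normalize_beta(0.05, 0.01, 100), 0.5)
  expect_equal(normalize_beta(10, 0.001, 100), 0.999)   # clamp
  expect_equal(normalize_beta(-10, 0.001, 100), -0.999)
  expect_error(normalize_beta(0.1, 0, 100), "se")
  expect_error(normalize_beta(0.1, 0.1, 2), "n")
})

test_that("normalized beta approximates the genotype-phenotype Pearson correlation", {
  # oracle: direct correlation on simulated individual-level data
  set.seed(42)
  n <- 5000
  x <- rbinom(n, 2, 0.3)
  y <- 0.1 * scale(x)[, 1] + rnorm(n)
  y <- scale(y)[, 1]
  fit <- summary(lm(y ~ x))$coefficients
  expect_lt(abs(normalize_beta(fit["x", 1], fit["x", 2], n) - cor(x, y)),
            0.02)
})

test_that("shrinkage to positive definiteness behaves per its contract", {
  I4 <- diag(4)
  out <- shrink_to_pd(I4)
  expect_equal(unclass(out), I4, ignore_attr = TRUE)
  expect_equal(attr(out, "iterations"), 0L)

  # 2x2 equicorrelation with a = 1: min eigenvalue is 1 - a, so the smallest
  # t with 1 - 0.999^t >= 1e-8 is t = 1
  S <- matrix(c(1, 1, 1, 1), 2)
  out <- shrink_to_pd(S)
  t_expect <- which(1 - 0.999^(1:10) >= 1e-8)[1]
  expect_equal(attr(out, "iterations"), t_expect)
  expect_equal(out[1, 2], 0.999^t_expect)
  expect_gte(min(eigen(out)$values), 1e-8)
  expect_equal(diag(out), c(1, 1))  # diagonal untouched

  # already-PD matrix unchanged; asymmetric input rejected
  P <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(unclass(shrink_to_pd(P)), P, ignore_attr = TRUE)
  expect_error(shrink_to_pd(matrix(c(1, 0.5, 0.1, 1), 2)), "asymmetric")

  # property: only off-diagonals change and the floor is respected
  set.seed(9)
  for (i in 1:10) {
    A <- tcrossprod(matrix(rnorm(12), 4, 3))
    D <- diag(1 / sqrt(diag(A)))
    R <- D %*% A %*% D   # rank-deficient correlation matrix
    out <- shrink_to_pd(R)
    expect_equal(diag(out), diag(R))
    expect_gte(min(eigen(out)$values), 1e-8 - 1e-12)
  }
})

test_that("canonical correlations: closed cases and invariants", {
  # 1-D CCA is |correlation|
  expect_equal(canonical_correlations(diag(1), matrix(-0.4), diag(1)), 0.4)
  # zero cross-block -> all zero; count = min(m, K), sorted descending in [0,1]
  cc <- canonical_correlations(diag(3), matrix(0, 3, 2), diag(2))
  expect_equal(cc, c(0, 0))
  set.seed(3)
  for (i in 1:10) {
    m <- sample(2:6, 1); K <- sample(2:4, 1)
    sxx <- shrink_to_pd(cor(matrix(rnorm(50 * m), 50, m)))
    syy <- shrink_to_pd(cor(matrix(rnorm(50 * K), 50, K)))
    sxy <- matrix(rnorm(m * K, sd = 0.1), m, K)
    cc <- canonical_correlations(sxx, sxy, syy)
    expect_length(cc, min(m, K))
    expect_true(all(diff(cc) <= 1e-12))
    expect_true(all(cc >= 0 & cc <= 1))
    # permuting SNP order leaves the values unchanged
    p <- sample(m)
    cc_perm <- canonical_correlations(sxx[p, p], sxy[p, , drop = FALSE], syy)
    expect_equal(cc_perm, cc, tolerance = 1e-10)
  }
})

test_that("summary-level CCA agrees with classical CCA on individual-level data", {
  # oracle: stats::cancor on the very individuals that produced the summaries
  cfg <- sim_config(n_genes = 1, snps_per_gene = c(5, 5),
                    snps_per_gene_mean = 5, ld_rho = 0.5,
                    traits = c("FG", "HDL", "TG"),
                    per_trait_n = c(FG = 2000, HDL = 2000, TG = 2000),
                    n_individuals = 2000, n_pleio = 1, n_single = 0,
                    h2_per_gene = 0.02, seed = 31)
  scn <- make_scenario(cfg)
  h <- harmonize_traits(scn$tables, scn$panel)
  blk <- build_gene_block("GENE001", h$snps$snp, h, scn$panel)
  syy <- cor(scn$phenotypes)
  r1 <- canonical_correlations(shrink_to_pd(blk$sigma_xx), blk$sigma_xy,
                               shrink_to_pd(syy))[1]
  oracle <- max(cancor(scale(scn$panel$dosages), scale(scn$phenotypes))$cor)
  expect_lt(abs(r1 - oracle), 0.02)
})

test_that("Bartlett p-value: closed forms and monotonicity", {
  expect_equal(cca_pvalue(0, n = 100, m = 1, K = 1)$p_value, 1)
  # m = K = 1 specializes to a 1-df chi-square tail with Bartlett's
  # coefficient n - 1 - (1 + 1 + 1)/2 = n - 2.5 (~ n - 2 for large n)
  r <- 0.25; n <- 500
  pv <- cca_pvalue(r, n, 1, 1)
  expect_equal(pv$statistic, -(n - 2.5) * log(1 - r^2))
  expect_equal(pv$p_value,
               pchisq(-(n - 2.5) * log(1 - r^2), 1, lower.tail = FALSE))
  expect_equal(pv$statistic, -(n - 2) * log(1 - r^2), tolerance = 2e-3)
  # monotone decreasing in each canonical correlation
  ps <- vapply(seq(0, 0.5, by = 0.05),
               function(r) cca_pvalue(c(r, 0.1), 1000, 4, 2)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(cca_pvalue(0.1, n = 8, m = 4, K = 6), "too small")
})

test_that("run_metacca applies Bonferroni control and ranks a planted gene first", {
  # 10 blocks, one with real signal; threshold = alpha / 10
  set.seed(77)
  n <- 5000
  R <- shrink_to_pd(0.5^abs(outer(1:3, 1:3, "-")))
  S <- shrink_to_pd(engage_trait_cor()[c("HDL", "TG"), c("HDL", "TG")])
  blocks <- lapply(1:10, function(i) {
    xy <- simulate_null_xy(1, R, S, n, seed = 100 + i)[[1]]
    if (i == 4) xy <- xy + outer(c(0.15, 0.075, 0), c(1, 1))
    structure(list(gene = sprintf("G%02d", i), snp_ids = letters[1:3],
                   sigma_xx = unclass(R), sigma_xy = xy,
                   n_effective = n), class = "gene_block")
  })
  res <- run_metacca(blocks, diag(2) * 0 + unclass(S), alpha = 0.05)
  expect_equal(attr(res, "threshold"), 0.005)
  expect_equal(res$gene[1], "G04")
  expect_true(res$significant[1])
  expect_true(all(diff(res$p) >= 0))
  expect_equal(attr(res, "n_tested"), 10L)
})

test_that("gene blocks have the documented shapes and per-trait normalization", {
  t1 <- make_sumstats("FG", c("s1", "s2", "s3"), beta = c(0.1, 0.2, 0.3),
                      se = 0.1, n = 46694)
  t2 <- make_sumstats("FI", c("s1", "s2", "s3"), beta = c(0.0, -0.1, 0.2),
                      se = 0.1, n = 24245)
  set.seed(8)
  dos <- matrix(rbinom(300, 2, 0.4), 100, 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
  panel <- make_test_panel(dos)
  h <- harmonize_traits(list(t1, t2), panel)
  blk <- build_gene_block("G", c("s1", "s2", "s3"), h, panel)
  expect_equal(dim(blk$sigma_xy), c(3L, 2L))
  expect_equal(dim(blk$sigma_xx), c(3L, 3L))
  # each trait column normalized with its own n
  expect_equal(unname(blk$sigma_xy[, "FG"]),
               normalize_beta(c(0.1, 0.2, 0.3), 0.1, 46694))
  expect_equal(unname(blk$sigma_xy[, "FI"]),
               normalize_beta(c(0.0, -0.1, 0.2), 0.1, 24245))
  expect_equal(blk$n_effective, 24245L)

  blk1 <- build_gene_block("G1", "s1", h, panel)
  expect_equal(dim(blk1$sigma_xx), c(1L, 1L))
  expect_equal(dim(blk1$sigma_xy), c(1L, 2L))
})
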