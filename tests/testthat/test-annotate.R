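test_that("harmonization intersects, flips swapped alleles and drops ambiguous SNPs", {
  t1 <- make_sumstats("T1", c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.3),
                      se = 0.1, n = 1000)
  # rs2 has EA/OA swapped; rs4 replaces rs3 (intersection of size 2)
  t2 <- make_sumstats("T2", c("rs1", "rs2", "rs4"), beta = c(0.1, 0.3, 0.4),
                      se = 0.1, n = 1000,
                      ea = c("A", "G", "A"), oa = c("G", "A", "G"))
  h <- harmonize_traits(list(t1, t2))
  expect_identical(h$snps$snp, c("rs1", "rs2"))
  expect_equal(unname(h$beta["rs2", "T2"]), -0.3)
  expect_equal(unname(h$report[["n_flipped"]]), 1)

  # strand-ambiguous SNP dropped wherever it appears
  a1 <- make_sumstats("T1", c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.1,
                      n = 100, ea = c("A", "A"), oa = c("T", "G"))
  a2 <- make_sumstats("T2", c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.1,
                      n = 100, ea = c("A", "A"), oa = c("T", "G"))
  h <- harmonize_traits(list(a1, a2))
  expect_identical(h$snps$snp, "rs2")
  expect_equal(unname(h$report[["n_dropped_ambiguous"]]), 1)

  # allele mismatch dropped and counted
  m2 <- make_sumstats("T2", c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.1,
                      n = 100, ea = c("A", "C"), oa = c("T", "G"))
  h <- harmonize_traits(list(a1, m2))
  expect_equal(nrow(h$snps), 0L)
  expect_equal(unname(h$report[["n_dropped_mismatch"]]), 1)

  # empty SNP intersection is an error
  d2 <- make_sumstats("T2", "rs9", beta = 0.2, se = 0.1, n = 100)
  expect_error(harmonize_traits(list(a1, d2)), "no SNPs shared")
})

test_that("harmonization is idempotent", {
  t1 <- make_sumstats("T1", c("rs1", "rs2", "rs3"),
                      beta = c(0.1, -0.2, 0.3), se = c(0.1, 0.2, 0.3),
                      n = 1000)
  t2 <- make_sumstats("T2", c("rs3", "rs1", "rs2"),
                      beta = c(0.5, 0.2, -0.4), se = c(0.3, 0.1, 0.2),
                      n = 2000, ea = c("G", "A", "G"), oa = c("A", "G", "A"))
  h1 <- harmonize_traits(list(t1, t2))
  h2 <- harmonize_traits(harmonized_to_tables(h1))
  expect_equal(h2$snps, h1$snps)
  expect_equal(h2$beta, h1$beta)
  expect_equal(unname(h2$report[["n_flipped"]]), 0)
})

test_that("SNP-to-gene assignment respects inclusive boundaries, overlap and flank", {
  ranges <- data.frame(chrom = c("1", "1", "2"),
                       start = c(100L, 150L, 100L),
                       end = c(200L, 250L, 200L),
                       gene = c("G1", "G2", "G3"),
                       stringsAsFactors = FALSE)
  snps <- data.frame(snp = c("s_at_start", "s_overlap", "s_past_end", "s_chr2"),
                     chrom = c("1", "1", "1", "2"),
                     pos = c(100L, 180L, 201L, 150L),
                     stringsAsFactors = FALSE)
  map0 <- assign_snps_to_genes(snps, ranges, flank = 0)
  expect_true("s_at_start" %in% map0$G1)          # pos == start included
  expect_true(all(c("G1", "G2") %in%
                  names(Filter(function(x) "s_overlap" %in% x, map0))))
  expect_false("s_past_end" %in% map0$G1)         # 1 bp past end, flank 0
  expect_identical(map0$G3, "s_chr2")             # chromosome matching

  map1 <- assign_snps_to_genes(snps, ranges, flank = 1)
  expect_true("s_past_end" %in% map1$G1)          # flank 1 pulls it in

  # flank > 0 yields a superset mapping (property, random instance)
  set.seed(11)
  rs <- data.frame(chrom = "1", start = sort(sample(1:5000, 30)),
                   gene = sprintf("R%02d", 1:30), stringsAsFactors = FALSE)
  rs$end <- rs$start + sample(50:500, 30, replace = TRUE)
  ss <- data.frame(snp = sprintf("s%03d", 1:200), chrom = "1",
                   pos = sample(1:6000, 200), stringsAsFactors = FALSE)
  m0 <- assign_snps_to_genes(ss, rs, flank = 0)
  mf <- assign_snps_to_genes(ss, rs, flank = 100)
  for (g in names(m0)) expect_true(all(m0[[g]] %in% mf[[g]]))
})

test_that("LD computation matches expectations and a sampling-error bound", {
  x <- c(0, 1, 2, 0, 1, 2, 1, 0)
  dos <- cbind(a = x, b = x, c = 2 - x)
  panel <- make_test_panel(dos)
  ld <- compute_ld(panel, c("a", "b", "c"))
  expect_equal(ld["a", "b"], 1)
  expect_equal(ld["a", "c"], -1)
  expect_equal(diag(ld), c(a = 1, b = 1, c = 1))
  expect_error(compute_ld(panel, c("a", "zzz")), "zzz")

  # mean imputation of missing dosages keeps correlations defined
  dos_na <- dos; dos_na[1, "a"] <- NA
  expect_silent(ld2 <- compute_ld(make_test_panel(dos_na), c("a", "b")))
  expect_true(abs(ld2["a", "b"]) <= 1)

  # independent columns, 10,000 individuals: all |r| < 0.05 (~3/sqrt(n) bound)
  set.seed(21)
  big <- matrix(rbinom(10000 * 12, 2, 0.3), 10000, 12,
                dimnames = list(NULL, sprintf("x%02d", 1:12)))
  ldb <- compute_ld(make_test_panel(big), colnames(big))
  expect_lt(max(abs(ldb[upper.tri(ldb)])), 0.05)
})

test_that("greedy pruning keeps first of correlated pairs and matches brute force", {
  ld2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(prune_ld(ld2), "a")

  I5 <- diag(5); dimnames(I5) <- list(letters[1:5], letters[1:5])
  expect_identical(prune_ld(I5), letters[1:5])

  # oracle: independent re-implementation of the greedy definition
  brute_prune <- function(ld, r2max) {
    kept <- character(0)
    for (s in colnames(ld)) {
      ok <- TRUE
      for (k in kept) if (ld[s, k]^2 > r2max) ok <- FALSE
      if (ok) kept <- c(kept, s)
    }
    kept
  }
  set.seed(5)
  for (rep in 1:20) {
    Z <- matrix(rnorm(60 * 5), 60, 5) %*%
      chol(shrink_to_pd(0.6^abs(outer(1:5, 1:5, "-"))))
    ld <- cor(Z); dimnames(ld) <- list(letters[1:5], letters[1:5])
    for (r2max in c(0.01, 0.1, 0.5)) {
      kept <- prune_ld(ld, r2max)
      expect_identical(kept, brute_prune(ld, r2max))
      if (length(kept) > 1) {
        sub <- ld[kept, kept]
        expect_lte(max(sub[upper.tri(sub)]^2), r2max)
      }
    }
  }
})

test_that("per-gene pruning leaves every kept pair at r2 <= threshold", {
  scn <- make_scenario(small_sim_config(seed = 3))
  h <- harmonize_traits(scn$tables, scn$panel)
  gm <- assign_snps_to_genes(h$snps, scn$gene_ranges)
  pm <- prune_gene_map(gm, scn$panel, r2_max = 0.01)
  for (g in names(pm)) {
    expect_gte(length(pm[[g]]), 1)
    if (length(pm[[g]]) > 1) {
      sub <- compute_ld(scn$panel, pm[[g]])
      expect_lte(max(sub[upper.tri(sub)]^2), 0.01)
    }
  }
})
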