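## Summary-level canonical correlation analysis per gene: covariance-block
## assembly, positive-definiteness shrinkage, canonical correlations and a
## Bartlett chi-square significance test with Bonferroni control.

#' Normalize a regression coefficient to the correlation scale
#'
#' `beta / (sqrt(n) * se)`, clamped to `[-0.999, 0.999]` so SNP-trait entries
#' stay inside the correlation domain even when the SE is tiny. For a
#' univariate regression of a standardized trait on a SNP this approximates
#' the sample Pearson correlation between genotype and phenotype.
#'
#' @param beta regression coefficient(s).
#' @param se standard error(s), strictly positive.
#' @param n sample size(s), > 2.
#' @return value(s) in (-1, 1).
#' @export
normalize_beta <- function(beta, se, n) {
  if (any(!is.finite(se)) || any(se <= 0)) stopf("se must be positive")
  if (any(!is.finite(n)) || any(n <= 2)) stopf("n must exceed 2")
  pmax(pmin(beta / (sqrt(n) * se), 0.999), -0.999)
}

#' Assemble a gene's covariance blocks from summary statistics and a panel
#'
#' `sigma_xx` is the SNP-SNP correlation from the reference panel and
#' `sigma_xy[j, k]` the normalized beta of trait k at SNP j (SNPs x traits
#' layout). `n_effective` is the minimum per-trait sample size over the
#' gene's records — a conservative choice when traits have unequal n.
#'
#' @param gene gene name.
#' @param snp_ids the gene's (pruned) SNP ids.
#' @param harmonized a `harmonized_stats` object.
#' @param panel a `reference_panel`.
#' @return a `gene_block`: list with `gene`, `snp_ids`, `sigma_xx`,
#'   `sigma_xy`, `n_effective`.
#' @export
build_gene_block <- function(gene, snp_ids, harmonized, panel) {
  missing <- setdiff(snp_ids, harmonized$snps$snp)
  if (length(missing) > 0)
    stopf("SNP(s) absent from harmonized statistics: %s",
          paste(missing, collapse = ", "))
  sigma_xx <- compute_ld(panel, snp_ids)
  i <- match(snp_ids, rownames(harmonized$beta))
  sigma_xy <- normalize_beta(harmonized$beta[i, , drop = FALSE],
                             harmonized$se[i, , drop = FALSE],
                             harmonized$n[i, , drop = FALSE])
  dimnames(sigma_xy) <- list(snp_ids, harmonized$traits)
  structure(list(gene = gene, snp_ids = snp_ids, sigma_xx = sigma_xx,
                 sigma_xy = sigma_xy,
                 n_effective = as.integer(min(harmonized$n[i, ]))),
            class = "gene_block")
}

#' Shrink a correlation matrix's off-diagonals until positive definite
#'
#' Repeatedly multiplies the off-diagonal entries by `factor` until the
#' smallest eigenvalue reaches `min_eig`; the unit diagonal is untouched.
#' This is the smallest perturbation toward the identity that guarantees
#' invertibility of the CCA blocks.
#'
#' @param S symmetric matrix with unit diagonal.
#' @param factor per-iteration off-diagonal multiplier (default 0.999).
#' @param min_eig target minimum eigenvalue (default 1e-8).
#' @return the shrunk matrix, with attribute `iterations`.
#' @export
shrink_to_pd <- function(S, factor = 0.999, min_eig = 1e-8) {
  check_symmetric(S, 1e-8, "matrix to shrink")
  S <- (S + t(S)) / 2
  d <- diag(S)
  iterations <- 0L
  while (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < min_eig) {
    S <- S * factor
    diag(S) <- d
    iterations <- iterations + 1L
    if (iterations > 1e5) stopf("shrinkage failed to reach min_eig")
  }
  attr(S, "iterations") <- iterations
  S
}

# Inverse symmetric square root of a positive-definite matrix.
inv_sqrtm <- function(S, what = "matrix") {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0)
    stopf("%s is not positive definite; shrink it first", what)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Canonical correlations from the three covariance blocks
#'
#' Singular values of `sigma_xx^(-1/2) %*% sigma_xy %*% sigma_yy^(-1/2)`,
#' clipped to `[0, 1]` and sorted descending; `min(m, K)` values.
#'
#' @param sigma_xx m x m SNP correlation block (positive definite).
#' @param sigma_xy m x K normalized-beta block.
#' @param sigma_yy K x K trait correlation block (positive definite).
#' @return numeric vector of canonical correlations.
#' @export
canonical_correlations <- function(sigma_xx, sigma_xy, sigma_yy) {
  if (nrow(sigma_xy) != nrow(sigma_xx) || ncol(sigma_xy) != nrow(sigma_yy))
    stopf("incompatible block dimensions")
  M <- inv_sqrtm(sigma_xx, "sigma_xx") %*% sigma_xy %*%
    inv_sqrtm(sigma_yy, "sigma_yy")
  d <- svd(M, nu = 0, nv = 0)$d
  sort(pmin(pmax(d, 0), 1), decreasing = TRUE)
}

#' Bartlett chi-square p-value for the joint canonical correlations
#'
#' Wilks-lambda approximation: the statistic
#' `-(n - 1 - (m + K + 1)/2) * sum(log(1 - r_i^2))` is referred to a
#' chi-square with `m * K` degrees of freedom, testing all canonical
#' correlations jointly.
#'
#' @param canonical_corrs values from [canonical_correlations()].
#' @param n effective sample size (must exceed `m + K + 1`).
#' @param m number of SNPs.
#' @param K number of traits.
#' @return list with `statistic` and `p_value`.
#' @export
cca_pvalue <- function(canonical_corrs, n, m, K) {
  if (n <= m + K + 1)
    stopf("sample size n = %d too small for m = %d SNPs and K = %d traits",
          n, m, K)
  r2 <- pmin(canonical_corrs^2, 1 - 1e-12)
  statistic <- -(n - 1 - (m + K + 1) / 2) * sum(log1p(-r2))
  list(statistic = statistic,
       p_value = pchisq(statistic, df = m * K, lower.tail = FALSE))
}

#' Run summary-level CCA over a list of gene blocks
#'
#' Per gene: shrink `sigma_xx` (and `sigma_yy`, once) to positive
#' definiteness, compute canonical correlations and the Bartlett p-value.
#' The Bonferroni threshold is `alpha / (number of genes tested)`; results
#' are sorted by p then by leading canonical correlation (descending). A
#' gene whose computation fails is recorded in the `failures` attribute, not
#' fatal.
#'
#' @param blocks list of `gene_block` objects.
#' @param sigma_yy trait correlation matrix (taken verbatim, then shrunk).
#' @param alpha family-wise error target (default 0.05).
#' @return data.frame (`cca_results`) with columns `gene, m_snps, r1,
#'   statistic, p, significant`, and attributes `threshold`, `alpha`,
#'   `n_tested`, `failures`.
#' @export
run_metacca <- function(blocks, sigma_yy, alpha = 0.05) {
  if (length(blocks) == 0) stopf("no gene blocks to test")
  validate_trait_correlations(sigma_yy)
  syy <- shrink_to_pd(sigma_yy)
  K <- nrow(syy)
  rows <- vector("list", length(blocks))
  failures <- character(0)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    res <- tryCatch({
      sxx <- shrink_to_pd(b$sigma_xx)
      cc <- canonical_correlations(sxx, b$sigma_xy, syy)
      pv <- cca_pvalue(cc, b$n_effective, length(b$snp_ids), K)
      data.frame(gene = b$gene, m_snps = length(b$snp_ids), r1 = cc[1],
                 statistic = pv$statistic, p = pv$p_value,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", b$gene, conditionMessage(e)))
      NULL
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stopf("every gene failed CCA")
  threshold <- alpha / nrow(out)
  out$significant <- out$p < threshold
  out <- out[order(out$p, -out$r1), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold, alpha = alpha, n_tested = nrow(out),
            failures = failures, class = c("cca_results", "data.frame"))
}
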