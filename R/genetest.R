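## Per-trait gene-based association tests: sum-of-chi-squares statistic with
## an LD-aware multivariate-normal Monte-Carlo null (adaptive staging), and
## the "significant for more than one trait" pleiotropy filter.

#' Per-SNP z-scores for one trait
#'
#' @param harmonized a `harmonized_stats` object.
#' @param trait trait label.
#' @param snp_ids SNP ids (order preserved in the output).
#' @return numeric vector `beta / se`.
#' @export
snp_z_scores <- function(harmonized, trait, snp_ids) {
  if (!trait %in% harmonized$traits)
    stopf("unknown trait '%s'", trait)
  i <- match(snp_ids, rownames(harmonized$beta))
  if (anyNA(i))
    stopf("SNP(s) absent from harmonized statistics: %s",
          paste(snp_ids[is.na(i)], collapse = ", "))
  unname(harmonized$beta[i, trait] / harmonized$se[i, trait])
}

#' Gene-level sum-of-chi-squares statistic
#' @param z vector of per-SNP z-scores (non-empty).
#' @return `sum(z^2)`.
#' @export
gene_statistic <- function(z) {
  if (length(z) == 0) stopf("empty z-score vector")
  sum(z^2)
}

#' Monte-Carlo gene-based p-value under an LD-aware null
#'
#' Null vectors are drawn from a zero-mean multivariate normal with
#' covariance equal to the (positive-definite-shrunk) LD matrix; each draw's
#' statistic is its sum of squares. The estimator `p = (#draws >= observed
#' + 1) / (sims + 1)` is never zero, and simulation escalates to the next
#' stage while `p < 10 / sims`, so small p-values are resolved down to the
#' floor `1 / (max(stages) + 1)` (about 1e-6 at the default stages).
#'
#' @param z per-SNP z-scores.
#' @param ld LD matrix matching `z` (same SNP order).
#' @param stages increasing Monte-Carlo sizes (default `c(1e3, 1e4, 1e6)`).
#' @param seed integer seed for this evaluation's RNG stream.
#' @return list with `p` and `sims_used`.
#' @export
vegas_pvalue <- function(z, ld, stages = c(1e3, 1e4, 1e6), seed = 1L) {
  m <- length(z)
  if (!is.matrix(ld) || nrow(ld) != m || ncol(ld) != m)
    stopf("LD matrix dimensions do not match the z-score vector")
  observed <- gene_statistic(z)
  U <- chol(shrink_to_pd(ld))
  stages <- sort(as.numeric(stages))
  p <- 1
  sims_used <- 0
  with_seed(seed, {
    for (s in seq_along(stages)) {
      sims <- stages[s]
      exceed <- 0
      left <- sims
      chunk_rows <- max(1, floor(2e6 / m))
      while (left > 0) {
        nr <- min(chunk_rows, left)
        Z <- matrix(rnorm(nr * m), nr, m) %*% U
        exceed <- exceed + sum(.rowSums(Z * Z, nr, m) >= observed)
        left <- left - nr
      }
      p <- (exceed + 1) / (sims + 1)
      sims_used <- sims
      if (p >= 10 / sims) break
    }
  })
  list(p = p, sims_used = sims_used)
}

#' Gene-based p-values for every (gene, trait) pair
#'
#' Each (gene, trait) cell gets its own RNG stream derived from the master
#' seed by a stable hash, so results are independent of execution order. The
#' significance threshold is `alpha / (number of genes tested)`.
#'
#' @param harmonized a `harmonized_stats` object.
#' @param gene_map gene -> SNP-id map (the SNP set actually tested; pass the
#'   pruned map to test pruned sets).
#' @param panel a `reference_panel` (LD source).
#' @param genes genes to test (default: all in `gene_map`); must be a subset
#'   of the map's names.
#' @param seed master seed.
#' @param stages Monte-Carlo stage sizes (see [vegas_pvalue()]).
#' @param alpha family-wise error target (default 0.05).
#' @return a `gene_trait_matrix`: list with `p` and `sims_used`
#'   (gene x trait matrices), `threshold`, `genes`, `traits`, `failures`.
#' @export
run_gene_tests <- function(harmonized, gene_map, panel,
                           genes = names(gene_map), seed = 1L,
                           stages = c(1e3, 1e4, 1e6), alpha = 0.05) {
  missing <- setdiff(genes, names(gene_map))
  if (length(missing) > 0)
    stopf("gene(s) absent from the gene map: %s",
          paste(missing, collapse = ", "))
  if (length(genes) == 0) stopf("no genes selected for gene-based testing")
  traits <- harmonized$traits
  p <- sims <- matrix(NA_real_, length(genes), length(traits),
                      dimnames = list(genes, traits))
  failures <- character(0)
  for (g in genes) {
    res <- tryCatch({
      snp_ids <- gene_map[[g]]
      ld <- compute_ld(panel, snp_ids)
      for (tr in traits) {
        z <- snp_z_scores(harmonized, tr, snp_ids)
        v <- vegas_pvalue(z, ld, stages = stages,
                          seed = derive_seed(seed, "genetest", g, tr))
        p[g, tr] <- v$p
        sims[g, tr] <- v$sims_used
      }
      TRUE
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", g, conditionMessage(e)))
      FALSE
    })
  }
  structure(list(p = p, sims_used = sims,
                 threshold = alpha / length(genes),
                 genes = genes, traits = traits, failures = failures),
            class = "gene_trait_matrix")
}

#' @export
print.gene_trait_matrix <- function(x, ...) {
  cat(sprintf("<gene_trait_matrix> %d genes x %d traits, threshold %.3g\n",
              length(x$genes), length(x$traits), x$threshold))
  invisible(x)
}

#' Call potentially pleiotropic genes
#'
#' A gene is kept iff it is significant (`p < threshold`) for **more than
#' one** trait. Calls are sorted by the number of significant traits, then by
#' the gene's minimum p-value.
#'
#' @param gtm a `gene_trait_matrix` from [run_gene_tests()].
#' @return data.frame with `gene`, `n_significant_traits`,
#'   `significant_traits` (semicolon-joined), `min_p`, and one `p_<trait>`
#'   column per trait. Zero rows when nothing passes.
#' @export
call_pleiotropy <- function(gtm) {
  stopifnot(inherits(gtm, "gene_trait_matrix"))
  sig <- gtm$p < gtm$threshold
  sig[is.na(sig)] <- FALSE
  n_sig <- rowSums(sig)
  keep <- which(n_sig >= 2)
  pcols <- as.data.frame(gtm$p, stringsAsFactors = FALSE)
  names(pcols) <- paste0("p_", gtm$traits)
  out <- data.frame(gene = gtm$genes,
                    n_significant_traits = n_sig,
                    significant_traits = vapply(seq_along(gtm$genes),
                      function(i) paste(gtm$traits[sig[i, ]], collapse = ";"),
                      ""),
                    min_p = apply(gtm$p, 1, min),
                    pcols,
                    stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$n_significant_traits, out$min_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
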