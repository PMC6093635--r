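## SNP intersection across traits, effect-allele alignment, gene assignment
## and within-gene LD pruning.

STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize summary statistics across traits (and a reference panel)
#'
#' Restricts all traits to their shared SNP set (intersected with the panel's
#' SNPs when a panel is given) and aligns every trait's effect allele to the
#' first trait's. Where a trait's (EA, OA) pair is the reverse of the
#' reference trait's, the beta sign is flipped; strand-ambiguous SNPs
#' (A/T or C/G pairs) and allele mismatches are dropped.
#'
#' @param tables list of `summary_stats` objects (>= 2 traits).
#' @param panel optional `reference_panel`; its SNP set joins the
#'   intersection.
#' @return a `harmonized_stats` object: `snps` (data.frame
#'   `snp, chrom, pos, ea, oa` in position order), per-trait `beta`, `se`,
#'   `n` matrices (SNP x trait), `traits`, and an alignment `report` with
#'   kept / flipped / dropped-ambiguous / dropped-mismatch counts.
#' @export
harmonize_traits <- function(tables, panel = NULL) {
  if (length(tables) < 2) stopf("harmonization needs at least 2 traits")
  traits <- vapply(tables, function(t) t$trait_name, "")
  if (anyDuplicated(traits)) stopf("duplicated trait names")
  ids <- Reduce(intersect, lapply(tables, function(t) t$records$snp))
  if (!is.null(panel)) ids <- intersect(ids, panel$snp_ids)
  if (length(ids) == 0)
    stopf("no SNPs shared across all traits%s; check that inputs use the same variant ids",
          if (is.null(panel)) "" else " and the reference panel")
  n_shared <- length(ids)

  ref <- tables[[1]]$records
  ref <- ref[match(ids, ref$snp), , drop = FALSE]
  ref <- ref[order(ref$chrom, ref$pos, ref$snp), , drop = FALSE]
  ids <- ref$snp

  ambiguous <- paste(ref$ea, ref$oa, sep = "/") %in% STRAND_AMBIGUOUS
  n_ambiguous <- sum(ambiguous)
  ref <- ref[!ambiguous, , drop = FALSE]
  ids <- ref$snp
  m <- length(ids)
  K <- length(tables)

  beta <- se <- nmat <- matrix(NA_real_, m, K, dimnames = list(ids, traits))
  drop_mismatch <- logical(m)
  n_flipped <- 0L
  for (k in seq_len(K)) {
    rk <- tables[[k]]$records
    rk <- rk[match(ids, rk$snp), , drop = FALSE]
    same <- rk$ea == ref$ea & rk$oa == ref$oa
    swapped <- rk$ea == ref$oa & rk$oa == ref$ea
    drop_mismatch <- drop_mismatch | !(same | swapped)
    b <- rk$beta
    b[swapped] <- -b[swapped]
    n_flipped <- n_flipped + sum(swapped)
    beta[, k] <- b
    se[, k] <- rk$se
    nmat[, k] <- rk$n
  }
  n_mismatch <- sum(drop_mismatch)
  keep <- !drop_mismatch
  structure(list(snps = ref[keep, c("snp", "chrom", "pos", "ea", "oa"),
                            drop = FALSE],
                 beta = beta[keep, , drop = FALSE],
                 se = se[keep, , drop = FALSE],
                 n = nmat[keep, , drop = FALSE],
                 traits = traits,
                 report = c(n_shared = n_shared,
                            n_kept = sum(keep),
                            n_flipped = n_flipped,
                            n_dropped_ambiguous = n_ambiguous,
                            n_dropped_mismatch = n_mismatch)),
            class = "harmonized_stats")
}

#' @export
print.harmonized_stats <- function(x, ...) {
  cat(sprintf("<harmonized_stats> %d SNPs x %d traits (%s)\n",
              nrow(x$snps), length(x$traits),
              paste(x$traits, collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' Convert harmonized statistics back into per-trait summary tables
#'
#' Mainly used to check that harmonization is idempotent.
#'
#' @param h a `harmonized_stats` object.
#' @return list of `summary_stats` objects, one per trait.
#' @export
harmonized_to_tables <- function(h) {
  lapply(seq_along(h$traits), function(k) {
    rec <- data.frame(snp = h$snps$snp, chrom = h$snps$chrom,
                      pos = h$snps$pos, ea = h$snps$ea, oa = h$snps$oa,
                      beta = h$beta[, k], se = h$se[, k],
                      n = as.integer(h$n[, k]), stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    structure(list(trait_name = h$traits[k], records = rec,
                   report = c(n_input = nrow(rec), n_kept = nrow(rec),
                              n_missing_dropped = 0L, n_se_dropped = 0L,
                              n_n_dropped = 0L, n_allele_dropped = 0L)),
              class = "summary_stats")
  })
}

#' Assign SNPs to gene ranges
#'
#' Inclusion test: `start - flank <= pos <= end + flank` on the matching
#' chromosome (1-based, inclusive). A SNP inside two overlapping genes is
#' assigned to both; genes without any SNP are omitted from the map but
#' counted.
#'
#' @param snps data.frame with columns `snp, chrom, pos`.
#' @param ranges gene ranges as from [read_gene_ranges()].
#' @param flank basepairs added on both sides of every gene (default 0:
#'   strict transcript boundaries).
#' @return a named list mapping gene name to its SNP ids in position order,
#'   with attributes `flank` and `n_genes_empty`.
#' @export
assign_snps_to_genes <- function(snps, ranges, flank = 0) {
  stopifnot(flank >= 0)
  if (nrow(ranges) == 0 || nrow(snps) == 0) {
    out <- structure(list(), flank = flank, n_genes_empty = nrow(ranges))
    return(out)
  }
  seqs <- union(unique(snps$chrom), unique(ranges$chrom))
  gr_snp <- GRanges(factor(snps$chrom, seqs), IRanges(snps$pos, width = 1))
  gr_gene <- GRanges(factor(ranges$chrom, seqs),
                     IRanges(pmax(1L, ranges$start - flank),
                             ranges$end + flank))
  hits <- findOverlaps(gr_snp, gr_gene)
  qi <- queryHits(hits)
  si <- subjectHits(hits)
  ord <- order(si, snps$pos[qi], snps$snp[qi])
  qi <- qi[ord]; si <- si[ord]
  map <- split(snps$snp[qi], ranges$gene[si])
  # split() sorts by factor level; restore annotation-file gene order
  map <- map[intersect(ranges$gene, names(map))]
  structure(map, flank = flank,
            n_genes_empty = nrow(ranges) - length(map))
}

#' Pairwise LD (Pearson r) between panel SNPs
#'
#' Missing dosages are imputed to the SNP mean only inside this computation
#' (never written back to the panel).
#'
#' @param panel a `reference_panel`.
#' @param snp_ids SNP ids, in the desired (position) order.
#' @return symmetric correlation matrix with `snp_ids` dimnames.
#' @export
compute_ld <- function(panel, snp_ids) {
  missing <- setdiff(snp_ids, panel$snp_ids)
  if (length(missing) > 0)
    stopf("SNP(s) absent from reference panel: %s",
          paste(missing, collapse = ", "))
  X <- panel$dosages[, snp_ids, drop = FALSE]
  if (nrow(X) < 2) stopf("LD computation needs at least 2 individuals")
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  r <- cor(X)
  if (anyNA(r)) stopf("zero-variance SNP among requested ids")
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

#' Greedy LD pruning of a gene's SNPs
#'
#' Scans SNPs in the matrix order (ascending genomic position by
#' construction) and keeps a SNP iff its squared correlation with every
#' already-kept SNP is at most `r2_max`, so the kept set is pairwise
#' near-independent.
#'
#' @param ld LD matrix from [compute_ld()].
#' @param r2_max maximum allowed pairwise r-squared (default 0.01).
#' @return character vector of kept SNP ids (in scan order).
#' @export
prune_ld <- function(ld, r2_max = 0.01) {
  check_symmetric(ld, 1e-8, "LD matrix")
  kept <- integer(0)
  for (j in seq_len(ncol(ld))) {
    if (all(ld[j, kept]^2 <= r2_max)) kept <- c(kept, j)
  }
  colnames(ld)[kept]
}

#' Prune every gene's SNP list against the panel
#'
#' @param gene_map map from [assign_snps_to_genes()].
#' @param panel a `reference_panel`.
#' @param r2_max pruning threshold.
#' @return named list like `gene_map` restricted to kept SNPs.
#' @export
prune_gene_map <- function(gene_map, panel, r2_max = 0.01) {
  out <- lapply(gene_map, function(ids) {
    if (length(ids) == 1) return(ids)
    prune_ld(compute_ld(panel, ids), r2_max)
  })
  structure(out, flank = attr(gene_map, "flank"),
            n_genes_empty = attr(gene_map, "n_genes_empty"))
}
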