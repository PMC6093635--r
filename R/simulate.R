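## Synthetic-data generator: LD-structured reference panels, multi-trait
## phenotypes with planted pleiotropic architecture, per-trait summary
## statistics from subsampled cohorts, and the ground-truth labels needed
## for recovery tests.

#' Simulation configuration
#'
#' Defaults state the emulated world: six metabolic traits with the
#' published phenotypic correlations ([engage_trait_cor()]) and the
#' published per-trait sample sizes scaled down 10x so the full pipeline
#' runs in minutes; genes carry a truncated-Poisson number of SNPs (mean
#' ~13, range 1-40) with AR(1) within-gene LD at rho = 0.5; a minority of
#' genes get planted standardized effects (1% trait variance each) on two
#' traits (HDL and TG by default, mirroring the trait pair on which most
#' reported pleiotropic genes act) or on one random trait.
#'
#' @param n_genes number of genes.
#' @param snps_per_gene `c(min, max)` SNP-count range per gene.
#' @param snps_per_gene_mean mean of the (truncated) Poisson SNP count.
#' @param maf_range minor-allele-frequency range, drawn uniformly.
#' @param ld_rho AR(1) correlation of the latent genotype process.
#' @param traits trait labels.
#' @param trait_cor phenotypic correlation matrix (defaults to the published
#'   six-trait values, subset to `traits`).
#' @param per_trait_n named per-trait GWAS sample sizes.
#' @param n_individuals cohort (and reference panel) size.
#' @param n_pleio planted pleiotropic genes (effects on `pleio_traits`).
#' @param n_single planted single-trait genes.
#' @param pleio_traits the two traits every pleiotropic gene affects.
#' @param h2_per_gene trait-variance fraction per planted (gene, trait)
#'   effect (gene-level heritability of the trait due to that gene).
#' @param causal_snps_per_gene causal SNPs per planted gene; `Inf` (default)
#'   distributes the gene's effect over all of its SNPs (allelic
#'   heterogeneity, so the signal is not an artifact of which single SNP
#'   survives LD pruning); `1` gives a point architecture.
#' @param seed master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 100,
                       snps_per_gene = c(1, 40),
                       snps_per_gene_mean = 13,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.5,
                       traits = colnames(engage_trait_cor()),
                       trait_cor = engage_trait_cor()[traits, traits],
                       per_trait_n = round(engage_trait_n()[traits] / 10),
                       n_individuals = 10000,
                       n_pleio = 5,
                       n_single = 5,
                       pleio_traits = c("HDL", "TG"),
                       h2_per_gene = 0.01,
                       causal_snps_per_gene = Inf,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, snps_per_gene = snps_per_gene,
              snps_per_gene_mean = snps_per_gene_mean,
              maf_range = maf_range, ld_rho = ld_rho, traits = traits,
              trait_cor = trait_cor, per_trait_n = per_trait_n,
              n_individuals = n_individuals, n_pleio = n_pleio,
              n_single = n_single, pleio_traits = pleio_traits,
              h2_per_gene = h2_per_gene,
              causal_snps_per_gene = causal_snps_per_gene,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1,
            length(cfg$snps_per_gene) == 2,
            cfg$snps_per_gene[1] >= 1,
            cfg$snps_per_gene[1] <= cfg$snps_per_gene[2])
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stopf("maf_range must lie in (0, 0.5]")
  if (abs(cfg$ld_rho) >= 1) stopf("ld_rho must satisfy |rho| < 1")
  validate_trait_correlations(cfg$trait_cor[cfg$traits, cfg$traits])
  if (!all(cfg$traits %in% names(cfg$per_trait_n)))
    stopf("per_trait_n must be named by trait")
  if (any(cfg$per_trait_n[cfg$traits] > cfg$n_individuals))
    stopf("per-trait n cannot exceed the cohort size")
  if (cfg$h2_per_gene <= 0 || cfg$h2_per_gene >= 1)
    stopf("h2_per_gene must lie in (0, 1)")
  if (cfg$causal_snps_per_gene < 1)
    stopf("causal_snps_per_gene must be >= 1")
  if (cfg$n_pleio + cfg$n_single > cfg$n_genes)
    stopf("n_pleio + n_single exceeds n_genes")
  if (cfg$n_pleio > 0) {
    if (length(cfg$pleio_traits) < 2)
      stopf("pleiotropic genes need at least 2 target traits")
    if (!all(cfg$pleio_traits %in% cfg$traits))
      stopf("pleio_traits must be among the configured traits")
  }
  invisible(cfg)
}

#' Simulate an LD-structured reference panel
#'
#' Per gene, two latent Gaussian AR(`ld_rho`) haplotype vectors are
#' thresholded at the allele-frequency quantile and summed, giving dosages
#' in {0, 1, 2}; genes are LD-independent of each other. SNP positions tile
#' chromosome "1" with genes 100 kb apart and SNPs 100 bp apart, and the
#' panel's `map` carries a `gene` column naming each SNP's source gene.
#'
#' @param config a [sim_config()].
#' @return a `reference_panel` (monomorphic SNPs dropped, as for real
#'   panels).
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "panel"), {
    n <- config$n_individuals
    m_per_gene <- draw_snp_counts(config)
    blocks <- vector("list", config$n_genes)
    maps <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      m <- m_per_gene[g]
      maf <- runif(m, config$maf_range[1], config$maf_range[2])
      thr <- qnorm(1 - maf)
      L <- if (m == 1) matrix(1) else t(chol(ar1_cor(m, config$ld_rho)))
      hap <- function() {
        Z <- matrix(rnorm(n * m), n, m) %*% t(L)
        sweep(Z, 2, thr, ">") * 1
      }
      blocks[[g]] <- hap() + hap()
      start <- (g - 1) * 100000 + 1
      maps[[g]] <- data.frame(
        snp = sprintf("g%03d_s%02d", g, seq_len(m)),
        chrom = "1",
        pos = as.integer(start + (seq_len(m) - 1) * 100),
        gene = sprintf("GENE%03d", g),
        stringsAsFactors = FALSE)
    }
    dosages <- do.call(cbind, blocks)
    map <- do.call(rbind, maps)
    colnames(dosages) <- map$snp
    make_panel(dosages, map)
  })
}

draw_snp_counts <- function(config) {
  pmin(config$snps_per_gene[2],
       pmax(config$snps_per_gene[1],
            rpois(config$n_genes, config$snps_per_gene_mean)))
}

ar1_cor <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

#' Plant the true effect architecture
#'
#' Pleiotropic genes receive a standardized gene-level effect of size
#' `sqrt(h2_per_gene)` on each trait in `pleio_traits`; single-trait genes
#' on one uniformly drawn trait. Each planted gene's causal SNP set is
#' either all of its SNPs (default: distributed allelic architecture) or a
#' random subset of `causal_snps_per_gene`.
#'
#' @param config a [sim_config()].
#' @param panel the panel the truth must index into (from
#'   [simulate_panel()]).
#' @return a `synthetic_truth`: list with `effect_matrix` (gene x trait),
#'   `pleiotropic_genes`, `single_trait_genes`, `causal_snps`
#'   (gene -> SNP ids).
#' @export
simulate_truth <- function(config, panel) {
  genes <- unique(panel$map$gene)
  with_seed(derive_seed(config$seed, "truth"), {
    effect <- matrix(0, length(genes), length(config$traits),
                     dimnames = list(genes, config$traits))
    planted <- sample(genes, config$n_pleio + config$n_single)
    pleio <- planted[seq_len(config$n_pleio)]
    single <- setdiff(planted, pleio)
    b <- sqrt(config$h2_per_gene)
    for (g in pleio) effect[g, config$pleio_traits] <- b
    for (g in single) effect[g, sample(config$traits, 1)] <- b
    causal <- lapply(planted, function(g) {
      ids <- panel$map$snp[panel$map$gene == g]
      k <- min(config$causal_snps_per_gene, length(ids))
      if (k == length(ids)) ids else sort(sample(ids, k))
    })
    names(causal) <- planted
    structure(list(effect_matrix = effect,
                   pleiotropic_genes = sort(pleio),
                   single_trait_genes = sort(single),
                   causal_snps = causal),
              class = "synthetic_truth")
  })
}

#' Simulate correlated multi-trait phenotypes with planted genetic effects
#'
#' Trait k of individual i is the sum of the planted gene scores (the
#' standardized equal-weight sum of a gene's causal standardized dosages,
#' scaled to explain exactly `h2_per_gene` of the trait variance) plus a
#' correlated Gaussian residual. Residual correlation equals `trait_cor`
#' and residual variance is scaled to `1 - (genetic variance)`, so total
#' phenotypic correlation approximately equals `trait_cor` when effects are
#' small.
#'
#' @param dosages individuals x SNPs dosage matrix (SNP ids as colnames).
#' @param truth a `synthetic_truth`.
#' @param trait_cor trait correlation matrix (shrunk to PD if needed).
#' @param seed integer seed.
#' @return individuals x traits phenotype matrix.
#' @export
simulate_phenotypes <- function(dosages, truth, trait_cor, seed = 1L) {
  traits <- colnames(truth$effect_matrix)
  n <- nrow(dosages)
  with_seed(seed, {
    U <- chol(shrink_to_pd(trait_cor[traits, traits]))
    resid <- matrix(rnorm(n * length(traits)), n) %*% U
    G <- matrix(0, n, length(traits), dimnames = list(NULL, traits))
    for (g in names(truth$causal_snps)) {
      snps <- intersect(truth$causal_snps[[g]], colnames(dosages))
      if (length(snps) == 0) next
      score <- rowSums(scale(dosages[, snps, drop = FALSE]))
      score <- (score - mean(score)) / sd(score)
      for (tr in traits) {
        b <- truth$effect_matrix[g, tr]
        if (b != 0) G[, tr] <- G[, tr] + b * score
      }
    }
    vg <- colSums(truth$effect_matrix[, traits, drop = FALSE]^2)
    if (any(vg >= 1)) stopf("planted genetic variance reaches 1 for a trait")
    Y <- G + sweep(resid, 2, sqrt(1 - vg), "*")
    colnames(Y) <- traits
    Y
  })
}

#' Per-trait GWAS summary statistics from subsampled cohorts
#'
#' Each trait draws its own subsample of `per_trait_n` individuals
#' (emulating distinct, partially overlapping consortium cohorts), the
#' trait is standardized within the subsample, and each SNP is tested with
#' univariate least squares, yielding (beta, SE, n) per SNP.
#'
#' @param dosages cohort dosage matrix (individuals x SNPs).
#' @param phenotypes cohort phenotype matrix from [simulate_phenotypes()].
#' @param per_trait_n named per-trait subsample sizes.
#' @param map SNP map (`snp, chrom, pos`) matching `dosages` columns.
#' @param seed integer seed.
#' @return list of `summary_stats`, one per trait.
#' @export
compute_summary_stats <- function(dosages, phenotypes, per_trait_n, map,
                                  seed = 1L) {
  traits <- colnames(phenotypes)
  if (any(per_trait_n[traits] > nrow(dosages)))
    stopf("per-trait subsample exceeds the cohort size")
  lapply(traits, function(tr) {
    with_seed(derive_seed(seed, "sumstats", tr), {
      nt <- per_trait_n[[tr]]
      idx <- sample(nrow(dosages), nt)
      X <- dosages[idx, , drop = FALSE]
      y <- as.vector(scale(phenotypes[idx, tr]))
      xm <- colMeans(X)
      sxx <- colSums(X^2) - nt * xm^2
      sxy <- as.vector(crossprod(X, y))          # y has mean 0
      syy <- sum(y^2)
      beta <- sxy / sxx
      rss <- pmax(syy - beta * sxy, 0)
      se <- sqrt(rss / (nt - 2) / sxx)
      rec <- data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos,
                        ea = "A", oa = "G", beta = beta, se = se,
                        n = as.integer(nt), stringsAsFactors = FALSE)
      ok <- is.finite(rec$beta) & is.finite(rec$se) & rec$se > 0
      structure(list(trait_name = tr, records = rec[ok, , drop = FALSE],
                     report = c(n_input = nrow(rec), n_kept = sum(ok),
                                n_missing_dropped = sum(!ok),
                                n_se_dropped = 0L, n_n_dropped = 0L,
                                n_allele_dropped = 0L)),
                class = "summary_stats")
    })
  })
}

#' Generate a complete, self-consistent synthetic input bundle
#'
#' Panel, truth, phenotypes, per-trait summary tables, gene ranges tiling
#' the simulated SNPs, and a GMT library whose planted set contains the
#' pleiotropic genes plus noise genes (alongside random decoy sets).
#'
#' @param config a [sim_config()].
#' @return list with `panel`, `truth`, `phenotypes`, `tables`,
#'   `gene_ranges`, `gmt`, `trait_cor`, `config`.
#' @export
make_scenario <- function(config = sim_config()) {
  validate_sim_config(config)
  panel <- simulate_panel(config)
  truth <- simulate_truth(config, panel)
  phenotypes <- simulate_phenotypes(panel$dosages, truth, config$trait_cor,
                                    seed = derive_seed(config$seed, "pheno"))
  tables <- compute_summary_stats(panel$dosages, phenotypes,
                                  config$per_trait_n, panel$map,
                                  seed = config$seed)
  ranges <- do.call(rbind, lapply(split(panel$map, panel$map$gene),
                                  function(d) data.frame(
                                    chrom = d$chrom[1],
                                    start = min(d$pos),
                                    end = max(d$pos),
                                    gene = d$gene[1],
                                    stringsAsFactors = FALSE)))
  ranges <- ranges[order(ranges$chrom, ranges$start), , drop = FALSE]
  rownames(ranges) <- NULL
  gmt <- with_seed(derive_seed(config$seed, "gmt"), {
    genes <- ranges$gene
    nulls <- setdiff(genes, truth$pleiotropic_genes)
    planted <- c(truth$pleiotropic_genes,
                 sample(nulls, min(5, length(nulls))))
    sets <- list(PLANTED_SET = sort(planted))
    for (i in seq_len(15)) {
      sets[[sprintf("RANDOM_SET_%02d", i)]] <-
        sort(sample(genes, min(10, length(genes))))
    }
    structure(sets, source_label = "synthetic", n_rejected = 0L,
              class = c("gene_set_library", "list"))
  })
  list(panel = panel, truth = truth, phenotypes = phenotypes,
       tables = tables, gene_ranges = ranges, gmt = gmt,
       trait_cor = config$trait_cor, config = config)
}

#' Write a scenario bundle to disk in the pipeline's external formats
#'
#' @param scenario a bundle from [make_scenario()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trait_cor = file.path(dir, "trait_cor.tsv"),
             gene_ranges = file.path(dir, "gene_ranges.txt"),
             panel = file.path(dir, "panel.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_trait_correlations(scenario$trait_cor, paths[["trait_cor"]])
  write_gene_ranges(scenario$gene_ranges, paths[["gene_ranges"]])
  write_reference_panel(scenario$panel, paths[["panel"]])
  write_gmt(scenario$gmt, paths[["gmt"]])
  truth_df <- data.frame(gene = rownames(scenario$truth$effect_matrix),
                         scenario$truth$effect_matrix,
                         check.names = FALSE)
  write.table(truth_df, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (tab in scenario$tables) {
    p <- file.path(dir, sprintf("sumstats_%s.tsv", tab$trait_name))
    write_summary_stats(tab, p)
    paths[[paste0("sumstats_", tab$trait_name)]] <- p
  }
  paths
}

#' Matrix-normal null SNP-trait blocks for calibration studies
#'
#' Draws the summary-level null: per gene, a z-score matrix with row
#' covariance `ld` (the SNP block) and column covariance `trait_cor` (the
#' fully-overlapping-cohorts case), scaled by `1/sqrt(n)` to the normalized
#' beta scale.
#'
#' @param n_genes number of null genes.
#' @param ld m x m SNP correlation matrix shared by all genes.
#' @param trait_cor K x K trait correlation matrix.
#' @param n sample size.
#' @param seed integer seed.
#' @return list of m x K `sigma_xy` matrices.
#' @export
simulate_null_xy <- function(n_genes, ld, trait_cor, n, seed = 1L) {
  m <- nrow(ld)
  K <- nrow(trait_cor)
  Lx <- t(chol(shrink_to_pd(ld)))
  Uy <- chol(shrink_to_pd(trait_cor))
  with_seed(seed, {
    lapply(seq_len(n_genes), function(i) {
      Z <- Lx %*% matrix(rnorm(m * K), m, K) %*% Uy
      Z / sqrt(n)
    })
  })
}
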