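## End-to-end orchestration: harmonize -> annotate/prune -> summary-level
## CCA -> per-trait gene tests on the CCA-significant genes -> pleiotropy
## calls -> enrichment, with a machine-readable manifest and deterministic
## seeding throughout.

#' Build a pipeline configuration
#'
#' Every input may be given either as a file path (read with the matching
#' reader at run start) or as an already-loaded object, so the pipeline can
#' run from disk or fully in memory.
#'
#' @param sumstats named list (by trait, in analysis order) of paths or
#'   `summary_stats` objects; the first trait is the allele-alignment
#'   reference.
#' @param trait_cor path or matrix of phenotypic trait correlations.
#' @param gene_ranges path or data.frame of gene ranges.
#' @param panel path or `reference_panel`.
#' @param gmt optional path or `gene_set_library` (enrichment skipped when
#'   absent).
#' @param r2_max within-gene LD-pruning threshold (default 0.01).
#' @param alpha family-wise error target for both Bonferroni stages.
#' @param flank basepairs around gene ranges (default 0).
#' @param stages Monte-Carlo stage sizes for the gene-based test.
#' @param seed master seed; all randomness derives from it.
#' @param universe `"tested"` (default: all genes that entered the CCA
#'   stage) or `"annotation"` (all genes in the range file) as the
#'   enrichment background.
#' @param genetest_pruned use the pruned SNP set in the gene-based test
#'   (default FALSE: all SNPs in the gene, the classical all-SNP statistic).
#' @param test_all_genes run gene-based tests on all genes rather than only
#'   the CCA-significant ones.
#' @param out_dir optional output directory for stage TSVs and the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sumstats, trait_cor, gene_ranges, panel,
                            gmt = NULL, r2_max = 0.01, alpha = 0.05,
                            flank = 0, stages = c(1e3, 1e4, 1e6), seed = 1L,
                            universe = c("tested", "annotation"),
                            genetest_pruned = FALSE,
                            test_all_genes = FALSE, out_dir = NULL) {
  stopifnot(r2_max > 0, r2_max < 1, alpha > 0, alpha < 1, flank >= 0)
  if (is.null(names(sumstats)) || any(!nzchar(names(sumstats))))
    stopf("sumstats must be a named list (names = trait order)")
  for (x in sumstats) {
    if (is.character(x) && !file.exists(x))
      stopf("summary-statistics file not found: %s", x)
  }
  for (x in list(trait_cor, gene_ranges, panel, gmt)) {
    if (is.character(x) && !file.exists(x))
      stopf("input file not found: %s", x)
  }
  structure(list(sumstats = sumstats, trait_cor = trait_cor,
                 gene_ranges = gene_ranges, panel = panel, gmt = gmt,
                 r2_max = r2_max, alpha = alpha, flank = flank,
                 stages = stages, seed = as.integer(seed),
                 universe = match.arg(universe),
                 genetest_pruned = isTRUE(genetest_pruned),
                 test_all_genes = isTRUE(test_all_genes),
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

#' Run the full pleiotropy pipeline
#'
#' Executes harmonization, gene annotation and pruning, summary-level CCA
#' with Bonferroni control, per-trait Monte-Carlo gene tests on the
#' CCA-significant genes, the more-than-one-trait pleiotropy filter, and
#' gene-set enrichment. Stage TSVs and a JSON manifest (input hashes, seed,
#' stage counts) are written when `out_dir` is set; a stage failure is
#' recorded in the manifest rather than aborting silently.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stderr progress logging.
#' @return a `pipeline_result`: list with `harmonized`, `gene_map`,
#'   `pruned_map`, `cca`, `gene_tests`, `pleiotropy`, `enrichment`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_msg <- function(fmt, ...) {
    if (!quiet)
      message(sprintf("[pleiocca %5.1fs] %s",
                      as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      sprintf(fmt, ...)))
  }
  manifest <- list(seed = config$seed,
                   alpha = config$alpha, r2_max = config$r2_max,
                   input_md5 = input_hashes(config),
                   completed_stages = character(0), failed_stage = NULL,
                   counts = list())
  res <- list(manifest = manifest)
  out <- tryCatch({
    traits <- names(config$sumstats)
    tables <- lapply(traits, function(tr)
      load_input(config$sumstats[[tr]], read_summary_stats, trait_name = tr))
    panel <- load_input(config$panel, read_reference_panel)
    trait_cor <- if (is.character(config$trait_cor))
      read_trait_correlations(config$trait_cor, expected_traits = traits)
    else config$trait_cor[traits, traits]
    ranges <- load_input(config$gene_ranges, read_gene_ranges)
    gmt <- if (is.null(config$gmt)) NULL else load_input(config$gmt, read_gmt)

    log_msg("harmonizing %d traits", length(tables))
    harmonized <- harmonize_traits(tables, panel)
    res$harmonized <- harmonized
    manifest$counts$n_snps_overlap <- unname(harmonized$report[["n_kept"]])
    manifest$completed_stages <- c(manifest$completed_stages, "harmonize")

    log_msg("annotating %d SNPs to %d gene ranges",
            nrow(harmonized$snps), nrow(ranges))
    gene_map <- assign_snps_to_genes(harmonized$snps, ranges,
                                     flank = config$flank)
    pruned_map <- prune_gene_map(gene_map, panel, r2_max = config$r2_max)
    res$gene_map <- gene_map
    res$pruned_map <- pruned_map
    manifest$counts$n_genes_mapped <- length(gene_map)
    manifest$completed_stages <- c(manifest$completed_stages, "annotate")

    log_msg("summary-level CCA over %d genes", length(pruned_map))
    blocks <- lapply(names(pruned_map), function(g)
      build_gene_block(g, pruned_map[[g]], harmonized, panel))
    cca <- run_metacca(blocks, trait_cor, alpha = config$alpha)
    res$cca <- cca
    manifest$counts$n_genes_tested <- attr(cca, "n_tested")
    manifest$counts$n_cca_significant <- sum(cca$significant)
    manifest$completed_stages <- c(manifest$completed_stages, "metacca")

    selected <- if (config$test_all_genes) cca$gene
      else cca$gene[cca$significant]
    test_map <- if (config$genetest_pruned) pruned_map else gene_map
    if (length(selected) == 0) {
      log_msg("no CCA-significant genes; downstream stages empty")
      gene_tests <- NULL
      pleio <- empty_pleiotropy(traits)
    } else {
      log_msg("gene-based tests on %d genes x %d traits",
              length(selected), length(traits))
      gene_tests <- run_gene_tests(harmonized, test_map, panel,
                                   genes = selected, seed = config$seed,
                                   stages = config$stages,
                                   alpha = config$alpha)
      pleio <- call_pleiotropy(gene_tests)
    }
    res$gene_tests <- gene_tests
    res$pleiotropy <- pleio
    sig_per_trait <- if (is.null(gene_tests)) setNames(rep(0L, length(traits)), traits)
      else colSums(gene_tests$p < gene_tests$threshold, na.rm = TRUE)
    manifest$counts$n_genes_selected <- length(selected)
    manifest$counts$per_trait_significant <- as.list(sig_per_trait)
    manifest$counts$n_pleiotropy_calls <- nrow(pleio)
    manifest$completed_stages <- c(manifest$completed_stages,
                                   "genetest", "pleiotropy")

    if (!is.null(gmt)) {
      universe <- if (config$universe == "tested") cca$gene else ranges$gene
      log_msg("enrichment of %d calls against %d sets",
              nrow(pleio), length(gmt))
      enr <- if (nrow(pleio) == 0) suppressWarnings(
        enrich(character(0), gmt, universe))
      else enrich(pleio$gene, gmt, universe)
      res$enrichment <- enr
      manifest$counts$n_sets_tested <- nrow(enr)
      manifest$counts$n_sets_significant <- sum(enr$p_bh < config$alpha)
      manifest$completed_stages <- c(manifest$completed_stages, "enrich")
    }
    res$manifest <- manifest
    res
  }, error = function(e) {
    manifest$failed_stage <- list(
      after = manifest$completed_stages,
      error = conditionMessage(e))
    res$manifest <- manifest
    res
  })
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

input_hashes <- function(config) {
  paths <- c(unlist(Filter(is.character, config$sumstats)),
             Filter(is.character, list(config$trait_cor, config$gene_ranges,
                                       config$panel, config$gmt)))
  paths <- unlist(paths)
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(paths))
}

empty_pleiotropy <- function(traits) {
  base <- data.frame(gene = character(), n_significant_traits = integer(),
                     significant_traits = character(), min_p = numeric(),
                     stringsAsFactors = FALSE)
  for (tr in traits) base[[paste0("p_", tr)]] <- numeric(0)
  base
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(config$out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$harmonized)) {
    rep <- result$harmonized$report
    tsv(data.frame(metric = names(rep), value = unname(rep)),
        "harmonization_report.tsv")
    map_df <- gene_map_to_df(result$gene_map, result$harmonized)
    tsv(map_df, "gene_snp_map.tsv")
    tsv(gene_map_to_df(result$pruned_map, result$harmonized),
        "gene_snp_map_pruned.tsv")
  }
  if (!is.null(result$cca)) {
    cca_df <- as.data.frame(result$cca)
    cca_df$p_bonferroni_threshold <- attr(result$cca, "threshold")
    tsv(cca_df, "cca_results.tsv")
  }
  if (!is.null(result$gene_tests)) {
    gt <- result$gene_tests
    long <- data.frame(gene = rep(gt$genes, times = length(gt$traits)),
                       trait = rep(gt$traits, each = length(gt$genes)),
                       p = as.vector(gt$p),
                       sims_used = as.vector(gt$sims_used),
                       significant = as.vector(gt$p < gt$threshold))
    tsv(long, "gene_trait_pvalues.tsv")
  }
  if (!is.null(result$pleiotropy)) tsv(result$pleiotropy, "pleiotropy_calls.tsv")
  if (!is.null(result$enrichment)) tsv(result$enrichment, "enrichment.tsv")
  jsonlite::write_json(result$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}

gene_map_to_df <- function(gene_map, harmonized) {
  if (length(gene_map) == 0)
    return(data.frame(gene = character(), snp = character(),
                      pos = integer()))
  genes <- rep(names(gene_map), lengths(gene_map))
  snps <- unlist(gene_map, use.names = FALSE)
  data.frame(gene = genes, snp = snps,
             pos = harmonized$snps$pos[match(snps, harmonized$snps$snp)],
             stringsAsFactors = FALSE)
}

#' Human-readable funnel summary of a pipeline run
#'
#' Prints the stage funnel (SNPs overlapped, genes mapped/tested,
#' CCA-significant genes, per-trait significant counts, pleiotropy calls,
#' enriched sets); a partial run has its failing stage flagged.
#'
#' @param manifest a manifest list (from a `pipeline_result` or read back
#'   from `manifest.json`).
#' @return the manifest, invisibly.
#' @export
stage_report <- function(manifest) {
  if (is.null(manifest)) stopf("manifest is missing")
  cn <- manifest$counts
  line <- function(label, value) {
    if (!is.null(value)) cat(sprintf("  %-28s %s\n", label, format(value)))
  }
  cat("pipeline funnel\n")
  line("SNPs overlapped:", cn$n_snps_overlap)
  line("genes with >=1 SNP:", cn$n_genes_mapped)
  line("genes CCA-tested:", cn$n_genes_tested)
  line("genes CCA-significant:", cn$n_cca_significant)
  line("genes gene-based-tested:", cn$n_genes_selected)
  if (!is.null(cn$per_trait_significant)) {
    pt <- unlist(cn$per_trait_significant)
    cat(sprintf("  per-trait significant:       %s\n",
                paste(sprintf("%s=%d", names(pt), pt), collapse = " ")))
  }
  line("pleiotropy calls:", cn$n_pleiotropy_calls)
  line("gene sets significant:", cn$n_sets_significant)
  if (!is.null(manifest$failed_stage)) {
    cat(sprintf("  ** FAILED after [%s]: %s\n",
                paste(manifest$failed_stage$after, collapse = ", "),
                manifest$failed_stage$error))
  }
  invisible(manifest)
}

#' @export
print.pipeline_result <- function(x, ...) {
  stage_report(x$manifest)
  invisible(x)
}
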