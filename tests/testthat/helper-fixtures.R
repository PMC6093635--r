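# Fixtures are built in code at test time; nothing is stored on disk.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal summary-statistics file: one row per (snp, beta, se, n, alleles).
sumstats_file <- function(snp, beta, se, n, ea = "A", oa = "G",
                          chrom = "1", pos = seq_along(snp) * 100) {
  lines <- c("SNP\tCHR\tPOS\tEA\tOA\tBETA\tSE\tN",
             sprintf("%s\t%s\t%d\t%s\t%s\t%g\t%g\t%d",
                     snp, chrom, as.integer(pos), ea, oa, beta, se,
                     as.integer(n)))
  write_lines_tmp(lines, ".tsv")
}

# In-memory summary_stats builder (bypasses file round trip).
make_sumstats <- function(trait, snp, beta, se, n, ea = "A", oa = "G",
                          chrom = "1", pos = seq_along(snp) * 100) {
  rec <- data.frame(snp = snp, chrom = chrom, pos = as.integer(pos),
                    ea = rep_len(ea, length(snp)),
                    oa = rep_len(oa, length(snp)),
                    beta = beta, se = se, n = as.integer(rep_len(n, length(snp))),
                    stringsAsFactors = FALSE)
  structure(list(trait_name = trait, records = rec,
                 report = c(n_input = nrow(rec), n_kept = nrow(rec),
                            n_missing_dropped = 0L, n_se_dropped = 0L,
                            n_n_dropped = 0L, n_allele_dropped = 0L)),
            class = "summary_stats")
}

# A panel from an explicit dosage matrix (columns = SNPs).
make_test_panel <- function(dosages, chrom = "1",
                            pos = seq_len(ncol(dosages)) * 100) {
  map <- data.frame(snp = colnames(dosages), chrom = chrom,
                    pos = as.integer(pos), stringsAsFactors = FALSE)
  structure(list(snp_ids = map$snp, map = map, dosages = dosages,
                 n_monomorphic_dropped = 0L, n_multiallelic_skipped = 0L),
            class = "reference_panel")
}

# Trait-correlation file matching the published six-trait table.
trait_cor_file <- function(M = engage_trait_cor()) {
  path <- tempfile(fileext = ".tsv")
  write_trait_correlations(M, path)
  path
}

# Small, fast end-to-end scenario (about 1.5 s to generate and run).
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(n_genes = 20, n_individuals = 4000,
                   per_trait_n = round(engage_trait_n() / 25),
                   n_pleio = 2, n_single = 1, h2_per_gene = 0.02,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_pipeline_config <- function(scn, seed, ...) {
  pipeline_config(sumstats = setNames(scn$tables, scn$config$traits),
                  trait_cor = scn$trait_cor,
                  gene_ranges = scn$gene_ranges,
                  panel = scn$panel, gmt = scn$gmt,
                  stages = c(1e3, 1e4, 1e5), seed = seed, ...)
}
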