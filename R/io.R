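## Readers/writers for every external format the pipeline touches.
## Coordinates are 1-based and ranges are inclusive on both ends throughout
## (glist-hg19 convention). Gene names are uppercased at ingest so annotation
## lists and GMT libraries compare case-insensitively.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Read one trait's GWAS summary statistics
#'
#' Parses a whitespace- or tab-delimited table with a header row into a
#' validated `summary_stats` object. Rows with missing beta or SE, a
#' non-positive SE, a sample size below 2, or a non-ACGT allele are dropped
#' and counted in the attached report; a duplicated SNP id is an error.
#'
#' @param path file path.
#' @param trait_name label for the trait.
#' @param column_map named character vector mapping the logical columns
#'   `snp, chr, pos, ea, oa, beta, se, n` to the file's header names.
#' @return a `summary_stats` object: list with `trait_name`, `records`
#'   (data.frame `snp, chrom, pos, ea, oa, beta, se, n`) and `report`
#'   (named integer vector of input/kept/rejection counts).
#' @export
read_summary_stats <- function(path, trait_name,
                               column_map = c(snp = "SNP", chr = "CHR",
                                              pos = "POS", ea = "EA",
                                              oa = "OA", beta = "BETA",
                                              se = "SE", n = "N")) {
  need <- c("snp", "chr", "pos", "ea", "oa", "beta", "se", "n")
  if (!all(need %in% names(column_map)))
    stopf("column_map must name columns: %s",
          paste(setdiff(need, names(column_map)), collapse = ", "))
  raw <- read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols) > 0)
    stopf("summary-statistics file '%s' lacks mapped column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  rec <- data.frame(snp   = as.character(raw[[column_map[["snp"]]]]),
                    chrom = as.character(raw[[column_map[["chr"]]]]),
                    pos   = as.integer(raw[[column_map[["pos"]]]]),
                    ea    = toupper(as.character(raw[[column_map[["ea"]]]])),
                    oa    = toupper(as.character(raw[[column_map[["oa"]]]])),
                    beta  = as.numeric(raw[[column_map[["beta"]]]]),
                    se    = as.numeric(raw[[column_map[["se"]]]]),
                    n     = as.integer(raw[[column_map[["n"]]]]),
                    stringsAsFactors = FALSE)
  n_input <- nrow(rec)
  miss <- is.na(rec$beta) | is.na(rec$se)
  rec <- rec[!miss, , drop = FALSE]
  bad_se <- rec$se <= 0
  rec <- rec[!bad_se, , drop = FALSE]
  bad_n <- is.na(rec$n) | rec$n <= 1
  rec <- rec[!bad_n, , drop = FALSE]
  bad_allele <- !(rec$ea %in% VALID_ALLELES & rec$oa %in% VALID_ALLELES)
  rec <- rec[!bad_allele, , drop = FALSE]
  dup <- duplicated(rec$snp)
  if (any(dup))
    stopf("duplicated SNP id(s) in trait '%s': %s", trait_name,
          paste(unique(rec$snp[dup]), collapse = ", "))
  rownames(rec) <- NULL
  structure(list(trait_name = trait_name,
                 records = rec,
                 report = c(n_input = n_input,
                            n_kept = nrow(rec),
                            n_missing_dropped = sum(miss),
                            n_se_dropped = sum(bad_se),
                            n_n_dropped = sum(bad_n),
                            n_allele_dropped = sum(bad_allele))),
            class = "summary_stats")
}

#' Write a summary-statistics table as a header TSV
#' @param x a `summary_stats` object.
#' @param path output path.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  out <- x$records
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE", "N")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait %s: %d records (of %d input rows)\n",
              x$trait_name, nrow(x$records), x$report[["n_input"]]))
  invisible(x)
}

#' Read a labeled square trait-correlation table
#'
#' The file must be a header TSV whose row and column labels agree. Symmetry
#' is enforced within `1e-12`, the diagonal must equal 1, and off-diagonals
#' must lie strictly inside (-1, 1).
#'
#' @param path file path.
#' @param expected_traits optional ordered trait labels; the matrix is
#'   reordered to them (error if any is absent).
#' @return a K x K numeric matrix with trait dimnames.
#' @export
read_trait_correlations <- function(path, expected_traits = NULL) {
  raw <- read.table(path, header = TRUE, sep = "", check.names = FALSE,
                    row.names = 1)
  M <- as.matrix(raw)
  if (nrow(M) != ncol(M) || !setequal(rownames(M), colnames(M)))
    stopf("trait correlation file must be square with matching labels")
  M <- M[colnames(M), , drop = FALSE]  # same label order on both axes
  validate_trait_correlations(M)
  if (!is.null(expected_traits)) {
    missing <- setdiff(expected_traits, rownames(M))
    if (length(missing) > 0)
      stopf("trait(s) absent from correlation file: %s",
            paste(missing, collapse = ", "))
    M <- M[expected_traits, expected_traits, drop = FALSE]
  }
  M
}

#' Validate a trait-correlation matrix (symmetry, unit diagonal, |r|<1)
#' @param M square numeric matrix with dimnames.
#' @return `M`, invisibly, if valid; error otherwise.
#' @export
validate_trait_correlations <- function(M) {
  check_symmetric(M, 1e-12, "trait correlation matrix")
  if (max(abs(diag(M) - 1)) > 1e-12)
    stopf("trait correlation matrix diagonal must equal 1")
  off <- M[row(M) != col(M)]
  if (length(off) > 0 && max(abs(off)) >= 1)
    stopf("off-diagonal trait correlations must satisfy |r| < 1")
  invisible(M)
}

#' Write a trait-correlation matrix as a labeled TSV
#' @param M matrix with trait dimnames.
#' @param path output path.
#' @export
write_trait_correlations <- function(M, path) {
  df <- data.frame(trait = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a glist-hg19-style gene-range file
#'
#' Four whitespace-delimited columns without a header: chrom, start, end,
#' gene name. Ranges are 1-based and inclusive on both ends. Rows with
#' `start > end` are rejected with a warning; duplicate gene names are an
#' error; an empty file yields an empty list with a warning.
#'
#' @param path file path.
#' @return data.frame `chrom, start, end, gene` sorted by (chrom, start),
#'   gene names uppercased, with attribute `n_rejected`.
#' @export
read_gene_ranges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gene = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) {
    warnf("gene-range file '%s' is empty", path)
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  raw <- read.table(text = lines, header = FALSE, sep = "",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "gene"))
  raw$chrom <- as.character(raw$chrom)
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  raw$gene <- toupper(as.character(raw$gene))
  bad <- raw$start > raw$end
  if (any(bad))
    warnf("rejected %d gene range(s) with start > end", sum(bad))
  raw <- raw[!bad, , drop = FALSE]
  dup <- duplicated(raw$gene)
  if (any(dup))
    stopf("duplicated gene name(s) in range file: %s",
          paste(unique(raw$gene[dup]), collapse = ", "))
  raw <- raw[order(raw$chrom, raw$start), , drop = FALSE]
  rownames(raw) <- NULL
  attr(raw, "n_rejected") <- sum(bad)
  raw
}

#' Write gene ranges in glist-hg19 layout (chrom start end gene, no header)
#' @param ranges data.frame as returned by [read_gene_ranges()].
#' @param path output path.
#' @export
write_gene_ranges <- function(ranges, path) {
  write.table(ranges[, c("chrom", "start", "end", "gene")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard GMT: set name, description, then member genes, tab-separated.
#' Genes are uppercased and deduplicated within each set; lines with fewer
#' than three fields, and sets left empty after cleaning, are dropped with a
#' warning.
#'
#' @param path file path.
#' @param source_label free-text provenance label stored on the result.
#' @return a `gene_set_library`: named list of character vectors with
#'   attributes `source_label` and `n_rejected`.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  n_rejected <- 0L
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(fields) < 3 || length(genes) == 0) {
      n_rejected <- n_rejected + 1L
      next
    }
    sets[[fields[[1]]]] <- genes
  }
  if (n_rejected > 0)
    warnf("dropped %d malformed/empty GMT line(s)", n_rejected)
  structure(sets, source_label = source_label, n_rejected = n_rejected,
            class = c("gene_set_library", "list"))
}

#' Write a gene-set library in GMT format
#' @param library a `gene_set_library` (or named list of gene vectors).
#' @param path output path.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library), function(nm) {
    paste(c(nm, "na", library[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference genotype panel (VCF or plain dosage matrix)
#'
#' For `format = "vcf"` (uncompressed or bgzipped VCF with GT fields;
#' requires the VariantAnnotation package) dosages are counts of the
#' alternate allele; multi-allelic records are skipped with a warning and a
#' non-diploid genotype is an error. For `format = "dosage"` the file is a
#' header TSV whose columns are SNP ids and rows are individuals (values 0, 1,
#' 2 or NA). In both cases monomorphic SNPs are dropped and counted.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage"` (`"auto"` guesses from the extension).
#' @return a `reference_panel`: list with `snp_ids`, `map` (data.frame
#'   `snp, chrom, pos`; NA positions for plain matrices without coordinates),
#'   `dosages` (individuals x SNPs matrix), and dropped/skipped counts.
#' @export
read_reference_panel <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") panel_from_vcf(path) else panel_from_dosage(path)
}

panel_from_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stopf("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt_n <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  multi <- alt_n > 1
  if (any(multi))
    warnf("skipped %d multi-allelic VCF record(s)", sum(multi))
  vcf <- vcf[!multi]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF has no GT field")
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(snp = rownames(gt),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    stringsAsFactors = FALSE)
  make_panel(t(dos), map, n_multiallelic_skipped = sum(multi))
}

gt_to_dosage <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  if (length(alleles) != 2)
    stopf("non-diploid genotype '%s' in VCF", g)
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

panel_from_dosage <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "", check.names = FALSE)
  M <- as.matrix(raw)
  storage.mode(M) <- "double"
  bad <- !(is.na(M) | M %in% c(0, 1, 2))
  if (any(bad)) stopf("dosage matrix contains values outside {0, 1, 2, NA}")
  map <- data.frame(snp = colnames(M), chrom = NA_character_,
                    pos = NA_integer_, stringsAsFactors = FALSE)
  make_panel(M, map)
}

# Shared panel constructor: drops monomorphic columns, builds the object.
make_panel <- function(dosages, map, n_multiallelic_skipped = 0L) {
  v <- apply(dosages, 2, function(x) stats::var(x, na.rm = TRUE))
  mono <- is.na(v) | v == 0
  if (any(mono)) {
    dosages <- dosages[, !mono, drop = FALSE]
    map <- map[!mono, , drop = FALSE]
  }
  rownames(map) <- NULL
  structure(list(snp_ids = map$snp,
                 map = map,
                 dosages = dosages,
                 n_monomorphic_dropped = sum(mono),
                 n_multiallelic_skipped = n_multiallelic_skipped),
            class = "reference_panel")
}

#' Write a reference panel as a plain dosage matrix (header TSV)
#' @param panel a `reference_panel`.
#' @param path output path.
#' @export
write_reference_panel <- function(panel, path) {
  write.table(panel$dosages, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d individuals x %d SNPs (%d monomorphic dropped)\n",
              nrow(x$dosages), ncol(x$dosages), x$n_monomorphic_dropped))
  invisible(x)
}

#' Published phenotypic correlations among six European metabolic traits
#'
#' Pairwise phenotypic Pearson correlations among fasting glucose (FG),
#' fasting insulin (FI), body-mass index (BMI), waist-hip ratio (WHR), HDL
#' cholesterol and triglycerides (TG), as published for the ENGAGE consortium
#' European-ancestry meta-analyses. Used as the default trait-trait block
#' (`Sigma_YY`) and as the default synthetic-data trait correlation.
#'
#' @return a 6 x 6 correlation matrix with trait dimnames.
#' @export
engage_trait_cor <- function() {
  traits <- c("FG", "FI", "BMI", "WHR", "HDL", "TG")
  M <- matrix(c(
     1.00, 0.35, 0.24, 0.17, -0.15,  0.19,
     0.35, 1.00, 0.52, 0.39, -0.37,  0.40,
     0.24, 0.52, 1.00, 0.51, -0.32,  0.30,
     0.17, 0.39, 0.51, 1.00, -0.30,  0.33,
    -0.15, -0.37, -0.32, -0.30, 1.00, -0.52,
     0.19, 0.40, 0.30, 0.33, -0.52,  1.00), 6, 6, byrow = TRUE,
    dimnames = list(traits, traits))
  M
}

#' Published per-trait sample sizes for the six metabolic traits
#'
#' Meta-analysis sample sizes matching [engage_trait_cor()] (FG 46,694;
#' FI 24,245; BMI 87,048; WHR 54,572; HDL 62,166; TG 62,166).
#'
#' @return named integer vector.
#' @export
engage_trait_n <- function() {
  c(FG = 46694L, FI = 24245L, BMI = 87048L, WHR = 54572L,
    HDL = 62166L, TG = 62166L)
}
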