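#' Construct a genotype dataset
#'
#' Bundles variant-allele call counts with SNP metadata.  Calls are counts of
#' the variant allele (0, 1 or 2 copies) per individual and SNP; every SNP
#' belongs to exactly one gene.
#'
#' @param calls integer matrix, individuals x SNPs, entries in \{0, 1, 2\},
#'   no missing values.  Column names, if present, must match `snp_id`.
#' @param snps data frame with columns `snp_id`, `gene`, `chrom`.
#' @param samples character vector of individual ids (defaults to the row
#'   names of `calls`).
#' @return An object of class `"genotype_dataset"`: a list with elements
#'   `samples`, `snps` and `calls`.
#' @export
genotype_dataset <- function(calls, snps, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("IND", seq_len(nrow(calls)))
  snps <- as.data.frame(snps)
  stopifnot(all(c("snp_id", "gene", "chrom") %in% names(snps)))
  if (nrow(snps) != ncol(calls))
    stop("`snps` must have one row per column of `calls`")
  if (anyNA(calls))
    stop("missing genotype calls are not supported (no imputation)")
  if (!all(calls %in% c(0L, 1L, 2L)))
    stop("genotype calls must be variant-allele counts in {0, 1, 2}")
  if (nrow(calls) < 2L)
    stop("at least 2 individuals are required")
  if (anyDuplicated(snps$snp_id))
    stop("duplicated SNP ids in metadata")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(samples, snps$snp_id)
  structure(
    list(samples = as.character(samples),
         snps = data.frame(snp_id = as.character(snps$snp_id),
                           gene = as.character(snps$gene),
                           chrom = as.character(snps$chrom),
                           stringsAsFactors = FALSE),
         calls = calls),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("Genotype dataset:", length(x$samples), "individuals,",
      nrow(x$snps), "SNPs in", length(unique(x$snps$gene)), "genes\n")
  invisible(x)
}

#' Per-SNP variant-allele frequency and MAF
#'
#' The variant-allele frequency is computed from the calls themselves,
#' `p = sum(calls) / (2 n)`; the MAF is `min(p, 1 - p)`.  A private
#' (singleton) variant carried by a single heterozygote among n individuals
#' has MAF `1 / (2 n)`.
#'
#' @param dataset a [genotype_dataset()].
#' @return Data frame with columns `snp_id`, `gene`, `p_variant`, `maf`.
#' @export
allele_frequencies <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- nrow(dataset$calls)
  p <- colSums(dataset$calls) / (2 * n)
  data.frame(snp_id = dataset$snps$snp_id,
             gene = dataset$snps$gene,
             p_variant = unname(p),
             maf = unname(pmin(p, 1 - p)),
             stringsAsFactors = FALSE)
}

read_gene_map <- function(path) {
  gm <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "gene", "chrom") %in% names(gm)))
  gm
}

read_phenotypes <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "affected")
  if (!all(need %in% names(ph)))
    stop("phenotype file must have columns sample_id and affected")
  ph
}

read_genotype_tsv <- function(path) {
  g <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  samples <- as.character(g[[1L]])
  calls <- as.matrix(g[, -1L, drop = FALSE])
  if (anyNA(calls)) stop("missing genotype calls in ", path)
  storage.mode(calls) <- "integer"
  rownames(calls) <- samples
  calls
}

read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids))
    stop("VCF records must carry SNP ids in the ID column")
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("multi-allelic VCF records are not supported")
  cnt <- vapply(strsplit(as.vector(gt), "[/|]"), function(al) {
    if (length(al) == 0L || anyNA(al) || any(al == "."))
      return(NA_integer_)
    sum(al != "0")
  }, integer(1))
  cnt[is.na(as.vector(gt))] <- NA_integer_
  if (anyNA(cnt))
    stop("missing genotype calls are not supported (no imputation)")
  calls <- t(matrix(cnt, nrow = nrow(gt)))     # individuals x SNPs
  colnames(calls) <- ids
  rownames(calls) <- colnames(gt)
  storage.mode(calls) <- "integer"
  calls
}

#' Load genotypes, gene map and phenotypes
#'
#' Reads the three input files, orients calls as counts of the variant
#' (VCF ALT) allele, and aligns the phenotype rows to the genotype sample
#' order.  Every SNP in the genotype file must appear in the gene map;
#' missing calls and non-binary phenotypes are errors.
#'
#' @param genotype_path VCF or genotype TSV (header of SNP ids, first column
#'   sample id, cells in \{0,1,2\}).
#' @param gene_map_path TSV with columns `snp_id`, `gene`, `chrom`.
#' @param phenotype_path TSV with columns `sample_id`, `affected` (0/1) and
#'   covariates (`age`, `sex`, `smoke`).
#' @param format `"tsv"` or `"vcf"`.
#' @return List with elements `dataset` (a [genotype_dataset()]),
#'   `phenotypes` (data frame aligned to the sample order) and `y`
#'   (the binary outcome vector).
#' @export
load_dataset <- function(genotype_path, gene_map_path, phenotype_path,
                         format = c("tsv", "vcf")) {
  format <- match.arg(format)
  calls <- switch(format,
                  tsv = read_genotype_tsv(genotype_path),
                  vcf = read_genotype_vcf(genotype_path))
  gm <- read_gene_map(gene_map_path)
  missing_snps <- setdiff(colnames(calls), gm$snp_id)
  if (length(missing_snps) > 0L)
    stop("SNP(s) absent from gene map: ",
         paste(missing_snps, collapse = ", "))
  gm <- gm[match(colnames(calls), gm$snp_id), , drop = FALSE]
  ds <- genotype_dataset(calls, gm)

  ph <- read_phenotypes(phenotype_path)
  idx <- match(ds$samples, ph$sample_id)
  if (anyNA(idx))
    stop("phenotype file lacks sample(s): ",
         paste(ds$samples[is.na(idx)], collapse = ", "))
  ph <- ph[idx, , drop = FALSE]
  rownames(ph) <- NULL
  y <- ph$affected
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("phenotype column `affected` must be binary 0/1")
  list(dataset = ds, phenotypes = ph, y = as.integer(y))
}

#' Write a dataset in the package's TSV dialects
#'
#' Writes `genotypes.tsv`, `gene_map.tsv` and `phenotypes.tsv` into `dir`.
#' Round-tripping through [load_dataset()] reproduces the calls exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param phenotypes data frame with `sample_id`, `affected` and covariates.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, phenotypes, dir) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gpath <- file.path(dir, "genotypes.tsv")
  mpath <- file.path(dir, "gene_map.tsv")
  ppath <- file.path(dir, "phenotypes.tsv")
  g <- data.frame(sample_id = dataset$samples, dataset$calls,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(g, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$snps, mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(phenotypes, ppath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(genotypes = gpath, gene_map = mpath, phenotypes = ppath))
}
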