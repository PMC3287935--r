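#' Additive genotype coding
#'
#' Traditional additive coding on the common/variant allele labels:
#' two variant alleles (aa) map to -1, the heterozygote to 0, two common
#' alleles (AA) to +1; equivalently `1 - calls`.
#'
#' @param dataset a [genotype_dataset()].
#' @return Numeric matrix with entries in \{-1, 0, +1\}.
#' @export
build_Z <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  Z <- 1 - dataset$calls
  storage.mode(Z) <- "double"
  Z
}

#' Allele-frequency-standardized genotype coding
#'
#' Standardizes each additive column to mean 0 and variance 1 under
#' Hardy-Weinberg proportions at its own allele frequencies:
#' `zstar = (z - (pA - pa)) / sqrt(2 pA pa)` with `pa` the variant-allele
#' frequency and `pA = 1 - pa`.  Effects on this scale are the scaled
#' average effect of substituting the common allele by the variant allele,
#' which is what gives rare variants leverage in the model.
#'
#' @param dataset a [genotype_dataset()].
#' @param freqs frequency table from [allele_frequencies()]; recomputed
#'   when omitted.
#' @return Numeric matrix, same shape and column order as [build_Z()].
#' @export
build_Zstar <- function(dataset, freqs = allele_frequencies(dataset)) {
  Z <- build_Z(dataset)
  p <- freqs$p_variant[match(colnames(Z), freqs$snp_id)]
  bad <- which(p <= 0 | p >= 1)
  if (length(bad) > 0L)
    stop("monomorphic SNP(s), standardization undefined: ",
         paste(colnames(Z)[bad], collapse = ", "))
  ctr <- (1 - p) - p                     # pA - pa
  scl <- sqrt(2 * (1 - p) * p)
  sweep(sweep(Z, 2L, ctr, "-"), 2L, scl, "/")
}

#' Greedy per-gene collinearity pruning
#'
#' Walks the SNPs of each gene in input order, tentatively appending each
#' additive column to the gene's matrix K; a column that leaves K'K
#' rank-deficient (its component orthogonal to the columns already kept has
#' relative norm below `tol`) is discarded with reason `"collinear"`.  The
#' first polymorphic SNP of a gene is always retained.  Rank is assessed by
#' orthogonalization with re-orthogonalization, the numerically robust
#' equivalent of the determinant-of-Gram-matrix test.
#'
#' @param Z additive design matrix (columns named by SNP).
#' @param gene character vector of gene labels, one per column of `Z`.
#' @param tol relative tolerance for rank deficiency.
#' @return List with `keep` (column indices retained, grouped contiguously
#'   by gene in order of first appearance) and `removed` (data frame
#'   `snp_id`, `gene`, `reason`).
#' @export
prune_collinear <- function(Z, gene, tol = 1e-8) {
  stopifnot(ncol(Z) == length(gene))
  genes <- unique(gene)
  keep <- integer(0)
  rem_id <- character(0)
  rem_gene <- character(0)
  for (g in genes) {
    cols <- which(gene == g)
    Q <- NULL                            # orthonormal basis of kept columns
    kept_g <- integer(0)
    for (j in cols) {
      v <- Z[, j]
      nv <- sqrt(sum(v^2))
      if (nv == 0) {                     # zero column can never add rank
        rem_id <- c(rem_id, colnames(Z)[j]); rem_gene <- c(rem_gene, g)
        next
      }
      r <- v
      if (!is.null(Q)) {
        r <- r - Q %*% crossprod(Q, r)
        r <- r - Q %*% crossprod(Q, r)   # re-orthogonalize
      }
      nr <- sqrt(sum(r^2))
      if (nr > tol * nv) {
        Q <- cbind(Q, r / nr)
        kept_g <- c(kept_g, j)
      } else {
        rem_id <- c(rem_id, colnames(Z)[j]); rem_gene <- c(rem_gene, g)
      }
    }
    if (length(kept_g) == 0L)
      stop("gene ", g, ": every SNP column discarded (zero columns only)")
    keep <- c(keep, kept_g)
  }
  list(keep = keep,
       removed = data.frame(snp_id = rem_id, gene = rem_gene,
                            reason = rep("collinear", length(rem_id)),
                            stringsAsFactors = FALSE))
}

#' Build pruned design matrices for the association model
#'
#' Full preparation pipeline: compute allele frequencies, drop monomorphic
#' SNPs (reason `"monomorphic"`; the standardization is undefined at
#' frequency 0 or 1), prune exact within-gene collinearity on the additive
#' coding (reason `"collinear"`), then build the additive matrix `Z` and its
#' allele-frequency-standardized counterpart `Zstar` on the retained SNPs.
#' Columns are grouped contiguously by gene; a gene whose every SNP is
#' monomorphic is dropped entirely (all its SNPs appear in the removal log).
#'
#' @param dataset a [genotype_dataset()].
#' @param tol relative collinearity tolerance, see [prune_collinear()].
#' @return Object of class `"spikegene_design"`: list with `Z`, `Zstar`,
#'   `gene_blocks` (named list of contiguous column index vectors),
#'   `snps` (retained SNP metadata with frequencies), `removed`
#'   (removal log), `samples`, `tol`.
#' @export
build_design <- function(dataset, tol = 1e-8) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  freqs <- allele_frequencies(dataset)
  mono <- freqs$p_variant <= 0 | freqs$p_variant >= 1
  removed <- data.frame(snp_id = freqs$snp_id[mono],
                        gene = freqs$gene[mono],
                        reason = rep("monomorphic", sum(mono)),
                        stringsAsFactors = FALSE)
  ds <- dataset
  if (any(mono)) {
    ds <- genotype_dataset(dataset$calls[, !mono, drop = FALSE],
                           dataset$snps[!mono, , drop = FALSE],
                           dataset$samples)
  }
  if (ncol(ds$calls) == 0L)
    stop("no polymorphic SNPs left after monomorphic removal")
  Zfull <- build_Z(ds)
  pr <- prune_collinear(Zfull, ds$snps$gene, tol = tol)
  removed <- rbind(removed, pr$removed)
  ds <- genotype_dataset(ds$calls[, pr$keep, drop = FALSE],
                         ds$snps[pr$keep, , drop = FALSE],
                         ds$samples)
  freqs <- allele_frequencies(ds)
  Z <- build_Z(ds)
  Zstar <- build_Zstar(ds, freqs)
  genes <- unique(ds$snps$gene)
  gene_blocks <- lapply(genes, function(g) which(ds$snps$gene == g))
  names(gene_blocks) <- genes
  structure(
    list(Z = Z, Zstar = Zstar, gene_blocks = gene_blocks,
         snps = cbind(ds$snps,
                      p_variant = freqs$p_variant, maf = freqs$maf),
         removed = removed, samples = ds$samples, tol = tol),
    class = "spikegene_design")
}

#' @export
print.spikegene_design <- function(x, ...) {
  cat("spikegene design:", ncol(x$Z), "retained SNPs in",
      length(x$gene_blocks), "genes (", nrow(x$removed), "removed;",
      sum(x$removed$reason == "collinear"), "collinear,",
      sum(x$removed$reason == "monomorphic"), "monomorphic )\n")
  cat(sprintf("mean SNPs/gene %.2f, mean MAF %.4f\n",
              ncol(x$Z) / length(x$gene_blocks), mean(x$snps$maf)))
  invisible(x)
}

#' Write prepared design artifacts
#'
#' Writes `Z.tsv`, `Zstar.tsv`, `gene_blocks.tsv`, `removed.tsv` and a
#' one-row `summary.tsv` (SNP/gene counts, mean SNPs per gene, mean MAF)
#' into `dir`.
#'
#' @param design a [build_design()] result.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_design <- function(design, dir) {
  stopifnot(inherits(design, "spikegene_design"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wr(data.frame(sample_id = design$samples, design$Z, check.names = FALSE),
     "Z.tsv")
  wr(data.frame(sample_id = design$samples, design$Zstar,
                check.names = FALSE), "Zstar.tsv")
  blocks <- data.frame(
    gene = names(design$gene_blocks),
    first = vapply(design$gene_blocks, min, integer(1)),
    last = vapply(design$gene_blocks, max, integer(1)))
  wr(blocks, "gene_blocks.tsv")
  wr(design$removed, "removed.tsv")
  wr(data.frame(n_snps = ncol(design$Z),
                n_genes = length(design$gene_blocks),
                n_removed = nrow(design$removed),
                mean_snps_per_gene =
                  round(ncol(design$Z) / length(design$gene_blocks), 2),
                mean_maf = mean(design$snps$maf)),
     "summary.tsv")
  invisible(dir)
}
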