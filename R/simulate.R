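#' Configuration of the synthetic mini-exome generator
#'
#' The generator emulates the structure of a mini-exome case-control
#' resource: a rare-skewed MAF spectrum with a point mass of private
#' (singleton) variants at frequency `1/(2n)`, genes holding between one
#' and a few hundred SNPs, a ~30% prevalence binary outcome driven by a
#' logit liability with covariate effects and sparse SNP effects on the
#' standardized scale.
#'
#' Two presets are provided.  `"gaw17"` matches the published marginals of
#' the mini-exome reference (697 individuals, 3,205 genes, 1-203 SNPs per
#' gene averaging about 7.5, mean MAF about 0.044, prevalence about 0.30).
#' `"desk"` is a scaled-down configuration for tests and demonstrations
#' (400 individuals, 200 genes, 2-25 SNPs per gene with the same
#' rare-skewed spectrum).  `"toy"` is a minimal smoke-test scale.
#'
#' @param preset `"desk"`, `"gaw17"`, `"toy"`, or `NULL` for the bare
#'   defaults; individual arguments override the preset.
#' @param n_individuals sample size.
#' @param n_genes number of genes.
#' @param snps_per_gene list `(min, max, mean, size)`: SNPs per gene are
#'   `min` plus a negative binomial with mean `mean - min` and dispersion
#'   `size`, redrawn above `max`.
#' @param maf_spectrum list `(singleton_prob, shape1, shape2)`: with
#'   probability `singleton_prob` a SNP is a singleton (exactly one
#'   heterozygous carrier, MAF exactly `1/(2 n)`); otherwise its population
#'   MAF is `0.5 * Beta(shape1, shape2)` and genotypes are drawn under
#'   Hardy-Weinberg.
#' @param prop_causal_genes probability a gene is causal (the true
#'   gene-level mixing proportion).
#' @param causal_snps_per_gene `"all"` (every SNP of a causal gene carries
#'   an effect, so the SNP-level slab proportion matches
#'   `prop_causal_genes` in expectation) or a list `(min, max)` for a
#'   uniform count capped at gene size.
#' @param effect_scale SD of causal SNP effects on the standardized
#'   liability scale.
#' @param covariate_effects named numeric `(age, sex, smoke)` liability
#'   coefficients.
#' @param prevalence target disease prevalence used to set the intercept
#'   when `intercept` is `NULL`.
#' @param intercept liability intercept; when `NULL`, chosen so the
#'   null-genetic model has the target prevalence at the covariate means.
#' @param collinearity_dup_rate probability that a SNP (after the first of
#'   its gene) is an exact duplicate of an earlier SNP in the same gene,
#'   exercising the collinearity pruner.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(preset = NULL,
                       n_individuals = 400,
                       n_genes = 200,
                       snps_per_gene = list(min = 3, max = 25, mean = 7.5,
                                            size = 1.2),
                       maf_spectrum = list(singleton_prob = 0.25,
                                           shape1 = 0.35, shape2 = 2.66),
                       prop_causal_genes = 0.05,
                       causal_snps_per_gene = "all",
                       effect_scale = 0.8,
                       covariate_effects = c(age = 0.01, sex = 0.25,
                                             smoke = 0.35),
                       prevalence = 0.30,
                       intercept = NULL,
                       collinearity_dup_rate = 0.02) {
  cfg <- list(n_individuals = n_individuals, n_genes = n_genes,
              snps_per_gene = snps_per_gene, maf_spectrum = maf_spectrum,
              prop_causal_genes = prop_causal_genes,
              causal_snps_per_gene = causal_snps_per_gene,
              effect_scale = effect_scale,
              covariate_effects = covariate_effects,
              prevalence = prevalence, intercept = intercept,
              collinearity_dup_rate = collinearity_dup_rate)
  supplied <- names(as.list(match.call()))[-1L]
  supplied <- setdiff(supplied, "preset")
  if (!is.null(preset)) {
    preset_cfg <- switch(
      match.arg(preset, c("desk", "gaw17", "toy")),
      desk = list(),
      gaw17 = list(n_individuals = 697, n_genes = 3205,
                   snps_per_gene = list(min = 1, max = 203, mean = 7.48,
                                        size = 0.55)),
      toy = list(n_individuals = 120, n_genes = 12,
                 snps_per_gene = list(min = 2, max = 6, mean = 3,
                                      size = 2),
                 maf_spectrum = list(singleton_prob = 0.1,
                                     shape1 = 0.8, shape2 = 2.0),
                 prop_causal_genes = 0.25, effect_scale = 1.2))
    keep <- setdiff(names(preset_cfg), supplied)
    cfg[keep] <- preset_cfg[keep]
  }
  stopifnot(cfg$n_individuals >= 2,
            cfg$prop_causal_genes >= 0, cfg$prop_causal_genes <= 1,
            cfg$effect_scale >= 0,
            cfg$maf_spectrum$singleton_prob >= 0,
            cfg$maf_spectrum$singleton_prob <= 1,
            cfg$collinearity_dup_rate >= 0, cfg$collinearity_dup_rate <= 1,
            cfg$prevalence > 0, cfg$prevalence < 1)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
gaw17_like_preset <- function() sim_config(preset = "gaw17")

#' @rdname sim_config
#' @export
desk_preset <- function() sim_config(preset = "desk")

draw_snp_counts <- function(n_genes, spec) {
  out <- integer(n_genes)
  todo <- seq_len(n_genes)
  while (length(todo) > 0L) {
    draw <- spec$min + rnbinom(length(todo), size = spec$size,
                               mu = spec$mean - spec$min)
    ok <- draw <= spec$max
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate a synthetic mini-exome case-control dataset
#'
#' Draws per-SNP population MAFs from the configured rare-skewed spectrum,
#' genotypes under Hardy-Weinberg (singletons are placed as exactly one
#' heterozygote), duplicates occasional columns to exercise pruning,
#' assigns causal genes Bernoulli(`prop_causal_genes`) with effects
#' `N(0, effect_scale^2)` on the population-standardized scale, and draws
#' the binary outcome from the logit liability.  Everything is reproducible
#' from `seed`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param dir if non-NULL, also write `genotypes.tsv`, `gene_map.tsv`,
#'   `phenotypes.tsv` and `truth.json` into this directory.
#' @return List with `dataset` (a [genotype_dataset()]), `phenotypes`
#'   (data frame `sample_id`, `affected`, `age`, `sex`, `smoke`) and
#'   `truth` (class `"spikegene_truth"`: `causal_genes`, `causal_snps`
#'   with true effects, `lambda_true`, `prevalence` realized, the config).
#' @export
simulate_exome <- function(config, seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_individuals
  ng <- config$n_genes
  singleton_maf <- 1 / (2 * n)

  counts <- draw_snp_counts(ng, config$snps_per_gene)
  genes <- sprintf("GENE%04d", seq_len(ng))
  chrom <- as.character(rep_len(1:22, ng))

  m_total <- sum(counts)
  snp_gene <- rep(genes, counts)
  snp_chrom <- rep(chrom, counts)
  calls <- matrix(0L, n, m_total)
  maf_drawn <- numeric(m_total)
  dup_of <- integer(m_total)               # 0 = original

  col <- 0L
  for (g in seq_len(ng)) {
    first <- col + 1L
    for (k in seq_len(counts[g])) {
      col <- col + 1L
      if (k > 1L && runif(1) < config$collinearity_dup_rate) {
        cand <- first:(col - 1L)
        src <- cand[sample.int(length(cand), 1L)]
        calls[, col] <- calls[, src]
        maf_drawn[col] <- maf_drawn[src]
        dup_of[col] <- src
        next
      }
      if (runif(1) < config$maf_spectrum$singleton_prob) {
        carrier <- sample.int(n, 1L)
        calls[carrier, col] <- 1L
        maf_drawn[col] <- singleton_maf
      } else {
        p <- 0.5 * rbeta(1, config$maf_spectrum$shape1,
                         config$maf_spectrum$shape2)
        p <- min(max(p, singleton_maf / 2), 0.5)
        calls[, col] <- rbinom(n, 2L, p)
        maf_drawn[col] <- p
      }
    }
  }
  snp_id <- paste0(snp_gene, "_S", unlist(lapply(counts, seq_len)))

  # covariates
  age <- round(pmin(pmax(rnorm(n, 45, 12), 18), 90))
  sex <- rbinom(n, 1L, 0.5)
  smoke <- rbinom(n, 1L, 0.25)
  ce <- config$covariate_effects
  intercept <- config$intercept
  if (is.null(intercept))
    intercept <- qlogis(config$prevalence) -
      sum(ce * c(age = 45, sex = 0.5, smoke = 0.25))

  # causal structure: effects on the population-standardized scale
  causal_gene <- runif(ng) < config$prop_causal_genes
  u_true <- numeric(m_total)
  is_causal_snp <- logical(m_total)
  for (g in which(causal_gene)) {
    idx <- which(snp_gene == genes[g] & dup_of == 0L)
    if (length(idx) == 0L) next
    pick <- if (identical(config$causal_snps_per_gene, "all")) {
      idx
    } else {
      kk <- sample(config$causal_snps_per_gene$min:
                     config$causal_snps_per_gene$max, 1L)
      sample(idx, min(kk, length(idx)))
    }
    is_causal_snp[pick] <- TRUE
    u_true[pick] <- rnorm(length(pick), 0, config$effect_scale)
  }

  eta <- intercept + ce["age"] * age + ce["sex"] * sex + ce["smoke"] * smoke
  eta <- unname(eta)
  for (j in which(is_causal_snp)) {
    pa <- maf_drawn[j]
    zstar <- ((1 - calls[, j]) - (1 - 2 * pa)) / sqrt(2 * pa * (1 - pa))
    eta <- eta + zstar * u_true[j]
  }
  y <- rbinom(n, 1L, plogis(eta))

  samples <- sprintf("IND%04d", seq_len(n))
  ds <- genotype_dataset(calls,
                         data.frame(snp_id = snp_id, gene = snp_gene,
                                    chrom = snp_chrom,
                                    stringsAsFactors = FALSE),
                         samples = samples)
  ph <- data.frame(sample_id = samples, affected = y, age = age,
                   sex = sex, smoke = smoke, stringsAsFactors = FALSE)
  truth <- structure(
    list(causal_genes = genes[causal_gene],
         causal_snps = data.frame(
           snp_id = snp_id[is_causal_snp],
           gene = snp_gene[is_causal_snp],
           effect = u_true[is_causal_snp],
           maf_drawn = maf_drawn[is_causal_snp],
           stringsAsFactors = FALSE),
         maf_drawn = setNames(maf_drawn, snp_id),
         duplicates = snp_id[dup_of > 0L],
         lambda_true = config$prop_causal_genes,
         prevalence = mean(y),
         seed = seed,
         config = unclass(config)),
    class = "spikegene_truth")
  out <- list(dataset = ds, phenotypes = ph, truth = truth)
  if (!is.null(dir)) {
    write_dataset(ds, ph, dir)
    write_truth(truth, file.path(dir, "truth.json"))
  }
  out
}

#' Serialize / read simulation truth
#'
#' @param truth a `"spikegene_truth"` object.
#' @param path JSON file path.
#' @return `write_truth` returns the path invisibly; `read_truth` the
#'   restored `"spikegene_truth"` object.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "spikegene_truth"))
  x <- unclass(truth)
  x$maf_drawn <- as.list(x$maf_drawn)   # keep SNP names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$causal_snps <- as.data.frame(x$causal_snps)
  x$maf_drawn <- unlist(x$maf_drawn)
  x$causal_genes <- as.character(x$causal_genes)
  x$duplicates <- as.character(x$duplicates)
  structure(x, class = "spikegene_truth")
}

#' @export
print.spikegene_truth <- function(x, ...) {
  cat("Simulation truth:", length(x$causal_genes), "causal genes,",
      nrow(x$causal_snps), "causal SNPs, lambda_true =", x$lambda_true,
      ", realized prevalence", round(x$prevalence, 3), "\n")
  invisible(x)
}
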