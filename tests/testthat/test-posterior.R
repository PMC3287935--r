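test_that("gene probabilities count any-active draws", {
  w <- rbind(c(1L, 0L), c(0L, 0L), c(0L, 0L), c(1L, 1L), c(0L, 0L))
  colnames(w) <- c("SNP1", "SNP2")
  gb <- list(G = 1:2)
  expect_equal(gene_probabilities(w, gb), c(G = 2 / 5))

  # all draws inactive
  expect_equal(gene_probabilities(matrix(0L, 5, 2), gb), c(G = 0))

  # single-SNP gene equals that SNP's inclusion mean
  gb2 <- list(A = 1L, B = 2L)
  expect_equal(gene_probabilities(w, gb2),
               c(A = mean(w[, 1]), B = mean(w[, 2])))

  # pooled chains = draw-count-weighted mean of per-chain values
  w2 <- rbind(c(0L, 1L), c(1L, 1L), c(0L, 0L))
  pooled <- gene_probabilities(rbind(w, w2), gb)
  expect_equal(pooled,
               (5 * gene_probabilities(w, gb) +
                  3 * gene_probabilities(w2, gb)) / 8)

  # monotone in added SNP columns
  expect_gte(gene_probabilities(w, list(G = 1:2))[["G"]],
             gene_probabilities(w, list(G = 1L))[["G"]])

  expect_error(gene_probabilities(w[0, , drop = FALSE], gb), "draws")
})

test_that("gene flagging is strict at the threshold", {
  gp <- c(g1 = 0.81, g2 = 0.80, g3 = 1.0)
  expect_identical(as.character(flag_genes(gp, 0.8)), c("g3", "g1"))
  expect_identical(as.character(flag_genes(gp, 1.0)), character(0))
  expect_identical(as.character(flag_genes(c(a = 0, b = 0.01), 0)), "b")
  expect_error(flag_genes(gp, 1.5), "threshold")
  expect_error(flag_genes(gp, -0.1), "threshold")
})

test_that("HPD interval is the shortest window of sorted draws", {
  expect_equal(hpd_interval(rep(3.3, 10)), c(lower = 3.3, upper = 3.3))
  # uniform ties: leftmost width-94 window
  expect_equal(hpd_interval(1:100, 0.95), c(lower = 1, upper = 95))
  expect_error(hpd_interval(1), "2 draws")

  set.seed(10)
  z <- rnorm(1e6)
  h <- hpd_interval(z, 0.95)
  expect_lt(abs(h["lower"] + 1.95996), 0.02)
  expect_lt(abs(h["upper"] - 1.95996), 0.02)

  # dominance over the equal-tailed interval on unimodal draws
  g <- rgamma(2e4, shape = 3)
  hg <- hpd_interval(g, 0.9)
  et <- quantile(g, c(0.05, 0.95), names = FALSE)
  expect_lte(diff(unname(hg)), et[2] - et[1])
})

test_that("posterior mode finds the densest histogram bin", {
  expect_equal(posterior_mode(rep(0.4, 20)), 0.4)
  set.seed(11)
  b <- rbeta(1e6, 12, 108)
  expect_lt(abs(posterior_mode(b) - (12 - 1) / (12 + 108 - 2)), 0.01)
  # taller left mode of a bimodal mixture wins
  mix <- c(rnorm(6e4, -2, 0.3), rnorm(3e4, 2, 0.3))
  expect_lt(abs(posterior_mode(mix) + 2), 0.2)
})

test_that("effective size matches white-noise and AR(1) closed forms", {
  set.seed(12)
  iid <- rnorm(5000)
  expect_lt(abs(effective_size(iid) - 5000) / 5000, 0.10)

  n <- 1e5
  x <- ar1_chain(n, 0.5, seed = 13)
  expect_lt(abs(effective_size(x) - n / 3) / (n / 3), 0.10)

  expect_error(effective_size(rep(1, 500)), "variance")

  # independent cross-check against coda's spectral estimator
  ess_coda <- unname(coda::effectiveSize(coda::mcmc(x)))
  expect_lt(abs(effective_size(x) - ess_coda) / ess_coda, 0.25)
})

test_that("Raftery-Lewis dependence factor separates mixing regimes", {
  set.seed(14)
  ind <- rnorm(1e5)
  rl <- raftery_lewis(ind)
  expect_lt(abs(rl$dependence_factor - 1), 0.2)

  sticky <- markov_binary_chain(1e5, 0.01, 0.01, seed = 15) +
    rnorm(1e5, sd = 0.01)
  rl2 <- raftery_lewis(sticky, q = 0.5)
  expect_gt(rl2$dependence_factor, 5)
  expect_gt(rl2$burn_in, 1)

  alternating <- rep(c(0, 1), 5000)
  expect_error(raftery_lewis(alternating, q = 0.5), "degenerate|constant")
  expect_error(raftery_lewis(rnorm(20)), "too short")
})

test_that("convergence report is pure and applies the 80% ESS rule", {
  set.seed(16)
  mk_chain <- function(lam) {
    structure(list(lambda = lam, sigma2 = abs(rnorm(length(lam))) + 0.5,
                   beta = matrix(rnorm(length(lam)), ncol = 1,
                                 dimnames = list(NULL, "(Intercept)")),
                   accept = c(wu = 1, lambda = 1)),
              class = "spikegene_chain")
  }
  mk_fit <- function(lam) {
    structure(list(chains = list(mk_chain(lam)),
                   gene_blocks = list(G = 1L),
                   snps = data.frame(snp_id = "s", gene = "G", maf = 0.1)),
              class = "spikegene")
  }
  good <- mk_fit(rnorm(5000))
  rep_good <- convergence_report(good)
  expect_true(all(rep_good$pass[rep_good$parameter == "lambda"]))
  expect_gt(rep_good$ess[rep_good$parameter == "lambda"][1], 4000)

  bad <- mk_fit(ar1_chain(5000, 0.98, seed = 17))
  rep_bad <- convergence_report(bad)
  expect_false(any(rep_bad$pass[rep_bad$parameter == "lambda"]))
  expect_lt(rep_bad$ess[rep_bad$parameter == "lambda"][1], 4000)

  expect_identical(convergence_report(good), rep_good)

  # trace plots are written when requested
  dir <- withr::local_tempdir()
  convergence_report(good, plot_dir = dir)
  expect_true(file.exists(file.path(dir, "trace_lambda.png")))
})

test_that("summary and result tables carry the documented columns", {
  sim <- simulate_exome(sim_config(preset = "toy"), seed = 5)
  des <- build_design(sim$dataset)
  fit <- spikegene(affected ~ age + sex + smoke, data = sim$phenotypes,
                   design = des,
                   mcmc = spikegene_mcmc(n_iter = 600, burn_in = 200,
                                         thin = 2, n_chains = 2),
                   seed = 8)
  s <- summary(fit)
  expect_named(s$genes, c("gene", "n_snps", "mean_maf", "prob", "flagged"))
  expect_named(s$snps, c("snp_id", "gene", "maf", "inclusion_prob",
                         "effect_mean", "hpd_low", "hpd_high"))
  expect_true(all(s$genes$prob >= 0 & s$genes$prob <= 1))
  expect_true(all(s$snps$hpd_low <= s$snps$hpd_high))
  # a gene's probability is at least its best SNP's inclusion
  for (g in s$genes$gene) {
    expect_gte(s$genes$prob[s$genes$gene == g] + 1e-12,
               max(s$snps$inclusion_prob[s$snps$gene == g]))
  }
  expect_identical(as.character(flag_genes(gene_probabilities(fit))),
                   s$genes$gene[s$genes$flagged])

  dir <- withr::local_tempdir()
  write_results(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("gene_results.tsv",
                                               "snp_results.tsv",
                                               "diagnostics.json")))))
  tab <- read.table(file.path(dir, "gene_results.tsv"), header = TRUE,
                    sep = "\t")
  expect_identical(nrow(tab), length(des$gene_blocks))

  expect_type(coef(fit), "double")
  expect_length(coef(fit), ncol(fit$X))
  expect_length(coef(fit, type = "snp"), ncol(des$Zstar))
  expect_length(fitted(fit, design = des), length(fit$y))
  expect_true(all(fitted(fit, design = des) > 0 &
                    fitted(fit, design = des) < 1))
})
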