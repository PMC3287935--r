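pooled_w <- function(object) {
  if (inherits(object, "spikegene")) {
    do.call(rbind, lapply(object$chains, `[[`, "w"))
  } else if (inherits(object, "spikegene_chain")) {
    object$w
  } else if (is.list(object) &&
             all(vapply(object, inherits, logical(1), "spikegene_chain"))) {
    do.call(rbind, lapply(object, `[[`, "w"))
  } else {
    as.matrix(object)
  }
}

pooled_par <- function(object, what) {
  chains <- if (inherits(object, "spikegene")) object$chains else object
  unlist(lapply(chains, `[[`, what), use.names = FALSE)
}

#' Gene-level posterior association probabilities
#'
#' For each gene, the fraction of stored posterior draws (pooled across
#' chains) in which at least one SNP of that gene is included (`w = 1`).
#' This approximates the marginal probability of the gene carrying an
#' associated variant; genes with more SNPs can only (weakly) gain
#' probability from extra columns.
#'
#' @param object a fitted [spikegene()] model, a single chain, a list of
#'   chains, or a draws-by-SNPs indicator matrix.
#' @param gene_blocks named list mapping gene to column indices; taken from
#'   the fit when omitted.
#' @return Named numeric vector of per-gene probabilities in \[0, 1\].
#' @export
gene_probabilities <- function(object, gene_blocks = NULL) {
  if (is.null(gene_blocks)) {
    if (!inherits(object, "spikegene"))
      stop("gene_blocks must be supplied unless object is a spikegene fit")
    gene_blocks <- object$gene_blocks
  }
  w <- pooled_w(object)
  if (nrow(w) == 0L) stop("no stored draws")
  vapply(gene_blocks, function(idx)
    mean(rowSums(w[, idx, drop = FALSE]) > 0), numeric(1))
}

#' Flag genes above a posterior-probability threshold
#'
#' Returns the genes whose association probability is strictly greater than
#' the threshold (0.8 by default), sorted by decreasing probability and then
#' by name.
#'
#' @param gene_prob named probability vector from [gene_probabilities()].
#' @param threshold probability cut-off in \[0, 1\].
#' @return Character vector of gene names with the probabilities attached as
#'   a `"prob"` attribute.
#' @export
flag_genes <- function(gene_prob, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a probability in [0, 1]")
  sel <- gene_prob[gene_prob > threshold]
  ord <- order(-sel, names(sel))
  out <- names(sel)[ord]
  attr(out, "prob") <- unname(sel[ord])
  out
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws; ties in width are broken by the leftmost window.  For
#' unimodal samples its width never exceeds the equal-tailed interval's.
#'
#' @param draws numeric sample vector (at least 2 draws).
#' @param mass interval probability mass (default 0.95).
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (length(draws) < 2L) stop("at least 2 draws required")
  if (mass <= 0 || mass > 1) stop("mass must lie in (0, 1]")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  width <- x[k:n] - x[1:(n - k + 1L)]
  i <- which.min(width)                  # which.min takes the first minimum
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Posterior mode from a histogram density estimate
#'
#' Midpoint of the modal bin of a histogram with Freedman-Diaconis bin
#' widths (leftmost bin on ties).  Degenerate zero-spread draws return the
#' common value.
#'
#' @param draws numeric sample vector (at least 10 draws).
#' @return Scalar mode estimate.
#' @export
posterior_mode <- function(draws) {
  if (length(draws) < 10L) stop("at least 10 draws required")
  rng <- range(draws)
  if (rng[1] == rng[2]) return(rng[1])
  h <- 2 * stats::IQR(draws) * length(draws)^(-1 / 3)
  if (h <= 0) h <- diff(rng) / ceiling(log2(length(draws)) + 1)  # Sturges
  nb <- max(1L, ceiling(diff(rng) / h))
  br <- seq(rng[1], rng[2], length.out = nb + 1L)
  ct <- tabulate(findInterval(draws, br, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = nb)
  i <- which.max(ct)
  (br[i] + br[i + 1L]) / 2
}

#' Effective sample size
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated by the
#' initial-monotone-sequence rule (consecutive lag pairs are kept while
#' their sums stay positive and are forced non-increasing).  Matches
#' `(1 - rho) / (1 + rho) * n` on AR(1) chains and `n` on white noise.
#'
#' @param draws numeric chain (at least 100 draws, nonzero variance).
#' @return Scalar effective size.
#' @export
effective_size <- function(draws) {
  n <- length(draws)
  if (n < 100L) stop("at least 100 draws required")
  if (var(draws) == 0) stop("zero-variance chain: ESS undefined")
  lag_max <- min(n - 1L, max(200L, floor(10 * log10(n)) * 10L))
  rho <- drop(acf(draws, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)       # rho[1] is lag 0
  # paired sums Gamma_t = rho_{2t} + rho_{2t+1}, t = 0, 1, ...
  npair <- length(rho) %/% 2L
  gam <- rho[2L * seq_len(npair) - 1L] + rho[2L * seq_len(npair)]
  neg <- which(gam <= 0)
  if (length(neg) > 0L) gam <- gam[seq_len(neg[1L] - 1L)]
  if (length(gam) == 0L) gam <- rho[1L] + rho[2L]  # degenerate fallback
  gam <- cummin(gam)                        # initial monotone sequence
  tau <- max(-1 + 2 * sum(gam), 1 / n)
  n / tau
}

#' Raftery-Lewis run-length diagnostic
#'
#' Binarizes the chain at its empirical `q`-quantile and fits a first-order
#' two-state Markov chain to the indicator.  Returns the estimated burn-in
#' `M`, the required chain length `N` to estimate the `q`-quantile to within
#' `r` with probability `s`, and the dependence factor `I = N / Nmin`
#' (`Nmin` the length needed by an independent chain; values well above 1
#' indicate strong autocorrelation).  Degenerate fits (constant or strictly
#' alternating indicator) are errors.
#'
#' @param draws numeric chain.
#' @param q quantile of interest (default 0.025).
#' @param r target precision (default 0.005).
#' @param s coverage probability (default 0.95).
#' @param eps burn-in convergence tolerance (default 0.001).
#' @return List with `burn_in`, `n_required`, `n_min`, `dependence_factor`,
#'   and the fitted transition probabilities `alpha` (0 to 1) and `beta`
#'   (1 to 0).
#' @export
raftery_lewis <- function(draws, q = 0.025, r = 0.005, s = 0.95,
                          eps = 0.001) {
  stopifnot(q > 0, q < 1, r > 0, s > 0, s < 1)
  phi <- qnorm((1 + s) / 2)
  nmin <- ceiling(q * (1 - q) * (phi / r)^2)
  n <- length(draws)
  if (n < 100L || n < nmin / 50)
    stop("chain too short for the two-state fit; need at least ",
         max(100L, ceiling(nmin / 50)), " draws")
  z <- as.integer(draws <= quantile(draws, probs = q, names = FALSE))
  from <- z[-n]; to <- z[-1L]
  n0 <- sum(from == 0L); n1 <- sum(from == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("binarized chain is constant: diagnostic undefined")
  alpha <- sum(from == 0L & to == 1L) / n0   # P(0 -> 1)
  beta <- sum(from == 1L & to == 0L) / n1    # P(1 -> 0)
  lam2 <- 1 - alpha - beta                   # second eigenvalue
  if (abs(lam2) >= 1 || alpha <= 0 || beta <= 0)
    stop("degenerate two-state fit (alternating or absorbing chain)")
  M <- ceiling(base::log(eps * (alpha + beta) / max(alpha, beta)) /
                 base::log(abs(lam2)))
  N <- ceiling((2 - alpha - beta) * alpha * beta / (alpha + beta)^3 *
                 (phi / r)^2)
  list(burn_in = M, n_required = N, n_min = nmin,
       dependence_factor = N / nmin, alpha = alpha, beta = beta)
}

#' Convergence report
#'
#' Per-parameter effective size and Raftery-Lewis diagnostics for the
#' monitored scalar parameters (lambda, sigma2_u and each covariate
#' effect), per chain.  A chain-parameter passes when its effective size
#' exceeds `ess_min`; the default is 80% of the stored draws per chain
#' (4,000 at the full 5,000-draw schedule).  Optionally writes trace plots.
#'
#' @param fit a fitted [spikegene()] model.
#' @param ess_min pass threshold on the effective size.
#' @param plot_dir if non-NULL, write one trace plot per parameter (PNG)
#'   into this directory.
#' @return Data frame of class `"spikegene_convergence"` with columns
#'   `parameter`, `chain`, `ess`, `ess_min`, `rl_burn_in`, `rl_n_required`,
#'   `rl_dependence`, `pass`.
#' @export
convergence_report <- function(fit, ess_min = NULL, plot_dir = NULL) {
  stopifnot(inherits(fit, "spikegene"))
  S <- length(fit$chains[[1L]]$lambda)
  if (is.null(ess_min)) ess_min <- 0.8 * S
  pars <- c(list(lambda = function(ch) ch$lambda,
                 sigma2 = function(ch) ch$sigma2),
            setNames(lapply(seq_len(ncol(fit$chains[[1L]]$beta)),
                            function(k) function(ch) ch$beta[, k]),
                     paste0("beta.", colnames(fit$chains[[1L]]$beta))))
  rows <- list()
  for (pn in names(pars)) {
    for (ci in seq_along(fit$chains)) {
      tr <- pars[[pn]](fit$chains[[ci]])
      ess <- tryCatch(effective_size(tr), error = function(e) NA_real_)
      rl <- tryCatch(raftery_lewis(tr), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = pn, chain = ci, ess = ess, ess_min = ess_min,
        rl_burn_in = if (is.null(rl)) NA_real_ else rl$burn_in,
        rl_n_required = if (is.null(rl)) NA_real_ else rl$n_required,
        rl_dependence = if (is.null(rl)) NA_real_ else rl$dependence_factor,
        pass = !is.na(ess) && ess > ess_min,
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  if (!is.null(plot_dir)) {
    if (!dir.exists(plot_dir)) dir.create(plot_dir, recursive = TRUE)
    for (pn in names(pars)) {
      png(file.path(plot_dir, paste0("trace_", gsub("[^A-Za-z0-9._-]", "_",
                                                    pn), ".png")),
          width = 900, height = 400)
      tr1 <- pars[[pn]](fit$chains[[1L]])
      plot(tr1, type = "l", xlab = "stored draw", ylab = pn,
           main = paste("Trace:", pn),
           ylim = range(unlist(lapply(fit$chains, pars[[pn]]))))
      if (length(fit$chains) > 1L)
        for (ci in 2:length(fit$chains))
          lines(pars[[pn]](fit$chains[[ci]]), col = ci)
      dev.off()
    }
  }
  class(rep) <- c("spikegene_convergence", "data.frame")
  rep
}

#' Summarize a fitted spike-and-slab gene association model
#'
#' @param object a fitted [spikegene()] model.
#' @param threshold gene-flagging probability threshold (default 0.8).
#' @param mass HPD interval mass (default 0.95).
#' @param ... unused.
#' @return List of class `"summary.spikegene"`: `genes` (gene, n_snps,
#'   mean_maf, prob, flagged), `snps` (inclusion probabilities, posterior
#'   mean effects and HPDs), `lambda` (mode and HPD), `sigma2`, `beta`
#'   summaries and acceptance rates.
#' @export
summary.spikegene <- function(object, threshold = 0.8, mass = 0.95, ...) {
  gp <- gene_probabilities(object)
  w <- pooled_w(object)
  u <- do.call(rbind, lapply(object$chains, `[[`, "u"))
  lam <- pooled_par(object, "lambda")
  sig <- pooled_par(object, "sigma2")
  beta <- do.call(rbind, lapply(object$chains, `[[`, "beta"))
  genes <- data.frame(
    gene = names(object$gene_blocks),
    n_snps = vapply(object$gene_blocks, length, integer(1)),
    mean_maf = vapply(object$gene_blocks, function(idx)
      mean(object$snps$maf[idx]), numeric(1)),
    prob = unname(gp),
    stringsAsFactors = FALSE)
  genes$flagged <- genes$prob > threshold
  genes <- genes[order(-genes$prob, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  snp_hpd <- t(apply(u, 2L, hpd_interval, mass = mass))
  snps <- data.frame(
    snp_id = object$snps$snp_id, gene = object$snps$gene,
    maf = object$snps$maf,
    inclusion_prob = unname(colMeans(w)),
    effect_mean = unname(colMeans(u)),
    hpd_low = unname(snp_hpd[, 1L]), hpd_high = unname(snp_hpd[, 2L]),
    stringsAsFactors = FALSE)
  bsum <- data.frame(
    term = colnames(beta), mean = colMeans(beta),
    t(apply(beta, 2L, hpd_interval, mass = mass)))
  names(bsum)[3:4] <- c("hpd_low", "hpd_high")
  rownames(bsum) <- NULL
  structure(
    list(genes = genes, snps = snps,
         lambda = list(mode = posterior_mode(lam),
                       mean = mean(lam), hpd = hpd_interval(lam, mass)),
         sigma2 = list(mean = mean(sig), hpd = hpd_interval(sig, mass)),
         beta = bsum, threshold = threshold, mass = mass,
         accept = rowMeans(vapply(object$chains, `[[`,
                                  numeric(2), "accept")),
         n_chains = length(object$chains),
         n_draws = nrow(w), design_matrix = object$design_matrix),
    class = "summary.spikegene")
}

#' @export
print.summary.spikegene <- function(x, ...) {
  cat(sprintf("spikegene summary (%d chains, %d pooled draws, design %s)\n",
              x$n_chains, x$n_draws, x$design_matrix))
  cat(sprintf("lambda: mode %.4f, mean %.4f, %.0f%% HPD [%.4f, %.4f]\n",
              x$lambda$mode, x$lambda$mean, 100 * x$mass,
              x$lambda$hpd["lower"], x$lambda$hpd["upper"]))
  cat(sprintf("sigma2_u: mean %.4f, %.0f%% HPD [%.4f, %.4f]\n",
              x$sigma2$mean, 100 * x$mass,
              x$sigma2$hpd["lower"], x$sigma2$hpd["upper"]))
  cat("covariates:\n")
  print(x$beta, digits = 3)
  nf <- sum(x$genes$flagged)
  cat(sprintf("genes with posterior probability > %.2f: %d of %d\n",
              x$threshold, nf, nrow(x$genes)))
  print(head(x$genes, max(nf, 5L)), digits = 3)
  invisible(x)
}

#' @export
coef.spikegene <- function(object, type = c("beta", "snp"), ...) {
  type <- match.arg(type)
  if (type == "beta") {
    beta <- do.call(rbind, lapply(object$chains, `[[`, "beta"))
    colMeans(beta)
  } else {
    u <- do.call(rbind, lapply(object$chains, `[[`, "u"))
    colMeans(u)                  # posterior mean of the gated effect w*u
  }
}

#' @export
fitted.spikegene <- function(object, design = NULL, ...) {
  Z <- if (!is.null(design)) {
    if (object$design_matrix == "Zstar") design$Zstar else design$Z
  } else {
    NULL
  }
  beta <- do.call(rbind, lapply(object$chains, `[[`, "beta"))
  eta <- object$X %*% t(beta)
  if (!is.null(Z)) {
    u <- do.call(rbind, lapply(object$chains, `[[`, "u"))
    eta <- eta + Z %*% t(u)
  }
  rowMeans(plogis(eta))
}

#' @export
residuals.spikegene <- function(object, design = NULL, ...) {
  object$y - fitted(object, design = design)
}

#' Diagnostic plots
#'
#' `which = "trace"` draws the lambda trace per chain; `which = "genes"`
#' draws the gene posterior probability against the number of SNPs per gene
#' (the mass-effect view), with the flagging threshold marked.
#'
#' @param x a fitted [spikegene()] model.
#' @param which `"trace"`, `"genes"` or both.
#' @param threshold gene-flagging threshold drawn on the gene panel.
#' @param ... passed to the base plotting calls.
#' @export
plot.spikegene <- function(x, which = c("trace", "genes"), threshold = 0.8,
                           ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1L) {
    op <- par(mfrow = c(1, length(which)))
    on.exit(par(op))
  }
  if ("trace" %in% which) {
    lam1 <- x$chains[[1L]]$lambda
    plot(lam1, type = "l", xlab = "stored draw", ylab = expression(lambda),
         main = "lambda trace",
         ylim = range(unlist(lapply(x$chains, `[[`, "lambda"))), ...)
    if (length(x$chains) > 1L)
      for (ci in 2:length(x$chains))
        lines(x$chains[[ci]]$lambda, col = ci)
  }
  if ("genes" %in% which) {
    gp <- gene_probabilities(x)
    ns <- vapply(x$gene_blocks, length, integer(1))
    plot(ns, gp, xlab = "SNPs in gene",
         ylab = "posterior probability of association",
         main = paste("Gene probabilities,", x$design_matrix, "design"),
         ylim = c(0, 1), ...)
    abline(h = threshold, lty = 2)
  }
  invisible(x)
}

#' Write gene/SNP result tables and diagnostics
#'
#' Writes `gene_results.tsv` (gene, n_snps, mean_maf, prob, flagged),
#' `snp_results.tsv` (snp_id, gene, maf, inclusion_prob, effect_mean,
#' hpd_low, hpd_high), `diagnostics.json` and trace plots into `dir`.
#'
#' @param fit a fitted [spikegene()] model.
#' @param dir output directory.
#' @param threshold,mass forwarded to [summary.spikegene()].
#' @return Invisibly, the summary object.
#' @export
write_results <- function(fit, dir, threshold = 0.8, mass = 0.95) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- summary(fit, threshold = threshold, mass = mass)
  write.table(s$genes, file.path(dir, "gene_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(s$snps, file.path(dir, "snp_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  conv <- convergence_report(fit, plot_dir = dir)
  diag <- list(
    lambda = s$lambda, sigma2 = s$sigma2,
    accept = as.list(s$accept),
    convergence = conv,
    n_flagged = sum(s$genes$flagged), threshold = threshold)
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(s)
}
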