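#' Polya-Gamma draws
#'
#' Draws from PG(1, z) by the exact Devroye-type rejection sampler.  The
#' augmentation makes every conditional of the logistic model Gaussian or
#' standard: given omega_i ~ PG(1, eta_i), the working observations
#' `kappa_i / omega_i` with `kappa_i = y_i - 1/2` are conditionally Gaussian
#' with precision omega_i.  Closed-form mean: `tanh(z/2) / (2 z)` (1/4 at
#' z = 0).
#'
#' @param n number of draws.
#' @param z tilting parameter(s), recycled to length `n`.
#' @return Numeric vector of positive draws.
#' @export
rpg <- function(n, z = 0) {
  .Call(C_rpg, as.integer(n), as.double(z))
}

#' Single-site conditional updates
#'
#' Fine-grained Gibbs / Metropolis-Hastings updates of the sampler, exposed
#' for testing and for building custom schedules.  [run_chain()] executes
#' the same updates in compiled code.
#'
#' `update_augmentation` draws the Polya-Gamma auxiliaries omega_i given the
#' current liabilities.
#'
#' @param eta liability vector.
#' @return `update_augmentation`: positive vector of PG(1, eta_i) draws.
#' @name updates
#' @export
update_augmentation <- function(eta) {
  rpg(length(eta), eta)
}

beta_conditional <- function(X, y, omega, offset = 0) {
  kappa <- y - 0.5
  A <- crossprod(X, X * omega)
  b <- crossprod(X, kappa - omega * offset)
  R <- tryCatch(chol(A), error = function(e)
    stop("singular precision matrix in beta update"))
  mean <- backsolve(R, backsolve(R, b, transpose = TRUE))
  list(mean = drop(mean), precision = A, chol = R)
}

#' @rdname updates
#' @param X covariate design matrix (full column rank).
#' @param y binary outcome vector.
#' @param omega current Polya-Gamma auxiliaries.
#' @param offset current genetic contribution `Zstar (w * u)` to the
#'   liability (0 when no SNP is active).
#' @return `update_beta`: draw from the MVN full conditional of beta, with
#'   attributes `mean` and `precision`.
#' @export
update_beta <- function(X, y, omega, offset = 0) {
  fc <- beta_conditional(X, y, omega, offset)
  z <- rnorm(ncol(X))
  draw <- fc$mean + drop(backsolve(fc$chol, z))
  attr(draw, "mean") <- fc$mean
  attr(draw, "precision") <- fc$precision
  draw
}

#' @rdname updates
#' @param Zstar SNP design matrix.
#' @param w,u current indicator and effect vectors.
#' @param beta current covariate effects.
#' @param lambda,sigma2 current mixing proportion and slab variance.
#' @param j SNP index to update.
#' @param mode `"marginal"` draws `w_j` from its exact Bernoulli full
#'   conditional with `u_j` integrated out analytically, then `u_j` from its
#'   conditional normal; `"mh_plugin"` proposes `w_j* ~ Bernoulli(1/2)` with
#'   the conditional-normal *mean* as plug-in effect and accepts by a
#'   Metropolis-Hastings ratio (the historical fast-sampling scheme).
#' @return `update_wu`: list with `w`, `u`, `p_include` (marginal mode) and
#'   `accepted` (mh mode).
#' @export
update_wu <- function(Zstar, y, omega, w, u, beta, X, lambda, sigma2, j,
                      mode = c("marginal", "mh_plugin")) {
  mode <- match.arg(mode)
  kappa <- y - 0.5
  zj <- Zstar[, j]
  eta_minus <- drop(X %*% beta + Zstar %*% (w * u)) - zj * w[j] * u[j]
  s1 <- sum(zj * (kappa - omega * eta_minus))
  d2 <- sum(omega * zj^2)
  v <- 1 / (d2 + 1 / sigma2)
  if (v <= 0) stop("nonpositive conditional variance in (w, u) update")
  mc <- v * s1

  if (mode == "marginal") {
    logodds <- base::log(lambda) - log1p(-lambda) +
      0.5 * base::log(v / sigma2) + 0.5 * mc^2 / v
    p1 <- plogis(logodds)
    wn <- as.integer(runif(1) < p1)
    un <- if (wn == 1L) rnorm(1, mc, sqrt(v)) else 0
    list(w = wn, u = un, p_include = p1, accepted = NA)
  } else {
    wp <- as.integer(runif(1) < 0.5)
    up <- if (wp == 1L) mc else 0
    cur <- if (w[j] == 1L) u[j] else 0
    lpiece <- function(uu, ww) {
      uu * s1 - 0.5 * uu^2 * d2 +
        if (ww == 1L) base::log(lambda) + dnorm(uu, 0, sqrt(sigma2), log = TRUE)
        else log1p(-lambda)
    }
    lq <- function(uu, ww)
      if (ww == 1L) dnorm(uu, mc, sqrt(v), log = TRUE) else 0
    loga <- lpiece(up, wp) - lpiece(cur, w[j]) + lq(cur, w[j]) - lq(up, wp)
    if (base::log(runif(1)) < loga)
      list(w = wp, u = up, p_include = NA, accepted = TRUE)
    else
      list(w = w[j], u = if (w[j] == 1L) u[j] else 0,
           p_include = NA, accepted = FALSE)
  }
}

#' @rdname updates
#' @param k number of active indicators.
#' @param m total number of SNPs.
#' @param prior a [spikegene_prior()].
#' @param lambda_mode `"gibbs"` draws from the exact conjugate
#'   Beta(c + k, d + m - k) full conditional; `"mh_prior_proposal"` proposes
#'   from the Beta(c, d) prior and accepts with the likelihood ratio
#'   (prior and proposal densities cancel).
#' @return `update_lambda`: list with `lambda` and `accepted`.
#' @export
update_lambda <- function(k, m, prior, lambda = NULL,
                          lambda_mode = c("gibbs", "mh_prior_proposal")) {
  lambda_mode <- match.arg(lambda_mode)
  cc <- prior$lambda[1]; dd <- prior$lambda[2]
  if (lambda_mode == "gibbs")
    return(list(lambda = rbeta(1, cc + k, dd + m - k), accepted = TRUE))
  stopifnot(!is.null(lambda), lambda > 0, lambda < 1)
  prop <- rbeta(1, cc, dd)
  loga <- k * (base::log(prop) - base::log(lambda)) +
    (m - k) * (log1p(-prop) - log1p(-lambda))
  if (base::log(runif(1)) < loga) list(lambda = prop, accepted = TRUE)
  else list(lambda = lambda, accepted = FALSE)
}

#' @rdname updates
#' @return `update_sigma2`: a draw from the
#'   Scaled-Inv-Chisq(df + k, (df*scale + sum u_j^2) / (df + k)) full
#'   conditional of the slab variance.
#' @export
update_sigma2 <- function(u, w, prior) {
  k <- sum(w)
  df <- unname(prior$sigma2["df"]); s2 <- unname(prior$sigma2["scale"])
  ssq <- sum(u[w == 1]^2)
  (df * s2 + ssq) / rchisq(1, df + k)
}

#' Sampler configuration
#'
#' The default schedule is the full analysis schedule: 4 chains of 100,000
#' iterations, the first 50,000 discarded as burn-in, thinned at rate 10,
#' leaving 5,000 stored draws per chain.  Scale `n_iter` down for
#' exploratory fits.
#'
#' @param n_iter iterations per chain.
#' @param burn_in discarded leading iterations (`< n_iter`).
#' @param thin thinning rate (store every `thin`-th post-burn-in state).
#' @param n_chains number of chains.
#' @param wu_update `"marginal"` (exact, default) or `"mh_plugin"`; see
#'   [update_wu()].
#' @param lambda_update `"gibbs"` (exact conjugate, default) or
#'   `"mh_prior_proposal"`; see [update_lambda()].
#' @param scan `"fixed"` (file order, default) or `"random"` SNP scan order
#'   within a sweep; both leave the posterior invariant.
#' @param fix character vector naming parameters to hold at their initial
#'   values (`"lambda"`, `"sigma2"`); used for conditional studies.
#' @return Object of class `"spikegene_mcmc"`.
#' @export
spikegene_mcmc <- function(n_iter = 100000, burn_in = 50000, thin = 10,
                           n_chains = 4,
                           wu_update = c("marginal", "mh_plugin"),
                           lambda_update = c("gibbs", "mh_prior_proposal"),
                           scan = c("fixed", "random"),
                           fix = character()) {
  wu_update <- match.arg(wu_update)
  lambda_update <- match.arg(lambda_update)
  scan <- match.arg(scan)
  stopifnot(burn_in < n_iter, thin >= 1,
            (n_iter - burn_in) / thin >= 1, n_chains >= 1,
            all(fix %in% c("lambda", "sigma2")))
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 wu_update = wu_update, lambda_update = lambda_update,
                 scan = scan, fix = fix),
            class = "spikegene_mcmc")
}

default_init <- function(y, p, m, prior) {
  prev <- mean(y)
  prev <- min(max(prev, 1 / (length(y) + 1)), length(y) / (length(y) + 1))
  list(beta = c(qlogis(prev), rep(0, p - 1L)),
       u = rep(0, m),
       w = rep(0L, m),
       lambda = prior$lambda[1] / sum(prior$lambda),
       sigma2 = unname(prior$sigma2["scale"]))
}

#' Run one MCMC chain
#'
#' One sweep updates, in order: the Polya-Gamma auxiliaries, beta, every
#' (w_j, u_j) pair, lambda, sigma2_u.  The chain is fully reproducible from
#' `(seed, chain_id)`: the RNG stream is seeded with `seed + chain_id`, so a
#' chain's draws do not depend on how many other chains run.
#'
#' @param y binary outcome vector.
#' @param X covariate design matrix.
#' @param Z SNP design matrix actually used (standardized or additive).
#' @param prior a [spikegene_prior()].
#' @param mcmc a [spikegene_mcmc()].
#' @param chain_id chain index (1-based).
#' @param seed base RNG seed.
#' @param init optional named list overriding any of `beta`, `u`, `w`,
#'   `lambda`, `sigma2` starting values.
#' @return Object of class `"spikegene_chain"`: thinned post-burn-in draws
#'   `lambda`, `sigma2` (vectors), `beta` (draws x p), `w` (integer draws x
#'   m), `u` (draws x m), plus `accept` rates (Gibbs updates count as 1 by
#'   convention).
#' @export
run_chain <- function(y, X, Z, prior, mcmc, chain_id = 1L, seed = 1L,
                      init = NULL) {
  stopifnot(inherits(prior, "spikegene_prior"),
            inherits(mcmc, "spikegene_mcmc"))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  X <- as.matrix(X); Z <- as.matrix(Z)
  storage.mode(X) <- "double"; storage.mode(Z) <- "double"
  p <- ncol(X); m <- ncol(Z)
  st <- default_init(y, p, m, prior)
  if (!is.null(init)) st[names(init)] <- init
  st$beta <- as.double(st$beta); st$u <- as.double(st$u)
  st$w <- as.integer(st$w)
  stopifnot(length(st$beta) == p, length(st$u) == m, length(st$w) == m,
            st$lambda > 0, st$lambda < 1, st$sigma2 > 0)
  modes <- c(wu = match(mcmc$wu_update, c("marginal", "mh_plugin")) - 1L,
             lambda = if ("lambda" %in% mcmc$fix) 2L else
               match(mcmc$lambda_update,
                     c("gibbs", "mh_prior_proposal")) - 1L,
             sigma2 = if ("sigma2" %in% mcmc$fix) 2L else 0L,
             scan = match(mcmc$scan, c("fixed", "random")) - 1L)
  set.seed(seed + chain_id)
  res <- .Call(C_run_chain, y, X, Z,
               as.double(c(prior$lambda, prior$sigma2)),
               c(mcmc$n_iter, mcmc$burn_in, mcmc$thin),
               list(st$beta, st$u, st$w,
                    as.double(st$lambda), as.double(st$sigma2)),
               as.integer(modes))
  acc <- res$accept
  colnames(res$beta) <- colnames(X)
  colnames(res$w) <- colnames(Z)
  colnames(res$u) <- colnames(Z)
  structure(
    list(lambda = res$lambda, sigma2 = res$sigma2, beta = res$beta,
         w = res$w, u = res$u,
         accept = c(
           wu = if (mcmc$wu_update == "marginal") 1 else acc[2] / acc[1],
           lambda = if (modes[["lambda"]] != 1L) 1 else acc[4] / acc[3]),
         chain_id = chain_id, seed = seed, mcmc = mcmc),
    class = "spikegene_chain")
}

#' Run several independent chains
#'
#' Chains use RNG streams derived from `seed + chain_id`, so results are
#' identical whether chains are run together or one at a time.
#'
#' @inheritParams run_chain
#' @return List of [run_chain()] results, length `mcmc$n_chains`.
#' @export
run_chains <- function(y, X, Z, prior, mcmc, seed = 1L, init = NULL) {
  lapply(seq_len(mcmc$n_chains), function(ch)
    run_chain(y, X, Z, prior, mcmc, chain_id = ch, seed = seed, init = init))
}

#' Fit the Bayesian spike-and-slab gene association model
#'
#' Fits the hierarchical mixture model
#' \deqn{logit(\pi_i) = \eta_i = x_i'\beta + \sum_j z^*_{ij} w_j u_j}
#' with spike-and-slab priors on SNP effects (`u_j | w_j=1 ~ N(0,
#' sigma2_u)`, `P(w_j=1) = lambda`), a Beta prior on lambda and a scaled
#' inverse chi-square prior on sigma2_u, by MH-within-Gibbs with Polya-Gamma
#' augmentation.
#'
#' @param formula model formula for the outcome and covariates, e.g.
#'   `affected ~ age + sex + smoke`; the intercept is kept by default.
#' @param data data frame holding the formula variables; if it has a
#'   `sample_id` column the rows are aligned to the design's sample order,
#'   otherwise row order must already match.
#' @param design a [build_design()] result.
#' @param design_matrix `"Zstar"` (allele-frequency-standardized, default)
#'   or `"Z"` (unweighted additive) — the two formulations of the SNP
#'   design matrix.
#' @param prior a [spikegene_prior()].
#' @param mcmc a [spikegene_mcmc()].
#' @param seed base RNG seed (chain `i` uses `seed + i`).
#' @param init optional starting-state overrides, see [run_chain()].
#' @return Object of class `"spikegene"` with the per-chain samples and the
#'   model frame; use [summary.spikegene()], [gene_probabilities()],
#'   `coef`, [plot.spikegene], [convergence_report()].
#' @examples
#' sim <- simulate_exome(sim_config(preset = "toy"), seed = 1)
#' des <- build_design(sim$dataset)
#' fit <- spikegene(affected ~ age + sex + smoke, data = sim$phenotypes,
#'                  design = des,
#'                  mcmc = spikegene_mcmc(n_iter = 400, burn_in = 200,
#'                                        thin = 2, n_chains = 2))
#' summary(fit)
#' @export
spikegene <- function(formula, data, design,
                      design_matrix = c("Zstar", "Z"),
                      prior = spikegene_prior(), mcmc = spikegene_mcmc(),
                      seed = 1L, init = NULL) {
  stopifnot(inherits(design, "spikegene_design"))
  design_matrix <- match.arg(design_matrix)
  if ("sample_id" %in% names(data)) {
    idx <- match(design$samples, data$sample_id)
    if (anyNA(idx))
      stop("data lacks sample(s): ",
           paste(design$samples[is.na(idx)], collapse = ", "))
    data <- data[idx, , drop = FALSE]
  } else if (nrow(data) != length(design$samples)) {
    stop("data rows do not match the design's samples")
  }
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1")
  X <- model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) stop("covariate design X is rank deficient")
  Z <- if (design_matrix == "Zstar") design$Zstar else design$Z
  chains <- run_chains(as.integer(y), X, Z, prior, mcmc,
                       seed = seed, init = init)
  structure(
    list(chains = chains, design_matrix = design_matrix,
         gene_blocks = design$gene_blocks, snps = design$snps,
         samples = design$samples, y = as.integer(y), X = X,
         prior = prior, mcmc = mcmc, seed = seed, call = match.call()),
    class = "spikegene")
}

#' @export
print.spikegene <- function(x, ...) {
  S <- length(x$chains[[1L]]$lambda)
  cat("Bayesian spike-and-slab gene association fit\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d SNPs in %d genes, %d individuals (%d affected), design %s\n",
              ncol(x$chains[[1L]]$w), length(x$gene_blocks),
              length(x$y), sum(x$y), x$design_matrix))
  cat(sprintf("  %d chain(s) x %d stored draws (n_iter %d, burn-in %d, thin %d)\n",
              length(x$chains), S, x$mcmc$n_iter, x$mcmc$burn_in,
              x$mcmc$thin))
  lam <- unlist(lapply(x$chains, `[[`, "lambda"))
  cat(sprintf("  posterior mean lambda %.4f; flagged genes (> 0.8): %d\n",
              mean(lam), length(flag_genes(gene_probabilities(x)))))
  invisible(x)
}
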