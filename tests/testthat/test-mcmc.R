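test_that("Polya-Gamma draws match the tanh closed-form mean", {
  set.seed(1)
  n <- 1e5
  x0 <- rpg(n, 0)
  expect_true(all(x0 > 0))
  expect_lt(abs(mean(x0) - 0.25), 3 * sd(x0) / sqrt(n))
  x2 <- rpg(n, 2)
  expect_equal(round(tanh(1) / 4, 5), 0.19040)
  expect_lt(abs(mean(x2) - tanh(1) / 4), 3 * sd(x2) / sqrt(n))
  # sign symmetry and extreme tilts stay finite
  x_neg <- rpg(n, -2)
  expect_lt(abs(mean(x_neg) - tanh(1) / 4), 3 * sd(x_neg) / sqrt(n))
  xe <- rpg(1e4, 1e4)
  expect_true(all(is.finite(xe)) && all(xe > 0))
})

test_that("beta full conditional is the weighted least-squares Gaussian", {
  set.seed(12)
  n <- 40
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.4)
  omega <- rpg(n, rnorm(n))
  kappa <- y - 0.5

  # conditional mean equals the dense WLS solve
  d <- update_beta(X, y, omega)
  oracle <- solve(t(X) %*% diag(omega) %*% X, t(X) %*% kappa)
  expect_equal(attr(d, "mean"), drop(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)

  # with an active-SNP offset the working response shifts
  off <- rnorm(n)
  d2 <- update_beta(X, y, omega, offset = off)
  oracle2 <- solve(t(X) %*% diag(omega) %*% X,
                   t(X) %*% (kappa - omega * off))
  expect_equal(attr(d2, "mean"), drop(oracle2), tolerance = 1e-10,
               ignore_attr = TRUE)

  # sampling covariance converges to the precision inverse
  draws <- t(replicate(20000, as.numeric(update_beta(X, y, omega))))
  target <- solve(t(X) %*% diag(omega) %*% X)
  expect_equal(cov(draws), target, tolerance = 0.05, ignore_attr = TRUE)

  # symmetry: intercept-only, flipping y flips the conditional mean
  X1 <- matrix(1, n, 1)
  m1 <- attr(update_beta(X1, y, omega), "mean")
  m2 <- attr(update_beta(X1, 1 - y, omega), "mean")
  expect_equal(m1, -m2, tolerance = 1e-10)

  expect_error(update_beta(cbind(X1, X1), y, omega), "singular")
})

test_that("lambda updates target Beta(c + k, d + m - k) in both modes", {
  prior <- spikegene_prior()          # Beta(2, 18)
  set.seed(3)
  # gibbs mode with no data returns the prior
  d0 <- replicate(2e4, update_lambda(0, 0, prior)$lambda)
  expect_lt(abs(mean(d0) - 0.1), 3 * sd(d0) / sqrt(length(d0)))

  # fixed w with m = 100, k = 10: Beta(12, 108) moments
  mB <- 12 / 120
  vB <- 12 * 108 / (120^2 * 121)
  g <- replicate(5e4, update_lambda(10, 100, prior)$lambda)
  expect_lt(abs(mean(g) - mB), 3 * sd(g) / sqrt(length(g)))
  expect_lt(abs(var(g) - vB), 3 * sd((g - mean(g))^2) / sqrt(length(g)))

  mh <- numeric(5e4)
  lam <- 0.1
  for (t in seq_along(mh)) {
    lam <- update_lambda(10, 100, prior, lambda = lam,
                         lambda_mode = "mh_prior_proposal")$lambda
    mh[t] <- lam
  }
  ess <- effective_size(mh)
  expect_lt(abs(mean(mh) - mB), 3 * sd(mh) / sqrt(ess))

  # the two modes agree in distribution (KS on near-independent subsamples)
  g_thin <- g[seq(1, length(g), by = 25)]
  mh_thin <- mh[seq(1, length(mh), by = 25)]
  ks <- suppressWarnings(stats::ks.test(g_thin, mh_thin))$statistic
  n1 <- length(g_thin); n2 <- length(mh_thin)
  expect_lt(ks, 1.628 * sqrt((n1 + n2) / (n1 * n2)))  # alpha = 0.01
})

test_that("sigma2 update draws the conjugate scaled inverse chi-square", {
  set.seed(9)
  # k = 0 recovers the prior; df = 6 gives a finite Monte-Carlo SE
  prior6 <- spikegene_prior(sigma2 = c(df = 6, scale = 0.5))
  d0 <- replicate(5e4, update_sigma2(numeric(5), rep(0L, 5), prior6))
  expect_true(all(d0 > 0))
  expect_lt(abs(mean(d0) - 6 * 0.5 / 4), 3 * sd(d0) / sqrt(length(d0)))

  # k = 10, sum u^2 = 5, df = 4, scale = 0.5: mean (2 + 5)/12
  prior <- spikegene_prior()
  u <- sqrt(rep(0.5, 10)); w <- rep(1L, 10)
  d1 <- replicate(1e5, update_sigma2(u, w, prior))
  expect_equal(sum(u^2), 5)
  expect_lt(abs(mean(d1) - 7 / 12), 3 * sd(d1) / sqrt(length(d1)))
})

test_that("the (w, u) update gates on lambda and matches enumeration", {
  set.seed(21)
  n <- 10
  X <- matrix(1, n, 1)
  y <- rbinom(n, 1, 0.5)
  Zs <- matrix(rnorm(2 * n), n, 2)
  omega <- rpg(n, rnorm(n))
  beta <- 0.2

  # prior gate: lambda -> 0 kills inclusion
  hits <- 0
  for (r in 1:1e4) {
    up <- update_wu(Zs, y, omega, c(0L, 0L), c(0, 0), beta, X,
                    lambda = 1e-12, sigma2 = 1, j = 1)
    hits <- hits + up$w
  }
  expect_identical(hits, 0)

  # 2-SNP toy: Gibbs frequencies match closed-form enumeration at fixed
  # omega and hyperparameters
  lam <- 0.35; sig2 <- 1.2
  oracle <- enum_w_fixed_omega(y, Zs, omega, lam, sig2, xb = beta)
  w <- c(0L, 0L); u <- c(0, 0)
  nsweep <- 3e4
  pat <- character(nsweep)
  for (t in seq_len(nsweep)) {
    for (j in 1:2) {
      up <- update_wu(Zs, y, omega, w, u, beta, X, lam, sig2, j)
      w[j] <- up$w; u[j] <- up$u
    }
    pat[t] <- paste(w, collapse = "")
  }
  est <- table(factor(pat, levels = names(oracle))) / nsweep
  for (cell in names(oracle)) {
    ind <- as.numeric(pat == cell)
    ess <- effective_size(ind)
    se <- max(sqrt(oracle[cell] * (1 - oracle[cell]) / ess), 1 / nsweep)
    expect_lt(abs(est[cell] - oracle[cell]), 3 * se)
  }

  # orthogonal columns: update of SNP 1 ignores the state of SNP 2
  Zorth <- rbind(cbind(rnorm(5), 0), cbind(0, rnorm(5)))
  up_a <- update_wu(Zorth, y, omega, c(0L, 0L), c(0, 0), beta, X, lam,
                    sig2, j = 1)
  up_b <- update_wu(Zorth, y, omega, c(0L, 1L), c(0, 2.7), beta, X, lam,
                    sig2, j = 1)
  expect_equal(up_a$p_include, up_b$p_include, tolerance = 1e-12)
})

test_that("plug-in MH mode accepts strictly between 0 and 1", {
  set.seed(6)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, 0.5)
  Zs <- matrix(rnorm(3 * n), n, 3)
  omega <- rpg(n, rnorm(n))
  acc <- replicate(2000, update_wu(Zs, y, omega, c(0L, 1L, 0L),
                                   c(0, 0.4, 0), c(0, 0), X, 0.2, 1,
                                   j = sample(3, 1),
                                   mode = "mh_plugin")$accepted)
  expect_gt(mean(acc), 0)
  expect_lt(mean(acc), 1)
})

test_that("chain schedule, determinism and gate conservation hold", {
  set.seed(77)
  n <- 60; m <- 8
  X <- cbind(1, rnorm(n))
  Z <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("s", 1:m)))
  y <- rbinom(n, 1, 0.4)
  prior <- spikegene_prior()

  cfg <- spikegene_mcmc(n_iter = 100, burn_in = 50, thin = 10, n_chains = 1)
  ch <- run_chain(y, X, Z, prior, cfg, seed = 5)
  expect_length(ch$lambda, 5L)           # (100 - 50)/10 stored draws
  expect_identical(dim(ch$w), c(5L, as.integer(m)))

  # same seed twice is bit-identical
  ch2 <- run_chain(y, X, Z, prior, cfg, seed = 5)
  expect_identical(ch, ch2)

  # chains from run_chains match individually run chains (seed + chain id)
  cfg4 <- spikegene_mcmc(n_iter = 200, burn_in = 100, thin = 5,
                         n_chains = 3)
  all3 <- run_chains(y, X, Z, prior, cfg4, seed = 9)
  expect_length(all3, 3L)
  solo2 <- run_chain(y, X, Z, prior, cfg4, chain_id = 2L, seed = 9)
  expect_identical(all3[[2]], solo2)
  expect_false(identical(all3[[1]]$lambda, all3[[2]]$lambda))

  # gate conservation on every stored state, all update modes
  for (wu in c("marginal", "mh_plugin")) {
    cfgw <- spikegene_mcmc(n_iter = 500, burn_in = 100, thin = 2,
                           n_chains = 1, wu_update = wu,
                           lambda_update = "mh_prior_proposal")
    chw <- run_chain(y, X, Z, prior, cfgw, seed = 3)
    expect_true(all(chw$u[chw$w == 0L] == 0))
    expect_true(all(chw$lambda > 0 & chw$lambda < 1))
    expect_true(all(chw$sigma2 > 0))
    expect_gt(chw$accept[["lambda"]], 0)
    expect_lt(chw$accept[["lambda"]], 1)
  }

  # random scan leaves the target invariant: posterior means agree
  cfg_f <- spikegene_mcmc(n_iter = 6000, burn_in = 1000, thin = 2,
                          n_chains = 1)
  cfg_r <- spikegene_mcmc(n_iter = 6000, burn_in = 1000, thin = 2,
                          n_chains = 1, scan = "random")
  chf <- run_chain(y, X, Z, prior, cfg_f, seed = 11)
  chr <- run_chain(y, X, Z, prior, cfg_r, seed = 12)
  expect_lt(abs(mean(chf$lambda) - mean(chr$lambda)), 0.03)
})

test_that("null data leave lambda near its prior", {
  set.seed(14)
  n <- 150; m <- 50
  X <- cbind(1, rnorm(n))
  Z <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("s", 1:m)))
  y <- rbinom(n, 1, 0.3)                 # no genetic signal at all
  prior <- spikegene_prior()
  cfg <- spikegene_mcmc(n_iter = 4000, burn_in = 2000, thin = 2,
                        n_chains = 1)
  ch <- run_chain(y, X, Z, prior, cfg, seed = 2)
  ci <- qbeta(c(0.025, 0.975), 2, 18)    # prior central 95%
  expect_gt(mean(ch$lambda), ci[1])
  expect_lt(mean(ch$lambda), ci[2])
})

test_that("distant initializations converge to the same posterior", {
  set.seed(33)
  sim <- simulate_exome(sim_config(preset = "toy"), seed = 4)
  des <- build_design(sim$dataset)
  m <- ncol(des$Zstar)
  cfg <- spikegene_mcmc(n_iter = 4000, burn_in = 2000, thin = 2,
                        n_chains = 1)
  f_cold <- spikegene(affected ~ age + sex + smoke, data = sim$phenotypes,
                      design = des, mcmc = cfg, seed = 21,
                      init = list(lambda = 0.01, sigma2 = 0.05))
  f_hot <- spikegene(affected ~ age + sex + smoke, data = sim$phenotypes,
                     design = des, mcmc = cfg, seed = 22,
                     init = list(lambda = 0.9, sigma2 = 5,
                                 w = rep(1L, m), u = rnorm(m)))
  expect_lt(abs(mean(f_cold$chains[[1]]$lambda) -
                  mean(f_hot$chains[[1]]$lambda)), 0.08)
  expect_lt(max(abs(gene_probabilities(f_cold) - gene_probabilities(f_hot))),
            0.2)
})
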