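# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately brute-force / closed-form and shares no
# code with the package internals it checks.

# overflow-safe log(1+exp(x)) for the oracles
o_log1pexp <- function(x) ifelse(x > 18, x, log1p(exp(pmin(x, 18))))

o_loglik <- function(eta, y) sum(y * eta - o_log1pexp(eta))

# Gauss-Hermite nodes/weights by Golub-Welsch
gauss_hermite <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J <- J + t(J)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = e$vectors[1, ]^2 * sqrt(pi))
}

# Brute-force posterior over the indicator grid for the exact logistic
# model with intercept-only X, flat beta (truncated grid), fixed lambda
# and sigma2: w grid x Gauss-Hermite quadrature over active u x trapezoid
# over beta.
enum_posterior_w <- function(y, Z, lambda, sigma2, n_gh = 20,
                             bgrid = seq(-8, 8, by = 0.1)) {
  n <- length(y); m <- ncol(Z)
  gh <- gauss_hermite(n_gh)
  pats <- as.matrix(expand.grid(rep(list(0:1), m)))
  post <- numeric(nrow(pats))
  for (r in seq_len(nrow(pats))) {
    act <- which(pats[r, ] == 1)
    k <- length(act)
    if (k == 0) {
      ll <- vapply(bgrid, function(b) o_loglik(rep(b, n), y), numeric(1))
      marg <- sum(exp(ll - max(ll))) * exp(max(ll))
    } else {
      nodes <- as.matrix(expand.grid(rep(list(seq_len(n_gh)), k)))
      uvals <- sqrt(2 * sigma2) * matrix(gh$x[nodes], nrow(nodes), k)
      wts <- apply(matrix(gh$w[nodes] / sqrt(pi), nrow(nodes), k), 1, prod)
      tot <- 0
      Zu <- Z[, act, drop = FALSE] %*% t(uvals)      # n x n_nodes
      for (b in bgrid) {
        etas <- b + Zu
        ll <- colSums(y * etas - o_log1pexp(etas))
        tot <- tot + sum(wts * exp(ll))
      }
      marg <- tot
    }
    post[r] <- lambda^k * (1 - lambda)^(m - k) * marg
  }
  names(post) <- apply(pats, 1, paste, collapse = "")
  post / sum(post)
}

# For FIXED omega the augmented model is exactly Gaussian, so the joint
# posterior over the indicator grid has a closed form: each pattern's
# marginal is |V|^(1/2) sigma^(-k) exp(mu' V^{-1} mu / 2) with
# V = (Z'Omega Z + I/sigma2)^{-1} restricted to the active columns.
enum_w_fixed_omega <- function(y, Z, omega, lambda, sigma2, xb = 0) {
  m <- ncol(Z)
  kap <- y - 0.5 - omega * xb
  pats <- as.matrix(expand.grid(rep(list(0:1), m)))
  lp <- numeric(nrow(pats))
  for (r in seq_len(nrow(pats))) {
    act <- which(pats[r, ] == 1)
    k <- length(act)
    lp[r] <- k * log(lambda) + (m - k) * log(1 - lambda)
    if (k > 0) {
      Za <- Z[, act, drop = FALSE]
      P <- crossprod(Za, Za * omega) + diag(k) / sigma2
      b <- crossprod(Za, kap)
      V <- solve(P)
      lp[r] <- lp[r] + 0.5 * determinant(V)$modulus -
        0.5 * k * log(sigma2) + 0.5 * drop(t(b) %*% V %*% b)
    }
  }
  p <- exp(lp - max(lp))
  names(p) <- apply(pats, 1, paste, collapse = "")
  p / sum(p)
}

# Prefix-rank pruning oracle: keep a column iff it raises the rank of the
# kept set, judged by singular values at relative tolerance tol.
prefix_rank_keep <- function(Z, tol = 1e-8) {
  rank_of <- function(M) {
    if (is.null(M) || ncol(M) == 0) return(0L)
    d <- svd(M, nu = 0, nv = 0)$d
    sum(d > tol * d[1])
  }
  kept <- NULL
  keep_idx <- integer(0)
  for (j in seq_len(ncol(Z))) {
    cand <- cbind(kept, Z[, j])
    if (rank_of(cand) > rank_of(kept)) {
      kept <- cand
      keep_idx <- c(keep_idx, j)
    }
  }
  keep_idx
}

# small deterministic dataset: 4 individuals, 2 genes, 5 SNPs
make_toy_dataset <- function() {
  calls <- matrix(c(0L, 1L, 2L, 0L,
                    1L, 1L, 1L, 1L,
                    0L, 0L, 2L, 1L,
                    0L, 0L, 2L, 1L,   # duplicate of SNP g2a
                    2L, 1L, 0L, 0L),
                  nrow = 4)
  snps <- data.frame(snp_id = c("g1a", "g1b", "g2a", "g2b", "g2c"),
                     gene = c("G1", "G1", "G2", "G2", "G2"),
                     chrom = c("1", "1", "2", "2", "2"),
                     stringsAsFactors = FALSE)
  genotype_dataset(calls, snps, samples = paste0("S", 1:4))
}

toy_phenotypes <- function(n = 4, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = paste0("S", seq_len(n)),
             affected = rep_len(c(1L, 0L), n),
             age = round(runif(n, 30, 60)),
             sex = rep_len(c(0L, 1L), n),
             smoke = rbinom(n, 1, 0.25),
             stringsAsFactors = FALSE)
}

# AR(1) chain with autocorrelation rho, marginal N(0, 1)
ar1_chain <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1, sd = sqrt(1 - rho^2))
  for (t in 2:n) x[t] <- rho * x[t - 1] + innov[t - 1]
  x
}

# two-state sticky Markov chain of 0/1 states
markov_binary_chain <- function(n, p01, p10, seed = 1) {
  set.seed(seed)
  s <- integer(n)
  s[1] <- 0L
  u <- runif(n - 1)
  for (t in 2:n)
    s[t] <- if (s[t - 1] == 0L) as.integer(u[t - 1] < p01)
            else 1L - as.integer(u[t - 1] < p10)
  s
}
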