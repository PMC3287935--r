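#' Prior specification for the hierarchical mixture model
#'
#' The mixing proportion lambda (prior probability that a SNP effect is in
#' the slab) carries a Beta(c, d) prior; Beta(2, 18), prior mean 0.1, is the
#' default and should be tailored to the outcome under study.  The slab
#' variance sigma2_u carries a scaled inverse chi-square prior with
#' `df` degrees of freedom and scale `scale`; the defaults (4, 0.5) are
#' weakly informative with prior mean `df*scale/(df-2) = 1` on the liability
#' scale, matching the unit variance of standardized genotype columns.
#' Covariate effects beta are flat (uniform).
#'
#' @param lambda length-2 numeric, the Beta shape parameters `c(c, d)`.
#' @param sigma2 named length-2 numeric `c(df = , scale = )`.
#' @return Object of class `"spikegene_prior"`.
#' @export
spikegene_prior <- function(lambda = c(2, 18), sigma2 = c(df = 4, scale = 0.5)) {
  stopifnot(length(lambda) == 2L, all(lambda > 0),
            length(sigma2) == 2L, all(sigma2 > 0))
  structure(list(lambda = unname(lambda),
                 sigma2 = c(df = unname(sigma2[1L]),
                            scale = unname(sigma2[2L]))),
            class = "spikegene_prior")
}

#' @export
print.spikegene_prior <- function(x, ...) {
  cat(sprintf("lambda ~ Beta(%g, %g); sigma2_u ~ Scaled-Inv-Chisq(df = %g, scale = %g); beta flat\n",
              x$lambda[1], x$lambda[2], x$sigma2["df"], x$sigma2["scale"]))
  invisible(x)
}

#' Liability linear predictor
#'
#' `eta = X beta + Zstar (w * u)`: covariate effects plus the sum of the
#' included SNP effects on the liability (logit) scale.  Indicators gate the
#' effects elementwise, so SNPs with `w = 0` contribute nothing.
#'
#' @param beta covariate effects (length = ncol(X)).
#' @param u SNP effects (length = ncol(Zstar)).
#' @param w 0/1 inclusion indicators, same length as `u`.
#' @param X covariate design matrix (first column the intercept).
#' @param Zstar SNP design matrix.
#' @return Numeric liability vector of length `nrow(X)`.
#' @export
linear_predictor <- function(beta, u, w, X, Zstar) {
  if (length(beta) != ncol(X) || length(u) != ncol(Zstar) ||
      length(w) != length(u) || nrow(X) != nrow(Zstar))
    stop("dimension mismatch in linear predictor")
  drop(X %*% beta + Zstar %*% (w * u))
}

log1pexp <- function(x) {
  # log(1 + exp(x)), safe over the whole double range
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

#' Bernoulli-logit log likelihood
#'
#' `sum(y * eta - log(1 + exp(eta)))`, computed without overflow for
#' liabilities of any magnitude.
#'
#' @param eta liability vector.
#' @param y binary outcome vector (0/1).
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(eta, y) {
  if (length(eta) != length(y)) stop("eta and y lengths differ")
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("y must be binary 0/1")
  sum(y * eta - log1pexp(eta))
}

#' Scaled inverse chi-square density and sampler
#'
#' Scaled-Inv-Chisq(df, scale) is the distribution of `df * scale / X` with
#' `X ~ chi-square(df)`; equivalently inverse-gamma(df/2, df*scale/2).  Used
#' as the prior and full conditional of the slab variance.
#'
#' @param x quantile (positive).
#' @param df degrees of freedom.
#' @param scale scale parameter (the prior guess of the variance).
#' @param log return the log density?
#' @return Density values (`dsinvchisq`) or draws (`rsinvchisq`).
#' @export
dsinvchisq <- function(x, df, scale, log = FALSE) {
  stopifnot(df > 0, scale > 0)
  ld <- (df / 2) * base::log(df * scale / 2) - lgamma(df / 2) -
    (df / 2 + 1) * base::log(x) - df * scale / (2 * x)
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dsinvchisq
#' @param n number of draws.
#' @export
rsinvchisq <- function(n, df, scale) {
  df * scale / rchisq(n, df)
}

#' Joint log prior of a model state
#'
#' Sum of the Beta log density at lambda, the scaled inverse chi-square log
#' density at sigma2_u, the Bernoulli(lambda) mass of the indicators, and
#' the slab normal log density of the included effects.  The flat beta prior
#' contributes 0.
#'
#' @param state list with elements `beta`, `u`, `w`, `lambda`, `sigma2`;
#'   `w_j = 0` must imply `u_j = 0`.
#' @param prior a [spikegene_prior()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(state, prior) {
  stopifnot(inherits(prior, "spikegene_prior"))
  lam <- state$lambda
  sig2 <- state$sigma2
  if (is.na(lam) || lam <= 0 || lam >= 1)
    stop("lambda must lie strictly in (0, 1)")
  if (is.na(sig2) || sig2 <= 0)
    stop("sigma2 must be positive")
  w <- as.integer(state$w)
  u <- state$u
  if (any(w == 0 & u != 0))
    stop("state violates the gate: w_j = 0 requires u_j = 0")
  k <- sum(w)
  unname(
    dbeta(lam, prior$lambda[1], prior$lambda[2], log = TRUE) +
      dsinvchisq(sig2, unname(prior$sigma2["df"]),
                 unname(prior$sigma2["scale"]), log = TRUE) +
      k * base::log(lam) + (length(w) - k) * log1p(-lam) +
      sum(dnorm(u[w == 1], 0, sqrt(sig2), log = TRUE)))
}
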