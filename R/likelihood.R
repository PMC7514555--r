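# Likelihood machinery for progressively first-failure censored Inverse
# Weibull samples.  Everything is built from the log-likelihood
#   l = log P + m log k + m log a + m log l - l * sum(x^-a)
#       - (a+1) * sum(log x) + sum_i c_i log(1 - exp(-l x_i^-a)),
# where c_i = k (R_i + 1) - 1.  The additive constant log P + m log k is
# excluded by default (it does not depend on the parameters).

# censoring exponents c_i = k (R_i + 1) - 1; zero for a complete sample
.cens_exponents <- function(scheme) {
  scheme$k * (scheme$R + 1) - 1
}

# log P = log n + log(n - 1 - R1) + ... (the ordering constant)
.log_norm_constant <- function(scheme) {
  m <- scheme$m
  n <- scheme$n
  if (m == 1L) return(log(n))
  avail <- n - seq_len(m) + 1 - c(0, cumsum(scheme$R[seq_len(m - 1L)]))
  sum(log(avail)) + m * log(scheme$k)
}

# Derivatives of g(z) = log(1 - e^{-z}), z > 0, written in terms of
# q = e^{-z} so they stay finite for large z.
.cens_g <- function(z) {
  q <- exp(-z)
  om <- -expm1(-z)                 # 1 - e^{-z}, accurate for small z
  list(g1 = q / om, g2 = -q / om^2, g3 = q * (1 + q) / om^3)
}

#' Log-likelihood of a censored Inverse Weibull sample
#'
#' @param sample a [pff_sample].
#' @param alpha,lambda parameter values (or an [iwd_params] as `alpha`).
#' @param include_constant if `TRUE`, adds the ordering constant
#'   \eqn{\log P + m \log k} with
#'   \eqn{P = n(n-1-R_1)\cdots(n-m+1-R_1-\dots-R_{m-1})}.
#' @return The log-likelihood; `-Inf` when a censoring factor underflows
#'   with positive exponent weight.
#' @examples
#' sc <- censoring_scheme(1, 5, R = c(2, 0, 0))
#' s <- simulate_pff(sc, iwd_params(2, 1), seed = 1)
#' pff_loglik(s, 2, 1)
#' @export
pff_loglik <- function(sample, alpha, lambda = NULL, include_constant = FALSE) {
  stopifnot(inherits(sample, "pff_sample"))
  pr <- .iwd_args(alpha, lambda)
  x <- sample$times
  m <- length(x)
  cc <- .cens_exponents(sample$scheme)
  u <- x^(-pr$alpha)
  z <- pr$lambda * u
  lg1m <- log(-expm1(-z))          # log(1 - e^{-z}); -Inf if z underflows
  cens <- cc * lg1m
  cens[cc == 0] <- 0               # 0 * -Inf := 0 for unweighted terms
  val <- m * log(pr$alpha) + m * log(pr$lambda) - pr$lambda * sum(u) -
    (pr$alpha + 1) * sum(log(x)) + sum(cens)
  if (include_constant) val <- val + .log_norm_constant(sample$scheme)
  if (is.nan(val)) val <- -Inf
  val
}

# All derivatives of the log-likelihood up to third order in one pass.
# Returned as a list: score (length 2), hess (2x2), l30, l21, l12, l03.
.pff_derivs <- function(x, cc, alpha, lambda) {
  m <- length(x)
  u <- x^(-alpha)
  tl <- log(x)
  z <- lambda * u
  G <- .cens_g(z)
  a <- alpha; l <- lambda
  l10 <- m / a + l * sum(u * tl) - sum(tl) - sum(cc * G$g1 * l * u * tl)
  l01 <- m / l - sum(u) + sum(cc * G$g1 * u)
  l20 <- -m / a^2 - l * sum(u * tl^2) +
    sum(cc * (G$g2 * (l * u * tl)^2 + G$g1 * l * u * tl^2))
  l11 <- sum(u * tl) - sum(cc * (G$g2 * l * u^2 * tl + G$g1 * u * tl))
  l02 <- -m / l^2 + sum(cc * G$g2 * u^2)
  l30 <- 2 * m / a^3 + l * sum(u * tl^3) +
    sum(cc * (-G$g3 * (l * u * tl)^3 - 3 * G$g2 * l^2 * u^2 * tl^3 -
                G$g1 * l * u * tl^3))
  l21 <- -sum(u * tl^2) +
    sum(cc * (G$g3 * l^2 * u^3 * tl^2 + 3 * G$g2 * l * u^2 * tl^2 +
                G$g1 * u * tl^2))
  l12 <- sum(cc * (-G$g3 * l * u^3 * tl - 2 * G$g2 * u^2 * tl))
  l03 <- 2 * m / l^3 + sum(cc * G$g3 * u^3)
  list(score = c(alpha = l10, lambda = l01),
       hess = matrix(c(l20, l11, l11, l02), 2, 2,
                     dimnames = list(c("alpha", "lambda"),
                                     c("alpha", "lambda"))),
       l30 = l30, l21 = l21, l12 = l12, l03 = l03)
}

#' Score vector of the censored log-likelihood
#'
#' First partial derivatives \eqn{(\partial l/\partial\alpha,
#' \partial l/\partial\lambda)}.  For a complete sample (`k = 1`, all
#' removals zero) the censoring terms vanish identically.
#'
#' @inheritParams pff_loglik
#' @return Named numeric vector of length 2.
#' @export
pff_score <- function(sample, alpha, lambda = NULL) {
  stopifnot(inherits(sample, "pff_sample"))
  pr <- .iwd_args(alpha, lambda)
  .pff_derivs(sample$times, .cens_exponents(sample$scheme),
              pr$alpha, pr$lambda)$score
}

#' Observed Fisher information matrix
#'
#' Negative Hessian of the log-likelihood at the supplied parameter values,
#' from the closed-form second derivatives.
#'
#' @inheritParams pff_loglik
#' @return A symmetric 2x2 matrix.
#' @export
pff_observed_info <- function(sample, alpha, lambda = NULL) {
  stopifnot(inherits(sample, "pff_sample"))
  pr <- .iwd_args(alpha, lambda)
  -.pff_derivs(sample$times, .cens_exponents(sample$scheme),
               pr$alpha, pr$lambda)$hess
}

#' Third-order log-likelihood derivatives
#'
#' The four third partial derivatives \eqn{l_{30}, l_{21}, l_{12}, l_{03}}
#' of the censored log-likelihood, required by the Lindley approximation.
#'
#' @inheritParams pff_loglik
#' @return Named numeric vector `c(l30, l21, l12, l03)`.
#' @export
pff_third_derivs <- function(sample, alpha, lambda = NULL) {
  stopifnot(inherits(sample, "pff_sample"))
  pr <- .iwd_args(alpha, lambda)
  d <- .pff_derivs(sample$times, .cens_exponents(sample$scheme),
                   pr$alpha, pr$lambda)
  c(l30 = unname(d$l30), l21 = unname(d$l21), l12 = unname(d$l12),
    l03 = unname(d$l03))
}
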