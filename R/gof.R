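#' Kolmogorov-Smirnov statistic against a fitted Inverse Weibull law
#'
#' Sup-distance between the empirical CDF of complete (uncensored) data and
#' the Inverse Weibull CDF:
#' \deqn{D = \max_i \max\left(i/n - F(x_{(i)}),\; F(x_{(i)}) - (i-1)/n\right).}
#'
#' @param x positive times (complete data; ties allowed).
#' @param alpha,lambda parameters (or an [iwd_params] as `alpha`).
#' @return `ks_statistic_iwd`: the statistic \eqn{D \in [0, 1]}.
#' @export
ks_statistic_iwd <- function(x, alpha, lambda = NULL) {
  pr <- .iwd_args(alpha, lambda)
  .check_x_positive(x)
  n <- length(x)
  Fi <- piwd(sort(x), pr)
  i <- seq_len(n)
  max(pmax(i / n - Fi, Fi - (i - 1) / n))
}

# Asymptotic Kolmogorov tail probability Q(x) = 2 sum (-1)^{j-1} e^{-2 j^2 x^2}.
# An approximation when parameters are estimated (no Lilliefors correction).
.kolmogorov_p <- function(stat, n) {
  xx <- sqrt(n) * stat
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * xx^2))
  min(max(p, 0), 1)
}

#' Goodness of fit for complete data
#'
#' Fits the Inverse Weibull model to complete data by maximum likelihood
#' (treating it as an uncensored sample: `k = 1`, no removals) and reports
#' the negative log-likelihood, the K-S statistic and its asymptotic
#' p-value.  The p-value uses the plain asymptotic Kolmogorov series
#' without a correction for estimated parameters, and is therefore an
#' approximation.
#'
#' @param x positive times.
#' @return A list with the `fit` (an `"iwd_fit"`), `neg_loglik`, `ks` and
#'   `p_value`, of class `"iwd_gof"`.
#' @examples
#' gof_iwd(load_dataset("guinea_complete")$times)
#' @export
gof_iwd <- function(x) {
  .check_x_positive(x)
  n <- length(x)
  sc <- censoring_scheme(k = 1, n = n, R = rep(0L, n))
  fit <- fit_iwd(pff_sample(sort(x), sc))
  D <- ks_statistic_iwd(x, fit$alpha, fit$lambda)
  structure(list(fit = fit, neg_loglik = -fit$loglik, ks = D,
                 p_value = .kolmogorov_p(D, n)),
            class = "iwd_gof")
}

#' @export
print.iwd_gof <- function(x, ...) {
  cat("Inverse Weibull goodness of fit (complete data)\n")
  cat(sprintf("  (alpha, lambda) = (%.4f, %.4f)\n", x$fit$alpha, x$fit$lambda))
  cat(sprintf("  -lnL = %.3f, K-S D = %.3f, asymptotic p = %.4f\n",
              x$neg_loglik, x$ks, x$p_value))
  invisible(x)
}
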