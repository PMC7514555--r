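# Importance sampling from the posterior under the Gamma(a, b) prior on
# lambda and the 1/alpha prior on alpha.  The joint posterior factors as
#   pi(alpha, lambda | x) = f1(lambda | alpha) f2(alpha) Q(alpha, lambda)
# with f1 = Gamma(m + a, rate b + sum x^-alpha),
#      f2(alpha) propto alpha^(m-1) exp(-alpha sum log x)
#                       / (b + sum x^-alpha)^(m+a)   (log-concave), and
#      Q = prod_i (1 - exp(-lambda x_i^-alpha))^(k(R_i+1)-1)
# the importance weight.  Draws from f2 use an adaptive grid inverse-CDF
# (4096 points spanning the region within 40 log-units of the mode);
# weights are normalised in log space with max-subtraction.

#' Unnormalised log marginal proposal density of the shape
#'
#' \eqn{\log f_2(\alpha)} up to its normalising constant:
#' \eqn{(m-1)\log\alpha - \alpha\sum\log x_i - (m+a)\log(b + \sum x_i^{-\alpha})}.
#' Log-concave in \eqn{\alpha}.
#'
#' @param alpha vector of positive shape values.
#' @param sample a [pff_sample].
#' @param prior a [prior_spec].
#' @return Vector of unnormalised log-densities.
#' @export
log_f2 <- function(alpha, sample, prior = prior_spec(1, 1)) {
  stopifnot(inherits(sample, "pff_sample"), inherits(prior, "pff_prior"))
  if (any(alpha <= 0)) stop("'alpha' must be positive")
  x <- sample$times
  m <- length(x)
  slx <- sum(log(x))
  vapply(alpha, function(a) {
    s <- prior$b + sum(x^(-a))
    if (s <= 0) return(-Inf)
    (m - 1) * log(a) - a * slx - (m + prior$a) * log(s)
  }, 0)
}

# grid-based inverse-CDF sampler state for f2: support and normalised CDF
.f2_grid <- function(sample, prior, n_grid = 4096L, drop = 40) {
  lf <- function(a) log_f2(a, sample, prior)
  md <- optimize(lf, c(1e-4, 200), maximum = TRUE)
  peak <- md$objective
  lo <- md$maximum
  while (lf(lo) > peak - drop && lo > 1e-10) lo <- lo / 1.5
  hi <- md$maximum
  while (lf(hi) > peak - drop && hi < 1e6) hi <- hi * 1.5
  grid <- seq(lo, hi, length.out = n_grid)
  lg <- lf(grid)
  w <- exp(lg - max(lg))
  cw <- cumsum((w[-1] + w[-n_grid]) / 2 * diff(grid))
  cw <- c(0, cw / cw[n_grid - 1L])
  keep <- c(TRUE, diff(cw) > 0)
  list(grid = grid[keep], cdf = cw[keep])
}

#' Draw weighted posterior samples by importance sampling
#'
#' Produces `M` pairs \eqn{(\alpha_i, \lambda_i)} with \eqn{\alpha_i} from
#' the log-concave marginal proposal \eqn{f_2} and
#' \eqn{\lambda_i \mid \alpha_i} from Gamma\eqn{(m + a,\;
#' b + \sum_j x_j^{-\alpha_i})}, together with self-normalised importance
#' weights \eqn{\vartheta_i \propto Q(\alpha_i, \lambda_i)} computed in log
#' space.  When `k = 1` and all removals are zero, \eqn{Q \equiv 1} and the
#' weights are exactly uniform.
#'
#' @param sample a [pff_sample] with `m >= 2`.
#' @param prior a [prior_spec].
#' @param M number of draws.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `"pff_posterior"`: list with `alpha`,
#'   `lambda`, `weights` (summing to 1), `M`, `ess` (effective sample
#'   size \eqn{1/\sum\vartheta_i^2}) and `seed`.
#' @examples
#' sc <- censoring_scheme(1, 20, R = c(5, rep(0, 14)))
#' s <- simulate_pff(sc, iwd_params(2, 1), seed = 2)
#' draw_posterior(s, prior_spec(1, 1), M = 500, seed = 3)
#' @export
draw_posterior <- function(sample, prior = prior_spec(1, 1), M = 5000,
                           seed = NULL) {
  stopifnot(inherits(sample, "pff_sample"), inherits(prior, "pff_prior"))
  if (sample$scheme$m < 2L) stop("need m >= 2 for the posterior sampler")
  if (M < 1) stop("'M' must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- sample$times
  m <- length(x)
  g2 <- .f2_grid(sample, prior)
  u <- runif(M)
  alpha <- approx(g2$cdf, g2$grid, xout = u, rule = 2, ties = "ordered")$y
  rate <- prior$b + vapply(alpha, function(a) sum(x^(-a)), 0)
  lambda <- rgamma(M, shape = m + prior$a, rate = rate)
  cc <- .cens_exponents(sample$scheme)
  if (all(cc == 0)) {
    logq <- rep(0, M)
  } else {
    logq <- vapply(seq_len(M), function(i) {
      z <- lambda[i] * x^(-alpha[i])
      lw <- cc * log(-expm1(-z))
      lw[cc == 0] <- 0
      sum(lw)
    }, 0)
  }
  mx <- max(logq)
  if (!is.finite(mx)) {
    stop("all importance weights underflowed; increase M or reconsider the scheme")
  }
  w <- exp(logq - mx)
  w <- w / sum(w)
  structure(list(alpha = alpha, lambda = lambda, weights = w, M = M,
                 ess = 1 / sum(w^2), seed = seed, prior = prior),
            class = "pff_posterior")
}

#' @export
print.pff_posterior <- function(x, ...) {
  cat(sprintf("Weighted posterior draws: M = %d, effective sample size %.1f\n",
              x$M, x$ess))
  invisible(x)
}

.posterior_target <- function(draws, target) {
  switch(target,
         alpha = draws$alpha,
         lambda = draws$lambda,
         entropy = .iwd_entropy_vec(draws$alpha, draws$lambda),
         stop("unknown target '", target, "'"))
}

#' Importance-sampling Bayes point estimate
#'
#' Weighted posterior functional under the chosen loss: squared error
#' gives \eqn{\sum \vartheta_i \mho_i}; Linex gives
#' \eqn{-(1/p)\log\sum\vartheta_i e^{-p\mho_i}} (computed by
#' log-sum-exp); general entropy gives
#' \eqn{(\sum\vartheta_i \mho_i^{-q})^{-1/q}} and requires all target
#' values positive.
#'
#' @param draws a [draw_posterior] result.
#' @param loss a [loss_spec].
#' @param target one of `"alpha"`, `"lambda"`, `"entropy"`, or a vector.
#' @return Named numeric vector of point estimates.
#' @export
is_estimate <- function(draws, loss = loss_spec("self"),
                        target = c("alpha", "lambda", "entropy")) {
  stopifnot(inherits(draws, "pff_posterior"), inherits(loss, "pff_loss"))
  vapply(target, function(tg) {
    v <- .posterior_target(draws, tg)
    switch(loss$kind,
      self = sum(draws$weights * v),
      linex = {
        # log sum w_i e^{-p v_i} with max-subtraction
        e <- -loss$p * v + log(draws$weights)
        mx <- max(e)
        -(log(sum(exp(e - mx))) + mx) / loss$p
      },
      gelf = {
        if (any(v <= 0)) {
          stop("general-entropy loss needs positive target draws")
        }
        sum(draws$weights * v^(-loss$q))^(-1 / loss$q)
      })
  }, 0)
}

# weighted p-quantile: largest sorted index whose cumulative weight <= p
# (clamped to the first draw), per the left bracket of the weighted
# quantile definition.
.weighted_quantile <- function(v_sorted, cw, p) {
  i <- findInterval(p, cw)
  v_sorted[max(i, 1L)]
}

#' Highest posterior density interval from weighted draws
#'
#' Sorts the target draws, accumulates their normalised weights, and scans
#' all candidate intervals holding at least `level` posterior mass (each
#' candidate starts at a draw and ends at the first draw whose cumulative
#' mass closes the level); the narrowest is returned, first-found winning
#' ties.  `level` close to 1 returns the full range of the draws.
#'
#' @param draws a [draw_posterior] result.
#' @param target one of `"alpha"`, `"lambda"`, `"entropy"`.
#' @param level credible level in (0, 1).
#' @return A `"pff_interval"` with method `"hpd"`.
#' @export
hpd_interval <- function(draws, target = "entropy", level = 0.95) {
  stopifnot(inherits(draws, "pff_posterior"))
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  v <- .posterior_target(draws, target)
  o <- order(v)
  vs <- v[o]
  ws <- draws$weights[o]
  cw <- cumsum(ws)
  M <- length(vs)
  best_lo <- NA_real_
  best_hi <- NA_real_
  best_w <- Inf
  j <- 1L
  mass_before <- 0
  for (i in seq_len(M)) {
    if (j < i) j <- i
    # advance j until the interval [i, j] holds >= level mass
    while (j <= M && cw[j] - mass_before < level - 1e-12) j <- j + 1L
    if (j > M) break
    wd <- vs[j] - vs[i]
    if (wd < best_w) {
      best_w <- wd
      best_lo <- vs[i]
      best_hi <- vs[j]
    }
    mass_before <- cw[i]
  }
  if (!is.finite(best_w)) {
    stop("requested credible mass unreachable with the available draws")
  }
  pt <- sum(draws$weights * v)
  structure(list(lower = best_lo, upper = best_hi, level = level,
                 method = "hpd", target = target, point = pt),
            class = "pff_interval")
}

#' Equal-tailed weighted-quantile credible interval
#'
#' Companion to [hpd_interval]: the interval between the weighted
#' \eqn{\xi/2} and \eqn{1-\xi/2} quantiles of the draws.  By construction
#' the HPD interval is never wider.
#'
#' @inheritParams hpd_interval
#' @return A `"pff_interval"` with method `"equal_tail"`.
#' @export
equal_tail_interval <- function(draws, target = "entropy", level = 0.95) {
  stopifnot(inherits(draws, "pff_posterior"))
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  v <- .posterior_target(draws, target)
  o <- order(v)
  vs <- v[o]
  cw <- cumsum(draws$weights[o])
  xi <- 1 - level
  # endpoints chosen so the interval holds at least `level` mass: the mass
  # strictly below the lower endpoint and strictly above the upper endpoint
  # are each at most xi/2
  iL <- min(findInterval(xi / 2, cw) + 1L, length(vs))
  iU <- max(sum(cw < 1 - xi / 2) + 1L, iL)
  iU <- min(iU, length(vs))
  lo <- vs[iL]
  hi <- vs[iU]
  pt <- sum(draws$weights * v)
  structure(list(lower = lo, upper = hi, level = level,
                 method = "equal_tail", target = target, point = pt),
            class = "pff_interval")
}
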