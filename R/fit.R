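# Maximum-likelihood fitting.  The score equations have no closed-form
# root, so the fit profiles the log-likelihood over log(alpha): for each
# alpha the inner stationarity condition in lambda is solved by bracketed
# root-finding (its root is unique upward of m / sum(x^-alpha), where the
# complete-data part vanishes and the censoring part is positive), and the
# resulting one-dimensional profile is maximised by golden-section search
# started from a coarse log-grid scan.  A final Newton polish on
# (alpha, lambda) drives the score below tolerance.

# profile lambda-hat(alpha): root of dl/dlambda
.lambda_profile <- function(x, cc, alpha) {
  u <- x^(-alpha)
  su <- sum(u)
  if (!is.finite(su) || su <= 0) stop("x^(-alpha) overflow")
  lo <- length(x) / su
  if (all(cc == 0)) return(lo)
  dl <- function(l) {
    z <- l * u
    length(x) / l - su + sum(cc * exp(-z) / (-expm1(-z)) * u)
  }
  hi <- lo * 2
  it <- 0L
  while (dl(hi) > 0 && it < 200L) {
    hi <- hi * 2
    it <- it + 1L
  }
  uniroot(dl, c(lo, hi), tol = 1e-12 * lo)$root
}

#' Fit the Inverse Weibull model to a censored sample
#'
#' Maximum-likelihood estimation of \eqn{(\alpha, \lambda)} from a
#' progressively first-failure censored sample, with the entropy estimate
#' obtained by plugging the MLEs into the closed form (invariance), and
#' the inverse observed information \eqn{\tau} for interval estimation.
#'
#' @param sample a [pff_sample] with at least two distinct times.
#' @param control list of knobs: `grid` (log-alpha scan range, default
#'   `c(0.02, 100)` on the alpha scale), `grid_n` (scan points, 60),
#'   `max_newton` (polish iterations, 200), `score_tol` (max-norm
#'   convergence tolerance on the score, 1e-6).
#' @return An object of class `"iwd_fit"`: list with `alpha`, `lambda`,
#'   `entropy`, `loglik` (constant excluded; see [pff_loglik]), `tau`
#'   (inverse observed information), `score`, `converged`, `n_eval`, and
#'   the `sample`.
#' @examples
#' sc <- censoring_scheme(1, 30, R = c(10, rep(0, 19)))
#' s <- simulate_pff(sc, iwd_params(2, 1), seed = 7)
#' fit_iwd(s)
#' @export
fit_iwd <- function(sample, control = list()) {
  stopifnot(inherits(sample, "pff_sample"))
  x <- sample$times
  if (length(x) < 2L) stop("need m >= 2 observations to fit both parameters")
  if (length(unique(x)) == 1L) stop("degenerate sample: all times equal")
  cc <- .cens_exponents(sample$scheme)
  ctl <- modifyList(list(grid = c(0.02, 100), grid_n = 60L,
                         max_newton = 200L, score_tol = 1e-6), control)
  n_eval <- 0L
  pl <- function(la) {
    n_eval <<- n_eval + 1L
    v <- tryCatch({
      a <- exp(la)
      l <- .lambda_profile(x, cc, a)
      .raw_loglik(x, cc, a, l)
    }, error = function(e) -Inf)
    if (is.finite(v)) v else -Inf
  }
  grid <- seq(log(ctl$grid[1]), log(ctl$grid[2]), length.out = ctl$grid_n)
  vals <- vapply(grid, pl, 0)
  i <- which.max(vals)
  opt <- optimize(pl, c(grid[max(1L, i - 1L)], grid[min(ctl$grid_n, i + 1L)]),
                  maximum = TRUE, tol = 1e-10)
  a <- exp(opt$maximum)
  l <- .lambda_profile(x, cc, a)
  # Newton polish on (alpha, lambda) with analytic score/Hessian
  converged <- FALSE
  for (it in seq_len(ctl$max_newton)) {
    d <- .pff_derivs(x, cc, a, l)
    if (max(abs(d$score)) < ctl$score_tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(d$hess, d$score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    step <- unname(step)
    # damped step keeping parameters positive
    sc <- 1
    repeat {
      a2 <- a - sc * step[1]
      l2 <- l - sc * step[2]
      if (a2 > 0 && l2 > 0) break
      sc <- sc / 2
      if (sc < 1e-8) break
    }
    if (a2 <= 0 || l2 <= 0) break
    a <- a2
    l <- l2
    n_eval <- n_eval + 1L
  }
  d <- .pff_derivs(x, cc, a, l)
  if (max(abs(d$score)) < ctl$score_tol) converged <- TRUE
  info <- -d$hess
  tau <- tryCatch(solve(info), error = function(e) NULL)
  singular <- is.null(tau)
  if (singular) tau <- matrix(NA_real_, 2, 2)
  dimnames(tau) <- list(c("alpha", "lambda"), c("alpha", "lambda"))
  structure(list(alpha = a, lambda = l,
                 entropy = iwd_entropy(a, l),
                 loglik = .raw_loglik(x, cc, a, l),
                 tau = tau, score = d$score,
                 converged = converged && !singular,
                 singular_info = singular,
                 n_eval = n_eval, sample = sample),
            class = "iwd_fit")
}

# log-likelihood without the ordering constant, on raw pieces
.raw_loglik <- function(x, cc, alpha, lambda) {
  m <- length(x)
  u <- x^(-alpha)
  z <- lambda * u
  cens <- cc * log(-expm1(-z))
  cens[cc == 0] <- 0
  v <- m * log(alpha) + m * log(lambda) - lambda * sum(u) -
    (alpha + 1) * sum(log(x)) + sum(cens)
  if (is.nan(v)) -Inf else v
}

#' @export
print.iwd_fit <- function(x, ...) {
  cat("Inverse Weibull fit (progressive first-failure censoring)\n")
  cat(sprintf("  alpha   = %.6g\n  lambda  = %.6g\n  entropy = %.6g nats\n",
              x$alpha, x$lambda, x$entropy))
  cat(sprintf("  log-likelihood = %.4f (ordering constant excluded)\n",
              x$loglik))
  cat(sprintf("  converged: %s (score max-norm %.2e)\n",
              x$converged, max(abs(x$score))))
  invisible(x)
}

#' @export
coef.iwd_fit <- function(object, ...) {
  c(alpha = object$alpha, lambda = object$lambda, entropy = object$entropy)
}

#' @export
vcov.iwd_fit <- function(object, ...) object$tau

#' @export
logLik.iwd_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, class = "logLik")
}

#' Delta-method variance of the entropy estimate
#'
#' \eqn{\widehat{Var}(\hat H) = \Psi' \tau \Psi} with \eqn{\Psi} the
#' entropy gradient at the MLE and \eqn{\tau} the inverse observed
#' information.
#'
#' @param fit a converged [fit_iwd] result.
#' @return Non-negative variance in nats squared.
#' @export
entropy_variance <- function(fit) {
  stopifnot(inherits(fit, "iwd_fit"))
  if (any(!is.finite(fit$tau))) stop("observed information is singular")
  g <- iwd_entropy_grad(fit$alpha, fit$lambda)
  v <- drop(t(g) %*% fit$tau %*% g)
  if (v < 0) stop("inverse information is not positive definite")
  v
}

.target_var <- function(fit, target) {
  switch(target,
         alpha = fit$tau["alpha", "alpha"],
         lambda = fit$tau["lambda", "lambda"],
         entropy = entropy_variance(fit),
         stop("unknown target '", target, "'"))
}

.target_point <- function(fit, target) {
  switch(target,
         alpha = fit$alpha, lambda = fit$lambda, entropy = fit$entropy,
         stop("unknown target '", target, "'"))
}

#' Asymptotic confidence intervals
#'
#' `ci_normal` is the plain Wald interval, point
#' \eqn{\pm Z_{\xi/2}\sqrt{var}}; `ci_lognormal` is the interval for the
#' log-transformed estimator, mapped back:
#' \eqn{\hat\theta \exp(\pm Z_{\xi/2}\sqrt{var}/\hat\theta)}, whose
#' endpoints are positive and satisfy `lower * upper = point^2`.
#'
#' @param fit a converged [fit_iwd] result.
#' @param target one of `"alpha"`, `"lambda"`, `"entropy"`.
#' @param level confidence level \eqn{1 - \xi}, default 0.95.
#' @return A `"pff_interval"`: list with `lower`, `upper`, `level`,
#'   `method`, `target`, `point`.
#' @export
ci_normal <- function(fit, target = "entropy", level = 0.95) {
  stopifnot(inherits(fit, "iwd_fit"))
  z <- qnorm(1 - (1 - level) / 2)
  pt <- .target_point(fit, target)
  hw <- z * sqrt(.target_var(fit, target))
  structure(list(lower = pt - hw, upper = pt + hw, level = level,
                 method = "normal", target = target, point = pt),
            class = "pff_interval")
}

#' @rdname ci_normal
#' @export
ci_lognormal <- function(fit, target = "entropy", level = 0.95) {
  stopifnot(inherits(fit, "iwd_fit"))
  pt <- .target_point(fit, target)
  if (pt <= 0) stop("log-transformed interval requires a positive estimate")
  z <- qnorm(1 - (1 - level) / 2)
  fac <- exp(z * sqrt(.target_var(fit, target)) / pt)
  structure(list(lower = pt / fac, upper = pt * fac, level = level,
                 method = "log_normal", target = target, point = pt),
            class = "pff_interval")
}

#' @export
print.pff_interval <- function(x, ...) {
  cat(sprintf("%.0f%% %s interval for %s: %.4f (%.4f, %.4f)\n",
              100 * x$level, x$method, x$target, x$point, x$lower, x$upper))
  invisible(x)
}

#' @export
confint.iwd_fit <- function(object, parm = c("alpha", "lambda", "entropy"),
                            level = 0.95,
                            method = c("normal", "lognormal"), ...) {
  method <- match.arg(method)
  f <- if (method == "normal") ci_normal else ci_lognormal
  out <- t(vapply(parm, function(tg) {
    ci <- f(object, tg, level)
    c(ci$lower, ci$upper)
  }, numeric(2)))
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}
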