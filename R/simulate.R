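#' Simulate a progressively first-failure censored sample
#'
#' Generates one censored sample from the Inverse Weibull law under a given
#' scheme by the uniform-spacings transformation for progressive Type-II
#' order statistics, combined with the reduction that a first-failure
#' sample from a base CDF \eqn{F} is a progressive Type-II sample from the
#' transformed CDF \eqn{1 - (1 - F)^k}:
#' \enumerate{
#'   \item draw \eqn{W_1, \dots, W_m} i.i.d. uniform(0, 1);
#'   \item \eqn{V_i = W_i^{1/(i + R_m + R_{m-1} + \dots + R_{m-i+1})}};
#'   \item \eqn{U_i = 1 - \prod_{j=m-i+1}^{m} V_j}, the progressive
#'     Type-II uniform order statistics;
#'   \item \eqn{X_i = F^{-1}\left(1 - (1 - U_i)^{1/k}\right)}.
#' }
#'
#' @param scheme a [censoring_scheme].
#' @param params an [iwd_params] pair (or a shape value, with `lambda`).
#' @param lambda scale, when `params` is given as a bare shape number.
#' @param seed optional integer; when supplied the generator is seeded so
#'   the sample is bitwise reproducible.  When `NULL` the current RNG
#'   stream is used (and advanced).
#' @return A [pff_sample] with times sorted ascending.
#' @examples
#' sc <- censoring_scheme(k = 1, n = 10, scheme = "(2, 0*6, 1)")
#' simulate_pff(sc, iwd_params(2, 1), seed = 1)
#' @export
simulate_pff <- function(scheme, params, lambda = NULL, seed = NULL) {
  stopifnot(inherits(scheme, "pff_scheme"))
  pr <- if (inherits(params, "iwd_params")) params else iwd_params(params, lambda)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- scheme$m
  R <- scheme$R
  W <- runif(m)
  # exponent for V_i: i plus the removals attached to the last i failures
  tail_removed <- cumsum(rev(R))
  V <- W^(1 / (seq_len(m) + tail_removed))
  tailprod <- rev(cumprod(rev(V)))          # prod_{j=t}^{m} V_j at position t
  U <- 1 - tailprod[m - seq_len(m) + 1L]
  # invert through the first-failure law 1 - (1 - F)^k
  u_base <- 1 - (1 - U)^(1 / scheme$k)
  x <- sort(qiwd(pmin(pmax(u_base, .Machine$double.xmin), 1 - 1e-16), pr))
  pff_sample(x, scheme)
}
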