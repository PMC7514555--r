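# Shared numerical oracles and fixture builders.  Oracles here are kept
# independent of the implementation paths they check: plain central
# differences, quadrature via stats::integrate, and brute-force loops.

euler_gamma <- 0.5772156649015329

# central finite differences of a scalar function of one variable
num_deriv <- function(f, x, h = 1e-5 * max(1, abs(x))) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# gradient of f(p) for a length-2 parameter vector
num_grad2 <- function(f, p, h = 1e-5) {
  vapply(1:2, function(i) {
    e <- c(0, 0)
    e[i] <- h * max(1, abs(p[i]))
    (f(p + e) - f(p - e)) / (2 * e[i])
  }, 0)
}

# Hessian of f(p) by repeated central differences
num_hess2 <- function(f, p, h = 1e-4) {
  H <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      ei <- ej <- c(0, 0)
      ei[i] <- h * max(1, abs(p[i]))
      ej[j] <- h * max(1, abs(p[j]))
      H[i, j] <- (f(p + ei + ej) - f(p + ei - ej) -
                    f(p - ei + ej) + f(p - ei - ej)) / (4 * ei[i] * ej[j])
    }
  }
  (H + t(H)) / 2
}

# definitional K-S sup-distance by explicit double loop (brute force)
ks_brute <- function(x, alpha, lambda) {
  xs <- sort(x)
  n <- length(xs)
  d <- 0
  for (i in seq_len(n)) {
    Fi <- exp(-lambda * xs[i]^(-alpha))
    d <- max(d, i / n - Fi, Fi - (i - 1) / n)
  }
  d
}

# entropy by adaptive quadrature of -f log f (the definitional integral)
entropy_quadrature <- function(alpha, lambda) {
  f <- function(x) {
    lf <- log(alpha) + log(lambda) - lambda * x^(-alpha) -
      (alpha + 1) * log(x)
    ifelse(is.finite(lf), -exp(lf) * lf, 0)
  }
  integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# exact posterior means of alpha, lambda and entropy by nested quadrature
# over the joint posterior under the Gamma(a,b) x 1/alpha prior
posterior_mean_quadrature <- function(sample, a = 1, b = 1) {
  f0 <- fit_iwd(sample)
  lp <- function(al, la) {
    pff_loglik(sample, al, la) + (a - 1) * log(la) - b * la - log(al)
  }
  lp0 <- lp(f0$alpha, f0$lambda)
  inner <- function(al, g) {
    integrate(function(la) {
      vapply(la, function(li) {
        v <- g(al, li) * exp(lp(al, li) - lp0)
        if (is.finite(v)) v else 0
      }, 0)
    }, 0, Inf, rel.tol = 1e-8)$value
  }
  outer_int <- function(g) {
    integrate(function(av) {
      vapply(av, function(al) inner(al, g), 0)
    }, 0, Inf, rel.tol = 1e-7)$value
  }
  Z <- outer_int(function(al, la) 1)
  c(alpha = outer_int(function(al, la) al) / Z,
    lambda = outer_int(function(al, la) la) / Z,
    entropy = outer_int(function(al, la) iwd_entropy(al, la)) / Z)
}

# small reusable fixtures
scheme_t1 <- function() censoring_scheme(1, 50, c(25L, rep(0L, 24)))
scheme_t10 <- function() censoring_scheme(1, 70, c(10L, rep(0L, 59)))
scheme_mid <- function() censoring_scheme(1, 50, c(10L, rep(0L, 39)))

sample_mid <- function(seed = 101) {
  simulate_pff(scheme_mid(), iwd_params(2, 1), seed = seed)
}

guinea_r1_sample <- function() as_pff_sample(load_dataset("guinea_R1"))

# random censored instances for property loops: moderate sizes, mixed k
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(8:20, 1)
  m <- sample(4:n, 1)
  k <- sample(1:3, 1)
  R <- as.integer(stats::rmultinom(1, n - m, rep(1, m)))
  sc <- censoring_scheme(k, n, R)
  s <- simulate_pff(sc, iwd_params(runif(1, 0.8, 3), runif(1, 0.5, 3)))
  list(sample = s,
       alpha = runif(1, 0.8, 3),
       lambda = runif(1, 0.5, 3))
}
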