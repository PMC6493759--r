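# shared fixture builders; everything is generated in code at test time

tiny_model <- function(family = "poisson", n = 4, m = 3, d = 1, k = 0,
                       row_effect = FALSE, seed = 1,
                       magnitude = list()) {
  spec <- model_spec(d, family, row_effect = row_effect)
  truth <- generate_parameters(m, k, d, spec, magnitude = magnitude,
                               seed = seed)
  X <- if (k > 0) {
    set.seed(seed + 500)
    matrix(stats::rnorm(n * k), n, k)
  } else NULL
  sim <- simulate_responses(truth, spec, n, X, seed = seed + 1000)
  list(spec = spec, truth = truth, X = X, data = sim$data,
       latent = sim$latent, mu = sim$mu)
}

# random constraint-valid variational state for bound checks
random_varstate <- function(n, p, seed, row_effect = FALSE, d = p) {
  set.seed(seed)
  a <- matrix(stats::rnorm(n * p), n, p)
  q <- if (row_effect) 1L + d * (d + 1) / 2 else p * (p + 1) / 2
  # diagonal entries (log scale) in a moderate range, small off-diagonals
  Lp <- matrix(stats::rnorm(n * q, sd = 0.2), n, q)
  variational_state(a, Lp)
}

# direct maximum-likelihood fit of the closed-form gaussian factor model
# (independent oracle for the exactness tests): marginal of y_i is
# N(beta0 + B x_i, Gamma Gamma' + diag(phi) [+ sigma2 11'])
gaussian_factor_ml <- function(data, spec) {
  dims0 <- list(n = data$n, m = data$m, k = data$k)
  m <- data$m; d <- spec$d
  nll <- function(th) {
    beta0 <- th[seq_len(m)]
    off <- m
    B <- if (data$k > 0) {
      Bv <- matrix(th[off + seq_len(m * data$k)], m, data$k)
      off <- off + m * data$k
      Bv
    } else NULL
    ng <- sum(pmin(seq_len(m), d))
    gv <- th[off + seq_len(ng)]; off <- off + ng
    Gamma <- matrix(0, m, d)
    pos <- 1L
    for (l in seq_len(d)) for (j in l:m) {
      Gamma[j, l] <- if (j == l) exp(gv[pos]) else gv[pos]
      pos <- pos + 1L
    }
    phi <- exp(th[off + seq_len(m)]); off <- off + m
    s2 <- if (spec$row_effect) exp(th[off + 1L]) else NULL
    Sig <- Gamma %*% t(Gamma) + diag(phi, m)
    if (spec$row_effect) Sig <- Sig + s2
    Mu <- matrix(beta0, data$n, m, byrow = TRUE)
    if (data$k > 0) Mu <- Mu + data$X %*% t(B)
    -sum(mvtnorm::dmvnorm(data$Y - Mu, sigma = Sig, log = TRUE))
  }
  np <- m + m * data$k + sum(pmin(seq_len(m), d)) + m +
    as.integer(spec$row_effect)
  set.seed(99)
  best <- NULL
  for (tryi in 1:3) {
    th0 <- stats::rnorm(np, sd = 0.3)
    o <- tryCatch(stats::nlminb(th0, nll,
                                control = list(iter.max = 2000,
                                               rel.tol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$objective < best$objective))
      best <- o
  }
  -best$objective
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(1, abs(y))), tol)
}

# plain central-difference gradient (numDeriv's Richardson extrapolation
# loses accuracy when the objective is numerically large)
central_grad <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + hi
    xm <- x; xm[i] <- xm[i] - hi
    (f(xp) - f(xm)) / (2 * hi)
  }, numeric(1))
}
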