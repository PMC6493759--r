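test_that("linear predictor matches hand arithmetic and drops absent terms", {
  # zero case
  p0 <- parameter_set(beta0 = 0, Gamma = matrix(1e-4, 1, 1))
  l0 <- latent_state(matrix(0, 1, 1))
  expect_equal(linear_predictor(p0, list(X = NULL), l0),
               matrix(1e-4 * 0, 1, 1))
  # n=m=d=1: beta0 = 0.5, gamma = 2, u = 1 -> 2.5
  p1 <- parameter_set(beta0 = 0.5, Gamma = matrix(2, 1, 1))
  l1 <- latent_state(matrix(1, 1, 1))
  expect_equal(linear_predictor(p1, list(X = NULL), l1)[1, 1], 2.5)
  # n=1, m=2, k=1: x=1, beta0=(0,1), B=(1,-1), Gamma=(1,0.5), u=2 -> (3,1)
  p2 <- parameter_set(beta0 = c(0, 1), Gamma = matrix(c(1, 0.5), 2, 1),
                      B = matrix(c(1, -1), 2, 1))
  l2 <- latent_state(matrix(2, 1, 1))
  eta <- linear_predictor(p2, list(X = matrix(1, 1, 1)), l2)
  expect_equal(as.vector(eta), c(3, 1))
  # row effect enters additively with loading one
  l3 <- latent_state(matrix(2, 1, 1), alpha = 0.7)
  eta3 <- linear_predictor(p2, list(X = matrix(1, 1, 1)), l3)
  expect_equal(as.vector(eta3), c(3.7, 1.7))
  # dimension errors name the offending axis
  expect_error(linear_predictor(p2, list(X = matrix(1, 3, 1)), l2), "sites")
  expect_error(
    linear_predictor(p2, list(X = matrix(1, 1, 1)),
                     latent_state(matrix(1, 1, 2))), "latent")
})

test_that("linear predictor is affine in each parameter block", {
  fx <- tiny_model("poisson", n = 5, m = 4, d = 2, k = 1, seed = 3)
  base <- linear_predictor(fx$truth, fx$data, fx$latent)
  for (block in c("beta0", "B")) {
    p2 <- fx$truth
    p2[[block]] <- p2[[block]] * 2
    eta2 <- linear_predictor(p2, fx$data, fx$latent)
    # doubling a block moves eta by exactly the block's contribution
    p0 <- fx$truth
    p0[[block]] <- p0[[block]] * 0
    eta0 <- linear_predictor(p0, fx$data, fx$latent)
    expect_equal(eta2 - base, base - eta0, tolerance = 1e-12)
  }
})

test_that("conditional_logpdf agrees with reference densities", {
  expect_equal(conditional_logpdf("poisson", 0, 0), -1)
  expect_equal(conditional_logpdf("bernoulli", 1, 0), log(0.5))
  expect_equal(conditional_logpdf("bernoulli", 1, 0.3, link = "logit"),
               stats::plogis(0.3, log.p = TRUE))
  # negative binomial vs the textbook pmf (independent implementation)
  for (y in c(0, 3, 17)) for (phi in c(0.2, 0.5, 2)) for (eta in c(-1, 0, 1.5))
    expect_equal(conditional_logpdf("negative_binomial", y, eta, phi),
                 stats::dnbinom(y, size = 1 / phi, mu = exp(eta), log = TRUE),
                 tolerance = 1e-12)
  # gaussian vs dnorm
  expect_equal(conditional_logpdf("gaussian", 1.2, 0.4, phi = 2),
               stats::dnorm(1.2, 0.4, sqrt(2), log = TRUE))
  expect_error(conditional_logpdf("poisson", -1, 0), "invalid response")
  expect_error(conditional_logpdf("poisson", 1, Inf), "non-finite")
  expect_error(conditional_logpdf("negative_binomial", 1, 0, phi = -1),
               "positive")
})

test_that("count log-densities integrate to probability one", {
  for (fam in c("poisson", "negative_binomial")) {
    for (eta in c(-1, 0, 2)) for (phi in c(0.3, 1.5)) {
      ymax <- stats::qnbinom(1 - 1e-12, size = 1 / phi, mu = exp(eta)) + 50
      tot <- sum(exp(conditional_logpdf(fam, 0:ymax, eta,
                                        if (fam == "poisson") NULL else phi)))
      expect_gte(tot, 1 - 1e-8)
      expect_lte(tot, 1 + 1e-8)
    }
  }
})

test_that("family derivative kernels match finite differences", {
  cases <- list(
    list("poisson", "log", 4, NULL),
    list("negative_binomial", "log", 6, 0.7),
    list("bernoulli", "probit", 1, NULL),
    list("bernoulli", "logit", 0, NULL),
    list("gaussian", "identity", 0.8, 1.3))
  for (cs in cases) {
    k <- gllvmlite:::family_kernel(cs[[1]], cs[[2]])
    for (eta in c(-1.2, 0.1, 1.7)) {
      expect_equal(k$d1(cs[[3]], eta, cs[[4]]),
                   numDeriv::grad(function(e) k$logpdf(cs[[3]], e, cs[[4]]),
                                  eta),
                   tolerance = 1e-6)
      expect_equal(k$d2(cs[[3]], eta, cs[[4]]),
                   numDeriv::grad(function(e) k$d1(cs[[3]], e, cs[[4]]),
                                  eta),
                   tolerance = 1e-6)
      expect_equal(k$d3(cs[[3]], eta, cs[[4]]),
                   numDeriv::grad(function(e) k$d2(cs[[3]], e, cs[[4]]),
                                  eta),
                   tolerance = 1e-6)
      if (k$has_phi) {
        for (fn in c("logpdf", "d1", "d2")) {
          dfn <- switch(fn, logpdf = "dlogphi", d1 = "d1_dlogphi",
                        d2 = "d2_dlogphi")
          expect_equal(
            k[[dfn]](cs[[3]], eta, cs[[4]]),
            numDeriv::grad(function(lp)
              k[[fn]](cs[[3]], eta, exp(lp)), log(cs[[4]])),
            tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("abundance_data validates entries and dimensions", {
  expect_error(abundance_data(matrix(c(0, -1), 1), family = "poisson"),
               "invalid")
  expect_error(abundance_data(matrix(0.5, 2, 2), family = "bernoulli"),
               "invalid")
  expect_error(abundance_data(matrix(NA_real_, 2, 2), family = "poisson"),
               "missing")
  expect_error(abundance_data(matrix(0L, 3, 2), X = matrix(1, 2, 1),
                              family = "poisson"), "rows")
  d <- abundance_data(matrix(c(0, 1, 2, 3), 2), family = "poisson")
  expect_s3_class(d, "gllvm_data")
  expect_equal(c(d$n, d$m, d$k), c(2L, 2L, 0L))
})

test_that("parameter_set enforces the loading constraint", {
  expect_error(parameter_set(beta0 = c(0, 0),
                             Gamma = matrix(c(1, 1, 1, 1), 2, 2)),
               "upper triangle")
  expect_error(parameter_set(beta0 = c(0, 0),
                             Gamma = matrix(c(-1, 1, 0, 1), 2, 2)),
               "positive")
  expect_error(parameter_set(beta0 = 0, Gamma = matrix(1, 1, 1), phi = -1),
               "positive")
})

test_that("constrain_loadings zeroes the upper triangle and preserves the product", {
  # already-constrained input is returned unchanged
  G <- matrix(c(1, 0.3, 0.5, 0, 2, -1), 3, 2)
  out <- constrain_loadings(G)
  expect_equal(out$Gamma, G, tolerance = 1e-12)
  # negative diagonal: sign flip, product preserved
  G2 <- G; G2[2, 2] <- 99  # make column independent
  G2[, 2] <- -G2[, 2]
  U <- matrix(stats::rnorm(10 * 2), 10, 2)
  out2 <- constrain_loadings(G2, U)
  expect_gt(out2$Gamma[2, 2], 0)
  expect_lt(max(abs(U %*% t(G2) - out2$U %*% t(out2$Gamma))), 1e-10)
  # random case: product preservation and idempotence
  set.seed(4)
  Gr <- matrix(stats::rnorm(12), 6, 2)
  Ur <- matrix(stats::rnorm(20), 10, 2)
  o <- constrain_loadings(Gr, Ur)
  expect_lt(max(abs(Ur %*% t(Gr) - o$U %*% t(o$Gamma))), 1e-10)
  expect_true(all(o$Gamma[col(o$Gamma) > row(o$Gamma)] == 0))
  expect_true(all(diag(o$Gamma[1:2, ]) > 0))
  o2 <- constrain_loadings(o$Gamma, o$U)
  expect_equal(o2$Gamma, o$Gamma, tolerance = 1e-10)
  expect_error(constrain_loadings(matrix(c(1, 1, 2, 2), 2, 2)),
               "rank deficient")
})

test_that("generate_parameters is constraint-valid, deterministic, floored", {
  spec <- model_spec(2, "negative_binomial", row_effect = TRUE)
  p1 <- generate_parameters(6, 2, 2, spec, seed = 9)
  p2 <- generate_parameters(6, 2, 2, spec, seed = 9)
  expect_identical(p1, p2)
  expect_s3_class(p1, "gllvm_params")
  expect_true(all(diag(p1$Gamma[1:2, ]) > 0))
  expect_true(all(p1$phi > 0) && p1$sigma2 > 0)
  # zero-magnitude loadings still get a strictly positive diagonal
  p0 <- generate_parameters(5, 0, 2, spec, magnitude = list(gamma = 0),
                            seed = 2)
  expect_true(all(diag(p0$Gamma[1:2, ]) >= 1e-4))
})

test_that("simulate_responses is deterministic with correct moments", {
  spec <- model_spec(1, "poisson")
  truth <- generate_parameters(4, 0, 1, spec, seed = 5)
  s1 <- simulate_responses(truth, spec, 30, seed = 11)
  s2 <- simulate_responses(truth, spec, 30, seed = 11)
  expect_identical(s1$data$Y, s2$data$Y)
  expect_identical(s1$latent$U, s2$latent$U)
  # eta forced to log(4): sample mean within 3 SE of 4 (poisson, nm = 1e4)
  pf <- parameter_set(beta0 = rep(log(4), 2),
                      Gamma = matrix(c(1e-4, 0), 2, 1))
  sf <- simulate_responses(pf, spec, 5000, seed = 12)
  se <- sqrt(4 / (5000 * 2))
  expect_lt(abs(mean(sf$data$Y) - 4), 3 * se)
  # Gamma ~ 0: columns are independent GLM draws, |cor| small at n = 5000
  p0 <- parameter_set(beta0 = c(0.5, 0.5),
                      Gamma = matrix(c(1e-4, 0), 2, 1))
  s0 <- simulate_responses(p0, spec, 5000, seed = 13)
  expect_lt(abs(stats::cor(s0$data$Y)[1, 2]), 0.05)
})
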