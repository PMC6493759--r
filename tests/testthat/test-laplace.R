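test_that("joint_logdensity decomposes and matches the marginal integrand", {
  fx <- tiny_model("poisson", n = 3, m = 4, d = 1, seed = 2)
  # u* = 0, Gamma ~ 0: conditional terms plus the normal constant
  p0 <- fx$truth
  p0$Gamma <- matrix(c(1e-12, rep(0, 3)), 4, 1)
  l0 <- latent_state(matrix(0, 3, 1))
  jd <- joint_logdensity(p0, fx$data, l0, fx$spec)
  ref <- rowSums(conditional_logpdf("poisson", fx$data$Y,
                                    matrix(p0$beta0, 3, 4, byrow = TRUE))) -
    0.5 * log(2 * pi)
  expect_equal(jd$per_site, ref, tolerance = 1e-10)
  # at any latent value it equals log of the Eq-3 integrand: check via
  # the single-node quadrature identity exp(jd) = f(y|u) f(u)
  lat <- latent_state(matrix(c(0.3, -1, 0.8), 3, 1))
  jd2 <- joint_logdensity(fx$truth, fx$data, lat, fx$spec)
  eta <- linear_predictor(fx$truth, fx$data, lat)
  man <- rowSums(conditional_logpdf("poisson", fx$data$Y, eta)) +
    stats::dnorm(lat$U[, 1], log = TRUE)
  expect_equal(jd2$per_site, man, tolerance = 1e-10)
})

test_that("inner gradient and curvature match finite differences", {
  fx <- tiny_model("negative_binomial", n = 4, m = 5, d = 2, k = 1,
                   row_effect = TRUE, seed = 13)
  p <- gllvmlite:::latent_dim(fx$spec)
  for (i in 1:4) {
    set.seed(400 + i)
    u <- stats::rnorm(p, sd = 0.7)
    f <- function(uu) {
      lat <- latent_state(matrix(0, 4, fx$spec$d),
                          alpha = numeric(4))
      lat$U[i, ] <- uu[-1]
      lat$alpha[i] <- uu[1]
      joint_logdensity(fx$truth, fx$data, lat, fx$spec)$per_site[i]
    }
    G <- G_matrix(fx$truth, fx$data, fx$spec, i, u)
    Hn <- -numDeriv::hessian(f, u)
    expect_equal(G, Hn, tolerance = 1e-5, ignore_attr = TRUE)
  }
  # poisson canonical-link curvature: G = sum_j e^eta gamma* gamma*' + I
  fp <- tiny_model("poisson", n = 2, m = 3, d = 1, seed = 14)
  u <- 0.4
  eta <- fp$truth$beta0 + fp$truth$Gamma[, 1] * u
  Gref <- sum(exp(eta) * fp$truth$Gamma[, 1]^2) + 1
  expect_equal(G_matrix(fp$truth, fp$data, fp$spec, 1, u)[1, 1], Gref,
               tolerance = 1e-12)
  # Gamma ~ 0: prior curvature only
  p0 <- fp$truth; p0$Gamma <- matrix(c(1e-12, 0, 0), 3, 1)
  expect_equal(G_matrix(p0, fp$data, fp$spec, 1, 0)[1, 1], 1,
               tolerance = 1e-6)
})

test_that("inner_maximize finds the exact gaussian posterior mode, robustly", {
  fx <- tiny_model("gaussian", n = 5, m = 4, d = 2, seed = 15)
  i <- 2
  # closed form: (Gamma' Sigma^-1 Gamma + I)^-1 Gamma' Sigma^-1 resid
  G <- fx$truth$Gamma
  W <- diag(1 / fx$truth$phi, 4)
  r <- fx$data$Y[i, ] - fx$truth$beta0
  uref <- solve(t(G) %*% W %*% G + diag(2), t(G) %*% W %*% r)
  res <- inner_maximize(fx$truth, fx$data, fx$spec, i)
  expect_equal(res$u_hat, as.vector(uref), tolerance = 1e-6)
  expect_lt(res$grad_norm, 1e-8)
  # independence of the starting point (log-concave instance)
  fp <- tiny_model("poisson", n = 4, m = 6, d = 1, seed = 16)
  sols <- sapply(1:10, function(s) {
    set.seed(s)
    inner_maximize(fp$truth, fp$data, fp$spec, 1,
                   u_init = stats::rnorm(1, sd = 2))$u_hat
  })
  expect_lt(max(sols) - min(sols), 1e-6)
  # symmetric case: y at the family mean for u* = 0 gives u_hat = 0
  ps <- parameter_set(beta0 = c(0, 0), Gamma = matrix(c(1, -1), 2, 1),
                      phi = c(1, 1))
  ds <- abundance_data(matrix(c(3, 3), 1), family = "gaussian")
  spec_g <- model_spec(1, "gaussian")
  # mean at u=0 is beta0=0; make y equal it
  ds0 <- abundance_data(matrix(c(0, 0), 1), family = "gaussian")
  expect_equal(inner_maximize(ps, ds0, spec_g, 1)$u_hat, 0,
               tolerance = 1e-10)
})

test_that("la_loglik is exact for gaussian and near the quadrature oracle", {
  fx <- tiny_model("gaussian", n = 7, m = 3, d = 1, seed = 17)
  Sig <- fx$truth$Gamma %*% t(fx$truth$Gamma) + diag(fx$truth$phi, 3)
  ref <- sum(mvtnorm::dmvnorm(sweep(fx$data$Y, 2, fx$truth$beta0),
                              sigma = Sig, log = TRUE))
  expect_equal(as.numeric(la_loglik(fx$truth, fx$data, fx$spec)), ref,
               tolerance = 1e-8)
  # poisson tiny model: within 0.05 of the 60-node quadrature, and the
  # gap shrinks when the same species layout is tiled from m=3 to m=12
  specp <- model_spec(1, "poisson")
  p3 <- generate_parameters(3, 0, 1, specp, seed = 18)
  p12 <- parameter_set(beta0 = rep(p3$beta0, 4),
                       Gamma = matrix(rep(p3$Gamma[, 1], 4), ncol = 1))
  d12 <- simulate_responses(p12, specp, 2, seed = 19)$data
  d3 <- abundance_data(d12$Y[, 1:3, drop = FALSE], family = "poisson")
  gap <- function(pars, dat)
    abs(as.numeric(la_loglik(pars, dat, specp)) -
          marginal_loglik_quad(pars, dat, specp, 60))
  g3 <- gap(p3, d3); g12 <- gap(p12, d12)
  expect_lt(g3, 0.05)
  expect_lt(g12, g3)
})

test_that("la_loglik is invariant to species permutation", {
  # permuting species labels (with matched parameters) preserves the
  # likelihood; keep species 1 fixed so the loading constraint still holds
  fx <- tiny_model("negative_binomial", n = 4, m = 5, d = 1, seed = 19)
  perm <- c(1, 4, 2, 5, 3)
  p2 <- parameter_set(beta0 = fx$truth$beta0[perm],
                      Gamma = fx$truth$Gamma[perm, , drop = FALSE],
                      phi = fx$truth$phi[perm])
  d2 <- abundance_data(fx$data$Y[, perm], family = "negative_binomial")
  expect_equal(as.numeric(la_loglik(fx$truth, fx$data, fx$spec)),
               as.numeric(la_loglik(p2, d2, fx$spec)), tolerance = 1e-8)
})

test_that("la outer gradient matches central finite differences", {
  cases <- list(
    list(fam = "poisson", d = 1, k = 1, row = FALSE),
    list(fam = "negative_binomial", d = 2, k = 0, row = TRUE),
    list(fam = "bernoulli", d = 1, k = 0, row = FALSE))
  ctrl <- gllvm_control()
  for (cs in cases) {
    fx <- tiny_model(cs$fam, n = 5, m = 4, d = cs$d, k = cs$k,
                     row_effect = cs$row, seed = 23)
    dims <- gllvmlite:::make_dims(fx$data, fx$spec)
    for (i in 1:5) {
      set.seed(700 + i)
      th <- stats::rnorm(dims$n_psi, sd = 0.3)
      env <- new.env(); env$U_warm <- matrix(0, 5, dims$p)
      g <- gllvmlite:::la_core(th, fx$data, fx$spec, dims, ctrl, env,
                               TRUE)$grad
      gn <- central_grad(function(t2) {
        e2 <- new.env(); e2$U_warm <- matrix(0, 5, dims$p)
        gllvmlite:::la_core(t2, fx$data, fx$spec, dims, ctrl, e2,
                            FALSE)$value
      }, th)
      expect_lt(max(abs(g - gn) / pmax(1, abs(gn))), 1e-4)
    }
  }
})

test_that("fit_la recovers parameters and matches fit_va on gaussian data", {
  # NB recovery at reduced scale (the full-size harness runs in the
  # acceptance suite): n = 100, m = 8, 6 replicates
  spec <- model_spec(1, "negative_binomial")
  truth <- generate_parameters(8, 0, 1, spec, seed = 50)
  biases <- NULL
  for (r in 1:6) {
    sim <- simulate_responses(truth, spec, 100, seed = 6000 + r)
    fit <- fit_la(sim$data, spec, make_start(sim$data, spec, "res",
                                             seed = r))
    expect_gte(fit$objective, fit$objective0)   # ascent contract
    biases <- c(biases, stats::median(abs(fit$params$beta0 - truth$beta0)))
  }
  expect_lt(stats::median(biases), 0.15)
  # dual exactness: both engines meet on the gaussian family
  fx <- tiny_model("gaussian", n = 30, m = 4, d = 1, seed = 51)
  st <- make_start(fx$data, fx$spec, "res", seed = 1)
  fva <- fit_va(fx$data, fx$spec, st)
  fla <- fit_la(fx$data, fx$spec, st)
  expect_equal(fva$objective, fla$objective, tolerance = 1e-4)
})

test_that("Laplace latent modes track the posterior mean on log-concave data", {
  fx <- tiny_model("poisson", n = 6, m = 8, d = 1, seed = 52,
                   magnitude = list(gamma = 0.7))
  res <- gllvmlite:::la_inner(fx$truth, fx$data, fx$spec,
                              gllvmlite:::make_dims(fx$data, fx$spec),
                              matrix(0, 6, 1), gllvm_control())
  # posterior mean per site by 60-node quadrature
  gh <- gllvmlite:::gauss_hermite_norm(60)
  for (i in 1:6) {
    lw <- vapply(gh$nodes, function(u)
      sum(conditional_logpdf("poisson", fx$data$Y[i, ],
                             fx$truth$beta0 + fx$truth$Gamma[, 1] * u)),
      numeric(1))
    w <- exp(lw - max(lw)) * gh$weights
    pm <- sum(w * gh$nodes) / sum(w)
    expect_lt(abs(res$U[i, 1] - pm), 0.1)
  }
})
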