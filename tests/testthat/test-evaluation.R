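test_that("procrustes_error is invariant under superposition transforms", {
  set.seed(90)
  Tr <- matrix(stats::rnorm(20), 10, 2)
  expect_equal(procrustes_error(Tr, Tr), 0, tolerance = 1e-12)
  # rotation, reflection, translation and positive scaling of the estimate
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  E <- 3.2 * Tr %*% R + matrix(c(1, -2), 10, 2, byrow = TRUE)
  expect_lt(procrustes_error(E, Tr), 1e-10)
  refl <- E %*% diag(c(1, -1))
  expect_lt(procrustes_error(refl, Tr), 1e-10)
  expect_error(procrustes_error(matrix(0, 3, 1), matrix(1, 3, 1)),
               "variation")
  expect_error(procrustes_error(matrix(1, 3, 2), matrix(1, 4, 2)),
               "matching")
})

test_that("procrustes_error matches a brute-force grid search", {
  # 2-column toy with a known residual after optimal alignment
  E <- matrix(c(1, 0, -1, 0, 0, 1.3, 0, -0.7), 4, 2)
  Tr <- matrix(c(0.9, 0.4, -1.2, -0.1, 0.2, 1.1, -0.3, -1.0), 4, 2)
  mine <- procrustes_error(E, Tr)
  Ec <- sweep(E, 2, colMeans(E)); Tc <- sweep(Tr, 2, colMeans(Tr))
  grid <- expand.grid(theta = seq(0, 2 * pi, length.out = 2001),
                      refl = c(1, -1))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    th <- grid$theta[i]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
      diag(c(1, grid$refl[i]))
    ER <- Ec %*% R
    cc <- sum(ER * Tc) / sum(ER^2)       # optimal scale given the rotation
    best <- min(best, sum((cc * ER - Tc)^2))
  }
  expect_equal(mine, sqrt(best / length(Tr)), tolerance = 1e-4)
})

test_that("procrustes_error agrees with the vegan reference", {
  set.seed(91)
  E <- matrix(stats::rnorm(24), 12, 2)
  Tr <- E %*% matrix(c(0.9, 0.2, -0.3, 1.1), 2, 2) +
    matrix(stats::rnorm(24, sd = 0.3), 12, 2)
  vp <- vegan::procrustes(Tr, E, scale = TRUE)   # align E onto Tr
  expect_equal(procrustes_error(E, Tr),
               sqrt(sum(stats::residuals(vp)^2) / length(Tr)),
               tolerance = 1e-8)
})

test_that("variation_explained evaluates the formula and its limits", {
  mu <- matrix(1:4, 2)
  expect_equal(variation_explained(mu, mu + 2, mu), 1)
  nul <- matrix(2, 2, 2)
  expect_equal(variation_explained(nul, nul, mu), 0)
  hat <- mu; hat[2, 2] <- 5
  expect_equal(variation_explained(hat, nul, mu), 0.75)
  expect_warning(ve <- variation_explained(hat, mu, mu), "undefined")
  expect_true(is.na(ve))
  # VE <= 1 always
  set.seed(92)
  for (i in 1:20) {
    a <- matrix(stats::rexp(6), 2); b <- matrix(stats::rexp(6), 2)
    cc <- matrix(stats::rexp(6), 2)
    expect_lte(variation_explained(a, b, cc), 1)
  }
})

test_that("summarize_cell reproduces hand-computed summaries", {
  spec <- model_spec(1, "poisson")
  truth <- parameter_set(beta0 = c(1, 2), Gamma = matrix(c(0.5, 0.1), 2, 1))
  dims <- gllvmlite:::make_dims(list(n = 1, m = 2, k = 0,
                                     family = "poisson", link = "log"),
                                spec)
  np <- dims$n_psi
  # two replicates, exact estimates, se = 1: bias 0, rmse 0, coverage 1
  f_exact <- list(params = truth, se = rep(1, np))
  cell <- summarize_cell(list(f_exact, f_exact), truth, spec)
  b0 <- subset(cell$table, block == "beta0")
  expect_equal(c(b0$bias, b0$rmse, b0$coverage), c(0, 0, 1))
  expect_equal(b0$ci_width, 2 * 1.959964, tolerance = 1e-6)
  # hand-computed two-replicate toy: estimates off by (+0.1, -0.3)
  t2 <- truth
  p1 <- parameter_set(beta0 = truth$beta0 + 0.1, Gamma = truth$Gamma)
  p2 <- parameter_set(beta0 = truth$beta0 - 0.3, Gamma = truth$Gamma)
  cell2 <- summarize_cell(list(list(params = p1, se = rep(0.01, np)),
                               list(params = p2, se = rep(1, np))),
                          truth, spec)
  b02 <- subset(cell2$table, block == "beta0")
  expect_equal(b02$bias, mean(c(0.1, 0.1, -0.3, -0.3)))
  expect_equal(b02$rmse, sqrt(mean(c(0.01, 0.01, 0.09, 0.09))))
  # replicate 1 intervals (width 0.039) miss, replicate 2 intervals cover
  expect_equal(b02$coverage, 0.5)
  # an interval that never contains the truth has coverage zero
  p3 <- parameter_set(beta0 = truth$beta0 + 10, Gamma = truth$Gamma)
  cell3 <- summarize_cell(list(list(params = p3, se = rep(0.5, np))),
                          truth, spec)
  expect_equal(subset(cell3$table, block == "beta0")$coverage, 0)
  # failed fits are excluded and counted
  cell4 <- summarize_cell(list(NULL, f_exact), truth, spec)
  expect_equal(cell4$n_failed, 1)
  expect_warning(summarize_cell(list(NULL), truth, spec), "failed")
})

test_that("run_design completes, is deterministic, and resumes from disk", {
  spec <- model_spec(1, "poisson")
  truth <- generate_parameters(4, 0, 1, spec, seed = 93)
  design <- list(truth = truth, spec = spec, grid = list(n = c(15, 25)),
                 n_reps = 2, engines = "va", start_method = "res",
                 seed_base = 7, inference = TRUE)
  dir1 <- file.path(tempdir(), "sim1")
  res1 <- run_design(design, out_dir = dir1)
  expect_named(res1, c("n15", "n25"))
  tab <- res1$n25$summary$va$table
  expect_true(all(c("bias", "rmse", "coverage", "ci_width") %in%
                    colnames(tab)))
  expect_true(all(is.finite(res1$n25$metrics$ve)))
  # deterministic re-run without persistence
  res2 <- run_design(design)
  expect_equal(res1$n25$summary$va$table, res2$n25$summary$va$table,
               tolerance = 1e-12)
  # resume: drop one replicate file, re-run, summaries identical
  files <- list.files(dir1, full.names = TRUE)
  expect_length(files, 4)
  unlink(files[2])
  res3 <- run_design(design, out_dir = dir1)
  expect_equal(res1$n25$summary$va$table, res3$n25$summary$va$table,
               tolerance = 1e-12)
  expect_equal(res1$n15$metrics$objective, res3$n15$metrics$objective,
               tolerance = 1e-9)
})

test_that("run_design dual-exactness: va and la objectives agree on gaussian cells", {
  spec <- model_spec(1, "gaussian")
  truth <- generate_parameters(4, 0, 1, spec, seed = 94,
                               magnitude = list(gamma = 0.8))
  design <- list(truth = truth, spec = spec, grid = list(n = 25),
                 n_reps = 2, engines = c("va", "la"),
                 start_method = "res", seed_base = 11, inference = FALSE)
  res <- run_design(design)
  mets <- res$n25$metrics
  ova <- subset(mets, engine == "va")$objective
  ola <- subset(mets, engine == "la")$objective
  expect_equal(ova, ola, tolerance = 1e-3)
})

test_that("compare_starts reports differences against res3", {
  fx <- tiny_model("poisson", n = 25, m = 4, d = 1, seed = 95,
                   magnitude = list(gamma = 0.8))
  cs <- compare_starts(fx$data, fx$spec, "va",
                       methods = c("res", "res3"), seed = 3)
  expect_equal(cs$diff_vs_res3[cs$method == "res3"], 0)
  expect_lt(abs(cs$diff_vs_res3[cs$method == "res"]), 1e-3)  # unimodal
  expect_error(compare_starts(fx$data, fx$spec, "va",
                              methods = character(0)), "nonempty")
})
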