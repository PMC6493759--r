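#' Per-species marginal GLM fits
#'
#' Fits an independent GLM \eqn{g(E(y_{ij})) = \beta_{0j} + x_i'\beta_j} to
#' every species with the same family and link as the target GLLVM.
#' Negative binomial dispersions are estimated by maximum likelihood
#' (\code{\link[MASS]{glm.nb}}, with a profile-likelihood fallback); a
#' species whose GLM fails (e.g. complete separation, degenerate column)
#' falls back to an intercept-only fit and is flagged.
#'
#' @param data an \code{\link{abundance_data}}.
#' @return list with \code{beta0} (length m), \code{B} (m x k or
#'   \code{NULL}), \code{phi} (length m or \code{NULL}), \code{eta} (n x m
#'   fitted linear predictors) and \code{flagged} (logical, length m).
#' @export
fit_marginal_glms <- function(data) {
  n <- data$n; m <- data$m; k <- data$k
  fam <- switch(data$family,
    poisson = stats::poisson(link = "log"),
    bernoulli = stats::binomial(link = data$link),
    gaussian = stats::gaussian(),
    negative_binomial = NULL)
  beta0 <- numeric(m)
  B <- if (k > 0) matrix(0, m, k) else NULL
  phi <- if (data$family %in% c("negative_binomial", "gaussian"))
    numeric(m) else NULL
  eta <- matrix(0, n, m)
  flagged <- logical(m)
  Xd <- if (k > 0) as.data.frame(data$X) else NULL
  if (k > 0) names(Xd) <- paste0("x", seq_len(k))
  for (j in seq_len(m)) {
    y <- data$Y[, j]
    df <- if (k > 0) cbind(data.frame(y = y), Xd) else data.frame(y = y)
    form <- if (k > 0) stats::as.formula(paste("y ~", paste(names(Xd),
                                                            collapse = "+")))
            else y ~ 1
    fit <- NULL
    if (data$family == "bernoulli" && length(unique(y)) < 2) {
      # degenerate column: clamp the success probability at the link floor
      pbar <- max(min(mean(y), 1 - 1 / (2 * n)), 1 / (2 * n))
      beta0[j] <- if (data$link == "probit") stats::qnorm(pbar)
                  else stats::qlogis(pbar)
      eta[, j] <- beta0[j]
      flagged[j] <- TRUE
      next
    }
    if (data$family == "negative_binomial") {
      fit <- tryCatch(
        suppressWarnings(MASS::glm.nb(form, data = df)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$theta) && fit$theta > 0) {
        cf <- stats::coef(fit)
        beta0[j] <- cf[1]
        if (k > 0) B[j, ] <- cf[-1]
        phi[j] <- min(max(1 / fit$theta, 1e-6), 1e4)
        eta[, j] <- log(stats::fitted(fit))
        next
      }
      # fallback: poisson coefficients + profile ML for the dispersion
      fit <- tryCatch(
        suppressWarnings(stats::glm(form, family = stats::poisson(),
                                    data = df)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        if (all(is.finite(cf))) {
          beta0[j] <- cf[1]
          if (k > 0) B[j, ] <- cf[-1]
          eta[, j] <- log(stats::fitted(fit))
          mu <- stats::fitted(fit)
          opt <- stats::optimize(function(lp)
            -sum(stats::dnbinom(y, size = exp(-lp), mu = mu, log = TRUE)),
            c(-10, 8))
          phi[j] <- exp(opt$minimum)
          flagged[j] <- TRUE
          next
        }
      }
      beta0[j] <- log(max(mean(y), 1 / (2 * n)))
      eta[, j] <- beta0[j]
      phi[j] <- 1
      flagged[j] <- TRUE
      next
    }
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, family = fam, data = df)),
      error = function(e) NULL)
    ok <- !is.null(fit) && all(is.finite(stats::coef(fit)))
    if (ok) {
      cf <- stats::coef(fit)
      beta0[j] <- cf[1]
      if (k > 0) B[j, ] <- cf[-1]
      eta[, j] <- fam$linkfun(stats::fitted(fit))
      if (data$family == "gaussian")
        phi[j] <- max(mean(stats::residuals(fit)^2), 1e-6)
    } else {
      # intercept-only fallback
      mbar <- mean(y)
      beta0[j] <- switch(data$family,
        poisson = log(max(mbar, 1 / (2 * n))),
        bernoulli = if (data$link == "probit")
          stats::qnorm(max(min(mbar, 1 - 1 / (2 * n)), 1 / (2 * n)))
          else stats::qlogis(max(min(mbar, 1 - 1 / (2 * n)), 1 / (2 * n))),
        gaussian = mbar)
      eta[, j] <- beta0[j]
      if (data$family == "gaussian") phi[j] <- max(stats::var(y), 1e-6)
      flagged[j] <- TRUE
    }
  }
  list(beta0 = beta0, B = B, phi = phi, eta = eta, flagged = flagged,
       family = data$family, link = data$link)
}

#' Dunn-Smyth (randomized quantile) residuals
#'
#' \deqn{r_{ij} = \Phi^{-1}\{z_{ij} F_{ij}(y_{ij}) + (1 - z_{ij})
#' F^-_{ij}(y_{ij})\}} with \eqn{z_{ij} \sim U(0,1)} i.i.d. and \eqn{F^-}
#' the left limit of the fitted CDF (for counts, \eqn{F(y-1)}; 0 at
#' \eqn{y = 0}).  Exactly standard normal when the fitted model is the
#' truth.  Arguments that would hit 0 or 1 are clamped to
#' \eqn{[10^{-10}, 1-10^{-10}]}.
#'
#' @param Y n x m response matrix.
#' @param F_upper n x m matrix of fitted CDF values \eqn{F_{ij}(y_{ij})}.
#' @param F_lower n x m matrix of left limits \eqn{F^-_{ij}(y_{ij})}; for
#'   continuous families pass \code{F_upper}.
#' @param seed integer seed for the uniform jitter.
#' @return n x m matrix of residuals.
#' @export
dunn_smyth_residuals <- function(Y, F_upper, F_lower, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- matrix(stats::runif(length(Y)), nrow(Y), ncol(Y))
  u <- z * F_upper + (1 - z) * F_lower
  u <- pmin(pmax(u, 1e-10), 1 - 1e-10)
  stats::qnorm(u)
}

# fitted CDF pair from marginal GLM output
glm_cdf_pair <- function(data, glms) {
  kern <- family_kernel(data$family, data$link)
  phi_row <- if (kern$has_phi) rep(glms$phi, each = data$n) else NULL
  Fu <- kern$cdf(data$Y, glms$eta, phi_row)
  Fl <- if (kern$is_discrete) kern$cdf(data$Y - 1, glms$eta, phi_row) else Fu
  list(F_upper = matrix(Fu, data$n, data$m),
       F_lower = matrix(Fl, data$n, data$m))
}

#' Factor analysis of a residual matrix
#'
#' Fits a \code{d}-factor model to the residual matrix by maximum
#' likelihood (\code{\link[stats]{factanal}}, regression scores), falling
#' back to a truncated SVD of the column-standardized residuals on Heywood
#' cases or non-convergence.  The loadings/scores are rotated with
#' \code{\link{constrain_loadings}} so the loading matrix is lower
#' triangular with positive diagonal.
#'
#' @param R n x m residual matrix.
#' @param d number of factors (\eqn{d < \min(n, m)}).
#' @return list with \code{U0} (n x d scores), \code{Gamma0} (m x d
#'   constrained loadings) and \code{fa_failed} (TRUE when the SVD fallback
#'   was used).
#' @export
residual_factor_analysis <- function(R, d) {
  R <- as.matrix(R)
  n <- nrow(R); m <- ncol(R)
  if (d >= min(n, m)) stop("need d < min(n, m)")
  ctr <- colMeans(R)
  sds <- apply(R, 2, stats::sd)
  sds[!is.finite(sds) | sds < 1e-12] <- 1
  fa <- tryCatch(
    suppressWarnings(stats::factanal(x = R, factors = d,
                                     scores = "regression",
                                     rotation = "none")),
    error = function(e) NULL)
  if (!is.null(fa)) {
    Gamma0 <- matrix(as.numeric(stats::loadings(fa)), m, d) * sds
    U0 <- fa$scores
    fa_failed <- FALSE
  } else {
    Rs <- scale(R, center = ctr, scale = sds)
    sv <- svd(Rs, nu = d, nv = d)
    U0 <- sv$u * sqrt(n - 1)
    Gamma0 <- (sv$v %*% diag(sv$d[seq_len(d)] / sqrt(n - 1), d)) * sds
    fa_failed <- TRUE
  }
  cl <- tryCatch(constrain_loadings(Gamma0, U0), error = function(e) NULL)
  if (is.null(cl)) {
    # rank-deficient loadings: perturb minimally to restore full rank
    Gamma0 <- Gamma0 + matrix(1e-6, m, d)
    cl <- constrain_loadings(Gamma0, U0)
  }
  Gamma0 <- cl$Gamma
  dg <- seq_len(min(m, d))
  Gamma0[cbind(dg, dg)] <- pmax(Gamma0[cbind(dg, dg)], 1e-4)
  list(U0 = cl$U, Gamma0 = Gamma0, fa_failed = fa_failed)
}

#' Construct starting values for a GLLVM fit
#'
#' Implements four strategies:
#' \describe{
#'   \item{\code{res}}{per-species GLM fits give the fixed parameters;
#'     factor analysis of the Dunn-Smyth residuals gives loadings and
#'     latent variables; row effects start at zero.}
#'   \item{\code{res3}}{as \code{res}, but \code{n_sets} copies whose
#'     latent variables are jittered with \eqn{N(0, \code{jitter_sd}^2)}
#'     noise (default 3 sets, sd 0.2); fixed parameters, loadings and
#'     dispersions are shared across sets.  A multi-start fit keeps the
#'     set with the highest final objective.}
#'   \item{\code{zero}}{all parameters zero except the loading diagonal at
#'     its floor (1e-4) and dispersions/variances at 1.}
#'   \item{\code{random}}{latent variables drawn from \eqn{N_d(0, I)}, then
#'     a per-species GLM on the covariates and the drawn latents supplies
#'     coefficients and (rotated) loadings.}
#' }
#'
#' @param data an \code{\link{abundance_data}}.
#' @param spec a \code{\link{model_spec}}.
#' @param method one of \code{"res"}, \code{"res3"}, \code{"zero"},
#'   \code{"random"}.
#' @param n_sets number of jittered sets for \code{res3}.
#' @param jitter_sd jitter standard deviation for \code{res3}.
#' @param seed integer seed (drives the residual jitter, the latent draws
#'   and the \code{res3} jitter).
#' @return a list of \code{gllvm_start} objects (length \code{n_sets} for
#'   \code{res3}, otherwise 1), each with \code{params0},
#'   \code{latents0}, \code{label} and \code{set_index}.
#' @export
make_start <- function(data, spec, method = c("res", "res3", "zero", "random"),
                       n_sets = 3L, jitter_sd = 0.2, seed = 1L) {
  method <- match.arg(method)
  d <- spec$d; m <- data$m; k <- data$k; n <- data$n
  has_phi <- spec$family %in% c("negative_binomial", "gaussian")
  mk <- function(params0, latents0, label, set_index = 1L)
    structure(list(params0 = params0, latents0 = latents0,
                   varstate0 = NULL, label = label, set_index = set_index),
              class = "gllvm_start")
  if (method == "zero") {
    Gamma <- matrix(0, m, d)
    Gamma[cbind(seq_len(min(m, d)), seq_len(min(m, d)))] <- 1e-4
    params0 <- parameter_set(
      beta0 = numeric(m), Gamma = Gamma,
      B = if (k > 0) matrix(0, m, k) else NULL,
      phi = if (has_phi) rep(1, m) else NULL,
      sigma2 = if (spec$row_effect) 1 else NULL)
    lat0 <- latent_state(matrix(0, n, d),
                         if (spec$row_effect) numeric(n) else NULL)
    return(list(mk(params0, lat0, "zero")))
  }
  if (method == "random") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    U <- matrix(stats::rnorm(n * d), n, d)
    aug <- abundance_data(data$Y, cbind(data$X, U), data$family, data$link)
    glms <- fit_marginal_glms(aug)
    Graw <- glms$B[, k + seq_len(d), drop = FALSE]
    cl <- tryCatch(constrain_loadings(Graw, U), error = function(e) NULL)
    if (is.null(cl)) cl <- constrain_loadings(
      Graw + matrix(stats::rnorm(m * d, sd = 1e-4), m, d), U)
    Gamma <- cl$Gamma
    dg <- seq_len(min(m, d))
    Gamma[cbind(dg, dg)] <- pmax(Gamma[cbind(dg, dg)], 1e-4)
    params0 <- parameter_set(
      beta0 = glms$beta0, Gamma = Gamma,
      B = if (k > 0) glms$B[, seq_len(k), drop = FALSE] else NULL,
      phi = if (has_phi) pmax(glms$phi, 1e-6) else NULL,
      sigma2 = if (spec$row_effect) 0.25 else NULL)
    lat0 <- latent_state(cl$U, if (spec$row_effect) numeric(n) else NULL)
    return(list(mk(params0, lat0, "random")))
  }
  # res / res3
  glms <- fit_marginal_glms(data)
  cds <- glm_cdf_pair(data, glms)
  R <- dunn_smyth_residuals(data$Y, cds$F_upper, cds$F_lower, seed = seed)
  fa <- residual_factor_analysis(R, d)
  params0 <- parameter_set(
    beta0 = glms$beta0, Gamma = fa$Gamma0,
    B = glms$B,
    phi = if (has_phi) pmax(glms$phi, 1e-6) else NULL,
    sigma2 = if (spec$row_effect) 0.25 else NULL)
  lat0 <- latent_state(fa$U0, if (spec$row_effect) numeric(n) else NULL)
  if (method == "res") return(list(mk(params0, lat0, "res")))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  lapply(seq_len(n_sets), function(s) {
    Uj <- fa$U0 + matrix(stats::rnorm(n * d, sd = jitter_sd), n, d)
    mk(params0, latent_state(Uj, if (spec$row_effect) numeric(n) else NULL),
       "res3", s)
  })
}
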