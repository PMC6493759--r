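#' Gaussian expectation of a conditional log-density
#'
#' Computes \eqn{E[\log f(y \mid \eta)]} for \eqn{\eta \sim N(\tilde\eta,
#' s^2)}: in closed form for poisson/log
#' (\eqn{y\tilde\eta - e^{\tilde\eta + s^2/2} - \log y!}) and
#' gaussian/identity, and by fixed-order Gauss-Hermite quadrature for the
#' bernoulli and negative binomial families.  \code{s2 = 0} reduces exactly
#' to \code{\link{conditional_logpdf}}.
#'
#' @inheritParams conditional_logpdf
#' @param eta_tilde mean of the normal distribution of \eqn{\eta}.
#' @param s2 variance of \eqn{\eta} (\eqn{\ge 0}).
#' @param K quadrature order for families without a closed form.
#' @return numeric vector of expected log-densities.
#' @export
expected_loglik_1d <- function(family, y, eta_tilde, s2, phi = NULL,
                               link = default_link(family), K = 32L) {
  if (any(s2 < 0)) stop("'s2' must be non-negative")
  kern <- family_kernel(family, link)
  if (family == "poisson")
    return(y * eta_tilde - exp(eta_tilde + s2 / 2) - lgamma(y + 1))
  if (family == "gaussian")
    return(-0.5 * log(2 * pi * phi) - ((y - eta_tilde)^2 + s2) / (2 * phi))
  gh <- gauss_hermite_norm(K)
  s <- sqrt(s2)
  out <- 0
  for (q in seq_len(K))
    out <- out + gh$weights[q] * kern$logpdf(y, eta_tilde + s * gh$nodes[q], phi)
  out
}

# expectation, first/second eta-derivatives and log-phi derivative of the
# expected log-density, as n x m matrices.  DS is d/d s2 = E[f'']/2 (Price's
# theorem), so it stays finite as s2 -> 0.
va_moments <- function(kern, Y, Etilde, S2, phi_row, gh) {
  if (kern$family == "poisson") {
    Mu <- exp(Etilde + S2 / 2)
    return(list(h = Y * Etilde - Mu - lgamma(Y + 1),
                DH = Y - Mu, DS = -Mu / 2, DLP = NULL))
  }
  if (kern$family == "gaussian") {
    R <- Y - Etilde
    return(list(h = -0.5 * log(2 * pi * phi_row) - (R^2 + S2) / (2 * phi_row),
                DH = R / phi_row, DS = -1 / (2 * phi_row) + 0 * R,
                DLP = -0.5 + (R^2 + S2) / (2 * phi_row)))
  }
  s <- sqrt(S2)
  h <- DH <- D2 <- DZ <- 0
  DLP <- if (kern$has_phi) 0 else NULL
  if (kern$family == "negative_binomial") {
    # hoist the node-independent special-function terms out of the
    # quadrature loop; they dominate the cost otherwise
    r <- 1 / phi_row
    ch <- lgamma(Y + r) - lgamma(r) - lgamma(Y + 1) + r * log(r)
    cd <- digamma(Y + r) - digamma(r) + log(r) + 1
    ry <- r + Y
    for (q in seq_along(gh$nodes)) {
      mu <- exp(Etilde + s * gh$nodes[q])
      w <- gh$weights[q]
      D <- r + mu
      d1 <- r * (Y - mu) / D
      h <- h + w * (ch - ry * log(D) + Y * (Etilde + s * gh$nodes[q]))
      DH <- DH + w * d1
      D2 <- D2 - w * (r * mu * ry / D^2)
      DZ <- DZ + (w * gh$nodes[q]) * d1
      DLP <- DLP - w * r * (cd - log(D) - ry / D)
    }
  } else {
    for (q in seq_along(gh$nodes)) {
      eta <- Etilde + s * gh$nodes[q]
      w <- gh$weights[q]
      d1 <- kern$d1(Y, eta, phi_row)
      h <- h + w * kern$logpdf(Y, eta, phi_row)
      DH <- DH + w * d1
      D2 <- D2 + w * kern$d2(Y, eta, phi_row)
      DZ <- DZ + (w * gh$nodes[q]) * d1
      if (kern$has_phi) DLP <- DLP + w * kern$dlogphi(Y, eta, phi_row)
    }
  }
  # d/d s2 of the quadrature itself: sum_k w_k f'(eta_k) z_k / (2s); this
  # keeps objective and gradient exactly consistent for the optimizer.
  # Price's theorem (E[f'']/2) is the s -> 0 limit and is used there.
  DS <- ifelse(S2 > 1e-12, DZ / (2 * pmax(s, 1e-300)), D2 / 2)
  list(h = h, DH = DH, DS = DS, DLP = DLP)
}

#' Variational lower bound of the GLLVM log-likelihood
#'
#' Evaluates the variational objective
#' \deqn{\underline\ell(\Psi, \xi) = \sum_{ij} E_q[\log f(y_{ij} \mid
#'   \eta_{ij})] + \frac12 \sum_i \{\log\det A_i - tr(C^{-1}A_i) -
#'   a_i'C^{-1}a_i - \log\det C + p\},}
#' where under \eqn{q} the predictor \eqn{\eta_{ij}} is normal with mean
#' \eqn{\tilde\eta_{ij} = \beta_{0j} + x_i'\beta_j + a_i'\gamma^*_j} and
#' variance \eqn{s^2_{ij} = \gamma^{*\prime}_j A_i \gamma^*_j}.  All
#' data-dependent constants (e.g. \eqn{\log y!}) are included, so the bound
#' is directly comparable with \code{\link{marginal_loglik_quad}} and
#' \code{\link{la_loglik}} and satisfies
#' \eqn{\underline\ell \le \ell} for every state.
#'
#' @param params a \code{\link{parameter_set}}.
#' @param varstate a \code{\link{variational_state}}.
#' @param data an \code{\link{abundance_data}}.
#' @param spec a \code{\link{model_spec}}.
#' @param K quadrature order for families without closed-form expectations.
#' @return the value of the bound (a single number).
#' @export
va_bound <- function(params, varstate, data, spec, K = 32L) {
  dims <- make_dims(data, spec)
  va_eval(params, varstate, data, spec, dims, gauss_hermite_norm(K),
          want_grad = FALSE)$value
}

# objective and analytic gradient over the joint vector (psi, xi)
va_core <- function(theta, data, spec, dims, gh, want_grad = TRUE) {
  pl <- unpack_psi(theta[seq_len(dims$n_psi)], dims)
  vs <- unpack_xi(theta[dims$n_psi + seq_len(dims$n_xi)], dims)
  va_eval(pl, vs, data, spec, dims, gh, want_grad)
}

# forward pass (and gradient, in the packed layout) from unpacked pieces
va_eval <- function(pl, vs, data, spec, dims, gh, want_grad = TRUE) {
  p <- dims$p; n <- dims$n; m <- dims$m
  kern <- dims$kern
  Gstar <- if (dims$row_effect) cbind(1, pl$Gamma) else pl$Gamma
  Gq <- loadings_outer(Gstar)
  AA <- varstate_A(vs, dims)
  Etilde <- matrix(pl$beta0, n, m, byrow = TRUE)
  if (dims$k > 0) Etilde <- Etilde + data$X %*% t(pl$B)
  Etilde <- Etilde + vs$a %*% t(Gstar)
  S2 <- AA$Amat %*% t(Gq)
  S2[S2 < 0] <- 0                       # numerical fuzz only; A_i is PD
  phi_row <- if (kern$has_phi) rep(pl$phi, each = n) else NULL
  mom <- va_moments(kern, data$Y, Etilde, S2, phi_row, gh)
  cinv <- 1 / cov_prior_diag(pl, spec)
  diag_cols <- (seq_len(p) - 1L) * p + seq_len(p)
  trCA <- AA$Amat[, diag_cols, drop = FALSE] %*% cinv
  aCa <- (vs$a^2) %*% cinv
  logdetC <- if (dims$row_effect) log(pl$sigma2) else 0
  value <- sum(mom$h) +
    0.5 * sum(AA$logdet - trCA - aCa - logdetC + p)
  if (!is.finite(value)) return(list(value = -Inf, grad = NULL))
  if (!want_grad) return(list(value = value))

  g <- numeric(dims$n_psi)
  g[dims$i_beta0] <- colSums(mom$DH)
  if (dims$k > 0) g[dims$i_B] <- as.vector(t(mom$DH) %*% data$X)
  dGstar <- t(mom$DH) %*% vs$a          # m x p
  W <- t(mom$DS) %*% AA$Amat            # m x p^2
  for (a in seq_len(p)) for (b in seq_len(p))
    dGstar[, a] <- dGstar[, a] + 2 * W[, (b - 1L) * p + a] * Gstar[, b]
  dGam <- dGstar[, dims$r + seq_len(dims$d), drop = FALSE]
  gfree <- dGam[cbind(dims$gj, dims$gl)]
  gfree[dims$gdiag] <- gfree[dims$gdiag] *
    pl$Gamma[cbind(dims$gj, dims$gl)][dims$gdiag]
  g[dims$i_gamma] <- gfree
  if (dims$has_phi) g[dims$i_phi] <- colSums(mom$DLP)
  if (dims$row_effect)
    g[dims$i_sigma2] <- 0.5 * sum((AA$Amat[, 1] + vs$a[, 1]^2) / pl$sigma2) -
      n / 2
  da <- mom$DH %*% Gstar - vs$a * rep(cinv, each = n)
  Mmat <- mom$DS %*% Gq
  Mmat[, diag_cols] <- Mmat[, diag_cols] -
    0.5 * rep(cinv, each = n)
  dL <- chol_chain(Mmat, AA$Lval, vs, dims)
  dL[, dims$ediag] <- dL[, dims$ediag, drop = FALSE] + 1   # d(1/2 logdet A)
  list(value = value, grad = c(g, as.vector(da), as.vector(dL)))
}

#' Control parameters for the fitting engines
#'
#' @param maxit maximum number of outer iterations.
#' @param rel_tol relative objective-change tolerance passed to the
#'   optimizer.
#' @param grad_tol gradient max-norm below which a fit is flagged converged.
#' @param quad Gauss-Hermite order for variational expectations.
#' @param a2_init initial variational variance (\eqn{A_i = a_2 I}).
#' @param inner_tol,inner_maxit Newton tolerance and iteration cap for the
#'   Laplace inner maximization.
#' @return a list of control settings.
#' @export
gllvm_control <- function(maxit = 2000L, rel_tol = 1e-12, grad_tol = 1e-4,
                          quad = 32L, a2_init = 0.1,
                          inner_tol = 1e-8, inner_maxit = 100L) {
  list(maxit = maxit, rel_tol = rel_tol, grad_tol = grad_tol, quad = quad,
       a2_init = a2_init, inner_tol = inner_tol, inner_maxit = inner_maxit)
}

#' Fit a GLLVM by the variational approximation
#'
#' Maximizes the variational lower bound jointly over model parameters
#' \eqn{\Psi} and variational parameters \eqn{\xi} with a quasi-Newton
#' method (\code{\link[stats]{nlminb}}) driven by the analytic gradient.
#' Dispersions, variances, the loading diagonal and the variational
#' Cholesky diagonals are optimized on the log scale.
#'
#' @param data an \code{\link{abundance_data}}.
#' @param spec a \code{\link{model_spec}}.
#' @param start starting values: one \code{gllvm_start} object or a list of
#'   them (multi-start; the fit with the highest final objective is kept),
#'   as produced by \code{\link{make_start}}.
#' @param control a \code{\link{gllvm_control}} list.
#' @return an object of class \code{c("gllvm_va_fit", "gllvm_fit")} with
#'   elements \code{params}, \code{varstate}, \code{objective},
#'   \code{objective0} (objective at the start), \code{converged},
#'   \code{n_iter}, \code{grad_norm}, \code{start_label}, and internals
#'   needed for inference.
#' @export
fit_va <- function(data, spec, start, control = gllvm_control()) {
  starts <- if (inherits(start, "gllvm_start")) list(start) else start
  dims <- make_dims(data, spec)
  gh <- gauss_hermite_norm(control$quad)
  best <- NULL
  for (st in starts) {
    vs0 <- st$varstate0
    if (is.null(vs0)) vs0 <- init_varstate(st$latents0, dims, control$a2_init)
    theta0 <- c(pack_psi(st$params0, dims), pack_xi(vs0, dims))
    f0 <- va_core(theta0, data, spec, dims, gh, want_grad = FALSE)$value
    if (!is.finite(f0))
      stop("non-finite variational objective at the starting values")
    memo <- new.env()
    core <- function(th, grad) {
      if (!is.null(memo$th) && identical(th, memo$th) &&
          (!grad || !is.null(memo$r$grad))) return(memo$r)
      r <- va_core(th, data, spec, dims, gh, want_grad = grad)
      memo$th <- th; memo$r <- r
      r
    }
    objfun <- function(th) -core(th, FALSE)$value
    gradfun <- function(th) {
      r <- core(th, TRUE)
      if (is.null(r$grad)) rep(NA_real_, length(th)) else -r$grad
    }
    lower <- c(psi_lower(dims), xi_lower(dims))
    opt <- stats::nlminb(
      theta0, objective = objfun, gradient = gradfun, lower = lower,
      control = list(iter.max = control$maxit, eval.max = 4 * control$maxit,
                     rel.tol = control$rel_tol))
    # nlminb's own stopping rules can leave the gradient just above
    # tolerance; polish until the projected gradient passes.  The
    # tolerance scales with the objective magnitude: below it, the
    # attainable improvement drops under the objective's noise floor.
    tol_eff <- control$grad_tol * max(1, abs(opt$objective) / 1000)
    pol <- polish_opt(opt$par, opt$objective, objfun, gradfun, lower,
                      function(th) va_core(th, data, spec, dims, gh,
                                           TRUE)$grad,
                      tol_eff)
    opt$par <- pol$par; opt$objective <- pol$value
    gn <- pol$gn
    # numerically converged also when dedicated polish rounds cannot
    # improve the objective measurably (flat to machine precision)
    stalled <- pol$improvement < 1e-7 * max(1, abs(pol$value))
    fit <- structure(list(
      params = as_parameter_set(unpack_psi(opt$par[seq_len(dims$n_psi)], dims)),
      varstate = unpack_xi(opt$par[dims$n_psi + seq_len(dims$n_xi)], dims),
      objective = -opt$objective, objective0 = f0,
      theta = opt$par, dims = dims, data = data, spec = spec,
      control = control, method = "va",
      converged = gn < tol_eff || stalled, n_iter = opt$iterations,
      grad_norm = gn, start_label = st$label %||% "custom"),
      class = c("gllvm_va_fit", "gllvm_fit"))
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  best
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Latent-variable predictions from a variational fit
#'
#' Returns the variational means \eqn{a_i} as point predictions of
#' \eqn{u^*_i} and the variational covariances \eqn{A_i} as prediction
#' covariances.
#'
#' @param fit a fit from \code{\link{fit_va}}.
#' @return list with \code{latent} (a \code{\link{latent_state}}),
#'   \code{cov} (list of per-site \eqn{p \times p} covariance matrices) and
#'   \code{sd} (\eqn{n \times p} matrix of prediction standard deviations).
#' @export
predict_latents_va <- function(fit) {
  stopifnot(inherits(fit, "gllvm_va_fit"))
  dims <- fit$dims
  AA <- varstate_A(fit$varstate, dims)
  covs <- lapply(seq_len(dims$n), function(i)
    matrix(AA$Amat[i, ], dims$p, dims$p))
  a <- fit$varstate$a
  lat <- if (dims$row_effect)
    latent_state(a[, -1, drop = FALSE], alpha = a[, 1])
  else latent_state(a)
  diag_cols <- (seq_len(dims$p) - 1L) * dims$p + seq_len(dims$p)
  list(latent = lat, cov = covs,
       sd = sqrt(AA$Amat[, diag_cols, drop = FALSE]))
}
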