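# forward-difference Hessian of a (negated) objective from its analytic
# gradient; symmetrized
fd_hessian <- function(gradfun, x, h_rel = 1e-5) {
  g0 <- gradfun(x)
  np <- length(x)
  H <- matrix(0, np, np)
  for (i in seq_len(np)) {
    h <- h_rel * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + h
    H[, i] <- (gradfun(xp) - g0) / h
  }
  (H + t(H)) / 2
}

# inverse with pseudo-inverse fallback (singular values below
# 1e-10 * max truncated); returns list(inv, pinv_used)
safe_inverse <- function(H) {
  out <- tryCatch(list(inv = chol2inv(chol(H)), pinv_used = FALSE),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  sv <- svd(H)
  keep <- sv$d > 1e-10 * max(sv$d)
  inv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(inv = inv, pinv_used = TRUE)
}

# psi-block of the inverse negative Hessian by Schur complement over xi
va_psi_covariance <- function(H, n_psi) {
  ip <- seq_len(n_psi)
  Hpp <- H[ip, ip, drop = FALSE]
  Hpx <- H[ip, -ip, drop = FALSE]
  Hxx <- H[-ip, -ip, drop = FALSE]
  sx <- safe_inverse(Hxx)
  S <- Hpp - Hpx %*% sx$inv %*% t(Hpx)
  si <- safe_inverse(S)
  list(cov = si$inv, pinv_used = si$pinv_used || sx$pinv_used)
}

# human-readable labels aligned with the packed psi vector
psi_labels <- function(dims) {
  lab <- data.frame(parameter = character(0), species = integer(0),
                    index = integer(0))
  add <- function(lab, parameter, species, index)
    rbind(lab, data.frame(parameter = parameter, species = species,
                          index = index))
  lab <- add(lab, "beta0", seq_len(dims$m), 0L)
  if (dims$k > 0)
    for (l in seq_len(dims$k))
      lab <- add(lab, paste0("beta", l), seq_len(dims$m), l)
  lab <- add(lab, "gamma", dims$gj, dims$gl)
  if (dims$has_phi) lab <- add(lab, "log_phi", seq_len(dims$m), 0L)
  if (dims$row_effect) lab <- add(lab, "log_sigma2", 0L, 0L)
  lab
}

#' Standard errors and Wald intervals for a fitted GLLVM
#'
#' For a Laplace fit, inverts the negative Hessian of the approximate
#' log-likelihood over the model parameters.  For a variational fit, takes
#' the \eqn{\Psi}-block of the inverse negative Hessian of the bound over
#' the joint vector (\eqn{\Psi, \xi}) via a Schur complement, which equals
#' the corresponding block of the full inverse.  Hessians are obtained by
#' differencing the analytic gradients.  Dispersions and variances are
#' treated on the log scale (the scale on which they are estimated);
#' natural-scale dispersion summaries use the delta method.  Latent
#' prediction standard deviations come from the variational covariances
#' (\eqn{A_i}) or the inverse curvature (\eqn{G_i^{-1}}).
#'
#' @param fit a fit from \code{\link{fit_va}} or \code{\link{fit_la}}.
#' @param level confidence level for the Wald intervals.
#' @return an object of class \code{"gllvm_inference"}: list with
#'   \code{table} (one row per scalar parameter: parameter, species, index,
#'   estimate, se, lower, upper), \code{cov} (parameter covariance),
#'   \code{lv_prediction_sd} (n x p matrix), \code{pinv_used} flag.
#' @export
standard_errors <- function(fit, level = 0.95) {
  dims <- fit$dims
  if (fit$method == "va") {
    gh <- gauss_hermite_norm(fit$control$quad)
    gradfun <- function(th)
      -va_core(th, fit$data, fit$spec, dims, gh, TRUE)$grad
    H <- fd_hessian(gradfun, fit$theta)
    vc <- va_psi_covariance(H, dims$n_psi)
    lv_sd <- predict_latents_va(fit)$sd
  } else {
    env <- new.env()
    env$U_warm <- latent_aug(fit$latents_hat, dims$row_effect)
    gradfun <- function(th)
      -la_core(th, fit$data, fit$spec, dims, fit$control, env, TRUE)$grad
    H <- fd_hessian(gradfun, fit$theta[seq_len(dims$n_psi)])
    si <- safe_inverse(H)
    vc <- list(cov = si$inv, pinv_used = si$pinv_used)
    lv_sd <- predict_latents_la(fit)$sd
  }
  est <- fit$theta[seq_len(dims$n_psi)]
  se <- sqrt(pmax(diag(vc$cov), 0))
  tab <- psi_labels(dims)
  tab$estimate <- est
  tab$se <- se
  ci <- wald_ci(est, se, level = level)
  tab$lower <- ci$lower
  tab$upper <- ci$upper
  # gamma diagonal entries are estimated as log(gamma_jj); report them on
  # the natural scale via the delta method, keeping the log-scale CI
  dgi <- which(tab$parameter == "gamma")[dims$gdiag]
  if (length(dgi)) {
    g <- exp(tab$estimate[dgi])
    tab$estimate[dgi] <- g
    tab$se[dgi] <- tab$se[dgi] * g
    tab$lower[dgi] <- exp(tab$lower[dgi])
    tab$upper[dgi] <- exp(tab$upper[dgi])
  }
  structure(list(table = tab, cov = vc$cov, level = level,
                 lv_prediction_sd = lv_sd, pinv_used = vc$pinv_used,
                 method = fit$method),
            class = "gllvm_inference")
}

#' Wald confidence intervals
#'
#' \eqn{\hat\theta \pm z_{1-\alpha/2}\, se} on the estimation scale.
#'
#' @param estimate,se numeric vectors.
#' @param level confidence level in (0, 1).
#' @return data.frame with columns \code{lower}, \code{upper}.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(lower = estimate - z * se, upper = estimate + z * se)
}
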