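#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int e^{-x^2} g(x)\,dx \approx \sum_k w_k
#' g(x_k)} ("physicists'" convention), computed by the Golub-Welsch
#' eigenvalue method on the Jacobi matrix of the Hermite recurrence.
#'
#' @param K number of nodes (\eqn{\ge 1}).
#' @return list with numeric vectors \code{nodes} and \code{weights}.
#' @export
gauss_hermite <- function(K) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(K - 1) / 2)
  J <- matrix(0, K, K)
  J[cbind(seq_len(K - 1), seq_len(K - 1) + 1)] <- off
  J[cbind(seq_len(K - 1) + 1, seq_len(K - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# standardized rule for E[g(Z)], Z ~ N(0,1): nodes z_k, weights summing to 1
gauss_hermite_norm <- function(K) {
  gh <- gauss_hermite(K)
  list(nodes = sqrt(2) * gh$nodes, weights = gh$weights / sqrt(pi))
}

#' Brute-force marginal log-likelihood by tensor quadrature
#'
#' Approximates the marginal log-likelihood of a GLLVM -- the integral of
#' the conditional likelihood over the site-level latent vector
#' \eqn{u^*_i = (\alpha_i, u_i')'} with prior \eqn{N(0, C)},
#' \eqn{C = bdiag(\sigma^2, I_d)} -- by a tensor product of Gauss-Hermite
#' rules.  Feasible only for small latent dimension; used throughout the
#' test suite as the independent oracle for both approximation engines.
#'
#' @param params a \code{\link{parameter_set}}.
#' @param data an \code{\link{abundance_data}}.
#' @param spec a \code{\link{model_spec}}.
#' @param quad_points nodes per latent dimension (\eqn{\ge 2}, or 1 for the
#'   single-node degenerate rule).
#' @return the approximate marginal log-likelihood (a single number).
#' @export
marginal_loglik_quad <- function(params, data, spec, quad_points = 40L) {
  p <- latent_dim(spec)
  if (p > 3L)
    stop("tensor quadrature supported only for d + row_effect <= 3, got ", p)
  if (quad_points < 1L) stop("quad_points must be >= 1")
  gh <- gauss_hermite_norm(quad_points)
  grids <- rep(list(seq_len(quad_points)), p)
  idx <- as.matrix(expand.grid(grids))
  Z <- matrix(gh$nodes[idx], nrow(idx), p)          # K^p x p standard nodes
  logw <- rowSums(matrix(log(gh$weights)[idx], nrow(idx), p))
  csd <- sqrt(cov_prior_diag(params, spec))         # C^{1/2} is diagonal
  Ustar <- Z * rep(csd, each = nrow(Z))             # nodes on the prior scale
  kern <- family_kernel(spec$family, spec$link)
  Gstar <- loadings_aug(params, spec$row_effect)    # m x p
  eta_fix <- matrix(params$beta0, data$n, params$m, byrow = TRUE)
  if (params$k > 0) eta_fix <- eta_fix + data$X %*% t(params$B)
  phi_row <- if (kern$has_phi) rep(params$phi, each = data$n) else NULL
  ll <- 0
  # per-site log integrand at every tensor node, combined by log-sum-exp
  site_log <- matrix(0, data$n, nrow(Ustar))
  for (q in seq_len(nrow(Ustar))) {
    eta <- eta_fix + matrix(Ustar[q, ], data$n, p, byrow = TRUE) %*% t(Gstar)
    lf <- kern$logpdf(data$Y, eta, phi_row)
    site_log[, q] <- rowSums(lf) + logw[q]
  }
  mx <- apply(site_log, 1, max)
  sum(mx + log(rowSums(exp(site_log - mx))))
}
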