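# Internal parameterization shared by the two engines.
#
# The optimizer works on an unconstrained vector theta:
#   [ beta0 (m) | vec(B) (m*k) | free Gamma entries | log phi (m) |
#     log sigma2 (1) ]
# Free Gamma entries are the lower triangle (l <= min(j, d)) in column-major
# order, with diagonal entries stored as log(gamma_jj).  For the variational
# engine, theta is extended by the variational parameters
#   [ vec(a) (n*p) | per-site Cholesky entries (n*q) ]
# where A_i = L_i L_i' and L_i is block diagonal (scalar row-effect block,
# unstructured d x d block), diagonal entries stored on the log scale.

make_dims <- function(data, spec) {
  m <- data$m; k <- data$k; d <- spec$d; n <- data$n
  r <- as.integer(spec$row_effect)
  p <- d + r
  kern <- family_kernel(spec$family, spec$link)
  # free loading entries, column-major
  gj <- gl <- integer(0)
  for (l in seq_len(d)) {
    rows <- seq.int(l, m)
    gj <- c(gj, rows); gl <- c(gl, rep.int(l, length(rows)))
  }
  gdiag <- gj == gl
  ng <- length(gj)
  nphi <- if (kern$has_phi) m else 0L
  nsig <- r
  off <- cumsum(c(0L, m, m * k, ng, nphi))
  n_psi <- off[5] + nsig
  # per-site Cholesky entry layout
  blocks <- if (r == 1L) list(1L, if (d > 0) 1L + seq_len(d)) else list(seq_len(p))
  er <- ec <- integer(0)
  for (b in blocks) for (cc in b) {
    rows <- b[b >= cc]
    er <- c(er, rows); ec <- c(ec, rep.int(cc, length(rows)))
  }
  ediag <- er == ec
  q <- length(er)
  list(n = n, m = m, k = k, d = d, r = r, p = p, q = q,
       has_phi = kern$has_phi, row_effect = spec$row_effect,
       gj = gj, gl = gl, gdiag = gdiag, ng = ng,
       er = er, ec = ec, ediag = ediag,
       i_beta0 = off[1] + seq_len(m),
       i_B = if (k > 0) off[2] + seq_len(m * k) else integer(0),
       i_gamma = off[3] + seq_len(ng),
       i_phi = if (nphi > 0) off[4] + seq_len(nphi) else integer(0),
       i_sigma2 = if (nsig > 0) off[5] + 1L else integer(0),
       n_psi = n_psi,
       n_xi = n * p + n * q,
       kern = kern)
}

pack_psi <- function(params, dims) {
  th <- numeric(dims$n_psi)
  th[dims$i_beta0] <- params$beta0
  if (dims$k > 0) th[dims$i_B] <- as.vector(params$B)
  g <- params$Gamma[cbind(dims$gj, dims$gl)]
  g[dims$gdiag] <- log(pmax(g[dims$gdiag], 1e-12))
  th[dims$i_gamma] <- g
  if (dims$has_phi) th[dims$i_phi] <- log(params$phi)
  if (dims$row_effect) th[dims$i_sigma2] <- log(params$sigma2)
  th
}

unpack_psi <- function(theta, dims) {
  beta0 <- theta[dims$i_beta0]
  B <- if (dims$k > 0) matrix(theta[dims$i_B], dims$m, dims$k) else NULL
  g <- theta[dims$i_gamma]
  g[dims$gdiag] <- exp(g[dims$gdiag])
  Gamma <- matrix(0, dims$m, dims$d)
  Gamma[cbind(dims$gj, dims$gl)] <- g
  phi <- if (dims$has_phi) exp(theta[dims$i_phi]) else NULL
  sigma2 <- if (dims$row_effect) exp(theta[dims$i_sigma2]) else NULL
  list(beta0 = beta0, B = B, Gamma = Gamma, phi = phi, sigma2 = sigma2,
       m = dims$m, d = dims$d, k = dims$k)
}

# promote the plain list from unpack_psi to a validated parameter_set
as_parameter_set <- function(pl) {
  parameter_set(beta0 = pl$beta0, Gamma = pl$Gamma, B = pl$B,
                phi = pl$phi, sigma2 = pl$sigma2)
}

# lower bounds implementing the parameter floors (phi >= 1e-6,
# sigma2 >= 1e-6, gamma_jj >= 1e-4; variational variances >= 1e-8)
psi_lower <- function(dims) {
  lo <- rep(-Inf, dims$n_psi)
  lo[dims$i_gamma[dims$gdiag]] <- log(1e-4)
  if (dims$has_phi) lo[dims$i_phi] <- log(1e-6)
  if (dims$row_effect) lo[dims$i_sigma2] <- log(1e-6)
  lo
}

xi_lower <- function(dims) {
  lo <- matrix(-Inf, dims$n, dims$q)
  lo[, dims$ediag] <- 0.5 * log(1e-8)
  c(rep(-Inf, dims$n * dims$p), as.vector(lo))
}

# gradient norm accounting for active lower bounds (maximization scale)
proj_grad_norm <- function(gr, theta, lower) {
  at <- theta <= lower + 1e-10
  max(ifelse(at, pmax(gr, 0), abs(gr)))
}

# after nlminb, push the gradient below tolerance with quasi-Newton and
# conjugate-gradient polish rounds; objfun/gradfun are on the minimization
# scale, grad_fn returns the maximization-scale gradient
polish_opt <- function(par, value, objfun, gradfun, lower, grad_fn,
                       grad_tol) {
  value0 <- value
  gr <- grad_fn(par)
  gn <- proj_grad_norm(gr, par, lower)
  for (round in 1:2) {
    if (gn < grad_tol) break
    po <- tryCatch(
      stats::optim(par, objfun, gradfun, method = "L-BFGS-B",
                   lower = lower, control = list(maxit = 200, factr = 10)),
      error = function(e) NULL)
    if (!is.null(po) && po$value <= value + 1e-10) {
      par <- po$par; value <- po$value
      gr <- grad_fn(par); gn <- proj_grad_norm(gr, par, lower)
      if (gn < grad_tol) break
    }
    if (all(par > lower + 1e-8)) {   # CG has no box support
      pc <- tryCatch(
        stats::optim(par, objfun, gradfun, method = "CG",
                     control = list(maxit = 100, reltol = 1e-16)),
        error = function(e) NULL)
      if (!is.null(pc) && pc$value <= value + 1e-10 &&
          all(pc$par >= lower)) {
        par <- pc$par; value <- pc$value
        gr <- grad_fn(par); gn <- proj_grad_norm(gr, par, lower)
      }
    }
  }
  list(par = par, value = value, grad = gr, gn = gn,
       improvement = value0 - value)
}

# ---- variational state ------------------------------------------------

#' Variational state for the VA engine
#'
#' Per-site variational means \eqn{a_i} and covariance Cholesky factors.
#' \code{Lpack} stores, per site, the free entries of the block-diagonal
#' Cholesky factor of \eqn{A_i} (diagonal on the log scale).
#'
#' @param a \eqn{n \times p} matrix of variational means
#'   (\eqn{p = d +} 1 if there is a row effect).
#' @param Lpack \eqn{n \times q} matrix of packed Cholesky entries.
#' @keywords internal
#' @export
variational_state <- function(a, Lpack) {
  structure(list(a = as.matrix(a), Lpack = as.matrix(Lpack)),
            class = "gllvm_varstate")
}

# default initialization: a from starting latents, A = a2 * I
init_varstate <- function(latents0, dims, a2 = 0.1) {
  a <- latent_aug(latents0, dims$row_effect)
  Lpack <- matrix(0, dims$n, dims$q)
  Lpack[, dims$ediag] <- 0.5 * log(a2)
  variational_state(a, Lpack)
}

pack_xi <- function(vs, dims) c(as.vector(vs$a), as.vector(vs$Lpack))

unpack_xi <- function(xi, dims) {
  a <- matrix(xi[seq_len(dims$n * dims$p)], dims$n, dims$p)
  Lpack <- matrix(xi[dims$n * dims$p + seq_len(dims$n * dims$q)],
                  dims$n, dims$q)
  variational_state(a, Lpack)
}

# materialize per-site covariance entries: Amat is n x p^2 (column-major
# vec of the full symmetric A_i); logdet is the n-vector log det A_i
varstate_A <- function(vs, dims) {
  p <- dims$p
  Lval <- vs$Lpack
  Lval[, dims$ediag] <- exp(Lval[, dims$ediag, drop = FALSE])
  Amat <- matrix(0, dims$n, p * p)
  for (cc in unique(dims$ec)) {
    ent <- which(dims$ec == cc)
    for (ia in ent) for (ib in ent) {
      a <- dims$er[ia]; b <- dims$er[ib]
      col <- (b - 1L) * p + a
      Amat[, col] <- Amat[, col] + Lval[, ia] * Lval[, ib]
    }
  }
  list(Amat = Amat, Lval = Lval,
       logdet = 2 * rowSums(vs$Lpack[, dims$ediag, drop = FALSE]))
}

# chain a full symmetric gradient matrix Mmat (n x p^2, counting every
# entry of A) back to the packed Cholesky entries; 'Lval' from varstate_A
chol_chain <- function(Mmat, Lval, vs, dims) {
  p <- dims$p
  dL <- matrix(0, dims$n, dims$q)
  for (e in seq_len(dims$q)) {
    a <- dims$er[e]; cc <- dims$ec[e]
    # dF/dL_{a,c} = 2 sum_b M[a,b] L[b,c] over packed (b,c)
    bs <- which(dims$ec == cc)
    acc <- 0
    for (ib in bs) {
      b <- dims$er[ib]
      acc <- acc + Mmat[, (b - 1L) * p + a] * Lval[, ib]
    }
    dL[, e] <- 2 * acc
  }
  dL[, dims$ediag] <- dL[, dims$ediag, drop = FALSE] *
    Lval[, dims$ediag, drop = FALSE]
  dL
}

# m x p^2 matrix whose j-th row is vec(gamma*_j gamma*_j')
loadings_outer <- function(Gstar) {
  p <- ncol(Gstar)
  out <- matrix(0, nrow(Gstar), p * p)
  for (a in seq_len(p)) for (b in seq_len(p))
    out[, (b - 1L) * p + a] <- Gstar[, a] * Gstar[, b]
  out
}
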