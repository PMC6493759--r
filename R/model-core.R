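#' Multivariate abundance data container
#'
#' Bundles a site-by-species response matrix with optional site covariates
#' and the response family/link, after validation.  Rows are sites
#' (\eqn{n}), columns are species (\eqn{m}); this orientation is used
#' throughout the package.
#'
#' @param Y numeric matrix, \eqn{n \times m}.  Non-negative integers for
#'   count families, 0/1 for bernoulli, any finite reals for gaussian.
#' @param X optional numeric covariate matrix, \eqn{n \times k}.
#' @param family,link response family and link, see
#'   \code{\link{family_kernel}}.
#' @return an object of class \code{"gllvm_data"}: list with elements
#'   \code{Y}, \code{X} (possibly \code{NULL}), \code{family}, \code{link},
#'   \code{n}, \code{m}, \code{k}.
#' @export
abundance_data <- function(Y, X = NULL, family, link = default_link(family)) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyNA(Y) || any(!is.finite(Y)))
    stop("Y contains missing or non-finite entries")
  k <- family_kernel(family, link)
  if (!k$valid_y(Y))
    stop("entries of Y are invalid for family '", family, "'",
         if (k$is_discrete) " (expected non-negative integers or 0/1)")
  if (!is.null(X)) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (nrow(X) != nrow(Y))
      stop("X has ", nrow(X), " rows but Y has ", nrow(Y),
           " (axis: sites/rows)")
    if (anyNA(X) || any(!is.finite(X)))
      stop("X contains missing or non-finite entries")
  }
  structure(list(Y = Y, X = X, family = k$family, link = k$link,
                 n = nrow(Y), m = ncol(Y),
                 k = if (is.null(X)) 0L else ncol(X)),
            class = "gllvm_data")
}

#' Model structure specification
#'
#' @param d number of latent variables (\eqn{1 \le d < m}).
#' @param family,link response family and link.
#' @param row_effect logical; include a random site intercept
#'   \eqn{\alpha_i \sim N(0, \sigma^2)} with implicit loading 1.
#' @return an object of class \code{"gllvm_spec"}.
#' @export
model_spec <- function(d, family, link = default_link(family),
                       row_effect = FALSE) {
  d <- as.integer(d)
  if (d < 1L) stop("'d' must be a positive integer")
  k <- family_kernel(family, link)
  structure(list(d = d, family = k$family, link = k$link,
                 row_effect = isTRUE(row_effect)),
            class = "gllvm_spec")
}

# total latent dimension per site: row effect (if any) is coordinate 1
latent_dim <- function(spec) spec$d + as.integer(spec$row_effect)

#' Model parameter set
#'
#' Collects all GLLVM parameters with their identifiability constraints:
#' the loading matrix \eqn{\Gamma} is lower triangular
#' (\eqn{\gamma_{jl} = 0} for \eqn{l > j}) with strictly positive diagonal,
#' dispersions and the row-effect variance are strictly positive.
#'
#' @param beta0 species intercepts, length \eqn{m}.
#' @param Gamma loading matrix, \eqn{m \times d}.
#' @param B species-by-covariate coefficient matrix, \eqn{m \times k}, or
#'   \code{NULL}.
#' @param phi species dispersions (length \eqn{m}) for families that use
#'   them, else \code{NULL}.
#' @param sigma2 row-effect variance, or \code{NULL} when there is no row
#'   effect.
#' @return an object of class \code{"gllvm_params"}.
#' @export
parameter_set <- function(beta0, Gamma, B = NULL, phi = NULL, sigma2 = NULL) {
  beta0 <- as.numeric(beta0)
  Gamma <- as.matrix(Gamma)
  m <- length(beta0); d <- ncol(Gamma)
  if (nrow(Gamma) != m)
    stop("Gamma has ", nrow(Gamma), " rows but beta0 has length ", m,
         " (axis: species)")
  if (d >= 1 && m > 1) {
    ut <- which(col(Gamma) > row(Gamma))
    if (length(ut) && any(abs(Gamma[ut]) > 1e-12))
      stop("Gamma must have a zero upper triangle (gamma_jl = 0 for l > j)")
    Gamma[ut] <- 0
  }
  dg <- Gamma[cbind(seq_len(min(m, d)), seq_len(min(m, d)))]
  if (any(dg <= 0))
    stop("diagonal entries of Gamma must be strictly positive")
  if (!is.null(B)) {
    B <- as.matrix(B)
    if (nrow(B) != m) stop("B has ", nrow(B), " rows; expected ", m,
                           " (axis: species)")
  }
  if (!is.null(phi)) {
    phi <- as.numeric(phi)
    if (length(phi) != m) stop("phi must have length m = ", m)
    if (any(phi <= 0)) stop("phi must be strictly positive")
  }
  if (!is.null(sigma2)) {
    sigma2 <- as.numeric(sigma2)
    if (length(sigma2) != 1 || sigma2 <= 0)
      stop("sigma2 must be a single positive number")
  }
  structure(list(beta0 = beta0, B = B, Gamma = Gamma, phi = phi,
                 sigma2 = sigma2, m = m, d = d,
                 k = if (is.null(B)) 0L else ncol(B)),
            class = "gllvm_params")
}

#' Latent state (latent variables plus optional row effects)
#'
#' @param U \eqn{n \times d} matrix of latent-variable values.
#' @param alpha optional length-\eqn{n} vector of row effects.
#' @return object of class \code{"gllvm_latent"}.
#' @export
latent_state <- function(U, alpha = NULL) {
  U <- as.matrix(U)
  if (any(!is.finite(U))) stop("latent values must be finite")
  if (!is.null(alpha)) {
    alpha <- as.numeric(alpha)
    if (length(alpha) != nrow(U))
      stop("alpha has length ", length(alpha), " but U has ", nrow(U),
           " rows (axis: sites)")
    if (any(!is.finite(alpha))) stop("row effects must be finite")
  }
  structure(list(U = U, alpha = alpha), class = "gllvm_latent")
}

# augmented latent matrix u*_i = (alpha_i, u_i')' as n x (d + r)
latent_aug <- function(latent, row_effect) {
  if (row_effect) {
    a <- latent$alpha
    if (is.null(a)) a <- numeric(nrow(latent$U))
    cbind(a, latent$U, deparse.level = 0)
  } else latent$U
}

# augmented loadings gamma*_j = (1, gamma_j')' as m x (d + r)
loadings_aug <- function(params, row_effect) {
  if (row_effect) cbind(1, params$Gamma, deparse.level = 0) else params$Gamma
}

# diagonal of C = bdiag(sigma2, I_d)
cov_prior_diag <- function(params, spec) {
  if (spec$row_effect) c(params$sigma2, rep(1, spec$d)) else rep(1, spec$d)
}

#' Linear predictor of a GLLVM
#'
#' Computes \eqn{\eta_{ij} = \alpha_i + \beta_{0j} + x_i'\beta_j +
#' u_i'\gamma_j} entrywise.  The \eqn{\alpha} term is dropped when the
#' latent state carries no row effects, the covariate term when \eqn{k=0}.
#'
#' @param params a \code{\link{parameter_set}}.
#' @param data a \code{\link{abundance_data}} (only \code{X} and dimensions
#'   are used).
#' @param latent a \code{\link{latent_state}}.
#' @return \eqn{n \times m} matrix of linear predictors.
#' @export
linear_predictor <- function(params, data, latent) {
  n <- nrow(latent$U)
  if (!is.null(data$X) && nrow(data$X) != n)
    stop("X has ", nrow(data$X), " rows but latent state has ", n,
         " (axis: sites)")
  if (ncol(latent$U) != params$d)
    stop("latent U has ", ncol(latent$U), " columns but Gamma has ",
         params$d, " (axis: latent variables)")
  eta <- matrix(params$beta0, n, params$m, byrow = TRUE)
  if (params$k > 0) {
    if (is.null(data$X)) stop("parameters include B but data has no X")
    eta <- eta + data$X %*% t(params$B)
  }
  eta <- eta + latent$U %*% t(params$Gamma)
  if (!is.null(latent$alpha)) eta <- eta + latent$alpha
  eta
}

#' Rotate loadings to the identifiable representation
#'
#' Post-multiplies a raw loading matrix by the orthogonal rotation that
#' zeroes its upper triangle and makes the diagonal positive, and applies
#' the same rotation to the latent scores so that \eqn{U\Gamma'} is
#' unchanged.
#'
#' @param Gamma_raw \eqn{m \times d} matrix of full column rank.
#' @param U_raw optional \eqn{n \times d} matrix of scores.
#' @return list with components \code{Gamma}, \code{U} (or \code{NULL}) and
#'   the rotation \code{R} used (\code{Gamma = Gamma_raw \%*\% R}).
#' @export
constrain_loadings <- function(Gamma_raw, U_raw = NULL) {
  Gamma_raw <- as.matrix(Gamma_raw)
  m <- nrow(Gamma_raw); d <- ncol(Gamma_raw)
  if (m < d) stop("need at least d rows in Gamma")
  if (qr(Gamma_raw)$rank < d) stop("Gamma_raw is rank deficient")
  A <- Gamma_raw[seq_len(d), , drop = FALSE]
  # LQ factorization of A via QR of t(A): A = t(R) t(Q), rotation = Q
  qrA <- qr(t(A))
  R <- qr.Q(qrA)
  Gamma <- Gamma_raw %*% R
  # flip column signs so the diagonal is positive
  dg <- Gamma[cbind(seq_len(d), seq_len(d))]
  s <- ifelse(dg < 0, -1, 1)
  if (d == 1) Gamma <- Gamma * s else Gamma <- Gamma %*% diag(s)
  R <- if (d == 1) R * s else R %*% diag(s)
  # clean numerical fuzz in the structural zeros
  Gamma[col(Gamma) > row(Gamma)] <- 0
  U <- if (is.null(U_raw)) NULL else as.matrix(U_raw) %*% R
  list(Gamma = Gamma, U = U, R = R)
}

#' Generate a constraint-valid random parameter set
#'
#' Synthetic stand-in for "true" parameters in simulation studies.  Entries
#' are drawn from simple uniform/normal distributions whose spread is
#' controlled by \code{magnitude}; the loading matrix is passed through
#' \code{\link{constrain_loadings}} and its diagonal floored away from zero.
#'
#' @param m,k,d numbers of species, covariates and latent variables.
#' @param spec a \code{\link{model_spec}} (determines whether \code{phi} and
#'   \code{sigma2} are present).
#' @param magnitude named list overriding the default scales:
#'   \code{beta0} (half-width of the uniform for intercepts, default 1),
#'   \code{beta} (sd of covariate slopes, default 0.5),
#'   \code{gamma} (sd of loadings, default 0.5),
#'   \code{phi} (dispersion level, default 0.7),
#'   \code{sigma2} (row-effect variance, default 0.25, the value used in the
#'   simulation designs).
#' @param seed integer seed.
#' @return a \code{\link{parameter_set}}.
#' @export
generate_parameters <- function(m, k, d, spec, magnitude = list(), seed = 1L) {
  mg <- utils::modifyList(list(beta0 = 1, beta = 0.5, gamma = 0.5,
                               phi = 0.7, sigma2 = 0.25), magnitude)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  beta0 <- stats::runif(m, -mg$beta0, mg$beta0)
  B <- if (k > 0) matrix(stats::rnorm(m * k, sd = mg$beta), m, k) else NULL
  Graw <- matrix(stats::rnorm(m * d, sd = max(mg$gamma, 1e-8)), m, d)
  Gamma <- constrain_loadings(Graw)$Gamma
  dg <- seq_len(min(m, d))
  Gamma[cbind(dg, dg)] <- pmax(Gamma[cbind(dg, dg)], 1e-4)
  phi <- if (spec$family %in% c("negative_binomial", "gaussian"))
    rep(mg$phi, m) else NULL
  sigma2 <- if (spec$row_effect) mg$sigma2 else NULL
  parameter_set(beta0 = beta0, Gamma = Gamma, B = B, phi = phi,
                sigma2 = sigma2)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

#' Simulate responses from a GLLVM
#'
#' Draws \eqn{u_i \sim N_d(0, I)}, optionally \eqn{\alpha_i \sim N(0,
#' \sigma^2)}, forms the linear predictor and samples each response
#' independently from the conditional family.
#'
#' @param params a \code{\link{parameter_set}}.
#' @param spec a \code{\link{model_spec}}.
#' @param n number of sites.
#' @param X optional \eqn{n \times k} covariate matrix (required when
#'   \code{params$k > 0}).
#' @param seed integer seed; a fixed seed reproduces the data exactly.
#' @return list with \code{data} (an \code{\link{abundance_data}}),
#'   \code{latent} (the generating \code{\link{latent_state}}) and \code{mu}
#'   (the true mean matrix).
#' @export
simulate_responses <- function(params, spec, n, X = NULL, seed = 1L) {
  if (params$k > 0 && is.null(X))
    stop("parameters include covariate coefficients; supply X")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  U <- matrix(stats::rnorm(n * spec$d), n, spec$d)
  alpha <- if (spec$row_effect)
    stats::rnorm(n, sd = sqrt(params$sigma2)) else NULL
  latent <- latent_state(U, alpha)
  dat0 <- list(X = X)
  eta <- linear_predictor(params, dat0, latent)
  kern <- family_kernel(spec$family, spec$link)
  phi_mat <- if (kern$has_phi)
    matrix(params$phi, n, params$m, byrow = TRUE) else NULL
  Y <- matrix(kern$rdraw(n * params$m, eta, phi_mat), n, params$m)
  list(data = abundance_data(Y, X, spec$family, spec$link),
       latent = latent,
       mu = kern$mean(eta, phi_mat))
}
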