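#' Response families for GLLVMs
#'
#' A GLLVM couples one generalized linear model per species through shared
#' site-level latent variables.  Each supported response family is
#' represented internally by a "kernel": the conditional log-density
#' \eqn{\log f(y \mid \eta)} on the linear-predictor scale together with its
#' first three derivatives in \eqn{\eta} (the Laplace engine needs third
#' derivatives for the exact gradient of the log-determinant curvature term)
#' and, for families with a dispersion parameter, derivatives with respect
#' to \eqn{\log\phi}.
#'
#' Supported combinations:
#' \itemize{
#'   \item \code{poisson} with log link;
#'   \item \code{negative_binomial} with log link, parameterized by the mean
#'     \eqn{\mu} and dispersion \eqn{\phi} with \eqn{Var(y) = \mu + \phi\mu^2}
#'     (\code{size} \eqn{= 1/\phi} in \code{\link[stats]{dnbinom}} terms);
#'   \item \code{bernoulli} with probit or logit link;
#'   \item \code{gaussian} with identity link.  This family exists as an
#'     internal test fixture: both approximations are exact for normal
#'     responses, which gives closed-form oracles.  \eqn{\phi} is the
#'     residual variance.
#' }
#'
#' @param family one of \code{"poisson"}, \code{"negative_binomial"},
#'   \code{"bernoulli"}, \code{"gaussian"}.
#' @param link link function; \code{"log"} for count families,
#'   \code{"probit"} or \code{"logit"} for bernoulli, \code{"identity"} for
#'   gaussian.  Defaults to the family's canonical choice.
#' @return an object of class \code{"gllvm_kernel"}: a list of vectorized
#'   functions \code{logpdf(y, eta, phi)}, \code{d1}, \code{d2}, \code{d3},
#'   \code{dlogphi}, \code{d1_dlogphi}, \code{d2_dlogphi}, \code{mean(eta)},
#'   \code{cdf(q, eta, phi)}, \code{rdraw(n, eta, phi)}, plus metadata
#'   (\code{family}, \code{link}, \code{has_phi}, \code{is_discrete}).
#' @keywords internal
#' @export
family_kernel <- function(family, link = default_link(family)) {
  family <- match.arg(family,
                      c("poisson", "negative_binomial", "bernoulli", "gaussian"))
  link <- match.arg(link, c("log", "probit", "logit", "identity"))
  ok <- switch(family,
    poisson = "log", negative_binomial = "log",
    bernoulli = c("probit", "logit"), gaussian = "identity")
  if (!link %in% ok)
    stop("link '", link, "' is not supported for family '", family, "'")
  k <- switch(family,
    poisson = kernel_poisson(),
    negative_binomial = kernel_negbin(),
    bernoulli = if (link == "probit") kernel_probit() else kernel_logit(),
    gaussian = kernel_gaussian())
  k$family <- family
  k$link <- link
  class(k) <- "gllvm_kernel"
  k
}

default_link <- function(family) {
  switch(family,
         poisson = "log",
         negative_binomial = "log",
         bernoulli = "probit",
         gaussian = "identity",
         stop("unknown family '", family, "'"))
}

kernel_poisson <- function() {
  list(
    has_phi = FALSE, is_discrete = TRUE,
    logpdf = function(y, eta, phi = NULL) y * eta - exp(eta) - lgamma(y + 1),
    d1 = function(y, eta, phi = NULL) y - exp(eta),
    d2 = function(y, eta, phi = NULL) -exp(eta),
    d3 = function(y, eta, phi = NULL) -exp(eta),
    mean = function(eta, phi = NULL) exp(eta),
    cdf = function(q, eta, phi = NULL) stats::ppois(q, lambda = exp(eta)),
    rdraw = function(n, eta, phi = NULL) stats::rpois(n, lambda = exp(eta)),
    valid_y = function(y) all(is.finite(y)) && all(y >= 0) && all(y == round(y))
  )
}

# mean/dispersion parameterization, size r = 1/phi, Var = mu + phi mu^2
kernel_negbin <- function() {
  list(
    has_phi = TRUE, is_discrete = TRUE,
    logpdf = function(y, eta, phi) {
      r <- 1 / phi; mu <- exp(eta)
      lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        r * log(r) - (r + y) * log(r + mu) + y * eta
    },
    d1 = function(y, eta, phi) {
      r <- 1 / phi; mu <- exp(eta)
      r * (y - mu) / (r + mu)
    },
    d2 = function(y, eta, phi) {
      r <- 1 / phi; mu <- exp(eta)
      -r * mu * (r + y) / (r + mu)^2
    },
    d3 = function(y, eta, phi) {
      r <- 1 / phi; mu <- exp(eta)
      -r * mu * (r + y) * (r - mu) / (r + mu)^3
    },
    dlogphi = function(y, eta, phi) {
      r <- 1 / phi; mu <- exp(eta)
      dr <- digamma(y + r) - digamma(r) + log(r) + 1 -
        log(r + mu) - (r + y) / (r + mu)
      -r * dr                       # d r / d log(phi) = -r
    },
    d1_dlogphi = function(y, eta, phi) {
      r <- 1 / phi; mu <- exp(eta)
      -r * (y - mu) * mu / (r + mu)^2
    },
    d2_dlogphi = function(y, eta, phi) {
      # derivative of d2 (not of w = -d2) with respect to log(phi)
      r <- 1 / phi; mu <- exp(eta)
      r * mu * (mu * (2 * r + y) - r * y) / (r + mu)^3
    },
    mean = function(eta, phi) exp(eta),
    cdf = function(q, eta, phi) stats::pnbinom(q, size = 1 / phi, mu = exp(eta)),
    rdraw = function(n, eta, phi) stats::rnbinom(n, size = 1 / phi, mu = exp(eta)),
    valid_y = function(y) all(is.finite(y)) && all(y >= 0) && all(y == round(y))
  )
}

kernel_probit <- function() {
  # write log f(y|eta) = log Phi(s eta) with s = 2y - 1; lambda is the
  # inverse Mills ratio evaluated stably through log densities
  mills <- function(z) exp(stats::dnorm(z, log = TRUE) -
                             stats::pnorm(z, log.p = TRUE))
  list(
    has_phi = FALSE, is_discrete = TRUE,
    logpdf = function(y, eta, phi = NULL) {
      s <- 2 * y - 1
      stats::pnorm(s * eta, log.p = TRUE)
    },
    d1 = function(y, eta, phi = NULL) {
      s <- 2 * y - 1
      s * mills(s * eta)
    },
    d2 = function(y, eta, phi = NULL) {
      s <- 2 * y - 1; z <- s * eta; l <- mills(z)
      -l * (l + z)
    },
    d3 = function(y, eta, phi = NULL) {
      s <- 2 * y - 1; z <- s * eta; l <- mills(z)
      lp <- -l * (l + z)            # lambda'(z)
      s * (-lp * (l + z) - l * (lp + 1))
    },
    mean = function(eta, phi = NULL) stats::pnorm(eta),
    cdf = function(q, eta, phi = NULL) {
      p <- stats::pnorm(eta)
      stats::pbinom(q, size = 1, prob = p)
    },
    rdraw = function(n, eta, phi = NULL) stats::rbinom(n, 1, stats::pnorm(eta)),
    valid_y = function(y) all(y %in% c(0, 1))
  )
}

kernel_logit <- function() {
  list(
    has_phi = FALSE, is_discrete = TRUE,
    logpdf = function(y, eta, phi = NULL)
      y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0),
    d1 = function(y, eta, phi = NULL) y - stats::plogis(eta),
    d2 = function(y, eta, phi = NULL) {
      p <- stats::plogis(eta); -p * (1 - p)
    },
    d3 = function(y, eta, phi = NULL) {
      p <- stats::plogis(eta); -p * (1 - p) * (1 - 2 * p)
    },
    mean = function(eta, phi = NULL) stats::plogis(eta),
    cdf = function(q, eta, phi = NULL)
      stats::pbinom(q, size = 1, prob = stats::plogis(eta)),
    rdraw = function(n, eta, phi = NULL) stats::rbinom(n, 1, stats::plogis(eta)),
    valid_y = function(y) all(y %in% c(0, 1))
  )
}

# phi is the residual variance
kernel_gaussian <- function() {
  list(
    has_phi = TRUE, is_discrete = FALSE,
    logpdf = function(y, eta, phi)
      -0.5 * log(2 * pi * phi) - (y - eta)^2 / (2 * phi),
    d1 = function(y, eta, phi) (y - eta) / phi,
    d2 = function(y, eta, phi) -1 / phi + 0 * (y + eta),
    d3 = function(y, eta, phi) 0 * (y + eta),
    dlogphi = function(y, eta, phi) -0.5 + (y - eta)^2 / (2 * phi),
    d1_dlogphi = function(y, eta, phi) -(y - eta) / phi,
    d2_dlogphi = function(y, eta, phi) (1 / phi) + 0 * (y + eta),
    mean = function(eta, phi) eta,
    cdf = function(q, eta, phi) stats::pnorm(q, mean = eta, sd = sqrt(phi)),
    rdraw = function(n, eta, phi) stats::rnorm(n, mean = eta, sd = sqrt(phi)),
    valid_y = function(y) all(is.finite(y))
  )
}

#' Conditional log-density of one response
#'
#' Evaluates \eqn{\log f(y \mid \eta)} for the given family and link, with
#' mean \eqn{\mu = g^{-1}(\eta)}.  Vectorized over \code{y}, \code{eta} and
#' \code{phi}.
#'
#' @inheritParams family_kernel
#' @param y response value(s), valid for the family.
#' @param eta linear predictor value(s), finite.
#' @param phi dispersion parameter(s), strictly positive; required for
#'   \code{negative_binomial} (variance \eqn{\mu + \phi\mu^2}) and
#'   \code{gaussian} (residual variance), ignored otherwise.
#' @return numeric vector of log-density values.
#' @examples
#' conditional_logpdf("poisson", y = 0, eta = 0)            # -1
#' conditional_logpdf("bernoulli", y = 1, eta = 0)          # log(0.5)
#' @export
conditional_logpdf <- function(family, y, eta, phi = NULL,
                               link = default_link(family)) {
  k <- family_kernel(family, link)
  if (any(!is.finite(eta))) stop("non-finite linear predictor 'eta'")
  if (!k$valid_y(y))
    stop("invalid response value for family '", family, "'")
  if (k$has_phi) {
    if (is.null(phi)) stop("family '", family, "' requires a dispersion 'phi'")
    if (any(phi <= 0)) stop("'phi' must be strictly positive")
  }
  k$logpdf(y, eta, phi)
}
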