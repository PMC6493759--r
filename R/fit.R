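#' Fit a generalized linear latent variable model
#'
#' High-level wrapper: builds starting values with the requested strategy
#' and dispatches to the variational (\code{\link{fit_va}}) or Laplace
#' (\code{\link{fit_la}}) engine; multi-start strategies keep the fit with
#' the highest final objective.
#'
#' @param data an \code{\link{abundance_data}}.
#' @param spec a \code{\link{model_spec}}.
#' @param method estimation engine, \code{"va"} (default) or \code{"la"}.
#' @param start starting-value strategy, see \code{\link{make_start}}.
#' @param n_starts,jitter_sd multi-start settings for \code{"res3"}.
#' @param seed integer seed for the stochastic parts of the start.
#' @param control a \code{\link{gllvm_control}} list.
#' @return a \code{gllvm_fit} object.
#' @examples
#' spec <- model_spec(d = 1, family = "poisson")
#' truth <- generate_parameters(m = 5, k = 0, d = 1, spec, seed = 7)
#' sim <- simulate_responses(truth, spec, n = 40, seed = 7)
#' fit <- fit_gllvm(sim$data, spec, method = "va")
#' fit$objective
#' @export
fit_gllvm <- function(data, spec, method = c("va", "la"), start = "res",
                      n_starts = 3L, jitter_sd = 0.2, seed = 1L,
                      control = gllvm_control()) {
  method <- match.arg(method)
  starts <- make_start(data, spec, start, n_sets = n_starts,
                       jitter_sd = jitter_sd, seed = seed)
  if (method == "va") fit_va(data, spec, starts, control)
  else fit_la(data, spec, starts, control)
}

#' Latent-variable predictions from a fitted GLLVM
#'
#' @param fit a \code{gllvm_fit}.
#' @return list with \code{latent}, \code{cov}, \code{sd}; see
#'   \code{\link{predict_latents_va}} and \code{\link{predict_latents_la}}.
#' @export
predict_latents <- function(fit) {
  if (inherits(fit, "gllvm_va_fit")) predict_latents_va(fit)
  else if (inherits(fit, "gllvm_la_fit")) predict_latents_la(fit)
  else stop("not a gllvm fit")
}

#' @export
logLik.gllvm_fit <- function(object, ...) {
  structure(object$objective,
            df = object$dims$n_psi,
            nobs = object$dims$n * object$dims$m,
            class = "logLik")
}

#' @export
coef.gllvm_fit <- function(object, ...) object$params

#' @export
print.gllvm_fit <- function(x, ...) {
  cat(sprintf("GLLVM fit (%s approximation)\n",
              if (x$method == "va") "variational" else "Laplace"))
  cat(sprintf("  family: %s (%s link), d = %d latent variable(s)%s\n",
              x$spec$family, x$spec$link, x$spec$d,
              if (x$spec$row_effect) ", random row effect" else ""))
  cat(sprintf("  n = %d sites, m = %d species, %d model parameters\n",
              x$dims$n, x$dims$m, x$dims$n_psi))
  cat(sprintf("  objective: %.4f  (start '%s', %d iterations, %s)\n",
              x$objective, x$start_label, x$n_iter,
              if (x$converged) "converged" else
                sprintf("NOT converged, |grad| = %.2g", x$grad_norm)))
  invisible(x)
}

#' @export
print.gllvm_data <- function(x, ...) {
  cat(sprintf("abundance data: %d sites x %d species, %d covariate(s), %s (%s)\n",
              x$n, x$m, x$k, x$family, x$link))
  invisible(x)
}

#' @export
print.gllvm_inference <- function(x, ...) {
  cat(sprintf("Wald inference (%s fit), level %.2f%s\n", x$method, x$level,
              if (x$pinv_used) " [pseudo-inverse fallback used]" else ""))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...", nrow(x$table) - 10, "more rows\n")
  invisible(x)
}
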