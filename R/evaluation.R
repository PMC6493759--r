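#' Procrustes error after optimal superposition
#'
#' Solves the full Procrustes problem — minimize \eqn{\|c\,E R + t -
#' T\|_F^2} over rotations \eqn{R}, uniform scale \eqn{c > 0} and
#' translation \eqn{t} — in closed form, and returns the per-entry RMS
#' residual \eqn{\sqrt{SS_{res}/(nd)}}.  Invariant to orthogonal
#' transformation, translation and positive scaling of the estimate.
#'
#' @param estimate,truth matrices of matching shape (rows =
#'   sites/species, columns = latent dimensions).
#' @param translate,scaling allow translation / uniform scaling in the
#'   superposition (both default \code{TRUE}).
#' @return the scaled Procrustes error (single number).
#' @export
procrustes_error <- function(estimate, truth, translate = TRUE,
                             scaling = TRUE) {
  E <- as.matrix(estimate); Tr <- as.matrix(truth)
  if (!all(dim(E) == dim(Tr)))
    stop("estimate and truth must have matching dimensions")
  if (translate) {
    E <- sweep(E, 2, colMeans(E))
    Tr <- sweep(Tr, 2, colMeans(Tr))
  }
  nE <- sum(E^2)
  if (nE <= 0) stop("estimate has no variation (rank 0)")
  sv <- svd(crossprod(E, Tr))        # E'T = U D V', R = U V'
  trD <- sum(sv$d)
  ss <- if (scaling) sum(Tr^2) - trD^2 / nE
        else sum(Tr^2) + nE - 2 * trD
  sqrt(max(ss, 0) / length(Tr))
}

#' Variation explained relative to an intercept-only null
#'
#' \deqn{VE = 1 - \frac{\sum_{ij} |\hat\mu_{ij} - \mu_{ij}|}
#'   {\sum_{ij} |\hat\mu_{ij,null} - \mu_{ij}|}}
#' computed on the mean scale against the true generating means.
#'
#' @param mu_hat fitted mean matrix of the model under evaluation.
#' @param mu_null fitted mean matrix of the species-intercept-only null.
#' @param mu_true true mean matrix.
#' @return the VE value; \code{NA} (with a warning) when the null error is
#'   zero.
#' @export
variation_explained <- function(mu_hat, mu_null, mu_true) {
  den <- sum(abs(mu_null - mu_true))
  if (den == 0) {
    warning("null-model error is zero; VE undefined")
    return(NA_real_)
  }
  1 - sum(abs(mu_hat - mu_true)) / den
}

# fitted mean matrix of a GLLVM fit, using the latent predictions
fitted_means <- function(fit) {
  lat <- if (fit$method == "va") predict_latents_va(fit)$latent
         else fit$latents_hat
  eta <- linear_predictor(fit$params, fit$data, lat)
  kern <- family_kernel(fit$spec$family, fit$spec$link)
  phi_row <- if (kern$has_phi)
    rep(fit$params$phi, each = fit$data$n) else NULL
  matrix(kern$mean(eta, phi_row), fit$data$n, fit$data$m)
}

# intercept-only per-species fitted means g^{-1}(hat beta_0j)
null_model_means <- function(data) {
  d0 <- abundance_data(data$Y, NULL, data$family, data$link)
  glms <- fit_marginal_glms(d0)
  kern <- family_kernel(data$family, data$link)
  eta <- matrix(glms$beta0, data$n, data$m, byrow = TRUE)
  phi_row <- if (kern$has_phi) rep(glms$phi, each = data$n) else NULL
  matrix(kern$mean(eta, phi_row), data$n, data$m)
}

#' Summarize a simulation cell
#'
#' Aggregates replicate fits against the truth: per parameter block the
#' average bias, RMSE, empirical coverage of the Wald intervals and mean
#' interval width, all on the estimation scale (dispersions as
#' \eqn{\log\phi}).
#'
#' @param fits list of replicate results; each element is a list with
#'   \code{params} (estimated \code{\link{parameter_set}}) and optionally
#'   \code{se} (estimation-scale standard errors aligned with the packed
#'   parameter vector, as produced by the fitting/inference pipeline).
#'   \code{NULL} elements (failed fits) are excluded and counted.
#' @param truth the generating \code{\link{parameter_set}}.
#' @param spec the \code{\link{model_spec}} used.
#' @param level confidence level.
#' @return list with \code{table} (one row per parameter block) and
#'   \code{n_failed}.
#' @export
summarize_cell <- function(fits, truth, spec, level = 0.95) {
  ok <- !vapply(fits, is.null, logical(1))
  n_failed <- sum(!ok)
  fits <- fits[ok]
  if (!length(fits)) {
    warning("all fits failed")
    return(list(table = NULL, n_failed = n_failed))
  }
  dims <- make_dims(list(n = 1L, m = truth$m, k = truth$k,
                         family = spec$family, link = spec$link), spec)
  truth_th <- pack_psi(truth, dims)
  lab <- psi_labels(dims)$parameter
  z <- stats::qnorm(1 - (1 - level) / 2)
  dev <- cov_hit <- width <- NULL
  for (f in fits) {
    est <- pack_psi(f$params, dims)
    dev <- rbind(dev, est - truth_th)
    if (!is.null(f$se)) {
      cov_hit <- rbind(cov_hit, abs(est - truth_th) <= z * f$se)
      width <- rbind(width, 2 * z * f$se)
    }
  }
  blocks <- unique(lab)
  tab <- do.call(rbind, lapply(blocks, function(b) {
    idx <- lab == b
    data.frame(block = b,
               bias = mean(dev[, idx]),
               rmse = sqrt(mean(dev[, idx]^2)),
               coverage = if (is.null(cov_hit)) NA_real_
                          else mean(cov_hit[, idx]),
               ci_width = if (is.null(width)) NA_real_
                          else mean(width[, idx]))
  }))
  list(table = tab, n_failed = n_failed, n_used = length(fits))
}

#' Run a simulation design
#'
#' For each grid cell and replicate: simulate data from the truth, build
#' starting values, fit the requested engines, compute Wald inference and
#' the latent-variable/loading Procrustes errors and variation explained,
#' then aggregate per cell with \code{\link{summarize_cell}}.  Replicate
#' results are persisted as one CSV per (cell, replicate, engine) when
#' \code{out_dir} is given, and existing files are reused, so an
#' interrupted run resumes deterministically.
#'
#' @param design list with components \code{truth}
#'   (\code{\link{parameter_set}}), \code{spec} (\code{\link{model_spec}}),
#'   \code{grid} (named list with one of \code{n} or \code{m}: vector of
#'   cell values), \code{n} (sites, when varying m), \code{X}
#'   (covariate matrix for the largest n, or \code{NULL}),
#'   \code{n_reps}, \code{engines} (subset of \code{c("va", "la")}),
#'   \code{start_method}, \code{seed_base}, and optionally \code{control},
#'   \code{level}, \code{inference} (logical, default \code{TRUE}).
#' @param out_dir optional directory for per-replicate CSVs.
#' @return nested list: one element per cell, each containing per-engine
#'   \code{summary} (from \code{\link{summarize_cell}}) and a data.frame
#'   \code{metrics} (objective, procrustes errors, VE per replicate).
#' @export
run_design <- function(design, out_dir = NULL) {
  d <- utils::modifyList(
    list(engines = c("va", "la"), start_method = "res", n_reps = 2L,
         seed_base = 1L, level = 0.95, control = gllvm_control(),
         inference = TRUE, X = NULL, n = NULL), design)
  vary <- names(d$grid)[1]
  if (!vary %in% c("n", "m")) stop("grid must vary 'n' or 'm'")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- list()
  for (v in d$grid[[vary]]) {
    if (vary == "n") {
      truth_v <- d$truth; n_v <- v
      X_v <- if (!is.null(d$X)) d$X[seq_len(v), , drop = FALSE] else NULL
    } else {
      keep <- seq_len(v)
      truth_v <- parameter_set(
        beta0 = d$truth$beta0[keep],
        Gamma = d$truth$Gamma[keep, , drop = FALSE],
        B = if (!is.null(d$truth$B)) d$truth$B[keep, , drop = FALSE],
        phi = if (!is.null(d$truth$phi)) d$truth$phi[keep],
        sigma2 = d$truth$sigma2)
      n_v <- d$n
      X_v <- d$X
    }
    cell <- list()
    per_engine_fits <- stats::setNames(
      vector("list", length(d$engines)), d$engines)
    metrics <- NULL
    for (r in seq_len(d$n_reps)) {
      seed_r <- d$seed_base + r
      sim <- simulate_responses(truth_v, d$spec, n_v, X_v, seed = seed_r)
      starts <- make_start(sim$data, d$spec, d$start_method, seed = seed_r)
      for (eng in d$engines) {
        tag <- sprintf("%s%s_rep%03d_%s.csv", vary, v, r, eng)
        path <- if (is.null(out_dir)) NULL else file.path(out_dir, tag)
        rec <- NULL
        if (!is.null(path) && file.exists(path))
          rec <- utils::read.csv(path)
        if (is.null(rec)) {
          rec <- tryCatch(
            run_one(sim, truth_v, d$spec, eng, starts, d$control, d$level,
                    d$inference),
            error = function(e) NULL)
          if (!is.null(rec) && !is.null(path))
            utils::write.csv(rec, path, row.names = FALSE)
        }
        if (is.null(rec)) {
          per_engine_fits[[eng]] <- c(per_engine_fits[[eng]], list(NULL))
          next
        }
        dims_v <- make_dims(sim$data, d$spec)
        est <- rec$estimate
        params_hat <- as_parameter_set(unpack_psi(est, dims_v))
        se <- if (all(is.na(rec$se))) NULL else rec$se
        per_engine_fits[[eng]] <- c(per_engine_fits[[eng]],
                                    list(list(params = params_hat, se = se)))
        metrics <- rbind(metrics, data.frame(
          cell = v, rep = r, engine = eng,
          objective = rec$objective[1],
          proc_lv = rec$proc_lv[1], proc_loadings = rec$proc_loadings[1],
          ve = rec$ve[1], converged = rec$converged[1]))
      }
    }
    cell$metrics <- metrics
    cell$summary <- lapply(per_engine_fits, summarize_cell,
                           truth = truth_v, spec = d$spec, level = d$level)
    out[[paste0(vary, v)]] <- cell
  }
  out
}

# fit one engine on one simulated replicate and flatten to a data.frame
run_one <- function(sim, truth, spec, engine, starts, control, level,
                    inference) {
  fit <- if (engine == "va") fit_va(sim$data, spec, starts, control)
         else fit_la(sim$data, spec, starts, control)
  dims <- fit$dims
  se <- rep(NA_real_, dims$n_psi)
  if (inference) {
    inf <- standard_errors(fit, level = level)
    se <- sqrt(pmax(diag(inf$cov), 0))
  }
  lat_hat <- if (engine == "va") predict_latents_va(fit)$latent
             else fit$latents_hat
  mu_hat <- fitted_means(fit)
  mu_null <- null_model_means(sim$data)
  data.frame(
    estimate = fit$theta[seq_len(dims$n_psi)], se = se,
    objective = fit$objective, converged = fit$converged,
    proc_lv = procrustes_error(lat_hat$U, sim$latent$U),
    proc_loadings = procrustes_error(fit$params$Gamma, truth$Gamma),
    ve = variation_explained(mu_hat, mu_null, sim$mu))
}

#' Compare starting-value strategies
#'
#' Fits the model once per strategy (for \code{res3}, the best of its
#' jittered sets) and reports each final objective and its difference from
#' the \code{res3} reference; negative differences mean the strategy
#' reached a worse optimum than \code{res3}.
#'
#' @param data an \code{\link{abundance_data}}.
#' @param spec a \code{\link{model_spec}}.
#' @param engine \code{"va"} or \code{"la"}.
#' @param methods strategies to compare.
#' @param seed integer seed shared by all strategies.
#' @param control a \code{\link{gllvm_control}} list.
#' @return data.frame with columns \code{method}, \code{objective},
#'   \code{diff_vs_res3}; failed fits appear with \code{NA}.
#' @export
compare_starts <- function(data, spec, engine = c("va", "la"),
                           methods = c("res", "res3", "zero", "random"),
                           seed = 1L, control = gllvm_control()) {
  engine <- match.arg(engine)
  if (!length(methods)) stop("'methods' must be nonempty")
  fit1 <- function(method) {
    starts <- make_start(data, spec, method, seed = seed)
    tryCatch({
      f <- if (engine == "va") fit_va(data, spec, starts, control)
           else fit_la(data, spec, starts, control)
      f$objective
    }, error = function(e) NA_real_)
  }
  objs <- vapply(unique(c(methods, "res3")), fit1, numeric(1))
  ref <- objs[["res3"]]
  data.frame(method = methods,
             objective = objs[methods],
             diff_vs_res3 = objs[methods] - ref,
             row.names = NULL)
}
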