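#' Read an abundance matrix (and optional covariates) from delimited text
#'
#' Expects sites in rows and species in columns: the first column holds the
#' site identifier and the header row the species names.  A covariate file
#' follows the same layout and is aligned to the response file by site
#' identifier, not by row order.
#'
#' @param path path to the response CSV/TSV (delimiter inferred from the
#'   extension, or set \code{sep}).
#' @param covariates_path optional covariate file.
#' @param family,link response family and link.
#' @param transpose set \code{TRUE} for species-in-rows files.
#' @param sep field separator; default \code{","} (\code{"\t"} for
#'   \code{.tsv} files).
#' @return an \code{\link{abundance_data}} with site/species names attached
#'   as dimnames of \code{Y}.
#' @export
read_abundance <- function(path, covariates_path = NULL, family,
                           link = default_link(family), transpose = FALSE,
                           sep = NULL) {
  sep_for <- function(p, s) if (!is.null(s)) s
    else if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep_for(path, sep),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected a site-identifier column plus data")
  ids <- as.character(raw[[1]])
  Y <- as.matrix(raw[, -1, drop = FALSE])
  if (transpose) {
    Y <- t(Y)
    tmp <- ids; ids <- colnames(Y); colnames(Y) <- NULL
    rownames(Y) <- NULL
    colnames(Y) <- tmp
    ids <- as.character(ids)
  }
  if (!is.numeric(Y))
    stop("non-numeric cells in ", path)
  rownames(Y) <- ids
  kern <- family_kernel(family, link)
  if (kern$is_discrete) {
    bad <- which(Y < 0 | Y != round(Y), arr.ind = TRUE)
    if (nrow(bad))
      stop("invalid count at site '", rownames(Y)[bad[1, 1]],
           "', species '", colnames(Y)[bad[1, 2]], "': ",
           Y[bad[1, , drop = FALSE]])
  }
  X <- NULL
  if (!is.null(covariates_path)) {
    rawx <- utils::read.table(covariates_path, header = TRUE,
                              sep = sep_for(covariates_path, sep),
                              check.names = FALSE,
                              stringsAsFactors = FALSE)
    xid <- as.character(rawx[[1]])
    X <- as.matrix(rawx[, -1, drop = FALSE])
    if (!setequal(xid, ids))
      stop("site identifiers in ", covariates_path,
           " do not match those in ", path)
    X <- X[match(ids, xid), , drop = FALSE]
    rownames(X) <- ids
  }
  abundance_data(Y, X, family, link)
}

#' Write an abundance matrix (and covariates) to CSV
#'
#' Inverse of \code{\link{read_abundance}}: sites in rows, first column
#' \code{site}, header row of species names.
#'
#' @param data an \code{\link{abundance_data}}.
#' @param path output path for the responses.
#' @param covariates_path optional output path for the covariates.
#' @export
write_abundance <- function(data, path, covariates_path = NULL) {
  ids <- rownames(data$Y)
  if (is.null(ids)) ids <- paste0("site", seq_len(data$n))
  Y <- data$Y
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(data$m))
  utils::write.csv(data.frame(site = ids, Y, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(covariates_path) && !is.null(data$X)) {
    X <- data$X
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(data$k))
    utils::write.csv(data.frame(site = ids, X, check.names = FALSE),
                     covariates_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Serialize / deserialize a parameter set as JSON
#'
#' Named blocks \code{beta0}, \code{B}, \code{Gamma}, \code{phi},
#' \code{sigma2}; matrices are stored with their dimensions.
#'
#' @param params a \code{\link{parameter_set}}.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  obj <- list(beta0 = params$beta0,
              B = if (!is.null(params$B))
                list(values = as.vector(params$B), nrow = nrow(params$B),
                     ncol = ncol(params$B)),
              Gamma = list(values = as.vector(params$Gamma),
                           nrow = nrow(params$Gamma),
                           ncol = ncol(params$Gamma)),
              phi = params$phi, sigma2 = params$sigma2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(b) if (is.null(b) || length(b) == 0) NULL
    else matrix(b$values, b$nrow, b$ncol)
  parameter_set(beta0 = obj$beta0,
                Gamma = mat(obj$Gamma),
                B = mat(obj$B),
                phi = if (length(obj$phi)) obj$phi else NULL,
                sigma2 = if (length(obj$sigma2)) obj$sigma2 else NULL)
}
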