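#' Iterative-PCA imputation of missing values
#'
#' EM-style low-rank matrix completion: missing cells are initialized
#' with column means, then the column-centered completed matrix is fitted
#' by a rank-\code{rank} truncated SVD and the missing cells replaced by
#' the fitted values, iterating until the maximum relative change in the
#' imputed cells drops below \code{tol} or \code{max_iter} is reached.
#' Observed cells are never altered.
#'
#' @param matrix feature x sample numeric matrix with \code{NA} for
#'   missing values; every row and column must have at least one
#'   observed value.
#' @param rank SVD rank, \code{< min(dim(matrix))}; \code{NULL} (default)
#'   selects the rank in \code{1..max_rank} by cross-validated masking of
#'   5\% of the observed cells, minimizing reconstruction RMSE.
#' @param tol convergence tolerance on the relative change of imputed
#'   cells (default 1e-6).
#' @param max_iter iteration cap (default 1000); non-convergence warns
#'   and returns the current completion.
#' @param max_rank upper bound for automatic rank selection (default 10).
#' @param cv_seed seed for the cross-validation mask.
#'
#' @return The completed matrix, with the chosen rank as attribute
#'   \code{rank}.
#' @export
impute_iterative_pca <- function(matrix, rank = NULL, tol = 1e-6,
                                 max_iter = 1000, max_rank = 10,
                                 cv_seed = 1L) {
  miss <- is.na(matrix)
  if (!any(miss)) {
    attr(matrix, "rank") <- if (is.null(rank)) NA_integer_ else rank
    return(matrix)
  }
  bad_r <- rowSums(!miss) == 0
  bad_c <- colSums(!miss) == 0
  if (any(bad_r) || any(bad_c))
    stop(sprintf("all-missing row(s)/column(s): %s",
                 paste(c(rownames(matrix)[bad_r], colnames(matrix)[bad_c]),
                       collapse = ", ")))
  if (is.null(rank)) {
    rank <- select_impute_rank(matrix, max_rank = max_rank, tol = tol,
                               seed = cv_seed)
  }
  if (rank >= min(dim(matrix)))
    stop("rank must be below min(rows, columns)")
  X <- matrix
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[miss[, j], j] <- mu[j]
  for (it in seq_len(max_iter)) {
    ctr <- colMeans(X)
    Xc <- sweep(X, 2, ctr)
    sv <- svd(Xc, nu = rank, nv = rank)
    fit <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    fit <- sweep(fit, 2, ctr, `+`)
    old <- X[miss]
    X[miss] <- fit[miss]
    delta <- max(abs(X[miss] - old) / pmax(abs(old), 1e-12))
    if (delta < tol) {
      attr(X, "rank") <- rank
      return(X)
    }
  }
  warning("iterative PCA imputation did not converge; returning result at max_iter")
  attr(X, "rank") <- rank
  X
}

# cross-validated rank choice: mask 5% of observed cells, impute at each
# candidate rank, pick the rank minimizing RMSE on the mask
select_impute_rank <- function(matrix, max_rank = 10, mask_frac = 0.05,
                               tol = 1e-6, seed = 1L) {
  obs <- which(!is.na(matrix))
  set.seed(seed)
  hold <- sample(obs, max(1L, round(mask_frac * length(obs))))
  masked <- matrix
  masked[hold] <- NA
  # masking may empty a row/column; drop those candidates from the mask
  miss <- is.na(masked)
  fix <- hold[(rowSums(!miss) == 0)[(hold - 1L) %% nrow(matrix) + 1L] |
              (colSums(!miss) == 0)[(hold - 1L) %/% nrow(matrix) + 1L]]
  masked[fix] <- matrix[fix]
  hold <- setdiff(hold, fix)
  ranks <- seq_len(min(max_rank, min(dim(matrix)) - 1L))
  rmse <- vapply(ranks, function(r) {
    imp <- suppressWarnings(
      impute_iterative_pca(masked, rank = r, tol = tol, max_iter = 200))
    sqrt(mean((imp[hold] - matrix[hold])^2))
  }, numeric(1))
  ranks[which.min(rmse)]
}

#' Quantile normalization across samples
#'
#' Forces every column (sample) to share the same empirical distribution:
#' the across-column mean of sorted values. Ties within a column receive
#' the mean of their reference quantiles. Backed by
#' \code{\link[limma]{normalizeQuantiles}}; run after imputation — a
#' matrix with missing values is rejected.
#'
#' @param matrix complete feature x sample numeric matrix.
#' @return The normalized matrix (dimnames preserved).
#' @export
quantile_normalize <- function(matrix) {
  if (any(is.na(matrix)))
    stop("matrix has missing values; impute first (see impute_iterative_pca)")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Covariate design for batch/nuisance removal
#'
#' Splits the modeled factors into protected terms, whose effects must
#' survive (e.g. HD stage), and nuisance terms to be removed (plex set,
#' site, gender, age, BMI). Factors are dummy-encoded with treatment
#' contrasts; numeric covariates enter linearly unless listed in
#' \code{factorize}, in which case they are binned into 5 equal-width
#' intervals first (the RNA-seq convention for age and BMI).
#'
#' @param metadata data.frame of per-sample covariates, rows aligned
#'   with the expression-matrix columns.
#' @param protected character vector of protected column names.
#' @param nuisance character vector of nuisance column names, in removal
#'   order (order matters only for \code{method = "sequential"} in
#'   \code{\link{remove_covariate_effects}}).
#' @param factorize names of numeric nuisance covariates to bin via
#'   \code{\link{factorize_covariate}}.
#'
#' @return An object of class \code{covariate_design} with the protected
#'   design matrix (intercept + protected dummies) and the per-term
#'   nuisance matrices.
#' @export
covariate_design <- function(metadata, protected = character(),
                             nuisance = character(),
                             factorize = character()) {
  if (length(intersect(protected, nuisance)))
    stop("protected and nuisance factors must be disjoint")
  missing_cols <- setdiff(c(protected, nuisance), names(metadata))
  if (length(missing_cols))
    stop(sprintf("covariate(s) not in metadata: %s",
                 paste(missing_cols, collapse = ", ")))
  enc <- function(v, name) {
    if (name %in% factorize && is.numeric(v)) v <- factorize_covariate(v)
    if (is.character(v) || is.logical(v)) v <- factor(v)
    if (is.factor(v)) {
      m <- model.matrix(~v)[, -1, drop = FALSE]
      colnames(m) <- paste0(name, levels(v)[-1])
      m
    } else {
      matrix(v, ncol = 1, dimnames = list(NULL, name))
    }
  }
  prot_mat <- cbind(`(Intercept)` = rep(1, nrow(metadata)))
  for (p in protected) prot_mat <- cbind(prot_mat, enc(metadata[[p]], p))
  nuis <- lapply(nuisance, function(nm) enc(metadata[[nm]], nm))
  names(nuis) <- nuisance
  full <- do.call(cbind, c(list(prot_mat), nuis))
  qrf <- qr(full)
  if (qrf$rank < ncol(full)) {
    aliased <- colnames(full)[qrf$pivot[seq(qrf$rank + 1L, ncol(full))]]
    stop(sprintf("aliased design: %s confounded with earlier terms",
                 paste(aliased, collapse = ", ")))
  }
  structure(list(protected = prot_mat, nuisance = nuis,
                 protected_names = protected, nuisance_names = nuisance),
            class = "covariate_design")
}

#' Remove nuisance covariate effects from an expression matrix
#'
#' Per feature, fits a linear model containing the protected and
#' nuisance terms by least squares and subtracts only the fitted
#' nuisance contribution, so protected effects and residuals are
#' retained. The engine is \code{\link[limma]{removeBatchEffect}}.
#' \code{method = "joint"} (default) removes all nuisance terms in one
#' model and is order-invariant; \code{method = "sequential"} removes
#' them one at a time in the listed order.
#'
#' @param matrix complete feature x sample numeric matrix.
#' @param design a \code{\link{covariate_design}}.
#' @param method \code{"joint"} or \code{"sequential"}.
#' @return The corrected matrix.
#' @export
remove_covariate_effects <- function(matrix, design,
                                     method = c("joint", "sequential")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "covariate_design"))
  if (!length(design$nuisance)) return(matrix)
  if (method == "joint") {
    limma::removeBatchEffect(matrix,
                             covariates = do.call(cbind, design$nuisance),
                             design = design$protected)
  } else {
    for (nm in design$nuisance_names)
      matrix <- limma::removeBatchEffect(matrix,
                                         covariates = design$nuisance[[nm]],
                                         design = design$protected)
    matrix
  }
}
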