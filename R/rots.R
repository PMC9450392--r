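#' Parameters for the reproducibility-optimized test
#'
#' The statistic family is \code{d = |m1 - m2| / (alpha1 + alpha2 * s)},
#' where \code{m1, m2} are group means and \code{s} is the standard error
#' of the mean difference. The grid of candidate \code{(alpha1, alpha2)}
#' pairs always contains the plain absolute mean difference
#' (\code{alpha1 = 1, alpha2 = 0}) and the t-like member
#' (\code{alpha1 = 0, alpha2 = 1}); top-list sizes \code{k} run over a
#' logarithmic ladder capped at the number of features.
#'
#' @param B number of bootstrap dataset pairs (default 1000).
#' @param alpha1_grid candidate offsets used with \code{alpha2 = 1}.
#' @param k_grid candidate top-list sizes; \code{NULL} defers to the
#'   default ladder \code{10, 25, 50, 100, 250, 500, ...} clipped to the
#'   feature count.
#' @param seed integer seed for bootstraps and permutations.
#'
#' @return An object of class \code{rots_params}.
#' @export
rots_params <- function(B = 1000,
                        alpha1_grid = c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 5),
                        k_grid = NULL, seed = 1L) {
  if (B < 2) stop("B must be >= 2")
  grid <- rbind(data.frame(alpha1 = as.numeric(alpha1_grid),
                           alpha2 = rep(1, length(alpha1_grid))),
                data.frame(alpha1 = 1, alpha2 = 0))
  structure(list(B = B, grid = grid, k_grid = k_grid, seed = seed),
            class = "rots_params")
}

default_k_grid <- function(p) {
  ladder <- c(10, 25, 50) * rep(10^(0:6), each = 3)
  k <- ladder[ladder < p]
  unique(c(k[k >= 1], p))
}

# per-group pairwise-complete mean and variance-of-mean for each feature;
# features with < 2 observations in the group get NA
group_stats <- function(X, cols) {
  G <- X[, cols, drop = FALSE]
  obs <- !is.na(G)
  n <- rowSums(obs)
  G0 <- G
  G0[!obs] <- 0
  m <- rowSums(G0) / n
  v <- (rowSums(G0^2) - n * m^2) / (n - 1)
  m[n < 1] <- NA_real_
  bad <- n < 2
  v[bad] <- NA_real_
  v <- pmax(v, 0)
  list(mean = m, se2 = v / n, n = n)
}

#' Reproducibility-optimized test statistic
#'
#' \code{d = |mean1 - mean2| / (alpha1 + alpha2 * s)} per feature, with
#' \code{s} the (Welch-style) standard error of the mean difference,
#' \code{sqrt(var1/n1 + var2/n2)}. With \code{alpha = (1, 0)} this is the
#' absolute mean difference; with \code{alpha = (0, 1)} it is the
#' absolute Welch t statistic.
#'
#' @param group1,group2 feature x sample matrix slices for the two
#'   groups; missing values handled pairwise-complete.
#' @param alpha1 non-negative offset.
#' @param alpha2 weight on the standard error (0 or 1).
#'
#' @return Numeric vector of per-feature statistics; \code{NA} where a
#'   group has fewer than 2 observations.
#' @export
rots_statistic <- function(group1, group2, alpha1, alpha2) {
  X <- cbind(group1, group2)
  rots_statistic_cols(X, seq_len(ncol(group1)),
                      ncol(group1) + seq_len(ncol(group2)), alpha1, alpha2)
}

rots_statistic_cols <- function(X, cols1, cols2, alpha1, alpha2) {
  s1 <- group_stats(X, cols1)
  s2 <- group_stats(X, cols2)
  num <- abs(s1$mean - s2$mean)
  if (alpha2 == 0) {
    d <- num / alpha1
  } else {
    se <- sqrt(s1$se2 + s2$se2)
    d <- num / (alpha1 + alpha2 * se)
  }
  d[s1$n < 2 | s2$n < 2] <- NA_real_
  d
}

# statistics for every grid row at once: features x grid matrix
rots_statistic_grid <- function(X, cols1, cols2, grid) {
  s1 <- group_stats(X, cols1)
  s2 <- group_stats(X, cols2)
  num <- abs(s1$mean - s2$mean)
  se <- sqrt(s1$se2 + s2$se2)
  bad <- s1$n < 2 | s2$n < 2
  out <- vapply(seq_len(nrow(grid)), function(i) {
    a1 <- grid$alpha1[i]; a2 <- grid$alpha2[i]
    d <- if (a2 == 0) num / a1 else num / (a1 + a2 * se)
    d[bad] <- NA_real_
    d
  }, numeric(length(num)))
  out
}

# overlap of the top-k sets of two statistic vectors for each k
topk_overlap <- function(d1, d2, k_grid) {
  r1 <- rank(-d1, ties.method = "first", na.last = TRUE)
  r2 <- rank(-d2, ties.method = "first", na.last = TRUE)
  vapply(k_grid, function(k) sum(r1 <= k & r2 <= k) / k, numeric(1))
}

draw_pair_cols <- function(cols1, cols2) {
  list(b1_1 = sample(cols1, replace = TRUE),
       b1_2 = sample(cols2, replace = TRUE),
       b2_1 = sample(cols1, replace = TRUE),
       b2_2 = sample(cols2, replace = TRUE))
}

# R_k per (grid row, k) averaged over B bootstrap pairs; when
# permute = TRUE, group labels are shuffled before each pair is drawn
# (within strata when given), giving the null overlap distribution.
# Returns list(mean = grid x k matrix, sd = grid x k matrix).
overlap_curves <- function(X, cols1, cols2, grid, k_grid, B,
                           permute = FALSE, strata = NULL) {
  n1 <- length(cols1)
  cols <- c(cols1, cols2)
  acc <- array(0, c(nrow(grid), length(k_grid), B))
  for (b in seq_len(B)) {
    if (permute) {
      perm <- permute_labels(cols, strata)
      c1 <- perm[seq_len(n1)]
      c2 <- perm[-seq_len(n1)]
    } else {
      c1 <- cols1
      c2 <- cols2
    }
    pr <- draw_pair_cols(c1, c2)
    D1 <- rots_statistic_grid(X, pr$b1_1, pr$b1_2, grid)
    D2 <- rots_statistic_grid(X, pr$b2_1, pr$b2_2, grid)
    for (g in seq_len(nrow(grid)))
      acc[g, , b] <- topk_overlap(D1[, g], D2[, g], k_grid)
  }
  list(mean = apply(acc, c(1, 2), mean), sd = apply(acc, c(1, 2), sd))
}

permute_labels <- function(cols, strata = NULL) {
  if (is.null(strata)) return(sample(cols))
  out <- cols
  for (s in unique(strata)) {
    idx <- which(strata == s)
    out[idx] <- sample(cols[idx])
  }
  out
}

#' Bootstrap top-list reproducibility curve
#'
#' For each grid point, draws \code{B} pairs of datasets resampled with
#' replacement within groups, ranks features by the statistic in each
#' member of a pair, and averages the fractional overlap of the two
#' top-\code{k} lists.
#'
#' @param matrix feature x sample matrix.
#' @param labels group label per sample (exactly two distinct values).
#' @param params a \code{\link{rots_params}}.
#'
#' @return A data.frame with one row per (alpha1, alpha2, k):
#'   \code{alpha1}, \code{alpha2}, \code{k}, \code{R} (mean overlap),
#'   \code{R_sd}.
#' @export
bootstrap_reproducibility <- function(matrix, labels, params = rots_params()) {
  gp <- split_two_groups(matrix, labels)
  k_grid <- params$k_grid
  if (is.null(k_grid)) k_grid <- default_k_grid(nrow(matrix))
  if (any(k_grid > nrow(matrix)))
    stop("k exceeds the number of features")
  set.seed(params$seed)
  oc <- overlap_curves(matrix, gp$cols1, gp$cols2, params$grid, k_grid,
                       params$B)
  data.frame(alpha1 = rep(params$grid$alpha1, times = length(k_grid)),
             alpha2 = rep(params$grid$alpha2, times = length(k_grid)),
             k = rep(k_grid, each = nrow(params$grid)),
             R = as.vector(oc$mean), R_sd = as.vector(oc$sd))
}

split_two_groups <- function(matrix, labels) {
  if (length(labels) != ncol(matrix))
    stop("labels must cover all samples")
  lev <- unique(as.character(labels))
  if (length(lev) != 2) stop("exactly two group labels are required")
  cols1 <- which(labels == lev[1])
  cols2 <- which(labels == lev[2])
  if (!length(cols1) || !length(cols2)) stop("a group is empty")
  if (length(cols1) < 2 || length(cols2) < 2)
    stop("each group needs at least 2 samples")
  list(cols1 = cols1, cols2 = cols2, levels = lev)
}

#' Optimize the statistic and top-list size by reproducibility Z-score
#'
#' Observed overlaps \code{R_k} come from bootstrap pairs under the true
#' labels; null overlaps \code{R0_k} from the same bootstrap scheme after
#' permuting the group labels. The reproducibility Z-score of a grid
#' point is \code{(R_k - R0_k) / sd(R0_k)} (sd over the null bootstrap
#' pairs), and the grid point maximizing Z is selected; ties break toward
#' smaller k, then smaller alpha2, then smaller alpha1. Grid points with
#' a degenerate null sd are skipped with a warning.
#'
#' @inheritParams bootstrap_reproducibility
#' @param strata optional per-sample stratum labels constraining the
#'   null permutations.
#'
#' @return List with \code{alpha1}, \code{alpha2}, \code{k},
#'   \code{z} (the maximized Z), \code{R_observed}, \code{R_null}, and
#'   the full \code{curve} data.frame.
#' @export
optimize_parameters <- function(matrix, labels, params = rots_params(),
                                strata = NULL) {
  gp <- split_two_groups(matrix, labels)
  k_grid <- params$k_grid
  if (is.null(k_grid)) k_grid <- default_k_grid(nrow(matrix))
  if (any(k_grid > nrow(matrix)))
    stop("k exceeds the number of features")
  set.seed(params$seed)
  obs <- overlap_curves(matrix, gp$cols1, gp$cols2, params$grid, k_grid,
                        params$B)
  nul <- overlap_curves(matrix, gp$cols1, gp$cols2, params$grid, k_grid,
                        params$B, permute = TRUE, strata = strata)
  Z <- (obs$mean - nul$mean) / nul$sd
  degenerate <- nul$sd == 0 | !is.finite(Z)
  if (any(degenerate)) {
    warning(sprintf("%d grid point(s) with degenerate null overlap sd skipped",
                    sum(degenerate)))
    Z[degenerate] <- -Inf
  }
  if (all(!is.finite(Z))) stop("no usable grid point")
  # tie-breaks: smaller k, then smaller alpha2, then smaller alpha1
  ord <- order(rep(k_grid, each = nrow(params$grid)),
               rep(params$grid$alpha2, times = length(k_grid)),
               rep(params$grid$alpha1, times = length(k_grid)))
  flatZ <- as.vector(Z)[ord]
  best <- ord[which.max(flatZ)]
  gi <- (best - 1L) %% nrow(params$grid) + 1L
  ki <- (best - 1L) %/% nrow(params$grid) + 1L
  curve <- data.frame(alpha1 = rep(params$grid$alpha1, times = length(k_grid)),
                      alpha2 = rep(params$grid$alpha2, times = length(k_grid)),
                      k = rep(k_grid, each = nrow(params$grid)),
                      R = as.vector(obs$mean), R0 = as.vector(nul$mean),
                      R0_sd = as.vector(nul$sd), z = as.vector(Z))
  list(alpha1 = params$grid$alpha1[gi], alpha2 = params$grid$alpha2[gi],
       k = k_grid[ki], z = Z[gi, ki],
       R_observed = obs$mean[gi, ki], R_null = nul$mean[gi, ki],
       curve = curve)
}

#' Permutation p-values and FDR for the chosen statistic
#'
#' Group labels are permuted (within strata when given) to build a null
#' distribution of the statistic. Per feature, the p-value is the
#' add-one-smoothed proportion of pooled null statistics at least as
#' large; the FDR is the mean over permutations of the number of null
#' statistics exceeding the feature's statistic divided by the feature's
#' observed rank, then enforced monotone (non-increasing in the
#' statistic) and capped at 1.
#'
#' @param matrix feature x sample matrix.
#' @param labels two-group label vector.
#' @param alpha1,alpha2 the chosen statistic parameters.
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   gives unreliable FDRs). If fewer distinct permutations exist, all
#'   distinct ones are used and a message reports the count.
#' @param strata optional permutation strata.
#' @param seed integer seed.
#'
#' @return A data.frame with one row per feature: \code{feature},
#'   \code{d}, \code{p}, \code{fdr}, ordered as the input rows.
#' @export
permutation_fdr <- function(matrix, labels, alpha1, alpha2, n_perm = 1000,
                            strata = NULL, seed = 1L) {
  gp <- split_two_groups(matrix, labels)
  set.seed(seed)
  cols <- c(gp$cols1, gp$cols2)
  n1 <- length(gp$cols1)
  d_obs <- rots_statistic_cols(matrix, gp$cols1, gp$cols2, alpha1, alpha2)
  n_distinct <- choose(length(cols), n1)
  if (n_distinct < n_perm) {
    message(sprintf("only %d distinct group assignments exist; using %d permutations",
                    n_distinct, n_distinct))
    n_perm <- n_distinct
  }
  null_mat <- matrix(NA_real_, nrow(matrix), n_perm)
  for (i in seq_len(n_perm)) {
    perm <- permute_labels(cols, strata)
    null_mat[, i] <- rots_statistic_cols(matrix, perm[seq_len(n1)],
                                         perm[-seq_len(n1)], alpha1, alpha2)
  }
  ok <- !is.na(d_obs)
  d_ok <- d_obs[ok]
  rk <- rank(-d_ok, ties.method = "max")  # observed rank, worst for ties
  pooled <- sort(null_mat[!is.na(null_mat)], decreasing = TRUE)
  exceed_pool <- findInterval(-d_ok, -pooled)  # pooled nulls >= d
  p <- (1 + exceed_pool) / (1 + length(pooled))
  fdr_raw <- numeric(length(d_ok))
  for (i in seq_len(n_perm)) {
    nl <- sort(null_mat[ok, i][!is.na(null_mat[ok, i])], decreasing = TRUE)
    fdr_raw <- fdr_raw + findInterval(-d_ok, -nl) / rk
  }
  fdr_raw <- fdr_raw / n_perm
  ord <- order(d_ok, decreasing = TRUE)
  enforced <- rev(cummin(rev(fdr_raw[ord])))
  fdr <- numeric(length(d_ok))
  fdr[ord] <- pmin(enforced, 1)
  out <- data.frame(feature = if (is.null(rownames(matrix)))
                      as.character(seq_len(nrow(matrix)))
                    else rownames(matrix),
                    d = d_obs, p = NA_real_, fdr = NA_real_)
  out$p[ok] <- p
  out$fdr[ok] <- fdr
  out
}

#' Two-group differential abundance via the reproducibility-optimized test
#'
#' Orchestrates \code{\link{optimize_parameters}} (bootstrap top-list
#' overlap against a permutation null, Z-score maximization over the
#' statistic grid) followed by \code{\link{permutation_fdr}} with the
#' selected statistic. Fully reproducible given the seed carried in
#' \code{params}.
#'
#' @inheritParams optimize_parameters
#' @param n_perm permutations for the FDR stage (default \code{params$B}).
#'
#' @return An object of class \code{rots_result}: a list with
#'   \code{table} (feature, d, p, fdr), \code{alpha1}, \code{alpha2},
#'   \code{k}, \code{z}, \code{R_observed}, \code{R_null},
#'   \code{curve}, and \code{params}.
#' @export
rots_test <- function(matrix, labels, params = rots_params(),
                      strata = NULL, n_perm = NULL) {
  if (is.null(n_perm)) n_perm <- params$B
  opt <- optimize_parameters(matrix, labels, params, strata = strata)
  tab <- permutation_fdr(matrix, labels, opt$alpha1, opt$alpha2,
                         n_perm = n_perm, strata = strata,
                         seed = params$seed)
  structure(list(table = tab, alpha1 = opt$alpha1, alpha2 = opt$alpha2,
                 k = opt$k, z = opt$z, R_observed = opt$R_observed,
                 R_null = opt$R_null, curve = opt$curve, params = params),
            class = "rots_result")
}

#' @export
print.rots_result <- function(x, ...) {
  cat(sprintf(paste0("Reproducibility-optimized test: alpha = (%.3g, %g), ",
                     "k = %d, Z = %.2f\n"),
              x$alpha1, x$alpha2, x$k, x$z))
  cat(sprintf("  %d features; %d at FDR < 0.05\n", nrow(x$table),
              sum(x$table$fdr < 0.05, na.rm = TRUE)))
  invisible(x)
}
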