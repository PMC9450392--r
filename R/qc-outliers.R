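#' Control-chart sample QC on median and IQR
#'
#' Two robust per-sample metrics are traced across a dataset: the median
#' (central tendency) and the inter-quartile range (scale) of each
#' sample's feature distribution. A sample is flagged on a metric when it
#' lies more than \code{sd_multiplier} standard deviations from the
#' across-sample mean of that metric, and is a "strong outlier" when
#' either metric flags it.
#'
#' @param matrix feature x sample numeric matrix (log2 scale); \code{NA}
#'   allowed.
#' @param sd_multiplier flag threshold in SD units (default 3).
#'
#' @return An object of class \code{qc_report}: a data.frame with one row
#'   per sample (\code{sample_id}, \code{median}, \code{iqr},
#'   \code{median_outlier}, \code{iqr_outlier}, \code{strong_outlier})
#'   and the threshold as an attribute.
#' @export
control_chart_qc <- function(matrix, sd_multiplier = 3) {
  if (ncol(matrix) < 3) stop("control charts need at least 3 samples")
  med <- apply(matrix, 2, median, na.rm = TRUE)
  iqr <- apply(matrix, 2, IQR, na.rm = TRUE)
  flag <- function(m) {
    s <- sd(m)
    if (is.na(s) || s == 0) {
      message("metric has zero spread; no flags raised")
      return(rep(FALSE, length(m)))
    }
    abs(m - mean(m)) > sd_multiplier * s
  }
  out <- data.frame(sample_id = colnames(matrix), median = med, iqr = iqr,
                    median_outlier = flag(med), iqr_outlier = flag(iqr),
                    row.names = NULL)
  out$strong_outlier <- out$median_outlier | out$iqr_outlier
  attr(out, "sd_multiplier") <- sd_multiplier
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Dual-criterion expression sample-outlier detector
#'
#' A sample is called an outlier only if it fails two independent
#' criteria simultaneously: (i) its (PC1, PC2) score lies outside a
#' probability ellipse (default 68%) fitted to all samples' scores under
#' a bivariate normal model, with PCA run on the centered (not scaled)
#' feature x sample matrix treating samples as observations; and (ii) its
#' standardized connectivity is below a cutoff (default -2.5), where
#' connectivity is minus the mean Euclidean distance of the sample to all
#' others, standardized to mean 0 / SD 1 — so strongly negative values
#' mark samples far from the rest.
#'
#' @param matrix feature x sample numeric matrix; >= 4 samples, >= 2
#'   features.
#' @param ellipse_prob coverage probability of the PCA ellipse (default
#'   0.68).
#' @param z_cutoff standardized-connectivity cutoff (default -2.5).
#'
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{pca_outside_ellipse}, \code{connectivity_z},
#'   \code{is_outlier} (the conjunction of the two criteria).
#' @export
detect_expression_outliers <- function(matrix, ellipse_prob = 0.68,
                                       z_cutoff = -2.5) {
  if (ncol(matrix) < 4) stop("outlier detection needs at least 4 samples")
  if (nrow(matrix) < 2) stop("outlier detection needs at least 2 features")
  sc <- prcomp(t(matrix), center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  md2 <- mahalanobis(sc, colMeans(sc), cov(sc))
  outside <- md2 > qchisq(ellipse_prob, df = 2)
  D <- as.matrix(dist(t(matrix)))
  k <- rowSums(D) / (ncol(matrix) - 1)
  z <- -(k - mean(k)) / sd(k)
  data.frame(sample_id = colnames(matrix),
             pca_outside_ellipse = unname(outside),
             connectivity_z = unname(z),
             is_outlier = unname(outside & z < z_cutoff),
             row.names = NULL)
}

#' Prevalence filter for count features
#'
#' Keeps a feature if, for at least one of the stated group comparisons,
#' at least one group in that comparison has a nonzero count in at least
#' \code{min_samples} samples.
#'
#' @param counts feature x sample count matrix.
#' @param groups named character vector or factor mapping sample id (or
#'   column position) to group.
#' @param min_samples prevalence threshold (default 9).
#' @param comparisons list of length-2 character vectors of group names;
#'   default: all pairwise comparisons among the observed groups.
#'
#' @return The row-filtered matrix.
#' @export
prevalence_filter <- function(counts, groups, min_samples = 9,
                              comparisons = NULL) {
  groups <- as.character(groups)
  if (length(groups) != ncol(counts))
    stop("groups must cover all samples")
  lev <- unique(groups)
  if (is.null(comparisons))
    comparisons <- utils::combn(lev, 2, simplify = FALSE)
  bad <- setdiff(unlist(comparisons), lev)
  if (length(bad))
    stop(sprintf("unknown group(s) in comparisons: %s",
                 paste(bad, collapse = ", ")))
  gset <- unique(unlist(comparisons))
  nz <- sapply(gset, function(g)
    rowSums(counts[, groups == g, drop = FALSE] > 0))
  keep <- apply(nz >= min_samples, 1, any)
  counts[keep, , drop = FALSE]
}

#' Factorize a continuous covariate into equal-width intervals
#'
#' Bins a continuous covariate (e.g. age or BMI) into \code{n_bins}
#' equal-width intervals spanning its range, widened by 0.1% at the edges
#' so the extremes fall inside — the convention of base R's
#' \code{\link[base]{cut}} on a numeric vector.
#'
#' @param values finite numeric vector with \code{max > min}.
#' @param n_bins number of intervals (default 5).
#'
#' @return A factor with levels \code{"1"} .. \code{"n_bins"}.
#' @export
factorize_covariate <- function(values, n_bins = 5) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to factorize")
  if (n_bins > 1 && max(v) == min(v))
    stop("constant covariate cannot be partitioned into intervals")
  if (n_bins == 1)
    return(factor(rep("1", length(values)), levels = "1"))
  cut(values, breaks = n_bins, labels = as.character(seq_len(n_bins)))
}
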