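#' TMT 10plex PSM table
#'
#' One peptide-spectrum-match (PSM) table from one TMT 10plex / MS run:
#' a matrix of raw reporter-ion intensities for the ten mono-isotopic
#' channels (126, 127N, 127C, 128N, 128C, 129N, 129C, 130N, 130C, 131)
#' plus peptide/protein annotations and the designated reference channel.
#'
#' @param intensities numeric matrix, PSMs x 10 channels; \code{NA} marks
#'   a missing reporter signal, present values must be >= 0.
#' @param psm_id,peptide character vectors, one per row.
#' @param protein_id character vector; \code{NA} for unassigned proteins.
#' @param shared_status logical; \code{TRUE} for peptides with non-unique
#'   peptide-to-gene mapping.
#' @param plex_id,run_id identifiers of the plex and MS run.
#' @param reference_channel reference channel index in 1..10 (default 10,
#'   the 131 label).
#'
#' @return An object of class \code{psm_table}.
#' @export
psm_table <- function(intensities, psm_id, peptide, protein_id,
                      shared_status = rep(FALSE, nrow(intensities)),
                      plex_id = "plex1", run_id = "run1",
                      reference_channel = 10L) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != 10L)
    stop("a TMT 10plex PSM table must have exactly 10 reporter channels")
  if (any(intensities < 0, na.rm = TRUE))
    stop("reporter intensities must be non-negative where present")
  if (!(reference_channel %in% 1:10))
    stop("reference_channel must be in 1..10")
  n <- nrow(intensities)
  stopifnot(length(psm_id) == n, length(peptide) == n,
            length(protein_id) == n, length(shared_status) == n)
  if (is.null(colnames(intensities)))
    colnames(intensities) <- tmt_channel_labels()
  rownames(intensities) <- psm_id
  structure(list(intensities = intensities,
                 psm_id = as.character(psm_id),
                 peptide = as.character(peptide),
                 protein_id = as.character(protein_id),
                 shared_status = as.logical(shared_status),
                 plex_id = plex_id, run_id = run_id,
                 reference_channel = as.integer(reference_channel)),
            class = "psm_table")
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("TMT 10plex PSM table: %d PSMs, plex %s, run %s, reference channel %s\n",
              nrow(x$intensities), x$plex_id, x$run_id,
              colnames(x$intensities)[x$reference_channel]))
  invisible(x)
}

subset_psm_table <- function(table, keep) {
  psm_table(table$intensities[keep, , drop = FALSE],
            table$psm_id[keep], table$peptide[keep],
            table$protein_id[keep], table$shared_status[keep],
            table$plex_id, table$run_id, table$reference_channel)
}

#' Filter PSMs on reporter signal
#'
#' Retains exactly the PSM rows with a signal (a present, positive
#' intensity) in at least one of the 10 reporter channels.
#'
#' @param table a \code{\link{psm_table}}.
#' @return The filtered \code{psm_table}.
#' @export
filter_psms <- function(table) {
  keep <- rowSums(!is.na(table$intensities) & table$intensities > 0) >= 1L
  subset_psm_table(table, keep)
}

#' Correct isotopic impurities
#'
#' Reporter channels cross-contaminate according to a batch-specific
#' impurity matrix \code{M} (column j gives the fractions of channel j's
#' true signal observed in each channel). Per PSM this solves
#' \code{M[present, present] \%*\% corrected = observed} restricted to the
#' present channels; small negative solutions are clamped to 0 and
#' missing channels stay missing.
#'
#' @param table a \code{\link{psm_table}}.
#' @param impurities 10x10 non-negative mixing matrix, diagonally
#'   dominant by column; an attribute or list element \code{batch_id}
#'   names the TMT lot in error messages.
#' @param max_condition reject matrices with 2-norm condition number
#'   above this bound (default 1e8).
#'
#' @return The corrected \code{psm_table}.
#' @export
correct_isotope_impurities <- function(table, impurities,
                                       max_condition = 1e8) {
  M <- as.matrix(impurities)
  batch <- attr(impurities, "batch_id")
  if (is.null(batch)) batch <- "unknown"
  stopifnot(nrow(M) == 10L, ncol(M) == 10L)
  if (any(M < 0)) stop("impurity matrix entries must be non-negative")
  if (kappa(M, exact = TRUE) > max_condition)
    stop(sprintf("impurity matrix for TMT batch '%s' is singular or ill-conditioned",
                 batch))
  X <- table$intensities
  out <- X
  for (i in seq_len(nrow(X))) {
    pres <- which(!is.na(X[i, ]))
    if (!length(pres)) next
    sol <- solve(M[pres, pres, drop = FALSE], X[i, pres])
    out[i, pres] <- pmax(sol, 0)
  }
  table$intensities <- out
  table
}

#' Sum-scaling normalization at the PSM level
#'
#' Equalizes total reporter intensity across the 10 channels of a run:
#' channel sums \code{S_c} are computed over present values, the median
#' \code{M} of the ten sums is taken, and every intensity in channel c is
#' multiplied by \code{M / S_c}, so that every channel's post-scaling sum
#' equals \code{M}. A printed-protocol variant that multiplies by
#' \code{S_c / M} instead is available via \code{direction = "literal"}.
#'
#' @param table a \code{\link{psm_table}}.
#' @param direction \code{"equalize"} (default; factor = median / sum) or
#'   \code{"literal"} (factor = sum / median).
#'
#' @return The normalized \code{psm_table}. Channels whose sum is zero
#'   are left unscaled with a warning.
#' @export
sum_scale_normalize <- function(table, direction = c("equalize", "literal")) {
  direction <- match.arg(direction)
  X <- table$intensities
  S <- colSums(X, na.rm = TRUE)
  if (all(S == 0)) stop("no channel has a positive sum")
  M <- median(S)
  fac <- if (direction == "equalize") M / S else S / M
  zero <- S == 0
  if (any(zero)) {
    warning(sprintf("channel(s) %s have zero sum; left unscaled",
                    paste(colnames(X)[zero], collapse = ", ")))
    fac[zero] <- 1
  }
  table$intensities <- sweep(X, 2, fac, `*`)
  table
}

#' Log2 ratios to the reference channel
#'
#' Converts reporter intensities to log2 ratios of each sample channel to
#' the designated reference channel of the plex. PSMs with a missing or
#' zero reference intensity yield an all-missing row (never +-Inf).
#'
#' @param table a \code{\link{psm_table}}.
#' @return A numeric matrix, PSMs x 9 sample channels, in log2 ratio
#'   units, with the PSM annotations attached as attributes
#'   \code{peptide}, \code{protein_id}, \code{shared_status} and the
#'   number of reference-missing rows as attribute \code{n_ref_missing}.
#' @export
reference_log_ratios <- function(table) {
  rc <- table$reference_channel
  X <- table$intensities
  ref <- X[, rc]
  bad <- is.na(ref) | ref == 0
  R <- log2(X[, -rc, drop = FALSE] / ref)
  R[bad, ] <- NA_real_
  R[is.infinite(R)] <- NA_real_
  structure(R, peptide = table$peptide, protein_id = table$protein_id,
            shared_status = table$shared_status,
            n_ref_missing = sum(bad))
}

# shared representative-row rule: per group, keep the row with maximum
# row mean (NA-stripped); ties broken by stable input order
max_mean_representative <- function(matrix, group) {
  means <- rowMeans(matrix, na.rm = TRUE)
  means[is.nan(means)] <- -Inf
  idx <- vapply(split(seq_len(nrow(matrix)), group),
                function(rows) rows[which.max(means[rows])], integer(1))
  idx[order(match(names(idx), unique(group)))]
}

#' Collapse a PSM-level matrix to unique peptides
#'
#' Applies the peptide-dataset cleanup: rows flagged as shared (peptide
#' maps to more than one gene) are removed first, then rows with an
#' unassigned protein ID, then rows are collapsed onto unique peptides by
#' keeping, per peptide, the PSM with the maximum row mean (ties go to
#' the first in input order).
#'
#' @param matrix PSM x sample numeric matrix (e.g. from
#'   \code{\link{reference_log_ratios}}).
#' @param peptide,protein_id,shared_status per-row annotations; taken
#'   from the matrix attributes when omitted.
#'
#' @return A peptide x sample matrix with rownames the peptide ids and a
#'   \code{protein_id} attribute giving each peptide's protein.
#' @export
collapse_to_peptides <- function(matrix, peptide = attr(matrix, "peptide"),
                                 protein_id = attr(matrix, "protein_id"),
                                 shared_status = attr(matrix, "shared_status")) {
  stopifnot(length(peptide) == nrow(matrix),
            length(protein_id) == nrow(matrix),
            length(shared_status) == nrow(matrix))
  keep <- !shared_status & !is.na(protein_id)
  m <- matrix[keep, , drop = FALSE]
  pep <- peptide[keep]
  prot <- protein_id[keep]
  if (!nrow(m))
    return(structure(m, protein_id = character(0)))
  idx <- max_mean_representative(m, pep)
  out <- m[idx, , drop = FALSE]
  rownames(out) <- pep[idx]
  structure(out, protein_id = prot[idx])
}

#' Aggregate a peptide matrix to proteins
#'
#' One row per protein, chosen by the same maximum-row-mean
#' representative rule used for peptide collapse.
#'
#' @param peptides peptide x sample matrix (rownames = peptide ids).
#' @param protein_id protein of each peptide row; taken from the
#'   \code{protein_id} attribute when omitted.
#'
#' @return A protein x sample matrix with rownames the protein ids.
#' @export
aggregate_to_proteins <- function(peptides,
                                  protein_id = attr(peptides, "protein_id")) {
  stopifnot(length(protein_id) == nrow(peptides))
  if (any(is.na(protein_id)))
    stop("peptide(s) map to no protein; filter upstream with collapse_to_peptides")
  if (!nrow(peptides)) return(peptides)
  idx <- max_mean_representative(peptides, protein_id)
  out <- peptides[idx, , drop = FALSE]
  rownames(out) <- protein_id[idx]
  attr(out, "protein_id") <- NULL
  out
}

#' Run the TMT processing chain across plexes
#'
#' Convenience driver applying, per plex and in order: signal filtering,
#' isotopic impurity correction, sum-scaling normalization, reference
#' log2-ratio computation, and peptide collapse; the per-plex peptide
#' matrices (9 sample channels each, different samples per plex) are then
#' merged column-wise on peptide identity (union of peptides, \code{NA}
#' where a peptide was not observed in a plex).
#'
#' @param tables list of \code{\link{psm_table}} objects (one per plex).
#' @param impurities 10x10 impurity matrix (default identity).
#' @return A peptide x sample log2-ratio matrix, columns named
#'   \code{<plex>_<channel>}, with a \code{protein_id} attribute.
#' @export
process_psm_tables <- function(tables, impurities = diag(10)) {
  pieces <- lapply(tables, function(tb) {
    tb <- filter_psms(tb)
    tb <- correct_isotope_impurities(tb, impurities)
    tb <- sum_scale_normalize(tb)
    R <- reference_log_ratios(tb)
    colnames(R) <- paste0(tb$plex_id, "_", colnames(R))
    collapse_to_peptides(R)
  })
  peps <- unique(unlist(lapply(pieces, rownames)))
  out <- do.call(cbind, lapply(pieces, function(p) {
    m <- matrix(NA_real_, length(peps), ncol(p),
                dimnames = list(peps, colnames(p)))
    m[rownames(p), ] <- p
    m
  }))
  prot <- rep(NA_character_, length(peps))
  names(prot) <- peps
  for (p in pieces) prot[rownames(p)] <- attr(p, "protein_id")
  structure(out, protein_id = unname(prot))
}
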