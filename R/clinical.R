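#' Disease burden score
#'
#' Cumulative mutation-exposure index for Huntington disease carriers:
#' \code{(CAG - 35.5) * age}, where CAG is the expanded (long) allele
#' repeat count and age is in years. Controls carry no expanded allele and
#' have no DBS.
#'
#' @param cag_long expanded-allele CAG repeat count (> 0); vectorized.
#' @param age age in years (> 0); vectorized.
#'
#' @return Numeric DBS, \code{(cag_long - 35.5) * age}.
#' @examples
#' compute_dbs(45.5, 40)  # 400
#' compute_dbs(40.5, 50)  # 250, the screening threshold
#' @export
compute_dbs <- function(cag_long, age) {
  if (any(is.na(cag_long))) stop("cag_long is missing: controls have no DBS")
  stopifnot(all(cag_long > 0), all(age > 0))
  (cag_long - 35.5) * age
}

#' Classify a participant's disease stage
#'
#' Staging convention of an HD observational cohort: non-carriers are
#' controls; carriers with a UHDRS diagnostic confidence level (DCL) of 2
#' or less are pre-manifest (pre-HD); carriers past diagnosis (DCL > 2)
#' with total functional capacity (TFC) 7--13 (TFC stages 1--2) are
#' early-HD. A carrier with DCL > 2 but TFC below 7 falls outside the
#' study strata and is returned as \code{"unclassified"}.
#'
#' @param is_carrier logical, expanded CAG allele present.
#' @param dcl diagnostic confidence level, 0--4.
#' @param tfc total functional capacity, 0--13.
#'
#' @return One of \code{"control"}, \code{"pre-HD"}, \code{"early-HD"},
#'   \code{"unclassified"}. Vectorized over its arguments.
#' @export
classify_stage <- function(is_carrier, dcl = NA_integer_, tfc = NA_integer_) {
  n <- max(length(is_carrier), length(dcl), length(tfc))
  is_carrier <- rep_len(is_carrier, n)
  dcl <- rep_len(dcl, n)
  tfc <- rep_len(tfc, n)
  if (any(is_carrier & (is.na(dcl) | dcl < 0 | dcl > 4)))
    stop("dcl must be in 0..4 for carriers")
  if (any(is_carrier & dcl > 2 & (is.na(tfc) | tfc < 0 | tfc > 13)))
    stop("tfc must be in 0..13 for manifest carriers")
  out <- rep("control", n)
  out[is_carrier & dcl <= 2] <- "pre-HD"
  out[is_carrier & dcl > 2 & tfc >= 7] <- "early-HD"
  out[is_carrier & dcl > 2 & tfc < 7] <- "unclassified"
  out
}

#' Per-group descriptive summary of a cohort
#'
#' Mean, minimum and maximum of every numeric field, by group — the shape
#' of a study's descriptive participant table.
#'
#' @param records data.frame of participant records with a \code{group}
#'   column (as from \code{\link{gen_cohort_metadata}}).
#'
#' @return A data.frame with one row per (group, variable) and columns
#'   \code{group}, \code{variable}, \code{mean}, \code{min}, \code{max}
#'   (NA for a variable entirely missing in a group).
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) stop("records table is empty")
  if (is.null(records$group)) stop("records must have a 'group' column")
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  res <- lapply(split(records, records$group), function(g) {
    do.call(rbind, lapply(num_cols, function(v) {
      x <- g[[v]][!is.na(g[[v]])]
      if (!length(x))
        data.frame(variable = v, mean = NA_real_, min = NA_real_,
                   max = NA_real_)
      else
        data.frame(variable = v, mean = mean(x), min = min(x), max = max(x))
    }))
  })
  out <- do.call(rbind, Map(function(g, tab) cbind(group = g, tab),
                            names(res), res))
  rownames(out) <- NULL
  out
}
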