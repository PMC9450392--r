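#' Write / read a PSM table as TSV
#'
#' Schema: \code{psm_id}, \code{peptide}, \code{protein_id},
#' \code{shared_status}, \code{plex_id}, \code{run_id}, then one column
#' per reporter channel (\code{channel_126} .. \code{channel_131});
#' missing intensities are empty fields.
#'
#' @param table a \code{\link{psm_table}}.
#' @param path file path.
#' @param reference_channel reference channel index used when reading
#'   (default 10).
#' @return \code{write_psm_tsv} returns \code{path} invisibly;
#'   \code{read_psm_tsv} returns a \code{psm_table}.
#' @export
write_psm_tsv <- function(table, path) {
  X <- table$intensities
  df <- data.frame(psm_id = table$psm_id, peptide = table$peptide,
                   protein_id = table$protein_id,
                   shared_status = table$shared_status,
                   plex_id = table$plex_id, run_id = table$run_id,
                   check.names = FALSE)
  ints <- as.data.frame(X)
  names(ints) <- paste0("channel_", colnames(X))
  utils::write.table(cbind(df, ints), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path, reference_channel = 10L) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(protein_id = "character"))
  ch <- grep("^channel_", names(df))
  X <- as.matrix(df[, ch])
  colnames(X) <- sub("^channel_", "", names(df)[ch])
  df$protein_id[df$protein_id == ""] <- NA_character_
  psm_table(X, df$psm_id, df$peptide, df$protein_id, df$shared_status,
            plex_id = df$plex_id[1], run_id = df$run_id[1],
            reference_channel = reference_channel)
}

#' Write / read a feature-by-sample matrix as TSV
#'
#' One header line of sample ids; first column \code{feature}.
#'
#' @param matrix numeric matrix with dimnames.
#' @param path file path.
#' @return \code{write_matrix_tsv} returns \code{path} invisibly;
#'   \code{read_matrix_tsv} returns the matrix.
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(feature = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a phased panel
#'
#' The TSV layout has columns \code{sample_id}, \code{phase}, then one
#' 0/1 column per locus. The VCF layout is a minimal VCFv4.2 with one
#' record per locus and phased genotypes \code{a|b} per sample.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param path file path.
#' @return writers return \code{path} invisibly; readers return a
#'   \code{haplotype_panel}.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- data.frame(sample_id = panel$sample_id, phase = panel$phase,
                   panel$alleles, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = ".")
  haplotype_panel(loci = names(df)[-(1:2)], sample_id = df$sample_id,
                  phase = df$phase,
                  alleles = as.matrix(df[, -(1:2), drop = FALSE]))
}

#' @rdname write_panel_tsv
#' @export
write_panel_vcf <- function(panel, path) {
  samples <- unique(panel$sample_id)
  i1 <- match(paste(samples, 1L), paste(panel$sample_id, panel$phase))
  i2 <- match(paste(samples, 2L), paste(panel$sample_id, panel$phase))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr4>",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  fmt_gt <- function(a, b) {
    a <- ifelse(is.na(a), ".", a)
    b <- ifelse(is.na(b), ".", b)
    paste0(a, "|", b)
  }
  for (j in seq_along(panel$loci)) {
    gts <- fmt_gt(panel$alleles[i1, j], panel$alleles[i2, j])
    writeLines(paste(c("chr4", j, panel$loci[j], "A", "G", ".", "PASS",
                       ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("not a VCF: no #CHROM header line")
  cols <- strsplit(hdr, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  recs <- strsplit(body, "\t")
  loci <- vapply(recs, `[[`, "", 3L)
  gt <- t(vapply(recs, function(r) r[-(1:9)], character(length(samples))))
  parse_side <- function(side) {
    a <- vapply(strsplit(gt, "|", fixed = TRUE), `[`, "", side)
    suppressWarnings(matrix(as.integer(a), nrow(gt), ncol(gt)))
  }
  a1 <- parse_side(1L)
  a2 <- parse_side(2L)
  haplotype_panel(loci = loci,
                  sample_id = rep(samples, each = 2L),
                  phase = rep(c(1L, 2L), length(samples)),
                  alleles = rbind_interleave(t(a1), t(a2)))
}

# interleave rows of two equally sized matrices: a1[1,], a2[1,], a1[2,], ...
rbind_interleave <- function(m1, m2) {
  out <- matrix(NA_integer_, 2L * nrow(m1), ncol(m1))
  out[seq(1, nrow(out), by = 2), ] <- m1
  out[seq(2, nrow(out), by = 2), ] <- m2
  out
}

#' Read reserved haplotype definitions
#'
#' TSV with columns \code{name} and either a single \code{haplotype}
#' allele-string column or 21 per-locus 0/1 columns. The package ships a
#' synthetic placeholder table
#' (\code{inst/extdata/reserved_haplotypes_synthetic.tsv}) illustrating
#' the schema; real reserved definitions are supplied by the user.
#'
#' @param path file path.
#' @return data.frame with columns \code{name}, \code{haplotype}.
#' @export
read_reserved_definitions <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!"haplotype" %in% names(df)) {
    loci <- setdiff(names(df), "name")
    df$haplotype <- apply(df[, loci, drop = FALSE], 1, paste, collapse = "")
  }
  df[, c("name", "haplotype")]
}
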