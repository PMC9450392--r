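#' Phased haplotype panel
#'
#' Phased chromosomes over an ordered set of defining variants (by
#' default the 21 HTT-region variants: 20 SNPs plus the rs149109767
#' indel). Alleles are coded 0 = reference, 1 = alternate; \code{NA}
#' marks a missing call.
#'
#' @param loci ordered character vector of variant identifiers.
#' @param sample_id sample identifier per chromosome.
#' @param phase phase index per chromosome (1 or 2, unique within a
#'   sample).
#' @param alleles integer matrix, chromosomes x loci, entries 0/1/NA.
#' @param mutant_flag optional logical per chromosome: carries the
#'   expanded CAG repeat (NA when unknown).
#'
#' @return An object of class \code{haplotype_panel}.
#' @export
haplotype_panel <- function(loci, sample_id, phase, alleles,
                            mutant_flag = rep(NA, length(sample_id))) {
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != length(loci))
    stop("allele matrix width must equal the number of loci")
  stopifnot(length(sample_id) == nrow(alleles),
            length(phase) == nrow(alleles),
            all(phase %in% c(1L, 2L)))
  if (anyDuplicated(paste(sample_id, phase)))
    stop("phase index must be unique within each sample")
  if (!all(alleles %in% c(0L, 1L, NA)))
    stop("alleles must be coded 0 (reference), 1 (alternate) or NA")
  colnames(alleles) <- loci
  structure(list(loci = loci, sample_id = as.character(sample_id),
                 phase = as.integer(phase), alleles = alleles,
                 mutant_flag = mutant_flag),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Phased panel: %d chromosomes (%d samples) x %d loci\n",
              nrow(x$alleles), length(unique(x$sample_id)), length(x$loci)))
  invisible(x)
}

allele_string <- function(alleles) {
  apply(alleles, 1, paste, collapse = "")
}

#' Construct haplotypes from a phased panel
#'
#' Tabulates the distinct allele vectors among the panel's chromosomes.
#' Chromosomes with any missing call are excluded (haplotype identity
#' requires all loci) and their count reported via the
#' \code{n_dropped} attribute; frequencies are relative to the retained
#' chromosomes.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @return A data.frame ordered by decreasing count: \code{haplotype}
#'   (allele string), \code{count}, \code{frequency}; attribute
#'   \code{n_dropped} gives the excluded-chromosome count.
#' @export
construct_haplotypes <- function(panel) {
  if (!nrow(panel$alleles)) stop("panel is empty")
  complete <- rowSums(is.na(panel$alleles)) == 0
  if (!any(complete)) stop("no chromosome has complete calls at all loci")
  vec <- allele_string(panel$alleles[complete, , drop = FALSE])
  tab <- sort(table(vec), decreasing = TRUE)
  out <- data.frame(haplotype = names(tab), count = as.integer(tab),
                    frequency = as.integer(tab) / length(vec),
                    row.names = NULL)
  attr(out, "n_dropped") <- sum(!complete)
  out
}

#' Name haplotypes by reserved identity and frequency
#'
#' Allele vectors matching a reserved definition keep the reserved name
#' regardless of their panel frequency; the remaining vectors are sorted
#' by descending frequency and assigned names continuing after the
#' reserved series (\code{hap.17}, \code{hap.18}, ... when 16 names are
#' reserved). Frequency ties break lexicographically on the allele
#' string.
#'
#' @param table haplotype frequency table from
#'   \code{\link{construct_haplotypes}}.
#' @param reserved data.frame with columns \code{name} and
#'   \code{haplotype} (allele string) giving the reserved definitions
#'   (e.g. hap.1 .. hap.16); may be empty.
#' @param prefix name prefix for novel haplotypes (default
#'   \code{"hap."}).
#'
#' @return A data.frame of definitions: \code{name}, \code{haplotype},
#'   \code{count}, \code{frequency}, \code{reserved} (logical).
#' @export
name_haplotypes <- function(table, reserved = NULL, prefix = "hap.") {
  if (is.null(reserved))
    reserved <- data.frame(name = character(0), haplotype = character(0))
  if (anyDuplicated(reserved$haplotype))
    stop("duplicate allele vectors in reserved definitions")
  if (anyDuplicated(reserved$name))
    stop("duplicate names in reserved definitions")
  hit <- match(table$haplotype, reserved$haplotype)
  out <- table
  out$name <- reserved$name[hit]
  out$reserved <- !is.na(hit)
  novel <- which(is.na(hit))
  novel <- novel[order(-out$frequency[novel], out$haplotype[novel])]
  out$name[novel] <- paste0(prefix, nrow(reserved) + seq_along(novel))
  out[, c("name", "haplotype", "count", "frequency", "reserved")]
}

#' Assign diplotypes to phased samples
#'
#' Maps each phased chromosome of each sample to its exact-match
#' haplotype definition; a chromosome matching no definition is
#' \code{"unassigned"}, and a sample is conclusive only if both phases
#' are assigned.
#'
#' @param panel a \code{\link{haplotype_panel}}.
#' @param definitions data.frame with columns \code{name} and
#'   \code{haplotype} (as from \code{\link{name_haplotypes}}).
#'
#' @return A data.frame with one row per sample: \code{sample_id},
#'   \code{hap1}, \code{hap2}, \code{conclusive}.
#' @export
assign_diplotypes <- function(panel, definitions) {
  if (!nrow(definitions)) stop("definitions table is empty")
  if (any(nchar(definitions$haplotype) != length(panel$loci)))
    stop("definition allele vectors do not match the panel's locus count")
  vec <- allele_string(panel$alleles)
  vec[rowSums(is.na(panel$alleles)) > 0] <- NA_character_
  nm <- definitions$name[match(vec, definitions$haplotype)]
  nm[is.na(nm)] <- "unassigned"
  samples <- unique(panel$sample_id)
  h1 <- nm[match(paste(samples, 1L), paste(panel$sample_id, panel$phase))]
  h2 <- nm[match(paste(samples, 2L), paste(panel$sample_id, panel$phase))]
  h1[is.na(h1)] <- "unassigned"
  h2[is.na(h2)] <- "unassigned"
  data.frame(sample_id = samples, hap1 = h1, hap2 = h2,
             conclusive = h1 != "unassigned" & h2 != "unassigned",
             row.names = NULL)
}

#' Binary (Jaccard-style) distance between haplotype definitions
#'
#' \code{d(a, b)} is the number of loci where exactly one of the two
#' haplotypes carries the alternate allele, divided by the number of
#' loci where at least one does; two all-reference haplotypes are at
#' distance 0 by convention. This is the asymmetric binary distance of
#' \code{\link[stats]{dist}(method = "binary")}.
#'
#' @param definitions data.frame with a \code{haplotype} column of 0/1
#'   allele strings (rownames of the result come from a \code{name}
#'   column when present), or a 0/1 matrix.
#'
#' @return A symmetric distance matrix.
#' @export
binary_distance_matrix <- function(definitions) {
  m <- definition_matrix(definitions)
  if (nrow(m) < 2) stop("need at least 2 definitions")
  D <- as.matrix(dist(m, method = "binary"))
  D[is.na(D)] <- 0  # dist() yields NA for a pair of all-zero vectors
  D
}

definition_matrix <- function(definitions) {
  if (is.matrix(definitions)) {
    m <- definitions
  } else {
    m <- do.call(rbind, lapply(strsplit(definitions$haplotype, ""),
                               as.integer))
    rownames(m) <- if (!is.null(definitions$name)) definitions$name
                   else definitions$haplotype
  }
  m
}

#' Cluster haplotypes: Ward dendrogram plus k-means labels
#'
#' Hierarchical agglomeration with Ward's linkage on the binary distance
#' matrix, and flat cluster labels from k-means (seeded, 100 restarts)
#' on the binary allele vectors. With \code{mutant_partition}, the
#' normal and mutant haplotype sets are clustered independently and two
#' results returned.
#'
#' @param definitions data.frame of definitions (\code{name},
#'   \code{haplotype}); with \code{mutant_partition}, also a logical
#'   \code{mutant} column.
#' @param k number of flat clusters (default 3).
#' @param mutant_partition cluster normal and mutant haplotypes
#'   separately (default FALSE).
#' @param seed seed for the k-means restarts.
#'
#' @return A list with \code{dendrogram} (an \code{hclust}),
#'   \code{clusters} (named integer vector of k-means labels) and
#'   \code{newick} (the dendrogram in Newick format, via \pkg{ape});
#'   with \code{mutant_partition}, a list of two such results named
#'   \code{normal} and \code{mutant}.
#' @export
cluster_haplotypes <- function(definitions, k = 3, mutant_partition = FALSE,
                               seed = 1L) {
  if (mutant_partition) {
    if (is.null(definitions$mutant))
      stop("mutant_partition requires a 'mutant' column")
    return(list(
      normal = cluster_haplotypes(definitions[!definitions$mutant, ],
                                  k = k, seed = seed),
      mutant = cluster_haplotypes(definitions[definitions$mutant, ],
                                  k = k, seed = seed)))
  }
  m <- definition_matrix(definitions)
  if (k > nrow(m)) stop("k exceeds the number of definitions")
  D <- binary_distance_matrix(definitions)
  hc <- hclust(as.dist(D), method = "ward.D2")
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = 100)
  list(dendrogram = hc, clusters = setNames(km$cluster, rownames(m)),
       newick = ape::write.tree(ape::as.phylo(hc)))
}
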