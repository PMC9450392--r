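# small constructors shared across test files

# a 10x10 impurity matrix: identity except a 2x2 mixing block on the
# given channel pair, so 2-channel hand calculations embed exactly
impurity_block <- function(ch = c(1, 2), p = c(0.95, 0.05)) {
  M <- diag(10)
  M[ch, ch] <- matrix(c(p[1], p[2], p[2], p[1]), 2)
  attr(M, "batch_id") <- "lotA"
  M
}

# a random strictly diagonally dominant column-stochastic impurity matrix
random_impurity <- function() {
  M <- matrix(runif(100, 0, 0.02), 10, 10)
  diag(M) <- 0
  diag(M) <- 1 - colSums(M)
  M
}

toy_psm_table <- function(intensities, ...) {
  n <- nrow(intensities)
  psm_table(intensities,
            psm_id = sprintf("psm%d", seq_len(n)),
            peptide = sprintf("pep%d", seq_len(n)),
            protein_id = sprintf("prot%d", seq_len(n)), ...)
}

# fill a 10-channel row with a base value and overrides
row10 <- function(base = 100, ...) {
  x <- rep(base, 10)
  ov <- list(...)
  for (nm in names(ov)) x[as.integer(nm)] <- ov[[nm]]
  x
}

# partition agreement up to label permutation
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# distinct random haplotype allele strings
random_haplotypes <- function(n, n_loci = 21) {
  repeat {
    m <- matrix(rbinom(n * n_loci, 1, 0.4), n, n_loci)
    s <- apply(m, 1, paste, collapse = "")
    if (!anyDuplicated(s)) return(s)
  }
}
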