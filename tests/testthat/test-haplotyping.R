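make_panel <- function(strings, sample_ids = NULL) {
  n <- length(strings)
  if (is.null(sample_ids))
    sample_ids <- rep(sprintf("S%02d", seq_len(ceiling(n / 2))),
                      each = 2)[seq_len(n)]
  phase <- ave(seq_len(n), sample_ids, FUN = seq_along)
  alle <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  haplotype_panel(loci = sprintf("L%02d", seq_len(nchar(strings[1]))),
                  sample_id = sample_ids, phase = phase, alleles = alle)
}

test_that("haplotype construction counts distinct allele vectors", {
  h <- random_haplotypes(3, 6)
  pan <- make_panel(rep(h, times = c(3, 2, 1)))
  tab <- construct_haplotypes(pan)
  expect_equal(tab$count, c(3, 2, 1))
  expect_equal(tab$frequency, c(0.5, 1/3, 1/6))
  expect_equal(sum(tab$frequency), 1)
  expect_equal(tab$haplotype[1], h[1])
  # single chromosome
  one <- haplotype_panel(loci = sprintf("L%02d", 1:6), sample_id = "S1",
                         phase = 1L,
                         alleles = matrix(c(1, 0, 0, 1, 1, 0), 1))
  expect_equal(construct_haplotypes(one)$frequency, 1)
  # chromosomes with missing calls are dropped and counted
  alle <- do.call(rbind, lapply(strsplit(rep(h, 2), ""), as.integer))
  alle[1, 3] <- NA
  panNA <- haplotype_panel(loci = sprintf("L%02d", 1:6),
                           sample_id = rep(c("A", "B", "C"), each = 2),
                           phase = rep(1:2, 3), alleles = alle)
  tabNA <- construct_haplotypes(panNA)
  expect_equal(attr(tabNA, "n_dropped"), 1)
  expect_equal(sum(tabNA$count), 5)
  empty <- haplotype_panel(loci = sprintf("L%02d", 1:6),
                           sample_id = character(0), phase = integer(0),
                           alleles = matrix(integer(0), 0, 6))
  expect_error(construct_haplotypes(empty), "empty")
})

test_that("naming keeps reserved identities and continues by frequency", {
  reserved <- data.frame(name = c("hap.1", "hap.2"),
                         haplotype = c("11000", "00110"))
  tab <- data.frame(haplotype = c("10101", "00110", "01010", "11111"),
                    count = c(40, 1, 30, 30),
                    frequency = c(40, 1, 30, 30) / 101)
  defs <- name_haplotypes(tab, reserved)
  # a rare vector matching a reserved definition keeps its name
  expect_equal(defs$name[defs$haplotype == "00110"], "hap.2")
  # most frequent novel vector gets the next free name (hap.3 here)
  expect_equal(defs$name[defs$haplotype == "10101"], "hap.3")
  # equal-frequency novels break ties lexicographically
  expect_equal(defs$name[defs$haplotype == "01010"], "hap.4")
  expect_equal(defs$name[defs$haplotype == "11111"], "hap.5")
  expect_error(name_haplotypes(tab, data.frame(
    name = c("hap.1", "hap.2"), haplotype = c("11000", "11000"))),
    "duplicate")
})

test_that("sixteen reserved names make the top novel haplotype hap.17", {
  res_file <- system.file("extdata", "reserved_haplotypes_synthetic.tsv",
                          package = "hdomics")
  reserved <- read_reserved_definitions(res_file)
  expect_equal(nrow(reserved), 16)
  expect_equal(nchar(reserved$haplotype[1]), 21)
  novel <- random_haplotypes(2)
  novel <- setdiff(novel, reserved$haplotype)[1]
  tab <- data.frame(haplotype = c(novel, reserved$haplotype[3]),
                    count = c(6, 4), frequency = c(0.6, 0.4))
  defs <- name_haplotypes(tab, reserved)
  expect_equal(defs$name, c("hap.17", "hap.3"))
})

test_that("diplotype assignment is exact-match and conclusive iff both phases", {
  defs <- data.frame(name = c("hap.1", "hap.2"),
                     haplotype = c("10110", "01001"))
  pan <- make_panel(c("10110", "10110",   # homozygous hap.1
                      "10110", "11111"))  # one novel phase
  asg <- assign_diplotypes(pan, defs)
  expect_equal(asg$hap1[1], "hap.1")
  expect_equal(asg$hap2[1], "hap.1")
  expect_true(asg$conclusive[1])
  expect_equal(asg$hap2[2], "unassigned")
  expect_false(asg$conclusive[2])
  expect_error(assign_diplotypes(make_panel(c("101", "010")), defs),
               "locus count")
})

test_that("construct + name + assign round trip is fully conclusive", {
  h <- random_haplotypes(4)
  tr <- sim_truth(haplotype_frequencies =
                    setNames(c(0.4, 0.3, 0.2, 0.1), h))
  pan <- gen_phased_panel(400, tr, seed = 17)
  defs <- name_haplotypes(construct_haplotypes(pan))
  asg <- assign_diplotypes(pan, defs)
  expect_true(all(asg$conclusive))
  expect_equal(sum(construct_haplotypes(pan)$frequency), 1)
})

test_that("naming is stable under panel input order", {
  h <- random_haplotypes(5)
  tr <- sim_truth(haplotype_frequencies =
                    setNames(c(0.3, 0.25, 0.2, 0.15, 0.1), h))
  pan <- gen_phased_panel(600, tr, seed = 19)
  defs <- name_haplotypes(construct_haplotypes(pan))
  set.seed(1)
  ord <- sample(nrow(pan$alleles))
  pan2 <- haplotype_panel(pan$loci, pan$sample_id[ord], pan$phase[ord],
                          pan$alleles[ord, ])
  defs2 <- name_haplotypes(construct_haplotypes(pan2))
  expect_equal(defs[order(defs$haplotype), ],
               defs2[order(defs2$haplotype), ], ignore_attr = TRUE)
})

test_that("binary distance is the Jaccard-style mismatch over the union", {
  d <- binary_distance_matrix(data.frame(name = c("a", "b"),
                                         haplotype = c("10110", "10011")))
  expect_equal(d["a", "b"], 0.5)  # 2 mismatches over a 4-locus union
  expect_equal(d["a", "a"], 0)
  d2 <- binary_distance_matrix(data.frame(name = c("a", "b"),
                                          haplotype = c("11000", "00111")))
  expect_equal(d2["a", "b"], 1)  # disjoint alternate-allele sets
  d0 <- binary_distance_matrix(data.frame(name = c("z", "a"),
                                          haplotype = c("00000", "10000")))
  expect_equal(d0["z", "z"], 0)  # all-zero pair convention
  expect_equal(d0["z", "a"], 1)
})

test_that("binary distance is a metric on all length-5 vectors", {
  vecs <- as.matrix(expand.grid(rep(list(0:1), 5)))
  D <- binary_distance_matrix(vecs)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  # identity of indiscernibles: distinct vectors are at positive distance
  # (the all-zero convention only affects the all-zero vector with itself)
  expect_true(all(D[lower.tri(D)] > 0))
  n <- nrow(vecs)
  viol <- 0
  for (i in 1:n) for (j in 1:n)
    viol <- viol + sum(D[i, j] > D[i, ] + D[, j] + 1e-12)
  expect_equal(viol, 0)
})

test_that("clustering recovers separated clades and exports Newick", {
  set.seed(23)
  centers <- random_haplotypes(3)
  # three clades: each center plus two one-locus variants
  strings <- unlist(lapply(centers, function(s) {
    v <- as.integer(strsplit(s, "")[[1]])
    c(s,
      paste(replace(v, 1, 1 - v[1]), collapse = ""),
      paste(replace(v, 2, 1 - v[2]), collapse = ""))
  }))
  defs <- data.frame(name = paste0("h", 1:9), haplotype = strings)
  cl <- cluster_haplotypes(defs, k = 3, seed = 2)
  expect_length(cl$dendrogram$order, 9)
  expect_true(same_partition(cl$clusters, rep(1:3, each = 3)))
  expect_match(cl$newick, "^\\(.*;$")
  expect_equal(sort(ape::read.tree(text = cl$newick)$tip.label),
               sort(defs$name))
  # k = 1: everything in one cluster
  cl1 <- cluster_haplotypes(defs, k = 1, seed = 2)
  expect_equal(unname(cl1$clusters), rep(1, 9))
  expect_error(cluster_haplotypes(defs[1:2, ], k = 3), "exceeds")
  # mutant partition clusters the two sets independently
  defs$mutant <- rep(c(FALSE, TRUE, FALSE), each = 3)
  clm <- cluster_haplotypes(defs, k = 2, mutant_partition = TRUE, seed = 2)
  expect_named(clm, c("normal", "mutant"))
  expect_length(clm$mutant$clusters, 3)
})
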