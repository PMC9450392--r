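test_that("signal filter keeps exactly the rows with >= 1 positive signal", {
  X <- rbind(rep(NA_real_, 10),           # all missing -> dropped
             row10(NA, "3" = 5),          # one present -> kept
             c(0, rep(NA, 9)),            # zero only -> dropped
             row10(100))                  # full row -> kept
  tb <- toy_psm_table(X)
  out <- filter_psms(tb)
  expect_equal(out$psm_id, c("psm2", "psm4"))
  empty <- filter_psms(toy_psm_table(X[0, , drop = FALSE]))
  expect_equal(nrow(empty$intensities), 0)
})

test_that("isotope correction solves the mixing system and clamps", {
  tb <- toy_psm_table(rbind(row10(100)))
  ident <- diag(10)
  expect_equal(correct_isotope_impurities(tb, ident)$intensities,
               tb$intensities)
  # 2-channel hand-solved system: [[.95,.05],[.05,.95]] %*% [100,0] = [95,5]
  M <- impurity_block(c(1, 2), c(0.95, 0.05))
  tb2 <- toy_psm_table(rbind(row10(100, "1" = 95, "2" = 5)))
  out <- correct_isotope_impurities(tb2, M)
  expect_equal(out$intensities[1, 1:2], c(`126` = 100, `127N` = 0))
  # observed [1, 0] gives a negative solution for channel 2 -> clamped
  tb3 <- toy_psm_table(rbind(row10(100, "1" = 1, "2" = 0)))
  out3 <- correct_isotope_impurities(tb3, M)
  expect_equal(unname(out3$intensities[1, 2]), 0)
  expect_gt(out3$intensities[1, 1], 1)
  # missing channels stay missing and are excluded from the system
  tb4 <- toy_psm_table(rbind(row10(100, "2" = NA)))
  out4 <- correct_isotope_impurities(tb4, M)
  expect_true(is.na(out4$intensities[1, 2]))
  expect_equal(unname(out4$intensities[1, 1]), 100 / 0.95)
  expect_error(correct_isotope_impurities(tb, matrix(1, 10, 10)),
               "ill-conditioned")
})

test_that("isotope correction round trip on random dominant matrices", {
  set.seed(42)
  for (i in 1:20) {
    M <- random_impurity()
    truth <- matrix(runif(50, 10, 1000), 5, 10)
    observed <- t(M %*% t(truth))
    tb <- toy_psm_table(observed)
    corr <- correct_isotope_impurities(tb, M)$intensities
    remixed <- t(M %*% t(corr))
    expect_lt(max(abs(remixed - observed) / observed), 1e-8)
    expect_lt(max(abs(corr - truth) / truth), 1e-8)
  }
})

test_that("sum-scaling equalizes channel sums at the median", {
  set.seed(5)
  X <- matrix(runif(200, 1, 100), 20, 10)
  tb <- toy_psm_table(X)
  out <- sum_scale_normalize(tb)
  M <- median(colSums(X))
  expect_equal(unname(colSums(out$intensities)), rep(M, 10),
               tolerance = 1e-12)
  # all channel sums equal -> unchanged
  tbE <- toy_psm_table(matrix(7, 5, 10))
  expect_equal(sum_scale_normalize(tbE)$intensities, tbE$intensities)
  # single PSM with 10 and 40 on two channels and 25 elsewhere: channel
  # sums [10, 40, 25 x 8] have median 25, so both scale to 25
  tb1 <- toy_psm_table(rbind(row10(25, "1" = 10, "2" = 40)))
  s1 <- sum_scale_normalize(tb1)
  expect_equal(unname(s1$intensities[1, 1:2]), c(25, 25))
  # an all-missing channel is left unscaled with a warning
  tb0 <- toy_psm_table(matrix(c(rep(1, 18), NA, NA), 2, 10))
  expect_warning(sum_scale_normalize(tb0), "zero sum")
  # the literal printed-protocol direction amplifies the high-sum channel
  lit <- sum_scale_normalize(tb, direction = "literal")
  expect_equal(unname(colSums(lit$intensities)),
               unname(colSums(X)^2 / M), tolerance = 1e-12)
})

test_that("reference log ratios handle the reference channel contract", {
  X <- rbind(row10(100),                      # sample == reference -> 0
             row10(100, "1" = 400),           # 4x reference -> 2
             row10(100, "10" = NA),           # reference missing
             row10(100, "10" = 0))            # reference zero
  tb <- toy_psm_table(X)
  R <- reference_log_ratios(tb)
  expect_equal(ncol(R), 9)
  expect_equal(unname(R[1, ]), rep(0, 9))
  expect_equal(unname(R[2, "126"]), 2)
  expect_true(all(is.na(R[3, ])))
  expect_true(all(is.na(R[4, ])))
  expect_equal(attr(R, "n_ref_missing"), 2)
})

test_that("peptide collapse applies shared/unassigned removal then max-mean", {
  m <- rbind(a1 = c(3, 3), a2 = c(5, 5), b = c(1, 1), c = c(2, 2))
  out <- collapse_to_peptides(m,
    peptide = c("pepA", "pepA", "pepB", "pepC"),
    protein_id = c("P1", "P1", NA, "P3"),
    shared_status = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(rownames(out), c("pepA"))  # pepB unassigned, pepC shared
  expect_equal(unname(out["pepA", ]), c(5, 5))  # the mean-5 PSM survives
  expect_equal(attr(out, "protein_id"), "P1")
  # no shared, one PSM per peptide -> identity
  out2 <- collapse_to_peptides(m[3:4, ], peptide = c("p3", "p4"),
                               protein_id = c("A", "B"),
                               shared_status = c(FALSE, FALSE))
  expect_equal(unname(out2), unname(m[3:4, ]), ignore_attr = TRUE)
})

test_that("protein aggregation keeps the max-mean peptide per protein", {
  m <- rbind(p1 = c(1, 1), p2 = c(2, 2), q1 = c(9, 9))
  out <- aggregate_to_proteins(m, protein_id = c("PA", "PA", "PB"))
  expect_equal(nrow(out), 2)
  expect_equal(unname(out["PA", ]), c(2, 2))
  expect_equal(unname(out["PB", ]), c(9, 9))
  expect_error(aggregate_to_proteins(m, protein_id = c("PA", NA, "PB")),
               "no protein")
})

test_that("noiseless pipeline recovers planted effects exactly", {
  prots <- sprintf("PROT%04d", 1:10)
  tr <- sim_truth(planted_effect_features = prots, effect_size = 2,
                  batch_shifts = c(plex1 = 0, plex2 = 1.5))
  ds <- gen_psm_dataset(2, 200, tr, missing_rate = 0, noise_sd = 0, seed = 9)
  pep <- process_psm_tables(ds$tables)
  labs <- rep(ds$truth$channel_groups, 2)
  est <- rowMeans(pep[, labs == "g2"]) - rowMeans(pep[, labs == "g1"])
  est <- est - median(est)  # channel-level constant is unidentifiable
  planted <- attr(pep, "protein_id") %in% prots
  expect_lt(max(abs(est[planted] - 2)), 1e-9)
  expect_lt(max(abs(est[!planted])), 1e-9)
  # protein-level aggregation preserves the recovery
  prot_mat <- aggregate_to_proteins(pep)
  estp <- rowMeans(prot_mat[, labs == "g2"]) - rowMeans(prot_mat[, labs == "g1"])
  estp <- estp - median(estp)
  expect_lt(max(abs(estp[rownames(prot_mat) %in% prots] - 2)), 1e-9)
})

test_that("stage order is stable: each stage feeds the next without renaming", {
  ds <- gen_psm_dataset(1, 100, sim_truth(), missing_rate = 0.2,
                        noise_sd = 0.3, seed = 13)
  tb <- ds$tables[[1]]
  f <- filter_psms(tb)
  c1 <- correct_isotope_impurities(f, diag(10))
  n1 <- sum_scale_normalize(c1)
  expect_identical(f$psm_id, c1$psm_id)
  expect_identical(c1$psm_id, n1$psm_id)
  R <- reference_log_ratios(n1)
  expect_identical(rownames(R), n1$psm_id)
})
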