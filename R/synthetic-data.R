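#' Simulation ground truth
#'
#' Container recording everything a generator planted into a synthetic
#' dataset, so downstream detectors and tests can be scored against the
#' truth: which features carry a true group effect and how large it is (in
#' log2 units), additive per-plex batch shifts, which samples were planted
#' as outliers, and the haplotype frequency spectrum a phased panel was
#' drawn from.
#'
#' @param planted_effect_features character vector of feature identifiers
#'   carrying a true group effect (may be empty).
#' @param effect_size group effect in log2 units; must be finite.
#' @param batch_shifts named numeric vector, additive log2 shift per batch
#'   (plex); may be empty.
#' @param outlier_samples character vector of planted outlier sample ids.
#' @param haplotype_frequencies named numeric vector mapping allele-vector
#'   strings (e.g. \code{"0101..."}) to frequencies; must sum to 1 when
#'   non-empty.
#' @param seed integer seed the generator used.
#'
#' @return An object of class \code{sim_truth}.
#' @export
sim_truth <- function(planted_effect_features = character(),
                      effect_size = 0,
                      batch_shifts = numeric(),
                      outlier_samples = character(),
                      haplotype_frequencies = numeric(),
                      seed = NA_integer_) {
  stopifnot(is.finite(effect_size))
  if (length(haplotype_frequencies)) {
    if (is.null(names(haplotype_frequencies)))
      stop("haplotype_frequencies must be named by allele-vector string")
    if (abs(sum(haplotype_frequencies) - 1) > 1e-9)
      stop("haplotype frequencies must sum to 1")
  }
  structure(list(planted_effect_features = as.character(planted_effect_features),
                 effect_size = effect_size,
                 batch_shifts = batch_shifts,
                 outlier_samples = as.character(outlier_samples),
                 haplotype_frequencies = haplotype_frequencies,
                 seed = seed),
            class = "sim_truth")
}

# Derive an independent substream seed from a module tag so generators
# called with the same global seed do not share random streams.
derive_seed <- function(seed, tag) {
  offsets <- c(cohort = 101L, psm = 211L, expr = 307L, panel = 401L)
  (as.integer(seed) * 7919L + offsets[[tag]]) %% .Machine$integer.max
}

#' Generate synthetic cohort metadata
#'
#' Draws participant records with the structure of a two-site HD
#' peripheral-tissue study: mutation carriers have an expanded CAG allele
#' in 40--55, all participants are aged 30--50, and groups are labeled
#' control / pre-HD / early-HD. Clinical scores respect the staging rules:
#' controls have TFC 13 and DCL 0, pre-HD participants have DCL <= 2, and
#' early-HD participants have TFC in 7--13 with DCL > 2. The disease
#' burden score is computed with \code{\link{compute_dbs}}.
#'
#' @param n_control,n_pre,n_early non-negative group sizes.
#' @param seed integer seed; the output is a pure function of the
#'   arguments.
#'
#' @return A data.frame of participant records with columns
#'   \code{subject_id}, \code{group}, \code{site}, \code{gender},
#'   \code{age}, \code{bmi}, \code{cag_short}, \code{cag_long},
#'   \code{dbs}, \code{tfc}, \code{dcl}.
#' @export
gen_cohort_metadata <- function(n_control, n_pre, n_early, seed = 1L) {
  if (any(c(n_control, n_pre, n_early) < 0))
    stop("group sizes must be non-negative")
  n <- n_control + n_pre + n_early
  cols <- c("subject_id", "group", "site", "gender", "age", "bmi",
            "cag_short", "cag_long", "dbs", "tfc", "dcl")
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    out$age <- out$bmi <- out$dbs <- numeric(0)
    out$cag_short <- out$cag_long <- out$tfc <- out$dcl <- integer(0)
    return(out)
  }
  set.seed(derive_seed(seed, "cohort"))
  group <- rep(c("control", "pre-HD", "early-HD"),
               times = c(n_control, n_pre, n_early))
  age <- round(runif(n, 30, 50), 1)
  gender <- sample(c("f", "m"), n, replace = TRUE)
  site <- sample(c(1L, 2L), n, replace = TRUE)
  bmi <- round(pmin(pmax(rnorm(n, 25, 3), 18), 30), 1)
  cag_short <- sample(15:25, n, replace = TRUE)
  carrier <- group != "control"
  cag_long <- ifelse(carrier, sample(40:55, n, replace = TRUE), NA_integer_)
  tfc <- integer(n)
  dcl <- integer(n)
  tfc[group == "control"] <- 13L
  dcl[group == "control"] <- 0L
  n_pre_i <- sum(group == "pre-HD")
  tfc[group == "pre-HD"] <- sample(11:13, n_pre_i, replace = TRUE)
  dcl[group == "pre-HD"] <- sample(0:2, n_pre_i, replace = TRUE)
  n_early_i <- sum(group == "early-HD")
  tfc[group == "early-HD"] <- sample(7:13, n_early_i, replace = TRUE)
  dcl[group == "early-HD"] <- sample(3:4, n_early_i, replace = TRUE)
  dbs <- rep(NA_real_, n)
  dbs[carrier] <- compute_dbs(cag_long[carrier], age[carrier])
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             group = group, site = site, gender = gender, age = age,
             bmi = bmi, cag_short = as.integer(cag_short),
             cag_long = as.integer(cag_long), dbs = dbs,
             tfc = tfc, dcl = dcl, stringsAsFactors = FALSE)
}

#' Generate synthetic TMT 10plex PSM tables
#'
#' Emulates reporter-intensity data from a TMT 10plex experiment: per-PSM
#' base abundances are log2-normal (default mean 20, SD 2 on the log2
#' scale), a planted group effect is added to the channels of the second
#' group, each plex carries an additive log2 batch shift, Gaussian log2
#' noise is added, true intensities are mixed by the isotopic impurity
#' matrix, and reporter cells are thinned missing-at-random. Channels 1--9
#' carry samples (alternating group 1 / group 2); channel 10 is the pooled
#' reference by default.
#'
#' @param n_plexes number of 10plex tables to generate (>= 1).
#' @param n_psms number of PSM rows per plex.
#' @param truth a \code{\link{sim_truth}}; \code{planted_effect_features}
#'   names the features (proteins) with a true effect of
#'   \code{effect_size} log2 units, and \code{batch_shifts} (if named
#'   \code{plex1}, \code{plex2}, ...) gives per-plex shifts.
#' @param missing_rate per-cell missing probability in [0, 1).
#' @param noise_sd log2-scale Gaussian noise SD.
#' @param impurities 10x10 impurity matrix used for mixing (default
#'   identity).
#' @param base_mean,base_sd log2-normal base abundance parameters.
#' @param reference_channel channel index of the pooled reference
#'   (default 10, the "131" label).
#' @param seed integer seed.
#'
#' @return A list with elements \code{tables} (a list of
#'   \code{\link{psm_table}} objects, one per plex) and \code{truth} (the
#'   input truth with \code{seed} recorded).
#' @export
gen_psm_dataset <- function(n_plexes, n_psms, truth = sim_truth(),
                            missing_rate = 0, noise_sd = 0.5,
                            impurities = diag(10),
                            base_mean = 20, base_sd = 2,
                            reference_channel = 10L, seed = 1L) {
  if (n_plexes < 1) stop("n_plexes must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  set.seed(derive_seed(seed, "psm"))
  ch_groups <- rep(c("g1", "g2"), length.out = 9)  # channels 1..9
  # fixed feature scaffold, identical across plexes: 4 PSMs per protein,
  # 2 peptides per protein (2 PSMs each)
  n_prot <- max(1L, n_psms %/% 4L)
  prot <- sprintf("PROT%04d", (seq_len(n_psms) - 1L) %/% 4L %% n_prot + 1L)
  pep <- paste0(prot, "_pep", (seq_len(n_psms) - 1L) %% 2L + 1L)
  tables <- vector("list", n_plexes)
  for (px in seq_len(n_plexes)) {
    shift <- truth$batch_shifts[paste0("plex", px)]
    if (is.null(shift) || is.na(shift)) shift <- 0
    base <- rnorm(n_psms, base_mean, base_sd)
    eff <- ifelse(prot %in% truth$planted_effect_features,
                  truth$effect_size, 0)
    log2int <- matrix(base + shift, n_psms, 10)
    g2 <- which(ch_groups == "g2")
    log2int[, g2] <- log2int[, g2] + eff
    # reference channel approximates the pooled sample: mean of the
    # sample channels on the log2 scale
    log2int[, reference_channel] <- rowMeans(log2int[, -reference_channel])
    if (noise_sd > 0)
      log2int <- log2int + matrix(rnorm(n_psms * 10, 0, noise_sd), n_psms, 10)
    intens <- 2^log2int
    intens <- t(impurities %*% t(intens))
    if (missing_rate > 0) {
      miss <- matrix(runif(n_psms * 10) < missing_rate, n_psms, 10)
      intens[miss] <- NA_real_
    }
    colnames(intens) <- tmt_channel_labels()
    tables[[px]] <- psm_table(
      intensities = intens,
      psm_id = sprintf("plex%d_psm%05d", px, seq_len(n_psms)),
      peptide = pep, protein_id = prot,
      shared_status = rep(FALSE, n_psms),
      plex_id = paste0("plex", px), run_id = paste0("run", px),
      reference_channel = reference_channel)
  }
  truth$seed <- seed
  truth$channel_groups <- ch_groups
  list(tables = tables, truth = truth)
}

#' Generate an expression matrix with planted outlier samples
#'
#' Non-outlier samples are drawn from a common Gaussian distribution
#' (independent features, per-feature SD 1). Each planted outlier sample
#' is shifted by \code{shift_sd} feature-SDs on a random half of the
#' features.
#'
#' @param n_features,n_samples matrix dimensions.
#' @param outliers number of planted outlier samples (<= n_samples).
#' @param shift_sd outlier shift in feature-SD multiples.
#' @param seed integer seed.
#'
#' @return List with \code{matrix} (features x samples, dimnames set) and
#'   \code{truth} (a \code{\link{sim_truth}} with
#'   \code{outlier_samples}).
#' @export
gen_expression_matrix <- function(n_features, n_samples, outliers = 0,
                                  shift_sd = 10, seed = 1L) {
  if (n_features < 1) stop("n_features must be >= 1")
  if (outliers > n_samples) stop("outliers must be <= n_samples")
  set.seed(derive_seed(seed, "expr"))
  m <- matrix(rnorm(n_features * n_samples), n_features, n_samples,
              dimnames = list(sprintf("feat%04d", seq_len(n_features)),
                              sprintf("samp%02d", seq_len(n_samples))))
  out_ids <- character(0)
  if (outliers > 0) {
    idx <- sample.int(n_samples, outliers)
    out_ids <- colnames(m)[idx]
    for (j in idx) {
      hit <- sample.int(n_features, n_features %/% 2L)
      m[hit, j] <- m[hit, j] + shift_sd
    }
  }
  list(matrix = m,
       truth = sim_truth(outlier_samples = out_ids, seed = seed))
}

#' Generate a phased haplotype panel from a frequency spectrum
#'
#' Chromosomes are drawn i.i.d. from the stated haplotype frequencies and
#' paired into samples (phase 1/2), emulating phased genotypes at the 21
#' HTT-region defining variants.
#'
#' @param n_chromosomes number of chromosomes to draw (paired into
#'   \code{n_chromosomes / 2} samples; must be even).
#' @param truth a \code{\link{sim_truth}} whose
#'   \code{haplotype_frequencies} is a named vector over allele-vector
#'   strings of length \code{n_loci} (characters "0"/"1").
#' @param n_loci number of loci (default 21, the HTT defining-variant
#'   count: 20 SNPs and the rs149109767 indel).
#' @param seed integer seed.
#'
#' @return A \code{\link{haplotype_panel}}.
#' @export
gen_phased_panel <- function(n_chromosomes, truth, n_loci = 21L, seed = 1L) {
  freqs <- truth$haplotype_frequencies
  if (!length(freqs)) stop("truth$haplotype_frequencies is empty")
  if (any(nchar(names(freqs)) != n_loci))
    stop("allele-vector strings must have length n_loci")
  if (n_chromosomes %% 2L != 0L) stop("n_chromosomes must be even")
  set.seed(derive_seed(seed, "panel"))
  draws <- sample(names(freqs), n_chromosomes, replace = TRUE, prob = freqs)
  alle <- do.call(rbind, lapply(strsplit(draws, ""), as.integer))
  n_samp <- n_chromosomes %/% 2L
  haplotype_panel(
    loci = c(sprintf("rs_sim%02d", seq_len(n_loci - 1L)), "rs149109767"),
    sample_id = rep(sprintf("HAP%04d", seq_len(n_samp)), each = 2L),
    phase = rep(c(1L, 2L), n_samp),
    alleles = alle)
}

tmt_channel_labels <- function() {
  c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N", "130C",
    "131")
}
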