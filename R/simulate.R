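# Generative model for cross-species two-color genomic hybridizations.
#
# The design emulated throughout: heterologous FEMALE genomic DNA (test) is
# competitively hybridized against platform-species MALE DNA (reference), so
# X-linked features carry a known 2:1 copy difference (log2 ratio +1) and
# autosomal features 2:2 (log2 ratio 0). Sequence divergence of the test
# species to the platform probes attenuates its hybridization efficiency
# linearly, which both depresses heterologous log ratios genome-wide and
# masks true duplications at high divergence.

#' Divergence model presets
#'
#' Truncated-normal sequence-identity distributions of the heterologous
#' species to the platform probes. \code{"platform"} is the within-species
#' control (identity exactly 1), \code{"simulans_like"} a closely related
#' species (~94-98\% identity), \code{"yakuba_like"} a more distant one
#' (~88-96\%).
#'
#' @param species One of \code{"platform"}, \code{"simulans_like"},
#'   \code{"yakuba_like"}.
#' @return A list with \code{mean_identity}, \code{sd_identity},
#'   \code{min_identity}.
#' @export
divergence_model <- function(species = c("simulans_like", "yakuba_like",
                                         "platform")) {
  species <- match.arg(species)
  switch(species,
         platform      = list(mean_identity = 1.00, sd_identity = 0,
                              min_identity = 1.00),
         simulans_like = list(mean_identity = 0.96, sd_identity = 0.020,
                              min_identity = 0.75),
         yakuba_like   = list(mean_identity = 0.92, sd_identity = 0.025,
                              min_identity = 0.75))
}

#' Build a simulation configuration
#'
#' Defaults describe the emulated study conditions: 18,849 analyzable
#' features of which ~16.7\% are X-linked, six dye-swapped arrays, a linear
#' identity-to-efficiency slope, probe-specific bias shared across arrays,
#' per-array measurement noise, an intensity-dependent dye trend, and rare
#' genome-difference confounders (paralog families, movement on/off the X,
#' deletion, heterochromatin).
#'
#' @param n_features Number of array features.
#' @param x_fraction Fraction of features that are X-linked.
#' @param n_arrays Number of hybridizations (dye-swap balanced).
#' @param species Divergence preset name, see \code{\link{divergence_model}}.
#' @param divergence Optional explicit divergence model list overriding
#'   \code{species}.
#' @param beta_div Efficiency loss per unit identity loss; hybridization
#'   efficiency is \code{max(cross_hyb_floor, 1 - beta_div * (1 - identity))}.
#' @param cross_hyb_floor Residual non-specific hybridization efficiency of a
#'   present but strongly diverged locus.
#' @param sigma_feature SD (log2) of the probe-specific effect shared across
#'   arrays.
#' @param sigma_array SD (log2) of per-array, per-feature measurement noise.
#' @param dye_amplitude Amplitude (log2) of the smooth cubic dye trend in
#'   centered A; sign flips with dye orientation.
#' @param a_mean,a_sd Mean and SD of per-feature log2 abundance A.
#' @param bg_mean,bg_sd Mean and SD of additive background fluorescence.
#' @param confounder_probs Named list of per-feature probabilities:
#'   \code{paralog_family}, \code{move_off_x}, \code{move_onto_x},
#'   \code{deletion}, \code{heterochromatic}.
#' @param het_suppression Multiplicative signal suppression for
#'   heterochromatic features (both channels).
#' @param het_jitter_sd SD (natural log) of independent per-channel lognormal
#'   jitter for heterochromatic features.
#' @param paralog_shared_prob Probability that a platform paralog is also
#'   present in the heterologous genome (the joint divergence of paralog
#'   pairs is not constrained by the emulated study; exposed as a knob).
#' @param test_sex Sex of the test sample; the reference is always the
#'   platform male. \code{"female"} gives X features the 2:1 copy difference
#'   that serves as ground-truth duplication; \code{"male"} gives a null
#'   experiment with all copy ratios equal.
#' @param seed Integer seed; the same seed reproduces all tables exactly.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_features = 18849,
                       x_fraction = 0.167,
                       n_arrays = 6,
                       species = "simulans_like",
                       divergence = NULL,
                       beta_div = 10.5,
                       cross_hyb_floor = 0.05,
                       sigma_feature = 0.2,
                       sigma_array = 0.45,
                       dye_amplitude = 0.3,
                       a_mean = 12, a_sd = 1,
                       bg_mean = 80, bg_sd = 30,
                       confounder_probs = list(paralog_family = 0.05,
                                               move_off_x = 0.05,
                                               move_onto_x = 0.01,
                                               deletion = 0.03,
                                               heterochromatic = 0.007),
                       het_suppression = 0.3,
                       het_jitter_sd = 0.5,
                       paralog_shared_prob = 0.5,
                       test_sex = c("female", "male"),
                       seed = 1) {
  test_sex <- match.arg(test_sex)
  if (is.null(divergence)) divergence <- divergence_model(species)
  cfg <- list(n_features = as.integer(n_features),
              x_fraction = x_fraction,
              n_arrays = as.integer(n_arrays),
              species = species,
              divergence = divergence,
              beta_div = beta_div,
              cross_hyb_floor = cross_hyb_floor,
              sigma_feature = sigma_feature,
              sigma_array = sigma_array,
              dye_amplitude = dye_amplitude,
              a_mean = a_mean, a_sd = a_sd,
              bg_mean = bg_mean, bg_sd = bg_sd,
              confounder_probs = confounder_probs,
              het_suppression = het_suppression,
              het_jitter_sd = het_jitter_sd,
              paralog_shared_prob = paralog_shared_prob,
              test_sex = test_sex,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  probs <- unlist(cfg$confounder_probs)
  if (any(probs < 0 | probs > 1)) {
    cgh_stop("sim_config: confounder probabilities must lie in [0, 1]",
             "crosscgh_config_error")
  }
  if (cfg$x_fraction < 0 || cfg$x_fraction > 1) {
    cgh_stop("sim_config: x_fraction must lie in [0, 1]",
             "crosscgh_config_error")
  }
  sds <- c(cfg$sigma_feature, cfg$sigma_array, cfg$a_sd, cfg$bg_sd,
           cfg$het_jitter_sd, cfg$divergence$sd_identity)
  if (any(sds < 0)) {
    cgh_stop("sim_config: standard deviations must be >= 0",
             "crosscgh_config_error")
  }
  if (cfg$beta_div < 0) {
    cgh_stop("sim_config: beta_div must be >= 0", "crosscgh_config_error")
  }
  if (floor(cfg$n_features * cfg$x_fraction) < 10) {
    cgh_stop("sim_config: fewer than 10 X-linked features; too few positives to evaluate",
             "crosscgh_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Hybridization efficiency as a function of sequence identity
#'
#' Linear-with-clamp model: \code{h(id) = max(floor, 1 - beta_div * (1 -
#' id))}. Perfect identity hybridizes at full efficiency; efficiency declines
#' linearly with divergence and is clamped below. The default clamp is zero;
#' the simulator passes a small positive \code{floor} representing residual
#' non-specific cross-hybridization, which keeps strongly diverged loci dimly
#' visible rather than perfectly dark.
#'
#' @param identity Sequence identity in [0, 1] (vectorized).
#' @param beta_div Slope, efficiency lost per unit identity loss.
#' @param floor Lower clamp for the efficiency.
#' @return Efficiency in [\code{floor}, 1].
#' @export
hybridization_efficiency <- function(identity, beta_div, floor = 0) {
  if (any(identity < 0 | identity > 1, na.rm = TRUE)) {
    cgh_stop("hybridization_efficiency: identity must lie in [0, 1]",
             "crosscgh_domain_error")
  }
  pmax(floor, 1 - beta_div * (1 - identity))
}

#' @noRd
rtruncnorm1 <- function(n, mean, sd, lower, upper = 1) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' @noRd
default_genome_meta <- function(genome) {
  data.frame(chromosome = c("X", "2L", "2R", "3L", "3R", "4",
                            "XHet", "2RHet", "3LHet"),
             length_bp = c(22.4e6, 23.0e6, 21.1e6, 24.5e6, 27.9e6, 1.35e6,
                           0.20e6, 3.30e6, 2.55e6),
             is_x = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      TRUE, FALSE, FALSE),
             is_heterochromatin = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                                    TRUE, TRUE, TRUE),
             stringsAsFactors = FALSE) -> df
  attr(df, "genome") <- genome
  df
}

#' Simulate ground truth for one heterologous-vs-platform experiment
#'
#' Generates the feature annotation, the per-feature/per-locus ground truth
#' and the genome metadata of both genomes. X assignment is deterministic:
#' the first \code{floor(n_features * x_fraction)} features are X-linked.
#' Confounders are drawn independently at the configured probabilities.
#' Conserved normalization sets are the features of highest test-species
#' identity (sizes 1000 and 100 at the default array size, scaled down as
#' \code{max(10, round(0.053 n))} and \code{max(5, round(0.005 n))} for
#' smaller arrays), emulating selection of genes conserved across species.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with elements \code{annotation}, \code{truth} (list with
#'   \code{features} and \code{loci} data frames), \code{meta_ref},
#'   \code{meta_het}.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_features
  n_x <- floor(n * config$x_fraction)
  meta_ref <- default_genome_meta("platform")
  meta_het <- default_genome_meta(config$species)

  ids <- sprintf("f%05d", seq_len(n))
  is_x <- c(rep(TRUE, n_x), rep(FALSE, n - n_x))
  autosomes <- c("2L", "2R", "3L", "3R")
  chrom <- ifelse(is_x, "X", sample(autosomes, n, replace = TRUE))
  length_bp <- pmax(150L, as.integer(round(stats::rnorm(n, 500, 60))))
  chrom_len <- meta_ref$length_bp[match(chrom, meta_ref$chromosome)]
  position <- as.integer(floor(stats::runif(n) * (chrom_len - length_bp))) + 1L
  gc <- pmin(0.8, pmax(0.2, stats::rnorm(n, 0.45, 0.05)))

  dv <- config$divergence
  identity_test <- rtruncnorm1(n, dv$mean_identity, dv$sd_identity,
                               dv$min_identity, 1)

  cp <- config$confounder_probs
  paralog_family <- stats::runif(n) < cp$paralog_family
  move_off_x <- is_x & stats::runif(n) < cp$move_off_x
  move_onto_x <- !is_x & stats::runif(n) < cp$move_onto_x
  deleted <- stats::runif(n) < cp$deletion
  heterochromatic <- stats::runif(n) < cp$heterochromatic

  # heterochromatic features live on heterochromatin-flagged scaffolds
  het_scaffold <- ifelse(is_x, "XHet",
                         sample(c("2RHet", "3LHet"), n, replace = TRUE))
  chrom[heterochromatic] <- het_scaffold[heterochromatic]
  chrom_len2 <- meta_ref$length_bp[match(chrom, meta_ref$chromosome)]
  relocate <- heterochromatic
  position[relocate] <- as.integer(floor(
    stats::runif(sum(relocate)) * (chrom_len2[relocate] - length_bp[relocate]))) + 1L

  # conserved sets: highest test-species identity (ties: lowest index)
  if (n >= 18849L) {
    n_c1000 <- 1000L; n_c100 <- 100L
  } else {
    n_c1000 <- max(10L, as.integer(round(0.053 * n)))
    n_c100 <- max(5L, as.integer(round(0.005 * n)))
  }
  # ties (e.g. the within-species control, identity all 1) broken by a random
  # permutation so the conserved sets stay genome-wide, not position-ordered
  rank_idx <- order(-identity_test, sample.int(n))
  conserved_1000 <- logical(n); conserved_1000[rank_idx[seq_len(n_c1000)]] <- TRUE
  conserved_100 <- logical(n); conserved_100[rank_idx[seq_len(n_c100)]] <- TRUE

  annotation <- data.frame(feature_id = ids, chromosome = chrom,
                           position_bp = position, is_x = is_x,
                           conserved_1000 = conserved_1000,
                           conserved_100 = conserved_100,
                           length_bp = length_bp, gc_fraction = gc,
                           stringsAsFactors = FALSE)

  # ---- loci -----------------------------------------------------------------
  # primary locus: platform copies are 1 for X (male reference) and 2 for
  # autosomes; heterologous female copies are 2 wherever the locus exists
  chrom_het <- chrom
  moved_auto <- sample(autosomes, n, replace = TRUE)
  chrom_het[move_off_x] <- moved_auto[move_off_x]
  chrom_het[deleted] <- NA_character_
  pos_het <- position
  pos_het[move_off_x] <- as.integer(floor(stats::runif(sum(move_off_x)) *
    (meta_het$length_bp[match(chrom_het[move_off_x], meta_het$chromosome)] -
       length_bp[move_off_x]))) + 1L

  # copies per locus: reference is always the platform male (1 copy of X
  # loci, 2 of autosomal); test copies depend on the test sample's sex
  test_copies <- function(chrom_het_vec, present) {
    on_x <- chrom_het_vec %in% c("X", "XHet")
    cp <- if (config$test_sex == "female") {
      rep(2L, length(chrom_het_vec))
    } else {
      ifelse(on_x, 1L, 2L)
    }
    ifelse(present, cp, 0L)
  }
  loci <- data.frame(feature_id = ids,
                     locus = "primary",
                     chrom_ref = chrom, pos_ref = position,
                     chrom_het = chrom_het, pos_het = pos_het,
                     identity_ref = 1.0,
                     identity_het = ifelse(deleted, NA_real_, identity_test),
                     copies_ref = ifelse(is_x, 1L, 2L),
                     copies_test = test_copies(chrom_het, !deleted),
                     stringsAsFactors = FALSE)

  # deletion dominates: a deleted feature has no heterologous loci at all
  # extra X-linked duplicate in the heterologous genome (movement onto X)
  k <- which(move_onto_x & !deleted)
  if (length(k) > 0L) {
    xlen <- meta_het$length_bp[meta_het$chromosome == "X"]
    loci_x <- data.frame(feature_id = ids[k], locus = "onto_x",
                         chrom_ref = NA_character_, pos_ref = NA_integer_,
                         chrom_het = "X",
                         pos_het = as.integer(floor(stats::runif(length(k)) *
                                                      (xlen - length_bp[k]))) + 1L,
                         identity_ref = NA_real_,
                         identity_het = identity_test[k],
                         copies_ref = 0L,
                         copies_test = test_copies(rep("X", length(k)), TRUE),
                         stringsAsFactors = FALSE)
    loci <- rbind(loci, loci_x)
  }

  # autosomal paralog family members, always in the platform genome and
  # shared with the heterologous genome at paralog_shared_prob
  k <- which(paralog_family)
  if (length(k) > 0L) {
    n_par <- 1L + stats::rbinom(length(k), 1L, 0.5)
    fk <- rep(k, n_par)
    m <- length(fk)
    par_chr <- sample(autosomes, m, replace = TRUE)
    par_id <- stats::runif(m, 0.85, 0.99)
    shared <- stats::runif(m) < config$paralog_shared_prob & !deleted[fk]
    par_len <- meta_ref$length_bp[match(par_chr, meta_ref$chromosome)]
    par_pos <- as.integer(floor(stats::runif(m) * (par_len - length_bp[fk]))) + 1L
    loci_p <- data.frame(feature_id = ids[fk], locus = "paralog",
                         chrom_ref = par_chr, pos_ref = par_pos,
                         chrom_het = ifelse(shared, par_chr, NA_character_),
                         pos_het = ifelse(shared, par_pos, NA_integer_),
                         identity_ref = par_id,
                         identity_het = ifelse(shared,
                                               par_id * identity_test[fk],
                                               NA_real_),
                         copies_ref = 2L,
                         copies_test = ifelse(shared, 2L, 0L),
                         stringsAsFactors = FALSE)
    loci <- rbind(loci, loci_p)
  }
  rownames(loci) <- NULL

  features <- data.frame(feature_id = ids,
                         is_x = is_x,
                         copies_test = loci$copies_test[match(ids, loci$feature_id)],
                         copies_ref = loci$copies_ref[match(ids, loci$feature_id)],
                         identity_test = identity_test,
                         identity_ref = 1.0,
                         paralog_family = paralog_family,
                         moved_off_x = move_off_x,
                         moved_onto_x = move_onto_x,
                         deleted = deleted,
                         heterochromatic = heterochromatic,
                         stringsAsFactors = FALSE)

  list(annotation = annotation,
       truth = list(features = features, loci = loci, config = config),
       meta_ref = meta_ref, meta_het = meta_het)
}

#' Expected log2 hybridization ratio of each feature
#'
#' Competitive-hybridization expectation over all loci a probe can capture:
#' \deqn{M = \log_2 \frac{\sum_l c^{test}_l \, h(id^{test}_l)}{\sum_l
#'   c^{ref}_l \, h(id^{ref}_l)}}
#' where the sum runs over the probe's target locus plus any paralogous or
#' duplicated loci, \eqn{c} are per-sample copy numbers and \eqn{h} is
#' \code{\link{hybridization_efficiency}}. Heterochromatic signal suppression
#' scales both channel sums equally and therefore cancels in \eqn{M}; its
#' asymmetric per-channel jitter is applied at the array stage.
#'
#' @param truth Output \code{truth} element of \code{\link{simulate_truth}}.
#' @param beta_div Efficiency slope (defaults to the config's value).
#' @param cross_hyb_floor Efficiency floor (defaults to the config's value).
#' @return Data frame with \code{feature_id}, channel sums \code{t_sum},
#'   \code{r_sum}, and \code{m_expected} (\code{-Inf} when the test channel
#'   sum is zero; a zero reference sum marks a dropout and yields \code{NA}).
#' @export
expected_log_ratio <- function(truth, beta_div = truth$config$beta_div,
                               cross_hyb_floor = truth$config$cross_hyb_floor) {
  loci <- truth$loci
  h_test <- ifelse(is.na(loci$identity_het), 0,
                   hybridization_efficiency(
                     ifelse(is.na(loci$identity_het), 1, loci$identity_het),
                     beta_div, cross_hyb_floor))
  h_ref <- ifelse(is.na(loci$identity_ref), 0,
                  hybridization_efficiency(
                    ifelse(is.na(loci$identity_ref), 1, loci$identity_ref),
                    beta_div, cross_hyb_floor))
  t_contrib <- loci$copies_test * h_test
  r_contrib <- loci$copies_ref * h_ref
  ids <- truth$features$feature_id
  fi <- match(loci$feature_id, ids)
  t_sum <- as.numeric(tapply_sum(t_contrib, fi, length(ids)))
  r_sum <- as.numeric(tapply_sum(r_contrib, fi, length(ids)))
  m <- ifelse(r_sum <= 0, NA_real_,
              ifelse(t_sum <= 0, -Inf, log2(t_sum / r_sum)))
  data.frame(feature_id = ids, t_sum = t_sum, r_sum = r_sum,
             m_expected = m, stringsAsFactors = FALSE)
}

#' @noRd
tapply_sum <- function(x, idx, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Build a dye-swap balanced hybridization design
#'
#' @param n_arrays Number of arrays.
#' @param test_sample Label for the test sample.
#' @param reference_sample Label for the common reference.
#' @return Design data frame with alternating dye orientations.
#' @export
make_design <- function(n_arrays, test_sample = "het_female",
                        reference_sample = "platform_male") {
  data.frame(array_id = sprintf("array%02d", seq_len(n_arrays)),
             test_sample = test_sample,
             reference_sample = reference_sample,
             dye_orientation = rep_len(c(1L, -1L), n_arrays),
             stringsAsFactors = FALSE)
}

#' @noRd
dye_curve <- function(A, a_mean, a_sd, amplitude) {
  if (a_sd <= 0) return(rep(0, length(A)))
  z <- (A - a_mean) / a_sd
  amplitude * (z^3 - 3 * z) / 6
}

#' Simulate scan tables for a set of arrays
#'
#' Per feature, a log2 abundance A is drawn once (shared across arrays) and a
#' probe-specific effect (SD \code{sigma_feature}) shifts the true log ratio
#' identically on every array. Per array, the observed (orientation-resolved)
#' log ratio is the expected ratio plus the probe effect, the dye-bias curve
#' times orientation, and measurement noise (SD \code{sigma_array}). Channel
#' intensities are reconstructed from (A, M), heterochromatic suppression and
#' per-channel lognormal jitter applied, foregrounds offset by truncated
#' normal backgrounds, and channels assigned to fg1/fg2 by dye orientation.
#'
#' @param truth Truth list from \code{\link{simulate_truth}}.
#' @param design Design data frame (\code{\link{make_design}}).
#' @param config The \code{\link{sim_config}} used to generate \code{truth}.
#' @return One scan table data frame covering all arrays.
#' @export
simulate_arrays <- function(truth, design, config = truth$config) {
  feats <- truth$features
  n <- nrow(feats)
  exp_lr <- expected_log_ratio(truth, config$beta_div)
  A <- stats::rnorm(n, config$a_mean, config$a_sd)
  fe <- stats::rnorm(n, 0, config$sigma_feature)
  t_sum <- exp_lr$t_sum
  r_sum <- exp_lr$r_sum
  # channel scale: recovers 2^(A +/- M/2) when both sums are positive,
  # degrades gracefully to a dark channel when one sum is zero
  c0 <- ifelse(t_sum > 0 & r_sum > 0, sqrt(t_sum * r_sum),
               pmax((t_sum + r_sum) / 2, 1e-12))
  het <- feats$heterochromatic
  supp <- ifelse(het, config$het_suppression, 1)

  out <- vector("list", nrow(design))
  for (j in seq_len(nrow(design))) {
    ori <- design$dye_orientation[j]
    m_arr <- fe + ori * dye_curve(A, config$a_mean, config$a_sd,
                                  config$dye_amplitude) +
      stats::rnorm(n, 0, config$sigma_array)
    half <- 2^(m_arr / 2)
    ch_test <- 2^A * (t_sum / c0) * half * supp
    ch_ref <- 2^A * (r_sum / c0) / half * supp
    if (any(het)) {
      ch_test[het] <- ch_test[het] * exp(stats::rnorm(sum(het), 0,
                                                      config$het_jitter_sd))
      ch_ref[het] <- ch_ref[het] * exp(stats::rnorm(sum(het), 0,
                                                    config$het_jitter_sd))
    }
    bg1 <- pmax(0, stats::rnorm(n, config$bg_mean, config$bg_sd))
    bg2 <- pmax(0, stats::rnorm(n, config$bg_mean, config$bg_sd))
    bga1 <- pmax(0, stats::rnorm(n, config$bg_mean, config$bg_sd))
    bga2 <- pmax(0, stats::rnorm(n, config$bg_mean, config$bg_sd))
    if (ori == 1L) {
      fg1 <- ch_test + bga1; fg2 <- ch_ref + bga2
    } else {
      fg1 <- ch_ref + bga1; fg2 <- ch_test + bga2
    }
    out[[j]] <- data.frame(array_id = design$array_id[j],
                           feature_id = feats$feature_id,
                           fg1 = fg1, bg1 = bg1, bg1_sd = config$bg_sd,
                           fg2 = fg2, bg2 = bg2, bg2_sd = config$bg_sd,
                           qc_flag = "ok",
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @noRd
sim_evalue <- function(identity, length_bp) {
  pmax(10^-(15 + 600 * pmax(0, identity - 0.75) * length_bp / 500), 1e-180)
}

#' Fabricate BLAST-style hit tables consistent with the ground truth
#'
#' Every locus present in a genome emits one tabular hit record on its
#' chromosome at its position, with percent identity equal to the true
#' sequence identity and an E-value scaling with identity and probe length
#' (always below 1e-14 for a real locus). Deleted loci emit no heterologous
#' hits; relocated loci emit hits on their new chromosome class; paralog
#' family members emit one extra hit per member.
#'
#' @param truth Truth list from \code{\link{simulate_truth}}.
#' @param annotation Feature annotation from the same simulation.
#' @return List with \code{het} and \code{ref} hit tables.
#' @export
simulate_hit_tables <- function(truth, annotation) {
  loci <- truth$loci
  len <- annotation$length_bp[match(loci$feature_id, annotation$feature_id)]

  make_hits <- function(chrom, pos, identity, genome) {
    keep <- !is.na(chrom)
    id <- pmin(1, identity[keep])
    l <- len[keep]
    df <- data.frame(query_id = loci$feature_id[keep],
                     subject_chromosome = chrom[keep],
                     percent_identity = round(100 * id, 2),
                     align_length = l,
                     mismatches = as.integer(round((1 - id) * l)),
                     gaps = 0L,
                     q_start = 1L, q_end = l,
                     subject_start = pos[keep],
                     subject_end = pos[keep] + l - 1L,
                     e_value = sim_evalue(id, l),
                     bitscore = round(1.8 * l * id, 1),
                     stringsAsFactors = FALSE)
    attr(df, "subject_genome") <- genome
    df
  }
  list(het = make_hits(loci$chrom_het, loci$pos_het, loci$identity_het,
                       attr(truth, "species")),
       ref = make_hits(loci$chrom_ref, loci$pos_ref, loci$identity_ref,
                       "platform"))
}

#' Simulate a complete experiment
#'
#' Convenience wrapper running \code{\link{simulate_truth}},
#' \code{\link{make_design}}, \code{\link{simulate_arrays}} and
#' \code{\link{simulate_hit_tables}} under the config's seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{annotation}, \code{truth}, \code{meta_ref},
#'   \code{meta_het}, \code{design}, \code{scans}, \code{hits_het},
#'   \code{hits_ref}.
#' @export
simulate_experiment <- function(config) {
  tr <- simulate_truth(config)
  design <- make_design(config$n_arrays, test_sample = config$species)
  scans <- simulate_arrays(tr$truth, design, config)
  hits <- simulate_hit_tables(tr$truth, tr$annotation)
  list(annotation = tr$annotation, truth = tr$truth,
       meta_ref = tr$meta_ref, meta_het = tr$meta_het,
       design = design, scans = scans,
       hits_het = hits$het, hits_ref = hits$ref)
}
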