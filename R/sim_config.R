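#' Simulation configuration for the synthetic reporter/CRISPRa generator
#'
#' Builds the single configuration object consumed by every simulator in the
#' package: the synthetic genome (chromatin-state segmentation, histone-mark
#' tracks, TADs, genes), the barcoded reporter pool with its piggyBac-style
#' AT-rich insertion bias, inverse-PCR reads and gDNA/cDNA amplicon count
#' tables, and the single-cell CRISPRa dataset drawn from the two-latent-state
#' negative-binomial model.
#'
#' The negative-binomial parameterisation used throughout the package is
#' variance = mu + mu^2/theta (theta is the \code{size} of
#' \code{\link[stats]{dnbinom}}).
#'
#' @param seed integer seed; identical configurations give byte-identical
#'   outputs.
#' @param n_chromosomes number of synthetic chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param n_states number of chromatin states (labels "E1".."E<n>").
#' @param segment_length_mean mean chromatin-state segment length in bp.
#' @param state_probs sampling probabilities over states for each segment;
#'   defaults to uniform.
#' @param n_insertions number of reporter insertions in the pool.
#' @param at_bias_strength non-negative strength of the AT-rich insertion
#'   bias; 0 means uniform insertion.
#' @param basal_mu_by_state per-state mean of log basal expression score.
#' @param basal_sigma_by_state per-state sd of log basal expression score.
#' @param frac_silent probability a reporter has undetectable basal
#'   expression (no cDNA signal).
#' @param tad_fraction fraction of the genome covered by TADs.
#' @param tad_length_mean mean TAD length in bp.
#' @param tad_shift_sd sd of the per-TAD, per-timepoint shared log-expression
#'   shift (drives within-TAD expression correlation).
#' @param lfc_sd sd of the per-reporter log fold change of basal expression
#'   between day 0 and day 5 of differentiation.
#' @param decay_params named vector (A, k, C) of the exponential-decay
#'   activation model: log fold activation = A*exp(-k*log basal) + C.
#' @param state_deviation_by_state per-state additive deviation (natural-log
#'   fold units) from the decay model; defaults boost the bivalent state and
#'   damp the H3K9me3 state.
#' @param activation_noise_sd sd of Gaussian noise on log fold activation.
#' @param gdna_depth_mean mean gDNA reads per barcode per replicate.
#' @param cdna_depth_scale cDNA reads per unit expression at nominal gDNA
#'   depth.
#' @param n_replicates biological replicates per condition.
#' @param ipcr_depth_mean mean inverse-PCR reads per barcode per enzyme.
#' @param ipcr_detect_prob named probabilities (TatI, MspI) that a barcode is
#'   recovered at all by each enzyme's digestion; the defaults give roughly
#'   three quarters of barcodes mapped independently by both enzymes.
#' @param malformed_read_frac fraction of structurally malformed inverse-PCR
#'   reads injected.
#' @param flank_length genomic flank length (nt) carried by each inverse-PCR
#'   read.
#' @param nb_beta0_by_state per-state basal intercept of the single-cell
#'   negative-binomial model (log scale, per total-UMI offset).
#' @param nb_beta_act_by_state per-state activation coefficient (log fold
#'   increase basal to active).
#' @param nb_theta_by_state per-state dispersion.
#' @param nb_pi_by_state per-state prior probability that a perturbed cell is
#'   in the active latent state.
#' @param total_umi_lognormal (meanlog, sdlog) of per-cell total UMI counts.
#' @param guides_per_target guides designed per target gene.
#' @param guide_multiplicity_probs probability distribution over 0..8 captured
#'   guides per cell; defaults follow the observed multiplicity spectrum
#'   (6.1\% zero, 81.27\% one to five, 12.63\% more than five).
#' @param sc_scramble_frac fraction of guide-bearing cells carrying scramble
#'   guides (pool ratio no-transfection:scramble:on-target of 5:5:90).
#' @param sc_cross_contamination probability a guide-bearing cell carries one
#'   guide from a foreign set.
#' @param sc_doublet_frac fraction of cells flagged as doublets.
#' @param mito_beta shape parameters (a, b) of the Beta distribution of
#'   per-cell mitochondrial fraction.
#'
#' @return an object of class \code{sim_config} (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1e6,
                       n_states = 10L,
                       segment_length_mean = 2000,
                       state_probs = NULL,
                       n_insertions = 3000L,
                       at_bias_strength = 1,
                       basal_mu_by_state = NULL,
                       basal_sigma_by_state = NULL,
                       frac_silent = 0.15,
                       tad_fraction = 0.6,
                       tad_length_mean = 1e5,
                       tad_shift_sd = 0.5,
                       lfc_sd = 1,
                       decay_params = c(A = 3, k = 0.5, C = 0.2),
                       state_deviation_by_state = NULL,
                       activation_noise_sd = 0.3,
                       gdna_depth_mean = 100,
                       cdna_depth_scale = 100,
                       n_replicates = 2L,
                       ipcr_depth_mean = 50,
                       ipcr_detect_prob = c(TatI = 0.80, MspI = 0.93),
                       malformed_read_frac = 0.05,
                       flank_length = 30L,
                       nb_beta0_by_state = NULL,
                       nb_beta_act_by_state = NULL,
                       nb_theta_by_state = NULL,
                       nb_pi_by_state = NULL,
                       total_umi_lognormal = c(meanlog = log(1e4), sdlog = 0.3),
                       guides_per_target = 5L,
                       guide_multiplicity_probs = NULL,
                       sc_scramble_frac = 5 / 95,
                       sc_cross_contamination = 0.02,
                       sc_doublet_frac = 0.02,
                       mito_beta = c(a = 2.5, b = 45)) {
  n_states <- as.integer(n_states)
  states <- state_labels(n_states)
  if (is.null(state_probs)) state_probs <- rep(1 / n_states, n_states)
  if (is.null(basal_mu_by_state)) {
    basal_mu_by_state <- default_state_vector(
      c(E1 = 1.0, E2 = 0.7, E3 = 0.5, E4 = 0.8, E5 = 0.3,
        E6 = -1.5, E7 = -2.0, E8 = -1.0, E9 = -2.5, E10 = 0.0),
      states, fill = 0
    )
  }
  if (is.null(basal_sigma_by_state)) {
    basal_sigma_by_state <- stats::setNames(rep(0.6, n_states), states)
  }
  if (is.null(state_deviation_by_state)) {
    state_deviation_by_state <- default_state_vector(
      c(E6 = 1.0, E9 = -0.5), states, fill = 0
    )
  }
  if (is.null(nb_beta0_by_state)) {
    nb_beta0_by_state <- stats::setNames(
      seq(-13.0, -14.0, length.out = n_states), states
    )
  }
  if (is.null(nb_beta_act_by_state)) {
    nb_beta_act_by_state <- stats::setNames(rep(3.9, n_states), states)
  }
  if (is.null(nb_theta_by_state)) {
    nb_theta_by_state <- stats::setNames(rep(0.5, n_states), states)
  }
  if (is.null(nb_pi_by_state)) {
    nb_pi_by_state <- stats::setNames(rep(0.4, n_states), states)
  }
  if (is.null(guide_multiplicity_probs)) {
    guide_multiplicity_probs <- c(
      0.061, rep(0.8127 / 5, 5), rep(0.1263 / 3, 3)
    )
  }
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    n_states = n_states,
    states = states,
    segment_length_mean = as.numeric(segment_length_mean),
    state_probs = state_probs,
    n_insertions = as.integer(n_insertions),
    at_bias_strength = as.numeric(at_bias_strength),
    basal_mu_by_state = basal_mu_by_state,
    basal_sigma_by_state = basal_sigma_by_state,
    frac_silent = frac_silent,
    tad_fraction = tad_fraction,
    tad_length_mean = tad_length_mean,
    tad_shift_sd = tad_shift_sd,
    lfc_sd = lfc_sd,
    decay_params = decay_params,
    state_deviation_by_state = state_deviation_by_state,
    activation_noise_sd = activation_noise_sd,
    gdna_depth_mean = gdna_depth_mean,
    cdna_depth_scale = cdna_depth_scale,
    n_replicates = as.integer(n_replicates),
    ipcr_depth_mean = ipcr_depth_mean,
    ipcr_detect_prob = ipcr_detect_prob,
    malformed_read_frac = malformed_read_frac,
    flank_length = as.integer(flank_length),
    nb_beta0_by_state = nb_beta0_by_state,
    nb_beta_act_by_state = nb_beta_act_by_state,
    nb_theta_by_state = nb_theta_by_state,
    nb_pi_by_state = nb_pi_by_state,
    total_umi_lognormal = total_umi_lognormal,
    guides_per_target = as.integer(guides_per_target),
    guide_multiplicity_probs = guide_multiplicity_probs,
    sc_scramble_frac = sc_scramble_frac,
    sc_cross_contamination = sc_cross_contamination,
    sc_doublet_frac = sc_doublet_frac,
    mito_beta = mito_beta
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

state_labels <- function(n_states) paste0("E", seq_len(n_states))

default_state_vector <- function(named, states, fill) {
  out <- stats::setNames(rep(fill, length(states)), states)
  keep <- intersect(names(named), states)
  out[keep] <- named[keep]
  out
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1,
    cfg$chrom_length >= 1,
    cfg$n_states >= 1,
    cfg$segment_length_mean >= 1,
    cfg$n_insertions >= 1,
    cfg$at_bias_strength >= 0,
    cfg$flank_length >= 1
  )
  if (cfg$segment_length_mean >= cfg$chrom_length) {
    stop("segment_length_mean must be smaller than chrom_length",
         call. = FALSE)
  }
  probs <- c(cfg$frac_silent, cfg$tad_fraction, cfg$malformed_read_frac,
             cfg$sc_scramble_frac, cfg$sc_cross_contamination,
             cfg$sc_doublet_frac, cfg$state_probs,
             cfg$guide_multiplicity_probs, cfg$nb_pi_by_state)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$state_probs) - 1) > 1e-8) {
    stop("state_probs must sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$guide_multiplicity_probs) - 1) > 1e-8) {
    stop("guide_multiplicity_probs must sum to 1", call. = FALSE)
  }
  if (any(cfg$nb_theta_by_state <= 0) || any(cfg$basal_sigma_by_state < 0)) {
    stop("dispersions must be positive and sds non-negative", call. = FALSE)
  }
  for (nm in c("basal_mu_by_state", "basal_sigma_by_state",
               "state_deviation_by_state", "nb_beta0_by_state",
               "nb_beta_act_by_state", "nb_theta_by_state",
               "nb_pi_by_state")) {
    if (length(cfg[[nm]]) != cfg$n_states) {
      stop(nm, " must have one entry per state", call. = FALSE)
    }
  }
  if (!all(c("A", "k", "C") %in% names(cfg$decay_params))) {
    stop("decay_params must be a named vector (A, k, C)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosome(s) x %g bp, %d chromatin states\n",
              x$n_chromosomes, x$chrom_length, x$n_states))
  cat(sprintf("  reporters: %d insertions, AT bias %.2f, %.0f%% silent\n",
              x$n_insertions, x$at_bias_strength, 100 * x$frac_silent))
  cat(sprintf("  activation: logFC = %.2f*exp(-%.2f*logB) + %.2f\n",
              x$decay_params["A"], x$decay_params["k"], x$decay_params["C"]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
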