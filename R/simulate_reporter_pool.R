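#' Simulate a barcoded reporter pool with AT-biased insertion sites
#'
#' Draws reporter insertion positions with probability proportional to
#' \code{exp(at_bias_strength * z)}, where \code{z} is the z-score of the
#' local AT fraction in a 100-bp window around each candidate base —
#' emulating the AT-rich integration preference of the piggyBac transposon.
#' Each insertion carries a unique random 17-nt barcode. The returned truth
#' table records, per barcode, its chromatin state, TAD membership, genomic
#' annotation, basal expression trajectory over differentiation (days 0, 2
#' and 5, including a shared per-TAD shift), a silent flag, and the
#' ground-truth log fold activation under CRISPRa at both cell states,
#' generated as
#' \code{log FC = log(A*exp(-k*log basal) + C) + state deviation + noise}.
#'
#' @param genome a \code{\link{simulate_genome}} result.
#' @param config the \code{\link{sim_config}} used to build \code{genome}.
#' @return a \code{reporter_pool}: list with \code{truth} (one row per
#'   barcode) and \code{at_window} (window size used for the AT fraction).
#' @export
simulate_reporter_pool <- function(genome, config, at_window = 100L) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  chroms <- names(genome$chrom_sizes)
  margin <- max(at_window, config$flank_length + 10L)

  # candidate positions and their local AT fraction, per chromosome
  at_frac <- lapply(chroms, function(ch) {
    local_at_fraction(genome$sequence[[ch]], at_window)
  })
  names(at_frac) <- chroms
  cand <- do.call(rbind, lapply(chroms, function(ch) {
    L <- genome$chrom_sizes[[ch]]
    pos <- seq.int(margin, L - margin)
    data.frame(chrom = ch, position = pos,
               at = at_frac[[ch]][pos + 1], stringsAsFactors = FALSE)
  }))
  z <- (cand$at - mean(cand$at)) / stats::sd(cand$at)
  w <- exp(config$at_bias_strength * z)

  if (config$n_insertions > nrow(cand)) {
    stop("more insertions requested than candidate positions", call. = FALSE)
  }
  # weighted sampling without replacement via exponential race
  keys <- stats::rexp(nrow(cand)) / w
  take <- order(keys)[seq_len(config$n_insertions)]
  ins <- cand[take, ]
  rownames(ins) <- NULL

  ins$barcode <- random_barcodes(config$n_insertions)
  ins$strand <- sample(c("+", "-"), config$n_insertions, replace = TRUE)
  ins$state <- assign_state(ins, genome$segmentation)
  ins$annotation <- annotate_positions(genome, ins$chrom, ins$position)
  tad_hit <- locate_in_intervals(ins, genome$tads)
  ins$tad_id <- ifelse(is.na(tad_hit), NA_character_,
                       genome$tads$tad_id[tad_hit])
  ins$tad_status <- ifelse(is.na(ins$tad_id), "interTAD", "intraTAD")

  # basal expression trajectory: state-level mean + per-barcode noise +
  # differentiation LFC + shared per-TAD per-timepoint shift
  mu <- config$basal_mu_by_state[ins$state]
  sig <- config$basal_sigma_by_state[ins$state]
  base <- stats::rnorm(config$n_insertions, mu, sig)
  lfc <- stats::rnorm(config$n_insertions, 0, config$lfc_sd)
  tad_ids <- unique(stats::na.omit(ins$tad_id))
  shifts <- matrix(stats::rnorm(length(tad_ids) * 3, 0, config$tad_shift_sd),
                   nrow = length(tad_ids), ncol = 3,
                   dimnames = list(tad_ids, c("d0", "d2", "d5")))
  shift_of <- function(day) {
    s <- rep(0, config$n_insertions)
    ok <- !is.na(ins$tad_id)
    s[ok] <- shifts[ins$tad_id[ok], day]
    s
  }
  ins$silent <- stats::runif(config$n_insertions) < config$frac_silent
  ins$basal_log_d0 <- base + shift_of("d0")
  ins$basal_log_d2 <- base + 0.4 * lfc + shift_of("d2")
  ins$basal_log_d5 <- base + lfc + shift_of("d5")

  dev <- config$state_deviation_by_state[ins$state]
  dp <- config$decay_params
  log_fold <- function(log_basal) {
    log(dp[["A"]] * exp(-dp[["k"]] * log_basal) + dp[["C"]]) + dev +
      stats::rnorm(config$n_insertions, 0, config$activation_noise_sd)
  }
  ins$log_fold_ipsc <- log_fold(ins$basal_log_d0)
  ins$log_fold_ineuron <- log_fold(ins$basal_log_d5)

  structure(list(truth = ins, at_window = at_window),
            class = "reporter_pool")
}

#' @export
print.reporter_pool <- function(x, ...) {
  cat(sprintf("<reporter_pool> %d barcodes (%.1f%% silent)\n",
              nrow(x$truth), 100 * mean(x$truth$silent)))
  invisible(x)
}

# AT fraction of the window of width `w` centred on each base (clipped at
# chromosome ends); returned per-position, 1-based indexing.
local_at_fraction <- function(seq, w = 100L) {
  counts <- Biostrings::letterFrequencyInSlidingView(seq, w, "AT")[, 1]
  # view starting at i covers [i, i+w-1]; centre view on each base
  L <- length(seq)
  start <- pmin(pmax(seq_len(L) - w %/% 2, 1L), L - w + 1L)
  counts[start] / w
}

random_barcodes <- function(n, width = 17L, max_retries = 50L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE),
                nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  bc <- unique(draw(n))
  tries <- 0L
  while (length(bc) < n) {
    tries <- tries + 1L
    if (tries > max_retries) {
      stop("barcode collision persists after max retries", call. = FALSE)
    }
    bc <- unique(c(bc, draw(n - length(bc))))
  }
  bc[seq_len(n)]
}

# index of the interval (0-based half-open rows of `ivs`) containing each
# point, NA if none
locate_in_intervals <- function(points, ivs) {
  if (is.null(ivs) || nrow(ivs) == 0) {
    return(rep(NA_integer_, nrow(points)))
  }
  pt <- GenomicRanges::GRanges(points$chrom,
                               IRanges::IRanges(points$position + 1, width = 1))
  hit <- GenomicRanges::findOverlaps(pt, df_to_granges(ivs), select = "first")
  as.integer(hit)
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483647L
}
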