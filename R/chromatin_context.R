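#' Assign a chromatin state to each insertion
#'
#' The state of an insertion is the label of the segmentation interval
#' (0-based half-open) containing its insertion base; positions falling in
#' no interval (gaps in real segmentations) are labelled "unassigned".
#'
#' @param insertions data.frame with chrom and position columns.
#' @param segmentation data.frame with chrom, start, end, state.
#' @return character vector of state labels, one per insertion.
#' @export
assign_state <- function(insertions, segmentation) {
  out <- rep("unassigned", nrow(insertions))
  for (ch in unique(insertions$chrom)) {
    seg <- segmentation[segmentation$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$start), , drop = FALSE]
    idx <- which(insertions$chrom == ch)
    p <- insertions$position[idx]
    k <- findInterval(p, seg$start)
    hit <- k >= 1 & p < seg$end[pmax(k, 1)]
    out[idx[hit]] <- seg$state[k[hit]]
  }
  out
}

#' Sum a signal track over windows around positions
#'
#' Sums a bedGraph-style track over \code{[position - half_width,
#' position + half_width)}, clipped to the chromosome; an interval partially
#' overlapping the window contributes its value times the overlap length.
#'
#' @param track data.frame with chrom, start, end, value (sorted,
#'   non-overlapping intervals).
#' @param chrom,position vectors locating the window centres (0-based).
#' @param half_width half window width in bp (default 5000, i.e. the 5-kb
#'   up/downstream window).
#' @param chrom_sizes named vector of chromosome lengths used for clipping
#'   and bounds checking; if NULL, bounds are not checked.
#' @return numeric vector of window sums.
#' @export
window_signal <- function(track, chrom, position, half_width = 5000,
                          chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) {
    L <- chrom_sizes[chrom]
    if (any(is.na(L)) || any(position < 0 | position >= L)) {
      stop("position outside chromosome bounds", call. = FALSE)
    }
  }
  out <- numeric(length(position))
  win_start <- pmax(position - half_width, 0)
  win_end <- position + half_width
  if (!is.null(chrom_sizes)) win_end <- pmin(win_end, chrom_sizes[chrom])
  for (ch in unique(chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    idx <- which(chrom == ch)
    if (nrow(tr) == 0) next
    win <- IRanges::IRanges(win_start[idx] + 1, win_end[idx])
    iv <- IRanges::IRanges(tr$start + 1, tr$end)
    ov <- IRanges::findOverlaps(win, iv)
    if (length(ov) == 0) next
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    inter_w <- pmin(IRanges::end(win)[qi], IRanges::end(iv)[si]) -
      pmax(IRanges::start(win)[qi], IRanges::start(iv)[si]) + 1
    contrib <- inter_w * tr$value[si]
    sums <- tapply(contrib, qi, sum)
    out[idx[as.integer(names(sums))]] <- as.numeric(sums)
  }
  out
}

#' Bin barcodes by expression and regress a covariate on bin index
#'
#' Detectable barcodes are split into equal-size quantile bins by
#' expression (ties broken by stable input order); when a vector of
#' detectability flags is supplied, undetectable barcodes form bin 1 and
#' detectable ones fill bins 2..n_bins (the 8-bin scheme used for
#' ChIP-signal windows). Ordinary least squares of the per-bin mean
#' covariate on the bin index gives the reported slope and confidence
#' interval.
#'
#' @param values per-barcode expression values.
#' @param covariate per-barcode covariate (e.g. a ChIP window sum).
#' @param n_bins total number of bins (>= 2).
#' @param detectable optional logical; if given, FALSE entries form bin 1.
#' @return list with \code{bin} (per barcode), \code{bin_stats} (per-bin
#'   mean and sd of the covariate), \code{slope}, \code{intercept},
#'   \code{ci} (95\% CI of the slope), \code{r_squared} and \code{model}.
#' @export
bin_and_regress <- function(values, covariate, n_bins = 8,
                            detectable = NULL) {
  n <- length(values)
  stopifnot(length(covariate) == n, n_bins >= 2)
  bin <- integer(n)
  if (is.null(detectable)) {
    if (n < n_bins) stop("fewer barcodes than bins", call. = FALSE)
    bin <- quantile_bins(values, n_bins)
  } else {
    det <- which(detectable)
    if (length(det) < n_bins - 1) {
      stop("fewer detectable barcodes than bins", call. = FALSE)
    }
    bin[!detectable] <- 1L
    bin[det] <- 1L + quantile_bins(values[det], n_bins - 1L)
  }
  stats_df <- data.frame(
    bin = sort(unique(bin)),
    mean = tapply(covariate, bin, mean),
    sd = tapply(covariate, bin, stats::sd),
    n = as.integer(table(bin))
  )
  fit <- stats::lm(mean ~ bin, data = stats_df)
  co <- stats::coef(fit)
  # summary/confint warn on numerically perfect fits; those are legitimate
  # degenerate inputs here
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(unname(stats::confint(fit)["bin", ]))
  list(
    bin = bin,
    bin_stats = stats_df,
    slope = unname(co["bin"]),
    intercept = unname(co["(Intercept)"]),
    ci = ci,
    r_squared = sm$r.squared,
    model = fit
  )
}

# equal-count quantile bins by rank; stable for ties (first occurrence wins)
quantile_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(x)))
}

#' Within-TAD versus between-TAD expression correlation
#'
#' Classifies barcodes as intraTAD (insertion base inside any half-open TAD
#' interval) or interTAD, computes the Pearson correlation of expression
#' trajectories for every pair of barcodes sharing a TAD, samples an equal
#' number of random pairs of intraTAD barcodes from different TADs, and
#' compares the two correlation distributions with Welch's two-sample t
#' test.
#'
#' @param expr matrix of expression values, rows = barcodes (rownames),
#'   columns = timepoints (>= 2).
#' @param insertions data.frame with barcode, chrom, position.
#' @param tads data.frame with chrom, start, end, tad_id.
#' @param n_random_pairs number of between-TAD pairs; defaults to the
#'   number of within-TAD pairs.
#' @param seed seed for the between-TAD pair sampling.
#' @return list: tad_status data.frame, within_r, between_r, mean_within,
#'   mean_between, t, p, degenerate flag.
#' @export
tad_analysis <- function(expr, insertions, tads, n_random_pairs = NULL,
                         seed = 1L) {
  if (ncol(expr) < 2) stop("need >= 2 timepoints", call. = FALSE)
  ins <- insertions[insertions$barcode %in% rownames(expr), , drop = FALSE]
  hit <- locate_in_intervals(ins, tads)
  ins$tad_id <- ifelse(is.na(hit), NA_character_, tads$tad_id[hit])
  ins$tad_status <- ifelse(is.na(ins$tad_id), "interTAD", "intraTAD")

  by_tad <- split(ins$barcode, ins$tad_id)
  by_tad <- by_tad[lengths(by_tad) >= 2]
  if (length(by_tad) == 0) {
    stop("no TAD contains >= 2 barcodes; within-TAD statistic undefined",
         call. = FALSE)
  }
  pair_cor <- function(b1, b2) {
    suppressWarnings(stats::cor(expr[b1, ], expr[b2, ]))
  }
  within_r <- unlist(lapply(by_tad, function(bcs) {
    cmb <- utils::combn(bcs, 2)
    vapply(seq_len(ncol(cmb)), function(j) pair_cor(cmb[1, j], cmb[2, j]),
           numeric(1))
  }), use.names = FALSE)

  if (is.null(n_random_pairs)) n_random_pairs <- length(within_r)
  set.seed(seed)
  intra <- ins[!is.na(ins$tad_id), , drop = FALSE]
  between_r <- numeric(0)
  guard <- 0
  while (length(between_r) < n_random_pairs && guard < 50) {
    guard <- guard + 1
    i <- sample(nrow(intra), n_random_pairs, replace = TRUE)
    j <- sample(nrow(intra), n_random_pairs, replace = TRUE)
    ok <- intra$tad_id[i] != intra$tad_id[j]
    take <- which(ok)[seq_len(min(sum(ok), n_random_pairs -
                                    length(between_r)))]
    between_r <- c(between_r,
                   vapply(take, function(k) {
                     pair_cor(intra$barcode[i[k]], intra$barcode[j[k]])
                   }, numeric(1)))
  }
  within_r <- within_r[!is.na(within_r)]
  between_r <- between_r[!is.na(between_r)]
  sd_w <- if (length(within_r) > 1) stats::sd(within_r) else 0
  sd_b <- if (length(between_r) > 1) stats::sd(between_r) else 0
  degenerate <- length(within_r) < 2 || length(between_r) < 2 ||
    (sd_w == 0 && sd_b == 0)
  if (degenerate) {
    t_stat <- NA_real_; p <- NA_real_
  } else {
    ht <- stats::t.test(within_r, between_r)
    t_stat <- unname(ht$statistic); p <- ht$p.value
  }
  list(
    tad_status = ins[, c("barcode", "tad_id", "tad_status")],
    within_r = within_r, between_r = between_r,
    mean_within = mean(within_r), mean_between = mean(between_r),
    t = t_stat, p = p, degenerate = degenerate
  )
}

#' Annotate barcodes with state, TAD status and per-mark window sums
#'
#' Convenience wrapper producing one context row per mapped barcode.
#'
#' @param pool mapped barcode table with barcode, chrom, position.
#' @param genome a \code{genome_context} (segmentation, tracks, tads).
#' @param half_width window half width for mark sums.
#' @return data.frame: barcode, state, tad_id, tad_status, one
#'   \code{sum_<mark>} column per track.
#' @export
annotate_context <- function(pool, genome, half_width = 5000) {
  out <- pool[, c("barcode", "chrom", "position")]
  out$state <- assign_state(out, genome$segmentation)
  hit <- locate_in_intervals(out, genome$tads)
  out$tad_id <- ifelse(is.na(hit), NA_character_, genome$tads$tad_id[hit])
  out$tad_status <- ifelse(is.na(out$tad_id), "interTAD", "intraTAD")
  for (mark in names(genome$tracks)) {
    out[[paste0("sum_", mark)]] <- window_signal(
      genome$tracks[[mark]], out$chrom, out$position, half_width,
      genome$chrom_sizes
    )
  }
  out
}
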