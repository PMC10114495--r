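#' Inverse-PCR read structure
#'
#' Describes the structure every well-formed genotyping read must follow:
#' \code{[upstream anchor][barcode][downstream anchor][genomic flank]}.
#' The anchors stand for the transposon-derived sequences flanking the
#' barcode in the amplicon.
#'
#' @param upstream_anchor,downstream_anchor anchor sequences.
#' @param barcode_length expected barcode length in nt (default 17).
#' @param max_anchor_mismatches mismatches tolerated per anchor.
#' @param min_flank_length minimum genomic flank retained for mapping.
#' @return a \code{read_structure_spec} list.
#' @export
read_structure_spec <- function(upstream_anchor = "CATGCGTCAACCACTGT",
                                downstream_anchor = "GGATCCTAGCAAGTC",
                                barcode_length = 17L,
                                max_anchor_mismatches = 1L,
                                min_flank_length = 20L) {
  stopifnot(nchar(upstream_anchor) > 0, nchar(downstream_anchor) > 0,
            barcode_length > 0)
  structure(list(
    upstream_anchor = upstream_anchor,
    downstream_anchor = downstream_anchor,
    barcode_length = as.integer(barcode_length),
    max_anchor_mismatches = as.integer(max_anchor_mismatches),
    min_flank_length = as.integer(min_flank_length)
  ), class = "read_structure_spec")
}

#' Simulate inverse-PCR genotyping reads for both restriction enzymes
#'
#' Per enzyme (TatI, MspI) each barcode is recovered with the configured
#' detection probability and, if recovered, contributes a Poisson number of
#' reads. Reads follow the \code{\link{read_structure_spec}} with the genomic
#' flank taken from the synthetic sequence at the insertion site; a
#' configurable fraction of malformed reads (16-nt barcode region, or a
#' corrupted downstream anchor) is injected.
#'
#' @param pool a \code{\link{simulate_reporter_pool}} result.
#' @param genome matching \code{\link{simulate_genome}} result.
#' @param config the shared \code{\link{sim_config}}.
#' @param spec read structure; defaults to \code{read_structure_spec()}.
#' @return list with per-enzyme read data frames (\code{read_id},
#'   \code{sequence}, \code{barcode}, \code{malformed}) and
#'   \code{truth_read_counts} (reads per barcode per enzyme).
#' @export
simulate_ipcr_reads <- function(pool, genome, config,
                                spec = read_structure_spec()) {
  set.seed(derive_seed(config$seed, 2L))
  truth <- pool$truth
  enzymes <- c("TatI", "MspI")
  out <- list()
  counts <- data.frame(barcode = truth$barcode)
  for (enz in enzymes) {
    detected <- stats::runif(nrow(truth)) < config$ipcr_detect_prob[[enz]]
    n_reads <- ifelse(detected,
                      1L + stats::rpois(nrow(truth),
                                        max(config$ipcr_depth_mean - 1, 0)),
                      0L)
    counts[[paste0("reads_", enz)]] <- n_reads
    idx <- rep(seq_len(nrow(truth)), n_reads)
    flank <- flank_sequence(genome, truth$chrom[idx], truth$position[idx],
                            config$flank_length)
    bc <- truth$barcode[idx]
    malformed <- stats::runif(length(idx)) < config$malformed_read_frac
    kind <- ifelse(stats::runif(length(idx)) < 0.5,
                   "barcode_length", "missing_anchor")
    bc_used <- bc
    bc_used[malformed & kind == "barcode_length"] <-
      substr(bc[malformed & kind == "barcode_length"], 1,
             spec$barcode_length - 1L)
    down <- rep(spec$downstream_anchor, length(idx))
    down[malformed & kind == "missing_anchor"] <-
      scramble_string(spec$downstream_anchor)
    seqs <- paste0(spec$upstream_anchor, bc_used, down, flank)
    out[[enz]] <- data.frame(
      read_id = sprintf("%s_read_%d", enz, seq_along(idx)),
      sequence = seqs,
      barcode = bc,
      malformed = malformed,
      stringsAsFactors = FALSE
    )
  }
  out$truth_read_counts <- counts
  out$spec <- spec
  out
}

flank_sequence <- function(genome, chrom, position, width) {
  if (length(chrom) == 0) return(character(0))
  gr <- split(seq_along(chrom), chrom)
  res <- character(length(chrom))
  for (ch in names(gr)) {
    i <- gr[[ch]]
    v <- Biostrings::Views(genome$sequence[[ch]],
                           start = position[i] + 1L,
                           width = width)
    res[i] <- as.character(v)
  }
  res
}

scramble_string <- function(s) {
  chartr("ACGT", "TGCA", s)
}

#' Simulate a gDNA/cDNA barcode count table for one condition
#'
#' Per barcode and replicate, gDNA counts are Poisson around the configured
#' depth and cDNA counts are Poisson with mean proportional to
#' gDNA x expression. Expression is the ground-truth basal level at the
#' requested differentiation day (0 = iPSC, 5 = iNeuron), multiplied under
#' the "VPR" condition by the ground-truth fold activation of the matching
#' cell state. Silent reporters have zero expected cDNA.
#'
#' @param pool a \code{\link{simulate_reporter_pool}} result.
#' @param config the shared \code{\link{sim_config}}.
#' @param timepoint differentiation day: 0, 2 or 5.
#' @param condition "control" (non-targeting sgRNA) or "VPR" (dCas9-VPR with
#'   targeting sgRNAs; only meaningful at days 0 and 5).
#' @return data.frame with columns barcode, sample_id, condition, timepoint,
#'   replicate, gdna_count, cdna_count.
#' @export
simulate_count_table <- function(pool, config, timepoint = 0,
                                 condition = c("control", "VPR")) {
  condition <- match.arg(condition)
  if (!timepoint %in% c(0, 2, 5)) {
    stop("timepoint must be one of 0, 2, 5", call. = FALSE)
  }
  if (condition == "VPR" && timepoint == 2) {
    stop("the VPR condition is simulated at days 0 and 5 only", call. = FALSE)
  }
  set.seed(derive_seed(config$seed,
                       100L + as.integer(timepoint) * 10L +
                         (condition == "VPR") * 1L))
  truth <- pool$truth
  log_basal <- switch(as.character(timepoint),
                      "0" = truth$basal_log_d0,
                      "2" = truth$basal_log_d2,
                      "5" = truth$basal_log_d5)
  expr <- ifelse(truth$silent, 0, exp(log_basal))
  if (condition == "VPR") {
    log_fold <- if (timepoint == 0) truth$log_fold_ipsc else
      truth$log_fold_ineuron
    expr <- expr * exp(log_fold)
  }
  n <- nrow(truth)
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    gdna <- stats::rpois(n, config$gdna_depth_mean)
    cdna_mean <- gdna * expr * config$cdna_depth_scale /
      config$gdna_depth_mean
    cdna <- stats::rpois(n, cdna_mean)
    data.frame(
      barcode = truth$barcode,
      sample_id = sprintf("d%d_%s_rep%d", timepoint, condition, r),
      condition = condition,
      timepoint = timepoint,
      replicate = r,
      gdna_count = gdna,
      cdna_count = cdna,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}
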