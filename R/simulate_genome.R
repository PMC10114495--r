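#' Simulate a chromatin-annotated synthetic genome
#'
#' Generates the genomic context every downstream analysis consumes: a DNA
#' sequence with a smoothly varying AT-content field (the substrate of the
#' piggyBac insertion bias), a chromatin-state segmentation tiling each
#' chromosome, per-mark signal tracks elevated within the states that carry
#' the mark (the bivalent state carries both an H3K4me3-like and an
#' H3K27me3-like signal), TAD intervals covering a configurable genome
#' fraction, and gene models with exons so that insertions can be classified
#' as exonic, intronic or intergenic.
#'
#' All intervals are 0-based half-open.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return an object of class \code{genome_context}: a list with
#'   \code{chrom_sizes}, \code{sequence} (a
#'   \code{\link[Biostrings]{DNAStringSet}}), \code{at_prob} (per-position
#'   AT-probability field), \code{segmentation}, \code{tracks} (named list of
#'   bedGraph-style data frames), \code{tads}, \code{genes} and \code{exons}.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chrom_length
  chrom_sizes <- stats::setNames(rep(L, length(chroms)), chroms)

  seqs <- vector("list", length(chroms))
  at_prob <- vector("list", length(chroms))
  seg_list <- vector("list", length(chroms))
  tad_list <- vector("list", length(chroms))
  gene_list <- vector("list", length(chroms))
  exon_list <- vector("list", length(chroms))

  marks <- default_marks()
  emission <- default_emission(config$states, marks)
  track_vals <- vector("list", length(chroms))

  for (i in seq_along(chroms)) {
    at_prob[[i]] <- simulate_at_field(L)
    seqs[[i]] <- simulate_sequence(at_prob[[i]])
    seg <- tile_segments(L, config$segment_length_mean,
                         config$states, config$state_probs)
    seg$chrom <- chroms[i]
    seg_list[[i]] <- seg[, c("chrom", "start", "end", "state")]
    # per-segment signal with modest multiplicative noise
    vals <- matrix(0, nrow(seg), length(marks),
                   dimnames = list(NULL, marks))
    for (m in marks) {
      base <- emission[seg$state, m]
      noise <- stats::rlnorm(nrow(seg), 0, 0.2)
      vals[, m] <- 0.05 + base * noise
    }
    track_vals[[i]] <- vals
    tads <- tile_tads(L, config$tad_fraction, config$tad_length_mean)
    tads$chrom <- rep(chroms[i], nrow(tads))
    tad_list[[i]] <- tads
    ge <- tile_genes(L)
    ge$genes$chrom <- rep(chroms[i], nrow(ge$genes))
    ge$exons$chrom <- rep(chroms[i], nrow(ge$exons))
    gene_list[[i]] <- ge$genes
    exon_list[[i]] <- ge$exons
  }

  segmentation <- do.call(rbind, seg_list)
  rownames(segmentation) <- NULL
  tracks <- stats::setNames(lapply(marks, function(m) {
    df <- segmentation[, c("chrom", "start", "end")]
    df$value <- unlist(lapply(track_vals, function(v) v[, m]))
    rownames(df) <- NULL
    df
  }), marks)

  tads <- do.call(rbind, tad_list)
  tads$tad_id <- sprintf("tad_%d", seq_len(nrow(tads)))
  tads <- tads[, c("chrom", "start", "end", "tad_id")]
  rownames(tads) <- NULL
  genes <- do.call(rbind, gene_list)
  genes$gene_id <- sprintf("gene_%d", seq_len(nrow(genes)))
  exons <- do.call(rbind, exon_list)
  exons$gene_id <- genes$gene_id[exons$gene_index]
  exons$gene_index <- NULL
  rownames(genes) <- rownames(exons) <- NULL

  sequence <- Biostrings::DNAStringSet(unlist(lapply(seqs, as.character)))
  names(sequence) <- chroms

  structure(list(
    chrom_sizes = chrom_sizes,
    sequence = sequence,
    at_prob = stats::setNames(at_prob, chroms),
    segmentation = segmentation,
    tracks = tracks,
    tads = tads,
    genes = genes[, c("chrom", "start", "end", "strand", "gene_id")],
    exons = exons[, c("chrom", "start", "end", "gene_id")],
    states = config$states
  ), class = "genome_context")
}

# Smooth AT-probability field: Gaussian knots every 2 kb, linearly
# interpolated, centred on the genome-wide human-like AT level.
simulate_at_field <- function(L, mean_at = 0.591, amp = 0.08,
                              knot_spacing = 2000) {
  knots <- seq(1, L + knot_spacing, by = knot_spacing)
  kv <- stats::rnorm(length(knots), 0, 1)
  field <- stats::approx(knots, kv, xout = seq_len(L), rule = 2)$y
  p <- mean_at + amp * field
  pmin(pmax(p, 0.05), 0.95)
}

simulate_sequence <- function(at_prob) {
  L <- length(at_prob)
  is_at <- stats::runif(L) < at_prob
  pick <- stats::runif(L) < 0.5
  base <- character(L)
  base[is_at & pick] <- "A"
  base[is_at & !pick] <- "T"
  base[!is_at & pick] <- "G"
  base[!is_at & !pick] <- "C"
  Biostrings::DNAString(paste(base, collapse = ""))
}

tile_segments <- function(L, mean_len, states, state_probs) {
  n_guess <- ceiling(L / mean_len * 1.5) + 10
  lens <- pmax(1, round(stats::rexp(n_guess, 1 / mean_len)))
  while (sum(lens) < L) {
    lens <- c(lens, pmax(1, round(stats::rexp(n_guess, 1 / mean_len))))
  }
  ends <- cumsum(lens)
  k <- which(ends >= L)[1]
  lens <- lens[seq_len(k)]
  ends <- ends[seq_len(k)]
  ends[k] <- L
  starts <- c(0, ends[-k])
  keep <- ends > starts
  st <- sample(states, sum(keep), replace = TRUE, prob = state_probs)
  data.frame(start = starts[keep], end = ends[keep], state = st,
             stringsAsFactors = FALSE)
}

tile_tads <- function(L, frac, tad_mean) {
  if (frac <= 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  gap_mean <- max(1, tad_mean * (1 - frac) / frac)
  pos <- 0
  starts <- ends <- numeric(0)
  while (pos < L) {
    gap <- round(stats::rexp(1, 1 / gap_mean))
    s <- min(pos + gap, L)
    len <- max(1, round(stats::rexp(1, 1 / tad_mean)))
    e <- min(s + len, L)
    if (e > s) {
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
    pos <- e
  }
  data.frame(start = starts, end = ends)
}

# Genes alternate with intergenic gaps; each gene carries short exons so
# exonic/intronic/intergenic annotation is well defined.
tile_genes <- function(L, gene_mean = 2e4, gap_mean = 3e4,
                       n_exons = 5, exon_len = 300) {
  pos <- 0
  genes <- list()
  exons <- list()
  gi <- 0
  while (pos < L) {
    gap <- max(1, round(stats::rexp(1, 1 / gap_mean)))
    s <- pos + gap
    len <- max(n_exons * exon_len * 2, round(stats::rexp(1, 1 / gene_mean)))
    e <- s + len
    if (e >= L) break
    gi <- gi + 1
    genes[[gi]] <- data.frame(
      start = s, end = e,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE
    )
    ex_starts <- round(seq(s, e - exon_len, length.out = n_exons))
    exons[[gi]] <- data.frame(start = ex_starts, end = ex_starts + exon_len,
                              gene_index = gi)
    pos <- e
  }
  if (gi == 0) {
    return(list(
      genes = data.frame(start = numeric(0), end = numeric(0),
                         strand = character(0)),
      exons = data.frame(start = numeric(0), end = numeric(0),
                         gene_index = integer(0))
    ))
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

default_marks <- function() {
  c("H3K4me3", "H3K4me1", "H3K27ac", "H3K36me3", "H3K27me3", "H3K9me3")
}

# Emission levels mirroring a 10-state segmentation: promoter, enhancer,
# transcribed, bivalent (K4me3 + K27me3), polycomb, heterochromatin,
# quiescent. States beyond the named ones are quiescent-like.
default_emission <- function(states, marks) {
  em <- matrix(0, length(states), length(marks),
               dimnames = list(states, marks))
  set_em <- function(state, mark, value) {
    if (state %in% states) em[state, mark] <<- value
  }
  set_em("E1", "H3K4me3", 1.0)
  set_em("E2", "H3K4me3", 0.5); set_em("E2", "H3K4me1", 0.5)
  set_em("E3", "H3K36me3", 1.0)
  set_em("E4", "H3K4me1", 1.0); set_em("E4", "H3K27ac", 1.0)
  set_em("E5", "H3K4me1", 0.5)
  set_em("E6", "H3K4me3", 0.8); set_em("E6", "H3K27me3", 0.8)
  set_em("E7", "H3K27me3", 1.0)
  set_em("E9", "H3K9me3", 1.0)
  set_em("E10", "H3K36me3", 0.3)
  em
}

#' @export
print.genome_context <- function(x, ...) {
  cat("<genome_context>\n")
  cat(sprintf("  %d chromosome(s), total %g bp\n",
              length(x$chrom_sizes), sum(x$chrom_sizes)))
  cat(sprintf("  %d segments over %d states; %d TADs; %d genes\n",
              nrow(x$segmentation), length(x$states),
              if (is.null(x$tads)) 0L else nrow(x$tads), nrow(x$genes)))
  invisible(x)
}

#' Classify a genomic position against the gene models
#'
#' @param genome a \code{genome_context} or a list with \code{genes} and
#'   \code{exons} data frames.
#' @param chrom,position vectors of positions (0-based).
#' @return character vector: "exonic", "intronic" or "intergenic".
#' @export
annotate_positions <- function(genome, chrom, position) {
  pt <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(position + 1, width = 1))
  gene_gr <- df_to_granges(genome$genes)
  exon_gr <- df_to_granges(genome$exons)
  in_gene <- IRanges::overlapsAny(pt, gene_gr)
  in_exon <- IRanges::overlapsAny(pt, exon_gr)
  out <- rep("intergenic", length(pt))
  out[in_gene] <- "intronic"
  out[in_exon] <- "exonic"
  out
}

# data.frame with 0-based half-open start/end -> GRanges (1-based closed)
df_to_granges <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end))
}
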