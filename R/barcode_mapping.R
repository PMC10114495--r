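#' Extract barcodes from inverse-PCR reads
#'
#' Filters reads to the declared structure
#' \code{[upstream anchor][barcode][downstream anchor][flank]} and pulls out
#' the barcode and genomic flank. A read is accepted only when both anchors
#' match within the allowed mismatches, exactly \code{barcode_length}
#' nucleotides lie between them, and the remaining flank is at least
#' \code{min_flank_length} long. Reads with a wrong-length barcode region are
#' removed and tallied.
#'
#' @param reads character vector of read sequences, a data.frame with a
#'   \code{sequence} column, or a path to a FASTQ file.
#' @param spec a \code{\link{read_structure_spec}}.
#' @return list with \code{records} (data.frame read_id, barcode, flank),
#'   \code{tally} (rejections by reason) and \code{n_total}.
#' @export
extract_barcodes <- function(reads, spec = read_structure_spec()) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    rs <- Biostrings::readDNAStringSet(reads, format = "fastq")
    ids <- names(rs)
    reads <- as.character(rs)
  } else if (is.data.frame(reads)) {
    ids <- if ("read_id" %in% names(reads)) reads$read_id else
      paste0("read_", seq_len(nrow(reads)))
    reads <- reads$sequence
  } else {
    ids <- paste0("read_", seq_along(reads))
  }
  if (length(reads) == 0) {
    return(list(records = data.frame(read_id = character(0),
                                     barcode = character(0),
                                     flank = character(0)),
                tally = c(anchor = 0L, barcode_length = 0L,
                          flank_length = 0L),
                n_total = 0L))
  }
  up <- spec$upstream_anchor
  down <- spec$downstream_anchor
  up_len <- nchar(up)
  down_len <- nchar(down)

  tally <- c(anchor = 0L, barcode_length = 0L, flank_length = 0L)

  up_mm <- hamming_to_pattern(substr(reads, 1, up_len), up)
  ok_up <- !is.na(up_mm) & up_mm <= spec$max_anchor_mismatches
  tally["anchor"] <- tally["anchor"] + sum(!ok_up)

  rest <- substr(reads[ok_up], up_len + 1L, nchar(reads[ok_up]))
  rest_ids <- ids[ok_up]
  hit <- first_match_position(rest, down, spec$max_anchor_mismatches)
  no_anchor <- is.na(hit)
  tally["anchor"] <- tally["anchor"] + sum(no_anchor)

  rest <- rest[!no_anchor]
  rest_ids <- rest_ids[!no_anchor]
  hit <- hit[!no_anchor]
  bc_len <- hit - 1L
  ok_len <- bc_len == spec$barcode_length
  tally["barcode_length"] <- sum(!ok_len)

  rest <- rest[ok_len]
  rest_ids <- rest_ids[ok_len]
  hit <- hit[ok_len]
  flank <- substr(rest, hit + down_len, nchar(rest))
  ok_flank <- nchar(flank) >= spec$min_flank_length
  tally["flank_length"] <- sum(!ok_flank)

  records <- data.frame(
    read_id = rest_ids[ok_flank],
    barcode = substr(rest[ok_flank], 1, spec$barcode_length),
    flank = flank[ok_flank],
    stringsAsFactors = FALSE
  )
  list(records = records, tally = tally, n_total = length(reads))
}

# mismatch count of equal-length strings against one pattern; NA if the
# string is shorter than the pattern
hamming_to_pattern <- function(strings, pattern) {
  n <- nchar(pattern)
  out <- integer(length(strings))
  short <- nchar(strings) < n
  for (j in seq_len(n)) {
    out <- out + (substr(strings, j, j) != substr(pattern, j, j))
  }
  out[short] <- NA_integer_
  out
}

# 1-based start of the first occurrence of `pattern` in each string, allowing
# up to max_mm mismatches; NA when absent
first_match_position <- function(strings, pattern, max_mm) {
  if (length(strings) == 0) return(integer(0))
  subj <- Biostrings::DNAStringSet(strings)
  m <- Biostrings::vmatchPattern(pattern, subj, max.mismatch = max_mm)
  starts <- Biostrings::startIndex(m)
  vapply(starts, function(s) if (length(s)) min(s) else NA_integer_,
         integer(1))
}

#' Map extracted flanks to the synthetic genome by exact substring search
#'
#' On synthetic data the genomic flank of a well-formed read is an exact
#' substring of the genome at the insertion point, so mapping is an exact
#' dictionary search. On real data a pre-aligned table (barcode, chrom,
#' position, read_count) is consumed instead of performing alignment.
#'
#' @param records output \code{records} of \code{\link{extract_barcodes}}.
#' @param genome a \code{\link{simulate_genome}} result.
#' @return candidate table: barcode, chrom, position (0-based), read_count,
#'   aggregated over reads.
#' @export
map_flanks <- function(records, genome) {
  if (nrow(records) == 0) {
    return(data.frame(barcode = character(0), chrom = character(0),
                      position = numeric(0), read_count = numeric(0)))
  }
  w <- min(nchar(records$flank))
  flanks <- substr(records$flank, 1, w)
  uf <- unique(flanks)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uf))
  hits <- list()
  for (ch in names(genome$chrom_sizes)) {
    m <- Biostrings::matchPDict(pd, genome$sequence[[ch]])
    st <- Biostrings::startIndex(m)
    n_hits <- lengths(st)
    if (sum(n_hits) == 0) next
    hits[[ch]] <- data.frame(
      flank = rep(uf, n_hits),
      chrom = ch,
      position = unlist(st) - 1,
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    return(data.frame(barcode = character(0), chrom = character(0),
                      position = numeric(0), read_count = numeric(0)))
  }
  per_read <- merge(data.frame(barcode = records$barcode, flank = flanks,
                               stringsAsFactors = FALSE),
                    hits, by = "flank")
  agg <- stats::aggregate(
    list(read_count = rep(1, nrow(per_read))),
    by = per_read[, c("barcode", "chrom", "position")],
    FUN = sum
  )
  agg[order(agg$barcode, agg$chrom, agg$position), , drop = FALSE]
}

#' Consolidate candidate mapping locations of one barcode
#'
#' Same-chromosome candidate positions are merged by single-linkage with a
#' 10-bp link threshold: read counts are summed and the merged position is
#' the midpoint of the cluster extremes, rounded down. A barcode whose
#' candidates survive as more than one cluster is flagged ambiguous and
#' reported without a position.
#'
#' @param candidates data.frame with columns chrom, position, read_count for
#'   a single barcode.
#' @param max_gap link threshold in bp (default 10).
#' @return one-row data.frame: chrom, position, read_count, ambiguous,
#'   n_clusters.
#' @export
consolidate_locations <- function(candidates, max_gap = 10) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    stop("empty candidate list", call. = FALSE)
  }
  clusters <- list()
  for (ch in unique(candidates$chrom)) {
    sub <- candidates[candidates$chrom == ch, , drop = FALSE]
    o <- order(sub$position)
    pos <- sub$position[o]
    cnt <- sub$read_count[o]
    brk <- c(0, cumsum(diff(pos) > max_gap))
    for (g in unique(brk)) {
      p <- pos[brk == g]
      clusters[[length(clusters) + 1]] <- data.frame(
        chrom = ch,
        position = floor((min(p) + max(p)) / 2),
        read_count = sum(cnt[brk == g]),
        stringsAsFactors = FALSE
      )
    }
  }
  merged <- do.call(rbind, clusters)
  if (nrow(merged) > 1) {
    data.frame(chrom = NA_character_, position = NA_real_,
               read_count = sum(merged$read_count), ambiguous = TRUE,
               n_clusters = nrow(merged), stringsAsFactors = FALSE)
  } else {
    cbind(merged, ambiguous = FALSE, n_clusters = 1L)
  }
}

#' Consolidate candidate locations for every barcode
#'
#' @param candidates table from \code{\link{map_flanks}} (or pre-aligned
#'   real-data input) with columns barcode, chrom, position, read_count.
#' @param max_gap link threshold in bp.
#' @return data.frame keyed by barcode with the
#'   \code{\link{consolidate_locations}} columns.
#' @export
consolidate_barcodes <- function(candidates, max_gap = 10) {
  parts <- split(candidates, candidates$barcode)
  rows <- lapply(parts, consolidate_locations, max_gap = max_gap)
  out <- do.call(rbind, rows)
  out <- cbind(barcode = names(parts), out)
  rownames(out) <- NULL
  out
}

#' Reconcile barcode mappings from the two restriction enzymes
#'
#' Barcodes mapped unambiguously by both enzymes to positions agreeing
#' within \code{max_gap} bp get support class "both" and a read-count
#' weighted consensus position (rounded down). Barcodes recovered
#' unambiguously by exactly one enzyme are retained as "single_enzyme".
#' Cross-enzyme disagreement, or ambiguity in every supporting enzyme, yields
#' "ambiguous" and exclusion from downstream analysis.
#'
#' @param tat,msp \code{\link{consolidate_barcodes}} outputs for the TatI and
#'   MspI digestions.
#' @param max_gap agreement threshold in bp.
#' @return list with \code{pool} (barcode, chrom, position, read counts per
#'   enzyme, support_class) and \code{summary} (fractions by support class
#'   among all barcodes seen).
#' @export
reconcile_enzymes <- function(tat, msp, max_gap = 10) {
  all_bc <- sort(union(tat$barcode, msp$barcode))
  ti <- match(all_bc, tat$barcode)
  mi <- match(all_bc, msp$barcode)
  n <- length(all_bc)
  chrom <- rep(NA_character_, n)
  position <- rep(NA_real_, n)
  support <- rep("ambiguous", n)
  reads_tat <- ifelse(is.na(ti), 0, tat$read_count[ti])
  reads_msp <- ifelse(is.na(mi), 0, msp$read_count[mi])

  t_ok <- !is.na(ti) & !tat$ambiguous[ti]
  m_ok <- !is.na(mi) & !msp$ambiguous[mi]

  for (k in seq_len(n)) {
    if (t_ok[k] && m_ok[k]) {
      tc <- tat[ti[k], ]; mc <- msp[mi[k], ]
      if (tc$chrom == mc$chrom &&
          abs(tc$position - mc$position) <= max_gap) {
        chrom[k] <- tc$chrom
        position[k] <- floor((tc$position * tc$read_count +
                                mc$position * mc$read_count) /
                               (tc$read_count + mc$read_count))
        support[k] <- "both"
      }
    } else if (t_ok[k] || m_ok[k]) {
      src <- if (t_ok[k]) tat[ti[k], ] else msp[mi[k], ]
      chrom[k] <- src$chrom
      position[k] <- src$position
      support[k] <- "single_enzyme"
    }
  }
  pool <- data.frame(
    barcode = all_bc, chrom = chrom, position = position,
    reads_tat = reads_tat, reads_msp = reads_msp,
    mapping_reads = reads_tat + reads_msp,
    support_class = support, stringsAsFactors = FALSE
  )
  summary <- as.list(table(factor(support,
                                  c("both", "single_enzyme",
                                    "ambiguous"))) / n)
  list(pool = pool, summary = summary)
}
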