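#' Compute per-barcode expression scores from gDNA/cDNA amplicon counts
#'
#' The expression score of a barcode within one biological replicate is
#' the sum of its cDNA counts divided by the sum of its gDNA counts.
#' Barcodes whose total gDNA + cDNA count in a replicate is below
#' \code{min_total} (default 100) are flagged low-coverage and carry no
#' score; barcodes with zero gDNA but nonzero cDNA get a missing score with
#' a warning.
#'
#' @param counts data.frame with columns barcode, sample_id, condition,
#'   timepoint, replicate, gdna_count, cdna_count (multiple amplicon rows
#'   per barcode and sample are summed).
#' @param min_total coverage threshold on gDNA + cDNA total.
#' @return data.frame of expression profiles: one row per barcode x sample
#'   with gdna_total, cdna_total, expression_score, detectable and
#'   low_coverage.
#' @export
compute_expression_scores <- function(counts, min_total = 100) {
  req <- c("barcode", "sample_id", "gdna_count", "cdna_count")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts$gdna_count < 0) || any(counts$cdna_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  key <- counts[, intersect(c("barcode", "sample_id", "condition",
                              "timepoint", "replicate"), names(counts))]
  agg <- stats::aggregate(
    counts[, c("gdna_count", "cdna_count")],
    by = key, FUN = sum
  )
  names(agg)[names(agg) == "gdna_count"] <- "gdna_total"
  names(agg)[names(agg) == "cdna_count"] <- "cdna_total"
  agg$low_coverage <- (agg$gdna_total + agg$cdna_total) < min_total
  agg$detectable <- agg$cdna_total > 0
  agg$expression_score <- ifelse(
    agg$low_coverage | agg$gdna_total == 0,
    NA_real_,
    agg$cdna_total / agg$gdna_total
  )
  bad <- agg$gdna_total == 0 & agg$cdna_total > 0 & !agg$low_coverage
  if (any(bad)) {
    warning(sum(bad), " barcode/sample pair(s) have cDNA but no gDNA; ",
            "score set to missing")
  }
  agg[order(agg$barcode, agg$sample_id), , drop = FALSE]
}

#' Pivot expression profiles into a barcode x sample score matrix
#'
#' @param profiles output of \code{\link{compute_expression_scores}}.
#' @param value column to spread (default \code{expression_score}).
#' @return numeric matrix, rows barcodes, columns sample ids.
#' @export
score_matrix <- function(profiles, value = "expression_score") {
  barcodes <- sort(unique(profiles$barcode))
  samples <- sort(unique(profiles$sample_id))
  m <- matrix(NA_real_, length(barcodes), length(samples),
              dimnames = list(barcodes, samples))
  m[cbind(match(profiles$barcode, barcodes),
          match(profiles$sample_id, samples))] <- profiles[[value]]
  m
}

#' Median-of-ratios (size factor) normalisation of a score matrix
#'
#' The pseudo-reference is the per-barcode geometric mean over samples
#' (barcodes with any zero or missing score are excluded from the
#' reference); each sample's size factor is the median of its ratios to the
#' reference, and scores are divided by it — the batch normalisation used
#' for count-derived expression in differential-expression practice.
#'
#' @param scores numeric matrix, barcodes x samples.
#' @return list with \code{size_factors} and \code{normalized}.
#' @export
normalize_median_of_ratios <- function(scores) {
  if (ncol(scores) < 2) stop("need at least two samples", call. = FALSE)
  usable <- rowSums(is.na(scores) | scores <= 0) == 0
  if (!any(usable)) {
    stop("no barcode with a nonzero score in every sample", call. = FALSE)
  }
  ref <- exp(rowMeans(log(scores[usable, , drop = FALSE])))
  size_factors <- apply(scores[usable, , drop = FALSE], 2,
                        function(col) stats::median(col / ref))
  normalized <- sweep(scores, 2, size_factors, "/")
  list(size_factors = size_factors, normalized = normalized)
}

#' Classify expression dynamics across differentiation
#'
#' Barcodes detectable at both timepoints are grouped by the day-5/day-0
#' fold change of normalized expression: group 1 (turned off) for fold
#' change in [0, 0.5), group 2 (always on) for [0.5, 2], group 3 (turned
#' on) above 2. All remaining barcodes with gDNA representation but
#' undetectable cDNA at either timepoint form group 4 (constitutively
#' silenced). A z-score of log fold change is computed within groups 1-3.
#'
#' @param day0,day5 data.frames with columns barcode, score (normalized)
#'   and detectable.
#' @return data.frame: barcode, fc, group (1-4), zscore.
#' @export
classify_dynamics <- function(day0, day5) {
  common <- intersect(day0$barcode, day5$barcode)
  dropped <- setdiff(union(day0$barcode, day5$barcode), common)
  if (length(dropped)) {
    warning(length(dropped),
            " barcode(s) absent at one timepoint were dropped")
  }
  i0 <- match(common, day0$barcode)
  i5 <- match(common, day5$barcode)
  s0 <- day0$score[i0]
  s5 <- day5$score[i5]
  both <- day0$detectable[i0] & day5$detectable[i5] &
    !is.na(s0) & !is.na(s5) & s0 > 0
  fc <- ifelse(both, s5 / s0, NA_real_)
  group <- ifelse(!both, 4L,
                  ifelse(fc < 0.5, 1L, ifelse(fc <= 2, 2L, 3L)))
  z <- rep(NA_real_, length(common))
  for (g in 1:3) {
    idx <- which(group == g)
    if (length(idx) >= 2) {
      lf <- log(fc[idx])
      z[idx] <- (lf - mean(lf)) / stats::sd(lf)
    }
  }
  data.frame(barcode = common, fc = fc, group = group, zscore = z,
             stringsAsFactors = FALSE)
}

#' Nominate putative safe-harbor insertion sites
#'
#' Retains barcodes with at least \code{min_count} reads in both the gDNA
#' and cDNA datasets, at least \code{min_mapping_reads} inverse-PCR mapping
#' reads, an unambiguous single mapped site, and an intronic or intergenic
#' annotation. The expression-dynamics group is carried as a report column
#' so constitutively expressed (group 2) candidates are identifiable.
#'
#' @param pool reconciled mapping table (\code{pool} element of
#'   \code{\link{reconcile_enzymes}}), with barcode, chrom, position,
#'   mapping_reads, support_class.
#' @param profiles expression profiles
#'   (\code{\link{compute_expression_scores}}); gDNA and cDNA totals are
#'   summed over samples per barcode.
#' @param dynamics \code{\link{classify_dynamics}} output.
#' @param annotations data.frame with barcode and annotation
#'   (exonic/intronic/intergenic).
#' @param min_count,min_mapping_reads count filters (defaults 20 and 30).
#' @return candidate table with annotation and dynamics group.
#' @export
select_safe_harbors <- function(pool, profiles, dynamics, annotations,
                                min_count = 20, min_mapping_reads = 30) {
  totals <- stats::aggregate(
    profiles[, c("gdna_total", "cdna_total")],
    by = list(barcode = profiles$barcode), FUN = sum
  )
  cand <- merge(pool, totals, by = "barcode")
  cand <- merge(cand, annotations[, c("barcode", "annotation")],
                by = "barcode")
  cand <- merge(cand, dynamics[, c("barcode", "group")],
                by = "barcode", all.x = TRUE)
  keep <- cand$gdna_total >= min_count &
    cand$cdna_total >= min_count &
    cand$mapping_reads >= min_mapping_reads &
    cand$support_class != "ambiguous" &
    cand$annotation %in% c("intronic", "intergenic")
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
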