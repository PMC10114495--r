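#' Assign a CRISPRa perturbation identity to each cell
#'
#' A guide is "present" in a cell when its UMI count reaches
#' \code{min_guide_umi}. Cells with no present guide are "unassigned";
#' cells with more than five are "excluded" (five guides were delivered per
#' target); cells with one to five guides all drawn from a single target's
#' guide set are assigned that target (scramble guides form their own set);
#' one to five guides spanning two or more sets give "excluded".
#'
#' @param dataset an \code{sc_dataset} (or any list with
#'   \code{guide_matrix} and \code{guide_sets}).
#' @param min_guide_umi presence threshold (default 1: any captured UMI).
#' @return list with \code{perturbation} (label per cell),
#'   \code{n_guides} (present guides per cell) and
#'   \code{multiplicity_summary} (fractions of cells with 0, 1-5, >5
#'   guides).
#' @export
assign_perturbations <- function(dataset, min_guide_umi = 1) {
  gm <- dataset$guide_matrix
  sets <- dataset$guide_sets
  unknown <- setdiff(colnames(gm), sets$guide_id)
  if (length(unknown)) {
    stop("guide(s) not in any set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  target_of <- stats::setNames(sets$target, sets$guide_id)

  tr <- Matrix::summary(methods::as(gm, "TsparseMatrix"))
  tr <- tr[tr$x >= min_guide_umi, , drop = FALSE]
  n_cells <- nrow(gm)
  n_guides <- tabulate(tr$i, nbins = n_cells)
  cell_target <- target_of[colnames(gm)[tr$j]]

  # one label per cell: its single set, or "multi" if sets are mixed
  single_set <- rep(NA_character_, n_cells)
  if (nrow(tr)) {
    f <- factor(tr$i, levels = seq_len(n_cells))
    uniq_per_cell <- tapply(cell_target, f, function(x) {
      u <- unique(x)
      if (length(u) == 1) u else "multi"
    })
    single_set <- as.character(uniq_per_cell)
  }

  perturbation <- rep("unassigned", n_cells)
  with_guides <- n_guides >= 1
  perturbation[with_guides & n_guides > 5] <- "excluded"
  in_range <- with_guides & n_guides <= 5
  perturbation[in_range] <- ifelse(single_set[in_range] == "multi",
                                   "excluded", single_set[in_range])
  multiplicity_summary <- c(
    zero = mean(n_guides == 0),
    one_to_five = mean(n_guides >= 1 & n_guides <= 5),
    over_five = mean(n_guides > 5)
  )
  list(perturbation = perturbation, n_guides = n_guides,
       multiplicity_summary = multiplicity_summary)
}

#' Quality control and per-cell depth normalization
#'
#' Removes cells whose mitochondrial fraction exceeds \code{mito_max}
#' (default 10\%), cells flagged as doublets, and cells with zero total
#' UMIs (with a warning); the counts of every remaining cell are scaled to
#' sum to \code{scale} (default 10,000).
#'
#' @param dataset an \code{sc_dataset} with \code{gene_matrix} (cells x
#'   genes), \code{mito_genes} and a \code{cell_meta$doublet} flag.
#' @param mito_max maximum mitochondrial fraction.
#' @param scale target per-cell total after normalization.
#' @return list with \code{normalized} (cells x genes), \code{kept}
#'   (logical per input cell) and \code{mito_frac}.
#' @export
qc_and_normalize <- function(dataset, mito_max = 0.1, scale = 1e4) {
  gm <- dataset$gene_matrix
  totals <- Matrix::rowSums(gm)
  mito <- intersect(dataset$mito_genes, colnames(gm))
  mito_frac <- if (length(mito)) {
    Matrix::rowSums(gm[, mito, drop = FALSE]) / pmax(totals, 1)
  } else rep(0, nrow(gm))
  doublet <- if (!is.null(dataset$cell_meta$doublet)) {
    dataset$cell_meta$doublet
  } else rep(FALSE, nrow(gm))
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total UMI removed")
  }
  kept <- !zero & !doublet & mito_frac <= mito_max
  normalized <- gm[kept, , drop = FALSE] * (scale / totals[kept])
  list(normalized = normalized, kept = kept, mito_frac = mito_frac)
}

#' Per-target CRISPRa activation tests
#'
#' For each target, compares normalized target-gene expression between
#' cells assigned that perturbation and scramble-control cells with
#' Welch's two-sample t test, Bonferroni-corrected over the number of
#' targets tested. Zero fractions are computed on raw counts. The
#' percentile rank places the on-target group's mean expression among the
#' per-gene mean expression of all endogenous genes in scramble cells.
#'
#' @param dataset an \code{sc_dataset}; raw counts and the endogenous gene
#'   set are taken from it.
#' @param perturbation per-cell labels from
#'   \code{\link{assign_perturbations}} (aligned with the rows of
#'   \code{dataset$gene_matrix}).
#' @param normalized normalized matrix from \code{\link{qc_and_normalize}}
#'   (row subset of the dataset cells).
#' @param targets targets to test; defaults to all design targets present.
#' @param min_cells minimum cells per target group (default 40, matching a
#'   well-represented perturbation; targets below it are skipped).
#' @return data.frame with one row per tested target: n_cells, means,
#'   welch_t, p_raw, p_bonferroni, significance_class, zero fractions and
#'   percentile_rank.
#' @export
activation_tests <- function(dataset, perturbation, normalized,
                             targets = NULL, min_cells = 40) {
  stopifnot(length(perturbation) == nrow(dataset$gene_matrix))
  cells_kept <- rownames(normalized)
  pert_kept <- perturbation[match(cells_kept,
                                  rownames(dataset$gene_matrix))]
  if (is.null(targets)) targets <- dataset$design$target
  missing <- setdiff(targets, colnames(normalized))
  if (length(missing)) {
    stop("target gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scramble_cells <- cells_kept[pert_kept == "scramble"]
  endo <- intersect(dataset$design$target, colnames(normalized))
  gene_means <- Matrix::colMeans(normalized[scramble_cells, endo,
                                            drop = FALSE])

  rows <- list()
  eligible <- targets[vapply(targets, function(t) {
    sum(pert_kept == t) >= max(min_cells, 2)
  }, logical(1))]
  n_tests <- length(eligible)
  for (t in eligible) {
    on_cells <- cells_kept[pert_kept == t]
    x_on <- as.numeric(normalized[on_cells, t])
    x_sc <- as.numeric(normalized[scramble_cells, t])
    ht <- stats::t.test(x_on, x_sc)
    p_raw <- ht$p.value
    p_bonf <- min(1, p_raw * n_tests)
    raw_on <- as.numeric(dataset$gene_matrix[on_cells, t])
    raw_sc <- as.numeric(dataset$gene_matrix[scramble_cells, t])
    rows[[t]] <- data.frame(
      target = t,
      n_cells = length(on_cells),
      mean_on = mean(x_on),
      mean_scramble = mean(x_sc),
      welch_t = unname(ht$statistic),
      p_raw = p_raw,
      p_bonferroni = p_bonf,
      significance_class = significance_band(p_bonf),
      zero_fraction_on = 100 * mean(raw_on == 0),
      zero_fraction_control = 100 * mean(raw_sc == 0),
      percentile_rank = 100 * mean(gene_means <= mean(x_on)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

significance_band <- function(p) {
  ifelse(p > 0.05, "ns",
         ifelse(p > 0.01, "*",
                ifelse(p > 0.001, "**",
                       ifelse(p > 1e-4, "***", "****"))))
}
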