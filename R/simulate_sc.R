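#' Design table for a single-cell CRISPRa experiment
#'
#' Assigns each target gene a ChromHMM class; classes cycle through the
#' configured state labels by default.
#'
#' @param n_targets number of target genes.
#' @param states chromatin-state labels to cycle over.
#' @return data.frame with columns \code{target} and \code{class_label}.
#' @export
sc_design <- function(n_targets = 93L, states = state_labels(10L)) {
  data.frame(
    target = sprintf("T%03d", seq_len(n_targets)),
    class_label = rep(states, length.out = n_targets),
    stringsAsFactors = FALSE
  )
}

#' Simulate a single-cell CRISPRa dataset from the latent-state NB model
#'
#' Per cell: the total UMI count is log-normal; a cell carrying on-target
#' guides is in the "active" latent state with the class probability
#' \code{pi_c} (scramble and non-transfected cells are always basal); the
#' target-gene UMI count is negative binomial with mean
#' \code{exp(beta0_c + beta_act_c * active + log N)} and dispersion
#' \code{theta_c}; every other target gene is drawn at its own basal level;
#' background and mitochondrial genes fill the remaining UMIs. Guide capture
#' places 0-8 guides per cell following the configured multiplicity
#' distribution, drawn from the cell's target's guide set with configurable
#' cross-set contamination; doublet flags are recorded.
#'
#' @param config a \code{\link{sim_config}}.
#' @param design a \code{\link{sc_design}} table mapping targets to classes.
#' @param cells_per_target expected assignable on-target cells per target.
#' @param n_background_genes,n_mito_genes filler and mitochondrial genes.
#' @return an \code{sc_dataset}: list with \code{gene_matrix} (cells x genes,
#'   sparse), \code{guide_matrix} (cells x guides, sparse),
#'   \code{guide_sets}, \code{cell_meta} (total UMI, mito fraction, doublet
#'   flag, ground-truth identity and latent state), \code{design},
#'   \code{mito_genes} and \code{truth} (the generative parameters).
#' @export
simulate_sc_dataset <- function(config, design = NULL,
                                cells_per_target = 301L,
                                n_background_genes = 50L,
                                n_mito_genes = 5L) {
  validate_sim_config(config)
  if (is.null(design)) design <- sc_design(states = config$states)
  if (!all(c("target", "class_label") %in% names(design))) {
    stop("design must have columns target and class_label", call. = FALSE)
  }
  if (anyNA(design$class_label) ||
      !all(design$class_label %in% config$states)) {
    stop("every target must be assigned a known chromatin class",
         call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 3L))

  probs <- config$guide_multiplicity_probs
  p_assignable <- sum(probs[2:min(6, length(probs))])
  n_targets <- nrow(design)
  n_cells <- ceiling(n_targets * cells_per_target /
                       (p_assignable * (1 - config$sc_scramble_frac)))

  # identity and guide multiplicity
  mult <- sample(seq_along(probs) - 1L, n_cells, replace = TRUE, prob = probs)
  identity <- rep("none", n_cells)
  has_guides <- mult > 0
  is_scramble <- has_guides &
    stats::runif(n_cells) < config$sc_scramble_frac
  identity[is_scramble] <- "scramble"
  on_target <- has_guides & !is_scramble
  identity[on_target] <- sample(design$target, sum(on_target),
                                replace = TRUE)

  # per-cell totals, latent state, mitochondrial load
  N <- round(stats::rlnorm(n_cells, config$total_umi_lognormal[["meanlog"]],
                           config$total_umi_lognormal[["sdlog"]]))
  N <- pmax(N, 100)
  class_of_target <- stats::setNames(design$class_label, design$target)
  cell_class <- ifelse(on_target, class_of_target[identity], NA)
  pi_c <- ifelse(on_target, config$nb_pi_by_state[cell_class], 0)
  active <- stats::runif(n_cells) < pi_c
  mito_frac <- stats::rbeta(n_cells, config$mito_beta[["a"]],
                            config$mito_beta[["b"]])
  doublet <- stats::runif(n_cells) < config$sc_doublet_frac

  # target-gene counts: each cell expresses every target gene at basal level
  # except its own target, which may be active
  target_counts <- matrix(0L, n_cells, n_targets,
                          dimnames = list(NULL, design$target))
  logN <- log(N)
  for (j in seq_len(n_targets)) {
    cl <- design$class_label[j]
    z <- active & identity == design$target[j]
    mu <- exp(config$nb_beta0_by_state[[cl]] +
                config$nb_beta_act_by_state[[cl]] * z + logN)
    target_counts[, j] <- stats::rnbinom(n_cells,
                                         size = config$nb_theta_by_state[[cl]],
                                         mu = mu)
  }

  # mitochondrial and background filler so each cell sums to its total
  mito_total <- round(N * mito_frac)
  used <- rowSums(target_counts) + mito_total
  N <- pmax(N, used)
  remainder <- N - used
  mito_counts <- split_evenly(mito_total, n_mito_genes)
  bg_props <- as.numeric(stats::rgamma(n_background_genes, 2, 1))
  bg_props <- bg_props / sum(bg_props)
  bg_counts <- rmultinom_rows(remainder, bg_props)

  gene_names <- c(design$target,
                  sprintf("BG%03d", seq_len(n_background_genes)),
                  sprintf("MT-%d", seq_len(n_mito_genes)))
  gene_matrix <- cbind(target_counts, bg_counts, mito_counts)
  colnames(gene_matrix) <- gene_names
  rownames(gene_matrix) <- sprintf("cell_%06d", seq_len(n_cells))
  gene_matrix <- methods::as(Matrix::Matrix(gene_matrix, sparse = TRUE),
                             "CsparseMatrix")

  # guide sets and per-cell guide placement
  guide_sets <- rbind(
    data.frame(
      guide_id = paste0(rep(design$target, each = config$guides_per_target),
                        "_g", seq_len(config$guides_per_target)),
      target = rep(design$target, each = config$guides_per_target),
      stringsAsFactors = FALSE
    ),
    data.frame(guide_id = paste0("scramble_g", 1:10), target = "scramble",
               stringsAsFactors = FALSE)
  )
  guide_matrix <- place_guides(identity, mult, guide_sets, config)
  rownames(guide_matrix) <- rownames(gene_matrix)

  cell_meta <- data.frame(
    cell_id = rownames(gene_matrix),
    total_umi = Matrix::rowSums(gene_matrix),
    mito_frac_true = mito_frac,
    doublet = doublet,
    true_target = identity,
    true_class = ifelse(on_target, cell_class, NA_character_),
    true_active = active,
    true_multiplicity = mult,
    offset_umi = N,
    stringsAsFactors = FALSE
  )

  structure(list(
    gene_matrix = gene_matrix,
    guide_matrix = guide_matrix,
    guide_sets = guide_sets,
    cell_meta = cell_meta,
    design = design,
    mito_genes = sprintf("MT-%d", seq_len(n_mito_genes)),
    truth = list(
      beta0 = config$nb_beta0_by_state,
      beta_act = config$nb_beta_act_by_state,
      theta = config$nb_theta_by_state,
      pi = config$nb_pi_by_state,
      multiplicity_probs = config$guide_multiplicity_probs
    )
  ), class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("<sc_dataset> %d cells x %d genes, %d guides, %d targets\n",
              nrow(x$gene_matrix), ncol(x$gene_matrix),
              ncol(x$guide_matrix), nrow(x$design)))
  invisible(x)
}

# deterministic near-even split of a count vector over k columns
split_evenly <- function(total, k) {
  base <- total %/% k
  rem <- total %% k
  out <- matrix(base, length(total), k)
  out[, 1] <- out[, 1] + rem
  colnames(out) <- NULL
  out
}

# row-wise multinomial via sequential conditional binomials (vectorised over
# rows)
rmultinom_rows <- function(sizes, probs) {
  k <- length(probs)
  out <- matrix(0L, length(sizes), k)
  left <- sizes
  p_left <- 1
  for (j in seq_len(k - 1)) {
    pj <- probs[j] / p_left
    out[, j] <- stats::rbinom(length(sizes), left, min(max(pj, 0), 1))
    left <- left - out[, j]
    p_left <- p_left - probs[j]
  }
  out[, k] <- left
  out
}

place_guides <- function(identity, mult, guide_sets, config) {
  n_cells <- length(identity)
  by_target <- split(guide_sets$guide_id, guide_sets$target)
  all_guides <- guide_sets$guide_id
  tri_i <- integer(0)
  tri_j <- integer(0)
  guide_index <- stats::setNames(seq_along(all_guides), all_guides)
  cells_with <- which(mult > 0)
  picks <- vector("list", length(cells_with))
  for (k in seq_along(cells_with)) {
    i <- cells_with[k]
    own <- by_target[[identity[i]]]
    m <- mult[i]
    g <- if (m <= length(own)) sample(own, m) else
      c(own, sample(setdiff(all_guides, own), m - length(own)))
    if (m <= 5 && stats::runif(1) < config$sc_cross_contamination) {
      g[1] <- sample(setdiff(all_guides, own), 1)
    }
    picks[[k]] <- guide_index[g]
  }
  lens <- lengths(picks)
  tri_i <- rep(cells_with, lens)
  tri_j <- unlist(picks, use.names = FALSE)
  umis <- 1L + stats::rpois(length(tri_i), 20)
  Matrix::sparseMatrix(i = tri_i, j = tri_j, x = umis,
                       dims = c(n_cells, length(all_guides)),
                       dimnames = list(NULL, all_guides))
}
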