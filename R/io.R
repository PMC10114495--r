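#' Write reads to FASTQ
#'
#' @param reads data.frame with read_id and sequence columns (as returned
#'   per enzyme by \code{\link{simulate_ipcr_reads}}).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED3 for plain intervals, BED4 when \code{name_col} is given, BED6 when
#' \code{score_col} and \code{strand_col} are also given. Starts are
#' written as-is (0-based half-open, the BED convention).
#'
#' @param df interval data.frame with chrom, start, end.
#' @param path output path.
#' @param name_col,score_col,strand_col optional column names.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path, name_col = NULL, score_col = NULL,
                      strand_col = NULL) {
  cols <- data.frame(chrom = df$chrom,
                     start = format_int(df$start),
                     end = format_int(df$end))
  if (!is.null(name_col)) cols$name <- df[[name_col]]
  if (!is.null(score_col)) cols$score <- df[[score_col]]
  if (!is.null(strand_col)) cols$strand <- df[[strand_col]]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a signal track as bedGraph
#'
#' @param track data.frame with chrom, start, end, value.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(chrom = track$chrom,
                    start = format_int(track$start),
                    end = format_int(track$end),
                    value = formatC(track$value, format = "g", digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_int <- function(x) formatC(x, format = "d")

#' Write a full synthetic study to a directory
#'
#' Emits every input file the pipeline consumes: per-enzyme FASTQ,
#' truth_insertions.bed (BED6), segmentation.bed (BED4), one bedGraph per
#' mark, tads.bed (BED3), barcode_counts.tsv across conditions, the
#' single-cell matrices (MatrixMarket + index files) and truth.json.
#' Identical configurations produce byte-identical outputs.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @param sc simulate the single-cell dataset too (slower).
#' @return invisible list of the simulated objects.
#' @export
write_simulation <- function(config, out_dir, sc = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  pool <- simulate_reporter_pool(genome, config)
  reads <- simulate_ipcr_reads(pool, genome, config)

  write_fastq(reads$TatI, file.path(out_dir, "reads_TatI.fastq"))
  write_fastq(reads$MspI, file.path(out_dir, "reads_MspI.fastq"))

  truth <- pool$truth
  truth$end <- truth$position + 1
  truth$read_count <- reads$truth_read_counts$reads_TatI +
    reads$truth_read_counts$reads_MspI
  truth$start <- truth$position
  write_bed(truth[, c("chrom", "start", "end", "barcode", "read_count",
                      "strand")],
            file.path(out_dir, "truth_insertions.bed"),
            name_col = "barcode", score_col = "read_count",
            strand_col = "strand")
  write_bed(genome$segmentation, file.path(out_dir, "segmentation.bed"),
            name_col = "state")
  write_bed(genome$tads, file.path(out_dir, "tads.bed"))
  for (mark in names(genome$tracks)) {
    write_bedgraph(genome$tracks[[mark]],
                   file.path(out_dir, paste0(mark, ".bedgraph")))
  }

  counts <- rbind(
    simulate_count_table(pool, config, 0, "control"),
    simulate_count_table(pool, config, 2, "control"),
    simulate_count_table(pool, config, 5, "control"),
    simulate_count_table(pool, config, 0, "VPR"),
    simulate_count_table(pool, config, 5, "VPR")
  )
  utils::write.table(counts, file.path(out_dir, "barcode_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sc_data <- NULL
  if (sc) {
    sc_data <- simulate_sc_dataset(config)
    Matrix::writeMM(Matrix::t(sc_data$gene_matrix),
                    file.path(out_dir, "matrix.mtx"))
    writeLines(rownames(sc_data$gene_matrix),
               file.path(out_dir, "barcodes.tsv"))
    writeLines(colnames(sc_data$gene_matrix),
               file.path(out_dir, "features.tsv"))
    Matrix::writeMM(Matrix::t(sc_data$guide_matrix),
                    file.path(out_dir, "guide_matrix.mtx"))
    writeLines(colnames(sc_data$guide_matrix),
               file.path(out_dir, "guides.tsv"))
    utils::write.table(sc_data$guide_sets,
                       file.path(out_dir, "guide_sets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sc_data$cell_meta,
                       file.path(out_dir, "cell_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  truth_json <- list(
    seed = config$seed,
    decay_params = as.list(config$decay_params),
    state_deviation = as.list(config$state_deviation_by_state),
    basal_mu = as.list(config$basal_mu_by_state),
    frac_silent = config$frac_silent,
    nb = list(beta0 = as.list(config$nb_beta0_by_state),
              beta_act = as.list(config$nb_beta_act_by_state),
              theta = as.list(config$nb_theta_by_state),
              pi = as.list(config$nb_pi_by_state))
  )
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(genome = genome, pool = pool, reads = reads,
                 counts = counts, sc = sc_data))
}
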