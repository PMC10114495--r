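# Shared small simulation, built once per test run
shared_sim <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$sim)) {
      cfg <- sim_config(seed = 11, n_chromosomes = 2, chrom_length = 4e5,
                        n_insertions = 600)
      genome <- simulate_genome(cfg)
      pool <- simulate_reporter_pool(genome, cfg)
      cache$sim <- list(cfg = cfg, genome = genome, pool = pool)
    }
    cache$sim
  }
})

# Independent brute-force single-linkage clustering oracle: connected
# components of the graph linking candidates on the same chromosome within
# max_gap bp
brute_force_clusters <- function(candidates, max_gap = 10) {
  n <- nrow(candidates)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            candidates$chrom[i] == candidates$chrom[j] &&
            abs(candidates$position[i] - candidates$position[j]) <= max_gap) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# aggregate per-barcode totals and raw score from a count-table-derived
# profile set
aggregate_profiles <- function(profiles) {
  a <- stats::aggregate(profiles[, c("gdna_total", "cdna_total")],
                        by = list(barcode = profiles$barcode), FUN = sum)
  a$score <- ifelse(a$gdna_total > 0, a$cdna_total / a$gdna_total, NA)
  a$detectable <- a$cdna_total > 0
  a
}
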