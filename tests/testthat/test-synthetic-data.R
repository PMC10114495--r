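test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(segment_length_mean = 2e6, chrom_length = 1e6),
               "segment_length_mean")
  expect_error(sim_config(frac_silent = 1.5), "probabilities")
  expect_error(sim_config(nb_theta_by_state = rep(-1, 10)), "positive")
  expect_error(sim_config(state_probs = rep(0.2, 10)), "sum to 1")
})

test_that("segmentation tiles each chromosome exactly", {
  sim <- shared_sim()
  seg <- sim$genome$segmentation
  for (ch in names(sim$genome$chrom_sizes)) {
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], unname(sim$genome$chrom_sizes[[ch]]))
    expect_true(all(s$start[-1] == s$end[-nrow(s)])) # no gaps, no overlap
  }
  expect_equal(sum(seg$end - seg$start), sum(sim$genome$chrom_sizes))
})

test_that("identical seeds give identical genomes and reads", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chrom_length = 1e5,
                    n_insertions = 50)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))
  expect_identical(g1$segmentation, g2$segmentation)
  expect_identical(g1$tracks, g2$tracks)
  p1 <- simulate_reporter_pool(g1, cfg)
  p2 <- simulate_reporter_pool(g2, cfg)
  expect_identical(p1$truth, p2$truth)
  r1 <- simulate_ipcr_reads(p1, g1, cfg)
  r2 <- simulate_ipcr_reads(p2, g2, cfg)
  expect_identical(r1$TatI$sequence, r2$TatI$sequence)
})

test_that("state segment counts follow the sampling distribution", {
  cfg <- sim_config(seed = 2, n_chromosomes = 2, chrom_length = 1e6,
                    segment_length_mean = 200, n_insertions = 10)
  g <- simulate_genome(cfg)
  counts <- table(factor(g$segmentation$state, levels = cfg$states))
  n <- sum(counts)
  expect_gt(n, 5000)
  p <- 1 / cfg$n_states
  sd3 <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= sd3))
})

test_that("insertion AT bias behaves as configured", {
  sim <- shared_sim()
  genome_at <- mean(unlist(lapply(names(sim$genome$chrom_sizes), function(ch) {
    Biostrings::letterFrequency(sim$genome$sequence[[ch]], "AT",
                                as.prob = TRUE)
  })))
  # biased pool (default at_bias_strength = 1): AT around insertions above
  # the genome average
  expect_gt(mean(sim$pool$truth$at), genome_at + 0.01)
  # unbiased pool: close to the genome average
  cfg0 <- sim_config(seed = 11, n_chromosomes = 2, chrom_length = 4e5,
                     n_insertions = 600, at_bias_strength = 0)
  pool0 <- simulate_reporter_pool(sim$genome, cfg0)
  expect_lt(abs(mean(pool0$truth$at) - genome_at), 0.02)
})

test_that("the pool has the requested size with distinct barcodes", {
  sim <- shared_sim()
  tr <- sim$pool$truth
  expect_equal(nrow(tr), sim$cfg$n_insertions)
  expect_equal(anyDuplicated(tr$barcode), 0)
  expect_true(all(nchar(tr$barcode) == 17))
  expect_true(all(tr$state %in% sim$cfg$states))
})

test_that("count tables obey the generative scalings", {
  sim <- shared_sim()
  counts <- simulate_count_table(sim$pool, sim$cfg, 0, "control")
  tr <- sim$pool$truth
  silent <- tr$barcode[tr$silent]
  # silent barcodes draw cDNA from a zero-mean Poisson: all zero
  expect_true(all(counts$cdna_count[counts$barcode %in% silent] == 0))
  # doubling cdna_depth_scale doubles cDNA in expectation, gDNA unchanged
  cfg2 <- sim$cfg
  cfg2$cdna_depth_scale <- sim$cfg$cdna_depth_scale * 2
  counts2 <- simulate_count_table(sim$pool, cfg2, 0, "control")
  # identical seed and draw order: replicate 1 gDNA is byte-identical
  r1 <- counts$replicate == 1
  expect_identical(counts2$gdna_count[r1], counts$gdna_count[r1])
  ratio <- sum(counts2$cdna_count[r1]) / sum(counts$cdna_count[r1])
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("low-basal reporters are activated more strongly than high-basal", {
  sim <- shared_sim()
  tr <- sim$pool$truth[!sim$pool$truth$silent, ]
  lo <- tr$basal_log_d0 < stats::median(tr$basal_log_d0)
  expect_gt(mean(tr$log_fold_ipsc[lo]), mean(tr$log_fold_ipsc[!lo]))
})

test_that("well-formed reads re-parse to their originating barcode", {
  sim <- shared_sim()
  reads <- simulate_ipcr_reads(sim$pool, sim$genome, sim$cfg)
  ex <- extract_barcodes(reads$TatI, reads$spec)
  good <- reads$TatI[!reads$TatI$malformed, ]
  got <- ex$records$barcode[match(good$read_id, ex$records$read_id)]
  expect_true(all(got == good$barcode))
})

test_that("single-cell counts conserve per-cell totals and honour pi", {
  cfg <- sim_config(seed = 21)
  des <- sc_design(n_targets = 4, states = cfg$states[1:4])
  ds <- simulate_sc_dataset(cfg, des, cells_per_target = 60)
  expect_equal(unname(Matrix::rowSums(ds$gene_matrix)),
               unname(ds$cell_meta$total_umi))
  # pi = 0 everywhere: no cell is active and target counts match the basal
  # mean
  cfg0 <- sim_config(seed = 21, nb_pi_by_state = stats::setNames(
    rep(0, 10), cfg$states))
  ds0 <- simulate_sc_dataset(cfg0, des, cells_per_target = 200)
  expect_true(all(!ds0$cell_meta$true_active))
  y <- as.numeric(ds0$gene_matrix[, des$target[1]])
  expected <- mean(exp(cfg$nb_beta0_by_state[[des$class_label[1]]] +
                         log(ds0$cell_meta$offset_umi)))
  se <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - expected), 4 * se + 0.005)
})

test_that("simulated NB counts match the model moments at scale", {
  # one class, fixed offset, 50,000 cells: empirical mean and variance of a
  # basal gene match mu and mu + mu^2/theta
  cfg <- sim_config(
    seed = 8,
    nb_beta0_by_state = stats::setNames(rep(-9, 10), state_labels(10)),
    nb_theta_by_state = stats::setNames(rep(0.8, 10), state_labels(10)),
    nb_pi_by_state = stats::setNames(rep(0, 10), state_labels(10)),
    total_umi_lognormal = c(meanlog = log(1e4), sdlog = 0)
  )
  des <- sc_design(n_targets = 1, states = "E1")
  ds <- simulate_sc_dataset(cfg, des, cells_per_target = 40000,
                            n_background_genes = 5)
  y <- as.numeric(ds$gene_matrix[, "T001"])
  n <- length(y)
  expect_gt(n, 49000)
  mu <- exp(-9 + log(ds$cell_meta$offset_umi[1]))
  v_theory <- mu + mu^2 / 0.8
  expect_lt(abs(mean(y) - mu), 3 * sqrt(v_theory / n))
  # variance of the sample variance for an overdispersed count ~ consistent
  expect_lt(abs(stats::var(y) - v_theory) / v_theory, 0.1)
})

test_that("guide multiplicity follows the configured distribution", {
  cfg <- sim_config(seed = 13)
  des <- sc_design(n_targets = 8, states = cfg$states[1:8])
  ds <- simulate_sc_dataset(cfg, des, cells_per_target = 150)
  m <- ds$cell_meta$true_multiplicity
  probs <- cfg$guide_multiplicity_probs
  n <- length(m)
  for (k in 0:8) {
    obs <- sum(m == k)
    expect_lt(abs(obs - n * probs[k + 1]),
              3 * sqrt(n * probs[k + 1] * (1 - probs[k + 1])) + 1)
  }
})

test_that("a target without a class assignment is rejected", {
  cfg <- sim_config(seed = 1)
  bad <- data.frame(target = "T1", class_label = "nonsense")
  expect_error(simulate_sc_dataset(cfg, bad), "class")
})

test_that("written simulation files are deterministic and well-formed", {
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chrom_length = 1e5,
                    n_insertions = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  for (f in c("reads_TatI.fastq", "truth_insertions.bed",
              "segmentation.bed", "tads.bed", "barcode_counts.tsv",
              "H3K4me3.bedgraph", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
  bed <- read.table(file.path(d1, "truth_insertions.bed"), sep = "\t")
  expect_equal(ncol(bed), 6)
  expect_equal(nrow(bed), 40)
})
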