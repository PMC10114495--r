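make_counts <- function(barcode, gdna, cdna, sample_id = "s1") {
  data.frame(barcode = barcode, sample_id = sample_id,
             condition = "control", timepoint = 0,
             replicate = 1, gdna_count = gdna, cdna_count = cdna)
}

test_that("expression scores follow the cDNA/gDNA ratio and filters", {
  counts <- rbind(make_counts("b1", c(50, 60), c(10, 12)),
                  make_counts("b2", 40, 50),
                  make_counts("b3", 120, c(0, 0)))
  pr <- compute_expression_scores(counts)
  expect_equal(pr$expression_score[pr$barcode == "b1"], 22 / 110)
  b2 <- pr[pr$barcode == "b2", ]      # total 90 < 100
  expect_true(b2$low_coverage)
  expect_true(is.na(b2$expression_score))
  b3 <- pr[pr$barcode == "b3", ]
  expect_equal(b3$expression_score, 0)
  expect_false(b3$detectable)
  expect_error(compute_expression_scores(make_counts("b", -1, 5)),
               "non-negative")
  expect_warning(
    compute_expression_scores(make_counts("b", 0, 200)), "no gDNA")
})

test_that("median-of-ratios factors satisfy the exact identities", {
  set.seed(4)
  base <- rlnorm(41, 0, 1)
  m <- cbind(s1 = base, s2 = base)
  nm <- normalize_median_of_ratios(m)
  expect_equal(unname(nm$size_factors), c(1, 1))

  m2 <- cbind(s1 = base, s2 = 2 * base)
  nm2 <- normalize_median_of_ratios(m2)
  expect_equal(unname(nm2$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(nm2$normalized[, 1], nm2$normalized[, 2])

  # permuting barcodes leaves the factors unchanged
  perm <- sample(nrow(m2))
  expect_equal(normalize_median_of_ratios(m2[perm, ])$size_factors,
               nm2$size_factors)

  # median ratio of each normalized sample to the reference equals 1
  ref <- exp(rowMeans(log(nm2$normalized)))
  for (j in 1:2) {
    expect_lt(abs(stats::median(nm2$normalized[, j] / ref) - 1), 1e-12)
  }
  expect_error(normalize_median_of_ratios(cbind(c(0, 1), c(1, 0))),
               "nonzero")
})

test_that("a per-sample scaling is exactly undone by normalization", {
  set.seed(5)
  m <- matrix(rlnorm(300), 100, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  scaled <- m
  scaled[, 2] <- scaled[, 2] * 7.3
  n1 <- normalize_median_of_ratios(m)$normalized
  n2 <- normalize_median_of_ratios(scaled)$normalized
  # the distortion of sample b is removed: the scaled run equals the clean
  # run up to one global factor (the reference absorbs c^(1/3))
  ratio <- n2 / n1
  expect_lt(max(abs(ratio - 7.3^(1 / 3))), 1e-10)
  # and the scaled sample is no longer an outlier against the others
  expect_equal(stats::median(n2[, 2] / n2[, 1]),
               stats::median(n1[, 2] / n1[, 1]), tolerance = 1e-10)
})

test_that("median-of-ratios agrees with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(6)
  m <- matrix(rlnorm(51 * 4), 51, 4)  # odd row count: medians coincide
  ours <- normalize_median_of_ratios(m)$size_factors
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("dynamics groups partition barcodes by the printed thresholds", {
  day0 <- data.frame(barcode = paste0("b", 1:6),
                     score = c(1, 1, 1, 1, 1, 1),
                     detectable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  day5 <- data.frame(barcode = paste0("b", 1:6),
                     score = c(0.3, 0.5, 1, 2, 2.5, 1),
                     detectable = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  dyn <- classify_dynamics(day0, day5)
  expect_equal(dyn$group, c(1L, 2L, 2L, 2L, 3L, 4L))
  # detectable at day0, zero cDNA at day5 -> group 4
  day5b <- day5
  day5b$score[1] <- 0
  day5b$detectable[1] <- FALSE
  expect_equal(classify_dynamics(day0, day5b)$group[1], 4L)
  # a barcode absent at one timepoint is dropped with a warning
  expect_warning(classify_dynamics(day0[-1, ], day5), "dropped")
  # groups 1-4 partition: every barcode gets exactly one group
  expect_false(anyNA(dyn$group))
})

test_that("z-scores are standardized within dynamics groups", {
  set.seed(8)
  n <- 30
  day0 <- data.frame(barcode = paste0("b", 1:n), score = rep(1, n),
                     detectable = TRUE)
  day5 <- data.frame(barcode = paste0("b", 1:n),
                     score = exp(rnorm(n, 0, 0.2)),  # all in group 2
                     detectable = TRUE)
  dyn <- classify_dynamics(day0, day5)
  expect_true(all(dyn$group == 2L))
  expect_lt(abs(mean(dyn$zscore)), 1e-10)
  expect_equal(stats::sd(dyn$zscore), 1, tolerance = 1e-10)
})

test_that("safe-harbor selection applies every filter", {
  pool <- data.frame(
    barcode = c("ok", "lowmap", "exonic", "ambig", "lowcount"),
    chrom = "chr1", position = 1:5 * 100,
    mapping_reads = c(35, 29, 50, 40, 60),
    support_class = c("both", "both", "single_enzyme", "ambiguous", "both")
  )
  profiles <- data.frame(
    barcode = rep(pool$barcode, each = 1),
    gdna_total = c(25, 30, 40, 50, 15),
    cdna_total = c(25, 30, 40, 50, 60)
  )
  dynamics <- data.frame(barcode = pool$barcode, group = c(2, 2, 2, 2, 2))
  ann <- data.frame(barcode = pool$barcode,
                    annotation = c("intergenic", "intronic", "exonic",
                                   "intergenic", "intronic"))
  out <- select_safe_harbors(pool, profiles, dynamics, ann)
  expect_equal(out$barcode, "ok")
  expect_equal(out$group, 2)
  expect_equal(out$annotation, "intergenic")
})

test_that("normalized scores track the ground-truth basal expression", {
  sim <- shared_sim()
  pr <- compute_expression_scores(
    simulate_count_table(sim$pool, sim$cfg, 0, "control"))
  a <- aggregate_profiles(pr)
  tr <- sim$pool$truth
  truth_expr <- ifelse(tr$silent, 0, exp(tr$basal_log_d0))
  truth_expr <- truth_expr[match(a$barcode, tr$barcode)]
  rho <- stats::cor(a$score, truth_expr, method = "spearman",
                    use = "complete.obs")
  expect_gt(rho, 0.9)
})
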