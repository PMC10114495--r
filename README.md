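# crispracontext

Analysis of massively parallel barcoded-reporter assays of CRISPR
activation (CRISPRa) efficacy across chromatin contexts, together with a
ground-truth synthetic-data generator for end-to-end validation.

In the assayed design, a barcoded minimal reporter is integrated thousands
of times genome-wide with the piggyBac transposon; expression of each
insertion is the ratio of its barcode counts in cDNA versus gDNA amplicon
sequencing, and insertion sites are recovered by inverse PCR with two
restriction enzymes. A companion single-cell experiment activates
endogenous genes with dCas9-VPR and captures guide identities per cell.
The package answers: how does chromatin context (ChromHMM state, histone
marks, TADs) shape basal expression, and how does basal expression shape
CRISPRa response?

It is aimed at computational biologists analysing TRIP-style reporter
assays or CRISPRa perturb-seq experiments, and at methodologists who need
a tested reference implementation of the models below.

## Core models

* **Expression score** per barcode and replicate: `sum(cDNA)/sum(gDNA)`,
  normalized across samples by median-of-ratios size factors
  (pseudo-reference = per-barcode geometric mean).
* **Exponential decay of activation.** With `x = log(basal expression)`
  and `y = log(fold activation)`, the model `y = A·exp(−k·x) + C` is
  fitted by nonlinear least squares; residual ranks define six activation
  bins, chromatin-state enrichment per bin is tested binomially against
  theoretical counts, and globally standardized residual z-scores are
  compared across states by one-way ANOVA.
* **Two-latent-state negative binomial.** Each cell's target-gene UMI
  count is NB with mean `exp(β0_c + βact_c·z_i + log N_i)` and dispersion
  `θ_c`, where `z_i` is the unobserved basal/active state, `c` the
  ChromHMM class and `N_i` the cell's total UMI (offset); variance is
  `μ + μ²/θ`. Fitting is EM with scramble-control cells anchored to the
  basal state; `βact_c` is the log fold increase from basal to active and
  `π_c` the active-state probability.

## Worked example

```r
library(crispracontext)

# a cell of ChromHMM class fitted at beta0 = -13.49, beta_act = 3.94,
# sequenced to 10,000 total UMIs:
predicted_mean(list(beta0 = -13.49, beta_act = 3.94), state = "basal",  N = 1e4)
#> [1] 0.01384737   # ~0.014 expected target UMIs in the basal state
predicted_mean(list(beta0 = -13.49, beta_act = 3.94), state = "active", N = 1e4)
#> [1] 0.7120126    # ~0.71 in the active state

# full synthetic study: simulate, map, score, model
cfg    <- sim_config(seed = 1, n_insertions = 1500)
genome <- simulate_genome(cfg)
pool   <- simulate_reporter_pool(genome, cfg)

reads <- simulate_ipcr_reads(pool, genome, cfg)
cons  <- lapply(reads[c("TatI", "MspI")], function(rd)
  consolidate_barcodes(map_flanks(extract_barcodes(rd, reads$spec)$records, genome)))
rec   <- reconcile_enzymes(cons$TatI, cons$MspI)
unlist(rec$summary)
#>          both single_enzyme     ambiguous
#>     0.7472973     0.2527027     0.0000000

agg <- function(cond) {
  pr <- compute_expression_scores(simulate_count_table(pool, cfg, 0, cond))
  a  <- aggregate(pr[, c("gdna_total", "cdna_total")],
                  by = list(barcode = pr$barcode), FUN = sum)
  a$score <- a$cdna_total / a$gdna_total
  a
}
fa  <- compute_fold_activation(agg("control"), agg("VPR"))
fit <- fit_exponential_decay(fa$table)
fit
#> <decay_fit> y = 501 * exp(-0.001009 x) + -499.8   (R^2 = 0.677, n = 1308)
```

About three quarters of barcodes are independently mapped by both enzymes
(the rest by one), every accepted barcode maps to its true insertion base,
and log fold activation decays with log basal expression with roughly
two-thirds of its variance explained — the characteristic signature the
assay is built to detect. `rank_and_enrich()` and `residual_state_anova()`
then show the bivalent state over-represented among the most
hyper-activated reporters.

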