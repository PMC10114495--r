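---
title: "Models and methods behind crispracontext"
author: "crispracontext maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crispracontext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispracontext)
```

# The assay and what the package computes

`crispracontext` analyses massively parallel barcoded-reporter experiments
that measure how the chromatin context of a genomic site shapes CRISPR
activation (CRISPRa) efficacy. In such an experiment a minimal reporter
carrying a random 17-nt barcode in its 3' UTR is integrated thousands of
times across the genome with the piggyBac transposon, which prefers AT-rich
sequence. Reporter expression is read out as the ratio of barcode counts in
cDNA and gDNA amplicon sequencing, insertion sites are recovered by inverse
PCR with two restriction enzymes, and a companion single-cell experiment
targets endogenous genes with dCas9-VPR and reads both transcripts and guide
identities per cell.

The package implements the complete downstream computation: barcode
genotyping, expression scoring and normalisation, chromatin-context
association, an exponential-decay model of activation versus basal
expression, single-cell guide assignment and activation testing, and a
two-latent-state negative-binomial model of per-cell activation. It also
ships a synthetic-data generator that produces every input with known ground
truth, so each step can be tested for exact recovery.

# Synthetic data: what it emulates, and what it does not

`sim_config()` fixes the whole study in one object; `simulate_genome()`,
`simulate_reporter_pool()`, `simulate_ipcr_reads()`,
`simulate_count_table()` and `simulate_sc_dataset()` derive every file the
pipeline consumes. Identical configurations give byte-identical outputs.

The generator emulates:

* **AT-biased integration.** The genome carries a smooth AT-probability
  field (Gaussian knots every 2 kb around a 59.1% AT level, the human
  genome-wide value); insertion sites are drawn with weight
  `exp(at_bias_strength * z)` where `z` is the z-score of the AT fraction in
  the 100-bp window around the site. With the default strength of 1 the
  mean AT content at insertions sits a few percentage points above the
  genome average, matching the direction and rough magnitude reported for
  piggyBac.
* **Chromatin states and marks.** Ten states `E1`..`E10` tile the genome in
  exponential segments (mean 2 kb). Marks are emitted per state the way a
  10-state segmentation behaves: promoter (H3K4me3), enhancer
  (H3K4me1/H3K27ac), transcription (H3K36me3), bivalent (H3K4me3 *and*
  H3K27me3), polycomb (H3K27me3), heterochromatin (H3K9me3), quiescent.
* **Basal expression.** Log expression is normal per state (active states
  high, polycomb/heterochromatin low, sd 0.6); a `frac_silent` fraction
  (default 15%) of reporters is undetectable. Differentiation is modelled
  as a per-reporter log fold change between day 0 and day 5 plus a shared
  per-TAD, per-timepoint shift (sd 0.5) that induces the within-TAD
  expression correlation the TAD analysis tests for.
* **CRISPRa response.** Ground-truth log fold activation is
  `log(A*exp(-k*log basal) + C) + state deviation + noise`, with defaults
  A = 3, k = 0.5, C = 0.2, noise sd 0.3, a +1 deviation for the bivalent
  state and −0.5 for the H3K9me3 state. These defaults reproduce the
  qualitative study findings: stronger activation at low basal expression,
  bivalent hyper-activation, most reporters activated more than 2-fold.
* **Counts.** gDNA is Poisson around its depth; cDNA is Poisson with mean
  proportional to gDNA × expression, so the cDNA/gDNA score estimates
  expression. Inverse-PCR reads follow
  `[upstream anchor][barcode][downstream anchor][genomic flank]`, with a
  configurable malformed fraction (wrong barcode length or corrupted
  anchor) and per-enzyme detection probabilities (defaults 0.80 and 0.93,
  which land near three quarters of barcodes supported by both enzymes).
* **Single cells.** Per cell, the total UMI count is log-normal (median
  10,000); a cell carrying on-target guides is in the "active" latent
  state with class probability `pi_c`; the target-gene count is negative
  binomial with mean `exp(beta0_c + beta_act_c*active + log N)` and
  dispersion `theta_c`; other target genes are drawn at their own basal
  level and background plus mitochondrial genes fill the cell to its
  total. Guides per cell follow a configurable distribution over 0..8
  whose default matches the observed multiplicity spectrum (6.1% zero,
  81.27% one to five, 12.63% more); the generative process behind that
  spectrum is not known, so it is exposed as a free distribution rather
  than asserted. Cells with zero guides represent the non-transfected pool;
  guide-bearing cells are scramble controls with probability 5/95,
  matching a 5:5:90 no-transfection:scramble:on-target pool ratio.

It does **not** emulate realistic sequence content, PCR chimeras,
sequencing errors beyond malformed-read injection, ambient RNA, or doublet
transcriptomes (doublets are boolean flags consumed by QC). Passing
recovery tests on this generator therefore demonstrates the correctness of
the computations, not robustness to artefacts absent from the model.

# Barcode genotyping

Reads are filtered to the declared structure; anchors may mismatch up to a
configured maximum (default 1), the barcode region must be exactly 17 nt,
and at least 20 nt of genomic flank must remain. On synthetic data flanks
are mapped by exact dictionary search against the synthetic genome; on real
data the module consumes a pre-aligned table instead, since read alignment
is out of its scope — the bespoke logic is everything after alignment.

Candidate locations of one barcode are merged when they lie within 10 bp.
"Within 10 bp" is implemented as single-linkage clustering with a 10-bp
link threshold (the minimal reading of a pairwise-distance rule); merged
read counts are summed and the reported position is the midpoint of the
cluster extremes, rounded down. A barcode surviving as more than one
cluster is ambiguous and carries no position. Across the two enzymes,
unambiguous positions agreeing within 10 bp become support class `both`
with a read-count-weighted midpoint (weighting respects evidence; plain
midpoint when counts tie); barcodes recovered by exactly one enzyme are
kept as `single_enzyme`; everything else is `ambiguous` and excluded
downstream.

# Expression, normalisation and dynamics

The expression score of a barcode in a biological replicate is
`sum(cDNA)/sum(gDNA)`. Barcodes with fewer than 100 total counts are
flagged low-coverage and not scored. Samples are normalised by the
median-of-ratios method: the pseudo-reference is the per-barcode geometric
mean across samples (barcodes with any zero excluded from the reference)
and each sample's size factor is the median ratio to that reference — the
same estimator DESeq2 uses for count matrices, and the test suite
cross-checks against it. Note the estimator removes *relative* distortion
between samples; a c-fold rescaling of one of m samples reappears as a
global factor c^(1/m) absorbed by the reference, which is irrelevant to
every downstream ratio.

Differentiation dynamics use the day-5/day-0 fold change of normalized
expression: group 1 below 0.5 (turned off), group 2 from 0.5 to 2
inclusive (always on), group 3 above 2 (turned on), group 4 everything
with gDNA representation but undetectable cDNA at either day. The interval
endpoints at 0.5 and 2 are taken closed for group 2 because the stated
ranges otherwise leave boundary assignment ambiguous. The within-group
z-score is the standard `(x - mean)/sd` of log fold change; a
fold-change-to-mean reading of the z-score is conceivable but the standard
definition is used and documented here. Safe-harbor candidates must have
at least 20 reads in both gDNA and cDNA, at least 30 inverse-PCR mapping
reads, a unique unambiguous site, and an intronic or intergenic
annotation; the dynamics group is carried as a report column (group 2 =
constitutive) rather than a hard filter, since only the count and
annotation filters are part of the selection rule.

# Chromatin context

Signal around an insertion is the base-weighted sum of a bedGraph track
over `[position - h, position + h)`, default h = 5 kb and configurable
from 1 to 100 kb; partial interval overlap contributes value × overlap
length, and windows are clipped at chromosome ends. Strand is ignored for
window sums and state assignment. State assignment is half-open interval
containment, so an insertion exactly at a segment boundary belongs to the
segment starting there. Expression bins are equal-count quantile bins with
ties broken by stable input order; in the 8-bin scheme, bin 1 is reserved
for undetectable barcodes. The TAD analysis computes Pearson correlations
of expression trajectories for all pairs of barcodes sharing a TAD, an
equal number of seeded random cross-TAD pairs, and compares the two
distributions with Welch's t test; all available timepoints enter the
trajectories. When every trajectory is identical the statistic is
undefined and the result is flagged degenerate instead of reported.

# The exponential-decay activation model

Per barcode, fold activation is the normalized dCas9-VPR expression over
the matched non-targeting control, computed on a shared size-factor set,
after removing under-represented barcodes (total gDNA below 10) and
barcodes silent in the control (cDNA zero, for which a fold is undefined).
The model `y = A*exp(-k*x) + C` is fitted to x = log basal expression,
y = log fold activation by Levenberg–Marquardt least squares with
initialisation `A = max(y) - min(y)`, `k = 1`, `C = min(y)`, the decay
rate constrained non-negative, and tolerance 1e-10; the fit is
deterministic given this initialisation. A constant response returns the
degenerate flat fit (`k = 0`, `C = mean`, R² defined as 0). Residuals are
ranked into six equal bins (remainder to the lowest bins), bin 6 holding
the reporters activated most relative to prediction. Per chromatin state
and bin, the observed count is compared with the theoretical count
(state total / 6) by a binomial test with Benjamini–Hochberg correction
across all state × bin cells — the simplest test matching an
observed-versus-theoretical display. Residual z-scores are standardized
globally (not per state) and compared across states by one-way ANOVA.

# Single-cell guide assignment and testing

A guide is present at one captured UMI by default, since five guides were
delivered per target and any capture is evidence of delivery; the
threshold is a parameter. Cells with no present guide are unassigned, more
than five are excluded, and one to five guides all from a single target's
set give that target; mixtures of sets are excluded. The mitochondrial QC
threshold is read as a 10% fraction rather than 10 raw reads — a raw-read
reading would discard almost nothing at typical depth and contradicts
standard practice — and is exposed as a parameter. Counts are scaled to
10,000 per cell. Per target, Welch's t test compares normalized
target-gene expression in on-target versus scramble cells,
Bonferroni-corrected over the number of targets tested (one global family;
a per-panel family is conceivable but not used). Targets below 40 assigned
cells are skipped, mirroring the well-represented-perturbation cut-off.
Zero fractions are computed on raw counts, and the percentile rank places
the on-target mean among all endogenous genes' means in scramble cells.

# The two-latent-state negative-binomial model

Each cell is in an unobserved basal or active state. The target-gene count
is negative binomial with mean `exp(beta0_c + beta_act_c*z + log N)` —
`N` the cell's total UMI entering as an offset — and per-class dispersion
`theta_c` shared between the two latent states (the package-wide NB
parameterisation is variance = mu + mu²/theta). `beta_act_c` is the log
fold increase of mean expression from basal to active and is constrained
non-negative, which resolves the label symmetry of the mixture. Scramble
and non-transfected cells are anchored to the basal state (responsibility
0) by default; they define what "basal" means and, because a scramble cell
carries a count for every gene, `sc_cell_observations()` lets the whole
control pool inform every class's intercept and dispersion. The mixing
probability `pi_c` is the mean responsibility of non-control cells of the
class; including anchored controls would bias the prior of treated cells
toward basal.

Fitting is EM: the E-step computes active-state responsibilities from the
current parameters; the M-step maximises the responsibility-weighted NB
likelihood per class (intercept, activation coefficient and dispersion
jointly, by bounded quasi-Newton with analytic gradients) and updates
`pi_c`. Initial responsibilities threshold each cell's detection rate
`y/N` at the class median; the dispersion starts at its method-of-moments
estimate. Convergence is a 1e-6 change in total log-likelihood, at most
500 iterations. Because mixture likelihoods have ridges and multiple local
optima, each class fit finishes with a direct multi-start maximisation of
the observed likelihood, warm-started at the EM solution; an update is
accepted only when it improves the likelihood, so the reported
log-likelihood trace is non-decreasing, as EM guarantees. An all-zero
class drives the intercept to a documented floor of −30 with a warning.

## A note on identifiability at small cell numbers

At realistic basal levels (around 0.01 expected UMIs per 10,000), a basal
cell is almost always a zero, so the latent split is informed only by the
minority of non-zero cells. With a few hundred cells per class the
observed likelihood develops near-equivalent modes — a lower-`pi`,
higher-`beta_act` mode and an all-active, lower-dispersion mode — and the
*maximum-likelihood estimate itself*, not merely the optimiser, lands in
them; we verified this by comparing truth-started direct maximisation with
multi-start search. The estimator is consistent: at tens of thousands of
cells per class the parameters are recovered closely. Practical
consequence: per-class activation coefficients and mixing probabilities
from a few hundred cells carry substantial uncertainty, and enlarging the
anchored control pool tightens the intercept and dispersion but cannot
fully resolve the active-state split. The test suite demonstrates accurate
recovery in a well-identified regime (basal mean near 1 UMI per cell) and
exercises the weakly identified regime as an honest stress case.

# Numerical and design choices collected

* NB parameterisation: variance = mu + mu²/theta, everywhere.
* Midpoints round down; intervals are 0-based half-open throughout.
* Quantile-bin ties: stable input order.
* Display pseudocount 0.00001 for non-expressed barcodes applies to
  plotting summaries only, never to classification.
* Decay fit: natural logs on both axes; the order-2 polynomial sometimes
  drawn over such data is display-only and not implemented.
* Guide sets: five guides per target plus a scramble set; cross-enzyme and
  cross-set conflicts always resolve to exclusion rather than arbitration.
* Test problem sizes: the packaged checks run a 2 × 0.4 Mb genome with 600
  reporters for pipeline recovery, 1,500 reporters for the end-to-end
  activation analysis, and single-cell designs of 8–60 targets at 60–300
  cells per target; these sizes keep the full suite in the minutes range
  while leaving every statistical conclusion comfortably powered.

# Known limitations

Real inverse-PCR data contain multi-mapping flanks from repeats; the
package only flags ambiguity and does not attempt repeat-aware rescue. The
expression model treats replicates as exchangeable and has no
amplification-bias term. The single-cell generator draws guide UMIs
independently of transcriptome depth. The NB model supports exactly two
latent states and no covariates beyond class and offset; per-guide effects
within a target are not modelled.
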