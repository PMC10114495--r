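#' Fold activation of reporters under CRISPRa
#'
#' Combines matched control (non-targeting sgRNA) and dCas9-VPR condition
#' expression into per-barcode fold activation. Model filters: barcodes
#' with a total gDNA read count below \code{min_gdna} (control + VPR) or
#' with zero cDNA in the control condition are removed. The activated
#' fraction is summarised at the conventional 2-fold threshold.
#'
#' @param control,vpr data.frames with one row per barcode: barcode, score
#'   (normalized expression on a shared size-factor set), gdna_total,
#'   cdna_total.
#' @param min_gdna gDNA representation filter (default 10).
#' @param fold_threshold activation call threshold (default 2).
#' @return list with \code{table} (barcode, basal, activated,
#'   fold_activation, log_basal, log_fold) and \code{pct_activated}
#'   (percentage of barcodes above the threshold).
#' @export
compute_fold_activation <- function(control, vpr, min_gdna = 10,
                                    fold_threshold = 2) {
  common <- intersect(control$barcode, vpr$barcode)
  ic <- match(common, control$barcode)
  iv <- match(common, vpr$barcode)
  gdna_total <- control$gdna_total[ic] + vpr$gdna_total[iv]
  keep <- gdna_total >= min_gdna &
    control$cdna_total[ic] > 0 &
    !is.na(control$score[ic]) & !is.na(vpr$score[iv]) &
    control$score[ic] > 0
  tab <- data.frame(
    barcode = common[keep],
    basal = control$score[ic][keep],
    activated = vpr$score[iv][keep],
    stringsAsFactors = FALSE
  )
  tab$fold_activation <- tab$activated / tab$basal
  tab$log_basal <- log(tab$basal)
  tab$log_fold <- log(tab$fold_activation)
  list(table = tab,
       pct_activated = 100 * mean(tab$fold_activation > fold_threshold))
}

#' Fit the exponential-decay model of fold activation
#'
#' Fits \code{y = A * exp(-k * x) + C} by nonlinear least squares with
#' x = log basal expression and y = log fold activation (both natural
#' logs). Initialisation A = max(y) - min(y), k = 1, C = min(y); the decay
#' rate is constrained non-negative. Degenerate (constant) responses return
#' A = 0, k = 0, C = mean(y) with R-squared 0.
#'
#' @param x,y numeric vectors, or a data.frame with log_basal and log_fold
#'   columns passed as \code{x}.
#' @param max_iter,tol optimiser controls.
#' @return a \code{decay_fit}: list with A, k, C, r_squared, fitted,
#'   residuals, converged.
#' @export
fit_exponential_decay <- function(x, y = NULL, max_iter = 10000,
                                  tol = 1e-10) {
  if (is.data.frame(x)) {
    y <- x$log_fold
    x <- x$log_basal
  }
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("need at least 10 points", call. = FALSE)
  if (stats::sd(y) < 1e-12) {
    return(structure(list(A = 0, k = 0, C = mean(y), r_squared = 0,
                          fitted = rep(mean(y), length(y)),
                          residuals = y - mean(y), x = x, y = y,
                          converged = TRUE),
                     class = "decay_fit"))
  }
  start <- list(A = max(y) - min(y), k = 1, C = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-k * x) + C,
      start = start,
      lower = c(A = -Inf, k = 0, C = -Inf),
      control = minpack.lm::nls.lm.control(
        maxiter = min(max_iter, 1024), ftol = tol, ptol = tol
      )
    ),
    error = function(e) {
      stop("decay fit did not converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  co <- stats::coef(fit)
  fitted <- co[["A"]] * exp(-co[["k"]] * x) + co[["C"]]
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(res^2) / ss_tot
  structure(list(A = co[["A"]], k = co[["k"]], C = co[["C"]],
                 r_squared = r2, fitted = fitted, residuals = res,
                 x = x, y = y, converged = TRUE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> y = %.4g * exp(-%.4g x) + %.4g   (R^2 = %.3f, n = %d)\n",
    x$A, x$k, x$C, x$r_squared, length(x$residuals)))
  invisible(x)
}

#' Rank reporters by decay-model residual and test state enrichment
#'
#' Ranks barcodes by their residual from the decay fit and splits them into
#' \code{n_bins} equal-size groups, bin 1 holding the reporters activated
#' least (relative to prediction) and bin \code{n_bins} those activated
#' most; any remainder is spread over the lowest bins. For each chromatin
#' state and bin the observed count is compared with the theoretical count
#' (state total / n_bins) by a binomial test, Benjamini-Hochberg corrected
#' across all state x bin cells.
#'
#' @param fit a \code{decay_fit} whose residuals align with \code{table}.
#' @param table the activation table used for the fit, carrying a
#'   \code{state} column.
#' @param n_bins number of activation bins (default 6).
#' @return list: \code{activation_bin} (per row of table),
#'   \code{enrichment} (state, bin, observed, expected, p, p_adj).
#' @export
rank_and_enrich <- function(fit, table, n_bins = 6) {
  n <- nrow(table)
  stopifnot(length(fit$residuals) == n)
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin_of_rank <- rep(seq_len(n_bins), sizes)
  ord <- order(fit$residuals)
  activation_bin <- integer(n)
  activation_bin[ord] <- bin_of_rank

  states <- unique(table$state)
  rows <- list()
  for (s in states) {
    in_state <- table$state == s
    total <- sum(in_state)
    for (b in seq_len(n_bins)) {
      obs <- sum(in_state & activation_bin == b)
      p <- stats::binom.test(obs, total, p = 1 / n_bins)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        state = s, bin = b, observed = obs,
        expected = total / n_bins, p = p, stringsAsFactors = FALSE
      )
    }
  }
  enr <- do.call(rbind, rows)
  enr$p_adj <- stats::p.adjust(enr$p, method = "BH")
  list(activation_bin = activation_bin, enrichment = enr)
}

#' One-way ANOVA of standardized decay residuals across chromatin states
#'
#' Residuals are z-scored over all barcodes (global standardization) and
#' compared across chromatin states with a one-way ANOVA.
#'
#' @param fit a \code{decay_fit}.
#' @param table activation table with a \code{state} column aligned with
#'   the fit residuals.
#' @return list: \code{residual_z}, \code{by_state} (per-state mean/sd/n),
#'   \code{f}, \code{p}.
#' @export
residual_state_anova <- function(fit, table) {
  stopifnot(length(fit$residuals) == nrow(table))
  counts <- table(table$state)
  if (sum(counts >= 2) < 2) {
    stop("need >= 2 states with >= 2 barcodes each", call. = FALSE)
  }
  z <- as.numeric(scale(fit$residuals))
  df <- data.frame(z = z, state = factor(table$state))
  fit_aov <- stats::aov(z ~ state, data = df)
  sm <- summary(fit_aov)[[1]]
  by_state <- data.frame(
    state = names(counts),
    n = as.integer(counts),
    mean_z = as.numeric(tapply(z, table$state, mean)[names(counts)]),
    sd_z = as.numeric(tapply(z, table$state, sd)[names(counts)])
  )
  list(residual_z = z, by_state = by_state,
       f = sm[["F value"]][1], p = sm[["Pr(>F)"]][1])
}
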