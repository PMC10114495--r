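#' Negative-binomial log probability mass
#'
#' Log mass of the negative binomial in the (mu, theta) parameterisation
#' used package-wide: variance = mu + mu^2/theta.
#'
#' @param y non-negative integer count(s).
#' @param mu mean(s), positive.
#' @param theta dispersion(s), positive.
#' @return log probability, vectorised.
#' @export
nb_log_pmf <- function(y, mu, theta) {
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    stop("y must be non-negative integers", call. = FALSE)
  }
  stopifnot(all(mu > 0), all(theta > 0))
  stats::dnbinom(round(y), size = theta, mu = mu, log = TRUE)
}

#' Expected target-gene count under the latent-state NB model
#'
#' Computes \code{exp(beta0 + beta_act * [state == "active"] + log N)} —
#' e.g. with beta0 = -13.49 and N = 10,000 a basal cell is expected to show
#' 0.014 target UMIs, and with beta_act = 3.94 an active cell 0.71.
#'
#' @param fit an \code{nb_fit}, or a list/vector with \code{beta0} and
#'   \code{beta_act} entries.
#' @param class_label class to look up when \code{fit} is an \code{nb_fit}.
#' @param state "basal" or "active".
#' @param N total UMI count (offset), positive.
#' @return expected count.
#' @export
predicted_mean <- function(fit, class_label = NULL,
                           state = c("basal", "active"), N = 1e4) {
  state <- match.arg(state)
  if (any(N <= 0)) stop("N must be positive", call. = FALSE)
  pars <- nb_params_of(fit, class_label)
  exp(pars$beta0 + pars$beta_act * (state == "active") + log(N))
}

nb_params_of <- function(fit, class_label) {
  if (inherits(fit, "nb_fit")) {
    if (is.null(class_label) || !class_label %in% names(fit$beta0)) {
      stop("class not present in fit", call. = FALSE)
    }
    list(beta0 = fit$beta0[[class_label]],
         beta_act = fit$beta_act[[class_label]],
         theta = fit$theta[[class_label]],
         pi = fit$pi[[class_label]])
  } else {
    list(beta0 = fit[["beta0"]],
         beta_act = if (!is.null(fit[["beta_act"]])) fit[["beta_act"]] else 0,
         theta = fit[["theta"]], pi = fit[["pi"]])
  }
}

#' Fit the two-latent-state NB regression with offset by EM
#'
#' Models each cell's target-gene UMI count as negative binomial with mean
#' \code{exp(beta0_c + beta_act_c * z_i + log N_i)} where \code{z_i} is the
#' unobserved basal/active latent state, \code{c} the cell's ChromHMM
#' class, \code{N_i} its total UMI count, and a per-class dispersion
#' \code{theta_c}. The E-step computes the posterior (responsibility) of
#' the active state per cell; control cells (scramble/no sgRNA) are
#' anchored to the basal state when \code{anchor_controls} is TRUE. The
#' M-step maximises the responsibility-weighted NB likelihood per class
#' (intercept, activation coefficient and dispersion jointly), and sets
#' \code{pi_c} to the mean responsibility of non-control cells. The
#' activation coefficient is constrained non-negative so "active" is the
#' higher-mean state.
#'
#' @param cells data.frame with columns \code{y} (target UMI count),
#'   \code{N} (total UMI), \code{class_label} and optionally
#'   \code{is_control}.
#' @param anchor_controls fix control cells at responsibility 0.
#' @param tol convergence tolerance on the total log-likelihood.
#' @param max_iter maximum EM iterations per class.
#' @param polish finish each class with direct maximisation of the observed
#'   likelihood from the EM solution plus a small multi-start, keeping the
#'   best (guards against ridges and local optima of the mixture
#'   likelihood).
#' @return an \code{nb_fit}: per-class named vectors \code{beta0},
#'   \code{beta_act}, \code{theta}, \code{pi}; per-cell
#'   \code{responsibilities} (input order); per-class \code{trace} and a
#'   combined non-decreasing \code{loglik_trace}; \code{converged};
#'   \code{n_iter}.
#' @export
em_fit <- function(cells, anchor_controls = TRUE, tol = 1e-6,
                   max_iter = 500, polish = TRUE) {
  stopifnot(all(c("y", "N", "class_label") %in% names(cells)))
  if (any(cells$N <= 0)) stop("offsets must be positive", call. = FALSE)
  is_control <- if ("is_control" %in% names(cells)) {
    as.logical(cells$is_control)
  } else rep(FALSE, nrow(cells))
  if (!anchor_controls) is_control <- rep(FALSE, nrow(cells))

  classes <- sort(unique(cells$class_label))
  beta0 <- beta_act <- theta <- pi_c <- stats::setNames(
    numeric(length(classes)), classes)
  resp <- numeric(nrow(cells))
  traces <- list()
  converged_all <- TRUE
  n_iter_max <- 0L

  for (cl in classes) {
    idx <- which(cells$class_label == cl)
    if (length(idx) < 2) stop("need >= 2 cells per class", call. = FALSE)
    fit <- em_fit_one_class(cells$y[idx], cells$N[idx], is_control[idx],
                            tol = tol, max_iter = max_iter,
                            polish = polish)
    beta0[cl] <- fit$beta0
    beta_act[cl] <- fit$beta_act
    theta[cl] <- fit$theta
    pi_c[cl] <- fit$pi
    resp[idx] <- fit$r
    traces[[cl]] <- fit$trace
    converged_all <- converged_all && fit$converged
    n_iter_max <- max(n_iter_max, fit$n_iter)
  }
  # combined trace: per-class traces padded to equal length with their
  # final value, then summed — non-decreasing as each class trace is
  len <- max(lengths(traces))
  padded <- vapply(traces, function(tr) {
    c(tr, rep(tr[length(tr)], len - length(tr)))
  }, numeric(len))
  loglik_trace <- if (len == 1) sum(padded) else rowSums(padded)

  structure(list(
    beta0 = beta0, beta_act = beta_act, theta = theta, pi = pi_c,
    responsibilities = resp, trace = traces,
    loglik_trace = loglik_trace,
    loglik = loglik_trace[length(loglik_trace)],
    converged = converged_all, n_iter = n_iter_max,
    classes = classes
  ), class = "nb_fit")
}

BETA0_FLOOR <- -30

em_fit_one_class <- function(y, N, ctrl, tol = 1e-6, max_iter = 500,
                             polish = TRUE) {
  logN <- log(N)
  free <- !ctrl
  if (all(y == 0)) {
    warning("all-zero counts in a class; intercept driven to the floor")
    return(list(beta0 = BETA0_FLOOR, beta_act = 0, theta = 1, pi = 0,
                r = rep(0, length(y)), trace = sum(nb_log_pmf(
                  y, exp(BETA0_FLOOR + logN), 1)),
                converged = TRUE, n_iter = 0L))
  }

  negQ <- function(p, rr) {
    mu0 <- exp(p[1] + logN)
    mu1 <- exp(p[1] + p[2] + logN)
    th <- exp(p[3])
    -sum((1 - rr) * stats::dnbinom(y, size = th, mu = mu0, log = TRUE) +
           rr * stats::dnbinom(y, size = th, mu = mu1, log = TRUE))
  }
  # analytic score of the NB log-likelihood in (log mu, log theta):
  # d/dlogmu = y - (y+th)mu/(mu+th);  d/dlogtheta = th * h(y, mu, th)
  nb_score <- function(mu, th) {
    g <- y - (y + th) * mu / (mu + th)
    h <- digamma(y + th) - digamma(th) + log(th) + 1 -
      log(mu + th) - (y + th) / (mu + th)
    list(g = g, h = h)
  }
  negQ_grad <- function(p, rr) {
    mu0 <- exp(p[1] + logN)
    mu1 <- exp(p[1] + p[2] + logN)
    th <- exp(p[3])
    s0 <- nb_score(mu0, th)
    s1 <- nb_score(mu1, th)
    -c(sum((1 - rr) * s0$g + rr * s1$g),
       sum(rr * s1$g),
       th * sum((1 - rr) * s0$h + rr * s1$h))
  }
  obs_loglik <- function(p, prior) {
    mu0 <- exp(p[1] + logN)
    mu1 <- exp(p[1] + p[2] + logN)
    th <- exp(p[3])
    l0 <- stats::dnbinom(y, size = th, mu = mu0, log = TRUE)
    l1 <- stats::dnbinom(y, size = th, mu = mu1, log = TRUE)
    ll <- numeric(length(y))
    ll[ctrl] <- l0[ctrl]
    a <- log(prior) + l1[free]
    b <- log1p(-prior) + l0[free]
    if (prior <= 0) {
      ll[free] <- l0[free]
    } else if (prior >= 1) {
      ll[free] <- l1[free]
    } else {
      mx <- pmax(a, b)
      ll[free] <- mx + log(exp(a - mx) + exp(b - mx))
    }
    sum(ll)
  }
  e_step <- function(p, prior) {
    if (prior <= 0) return(rep(0, length(y)))
    mu0 <- exp(p[1] + logN)
    mu1 <- exp(p[1] + p[2] + logN)
    th <- exp(p[3])
    r <- if (prior >= 1) as.numeric(free) else {
      l1 <- log(prior) + stats::dnbinom(y, size = th, mu = mu1, log = TRUE)
      l0 <- log1p(-prior) + stats::dnbinom(y, size = th, mu = mu0,
                                           log = TRUE)
      1 / (1 + exp(l0 - l1))
    }
    r[ctrl] <- 0
    r
  }

  # init: threshold detection rate at its median among non-control cells
  ratio <- y / N
  thr <- stats::median(ratio[free])
  r <- ifelse(free & ratio > thr, 1, 0)
  if (sum(r) == 0) r[free & y > 0] <- 1  # degenerate median, e.g. all zeros
  # method-of-moments dispersion from the pooled counts
  m <- mean(y); v <- stats::var(y)
  theta <- if (is.finite(v) && v > m) m^2 / (v - m) else 10
  theta <- min(max(theta, 1e-3), 1e6)
  par <- c(b0 = init_log_rate(y[r < 0.5], N[r < 0.5]),
           bact = 0, ltheta = log(theta))
  if (sum(r) > 0) {
    mu1 <- init_log_rate(y[r >= 0.5], N[r >= 0.5])
    par["bact"] <- max(mu1 - par["b0"], 0)
  }

  lower <- c(BETA0_FLOOR, 0, log(1e-4))
  upper <- c(10, 30, log(1e7))
  trace <- numeric(0)
  last_ll <- -Inf
  converged <- FALSE
  it <- 0L
  pi_c <- 0.5
  for (it in seq_len(max_iter)) {
    # M-step: weighted NB regression; keep the previous iterate if the
    # optimiser fails to improve the weighted likelihood
    opt <- stats::optim(par, negQ, gr = negQ_grad, rr = r,
                        method = "L-BFGS-B", lower = lower, upper = upper)
    if (opt$value <= negQ(par, r)) par <- opt$par
    pi_c <- if (sum(free) > 0) mean(r[free]) else 0

    ll <- obs_loglik(par, pi_c)
    trace <- c(trace, ll)
    if (is.finite(last_ll) && abs(ll - last_ll) < tol) {
      converged <- TRUE
      break
    }
    last_ll <- ll
    r <- e_step(par, pi_c)
  }

  if (polish) {
    # the EM path can stall on a likelihood ridge; finish with direct
    # maximisation of the observed likelihood from the EM solution and a
    # few alternative starts, keeping the best (standard mixture-model
    # multi-start practice)
    nll4 <- function(p4) {
      v <- -obs_loglik(p4[1:3], stats::plogis(p4[4]))
      if (!is.finite(v)) 1e12 else v
    }
    nll4_grad <- function(p4) {
      prior <- stats::plogis(p4[4])
      rr <- e_step(p4[1:3], prior)
      g <- negQ_grad(p4[1:3], rr)
      c(g, -sum(rr[free] - prior))
    }
    pi_for_opt <- min(max(pi_c, 1e-4), 1 - 1e-4)
    starts <- list(c(par, stats::qlogis(pi_for_opt)))
    for (ba0 in c(2, 6)) for (p0 in c(0.25, 0.75)) {
      starts[[length(starts) + 1]] <- c(par[1], ba0, par[3],
                                        stats::qlogis(p0))
    }
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        stats::nlminb(s, nll4, gradient = nll4_grad,
                      lower = c(lower, -12), upper = c(upper, 12)),
        error = function(e) NULL
      )
      if (!is.null(o) && (is.null(best) || o$objective < best$objective)) {
        best <- o
      }
    }
    if (!is.null(best) && -best$objective >= trace[length(trace)]) {
      par <- best$par[1:3]
      names(par) <- c("b0", "bact", "ltheta")
      pi_c <- stats::plogis(best$par[4])
      if (sum(free) == 0) pi_c <- 0
      trace <- c(trace, -best$objective)
      converged <- TRUE
    }
  }

  r <- e_step(par, pi_c)
  if (par[1] <= BETA0_FLOOR + 1e-8) {
    warning("intercept at the floor (", BETA0_FLOOR, ")")
  }
  list(beta0 = unname(par[1]), beta_act = unname(par[2]),
       theta = unname(exp(par[3])), pi = pi_c, r = r, trace = trace,
       converged = converged, n_iter = it)
}

init_log_rate <- function(y, N) {
  s <- sum(y)
  if (length(y) == 0 || s == 0) return(BETA0_FLOOR / 2)
  max(log(s / sum(N)), BETA0_FLOOR)
}

#' Build the cell-observation table for the latent-state NB model
#'
#' For every target, each cell assigned that perturbation contributes one
#' observation (its UMI count of the target gene, its total UMI offset, the
#' target's ChromHMM class); every scramble-control cell contributes a
#' basal-anchored observation of the same gene. Control cells therefore
#' inform the basal intercept and dispersion of every class — the reason
#' the scramble pool is sequenced alongside the perturbations.
#'
#' @param dataset an \code{sc_dataset}.
#' @param perturbation per-cell labels from
#'   \code{\link{assign_perturbations}}.
#' @param targets targets to include; defaults to all design targets.
#' @return data.frame with cell_id, target, class_label, y, N, is_control.
#' @export
sc_cell_observations <- function(dataset, perturbation, targets = NULL) {
  stopifnot(length(perturbation) == nrow(dataset$gene_matrix))
  if (is.null(targets)) targets <- dataset$design$target
  class_of <- stats::setNames(dataset$design$class_label,
                              dataset$design$target)
  totals <- Matrix::rowSums(dataset$gene_matrix)
  ctrl_idx <- which(perturbation == "scramble")
  rows <- lapply(targets, function(t) {
    on_idx <- which(perturbation == t)
    idx <- c(on_idx, ctrl_idx)
    data.frame(
      cell_id = rownames(dataset$gene_matrix)[idx],
      target = t,
      class_label = class_of[[t]],
      y = as.numeric(dataset$gene_matrix[idx, t]),
      N = as.numeric(totals[idx]),
      is_control = rep(c(FALSE, TRUE),
                       c(length(on_idx), length(ctrl_idx))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixture mean and variance of UMI counts for a class
#'
#' Combines the basal and active components:
#' mean = (1 - pi) mu_b + pi mu_a;
#' variance = (1 - pi)(mu_b + mu_b^2/theta) + pi(mu_a + mu_a^2/theta) +
#' pi(1 - pi)(mu_a - mu_b)^2.
#'
#' @param fit an \code{nb_fit} (or list with beta0, beta_act, theta, pi).
#' @param class_label class to evaluate.
#' @param N total UMI count.
#' @return named vector (mean, variance).
#' @export
class_moments <- function(fit, class_label = NULL, N = 1e4) {
  pars <- nb_params_of(fit, class_label)
  mu_b <- exp(pars$beta0 + log(N))
  mu_a <- exp(pars$beta0 + pars$beta_act + log(N))
  p <- pars$pi
  th <- pars$theta
  m <- (1 - p) * mu_b + p * mu_a
  v <- (1 - p) * (mu_b + mu_b^2 / th) + p * (mu_a + mu_a^2 / th) +
    p * (1 - p) * (mu_a - mu_b)^2
  c(mean = m, variance = v)
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit> %d class(es), loglik %.2f, %s in <= %d iter\n",
              length(x$classes), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  df <- data.frame(beta0 = round(x$beta0, 2),
                   beta_act = round(x$beta_act, 2),
                   theta = round(x$theta, 3), pi = round(x$pi, 3))
  print(df)
  invisible(x)
}
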