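test_that("the NB mass normalises, hits its Poisson limit and closed form", {
  p <- exp(nb_log_pmf(0:1000, mu = 5, theta = 2))
  expect_lt(abs(sum(p) - 1), 1e-8)

  # the NB -> Poisson gap grows like y^2 / theta; at theta = 1e6 the 1e-4
  # agreement holds over the bulk of the mass
  y <- 0:15
  expect_lt(max(abs(nb_log_pmf(y, 5, 1e6) - dpois(y, 5, log = TRUE))),
            1e-4)
  expect_lt(max(abs(nb_log_pmf(0:60, 5, 1e8) -
                      dpois(0:60, 5, log = TRUE))), 1e-4)

  # gamma-function closed form evaluated independently
  expect_equal(nb_log_pmf(3, 2.5, 1.7), -2.053503671937, tolerance = 1e-10)

  expect_error(nb_log_pmf(2.5, 1, 1), "integer")
})

test_that("predicted means reproduce the worked basal/active examples", {
  basal <- predicted_mean(list(beta0 = -13.49, beta_act = 3.94),
                          state = "basal", N = 1e4)
  active <- predicted_mean(list(beta0 = -13.49, beta_act = 3.94),
                           state = "active", N = 1e4)
  expect_equal(signif(basal, 2), 0.014)
  expect_equal(signif(active, 2), 0.71)
  expect_equal(predicted_mean(list(beta0 = 0, beta_act = 0),
                              state = "basal", N = 1), 1)
  expect_equal(predicted_mean(list(beta0 = 0, beta_act = 0),
                              state = "active", N = 1), 1)
  expect_error(predicted_mean(list(beta0 = 0, beta_act = 0), N = -5),
               "positive")
})

test_that("an all-control fit collapses to plain NB regression", {
  skip_if_not_installed("MASS")
  set.seed(42)
  n <- 800
  N <- round(rlnorm(n, log(1e4), 0.3))
  y <- rnbinom(n, size = 0.8, mu = exp(-9 + log(N)))
  cells <- data.frame(y = y, N = N, class_label = "c", is_control = TRUE)
  fit <- em_fit(cells)
  ref <- MASS::glm.nb(y ~ 1 + offset(log(N)))
  expect_equal(unname(fit$beta0), unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$theta), unname(ref$theta), tolerance = 1e-4)
  expect_equal(unname(fit$pi), 0)
  expect_true(all(fit$responsibilities == 0))
})

test_that("the EM log-likelihood never decreases", {
  set.seed(9)
  for (s in 1:3) {
    n <- 300
    N <- round(rlnorm(n, log(1e4), 0.3))
    z <- runif(n) < 0.5
    y <- rnbinom(n, size = 1, mu = exp(-9 + 3 * z + log(N)))
    fit <- em_fit(data.frame(y = y, N = N, class_label = "c"),
                  polish = FALSE)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
    fit2 <- em_fit(data.frame(y = y, N = N, class_label = "c"))
    expect_true(all(diff(fit2$loglik_trace) > -1e-6))
    expect_gte(fit2$loglik, fit$loglik - 1e-8)  # polish only improves
    expect_gte(fit2$beta_act, 0)                # label symmetry resolved
  }
})

test_that("parameters are recovered in an identifiable regime", {
  # basal mean ~1.2 at N = 1e4: both latent states leave counts, so the
  # mixture is well identified at moderate n
  errs <- matrix(NA_real_, 6, 3)
  for (s in 1:6) {
    set.seed(s)
    n <- 500; nc <- 200
    N <- round(rlnorm(n + nc, log(1e4), 0.3))
    z <- c(runif(n) < 0.4, rep(FALSE, nc))
    y <- rnbinom(n + nc, size = 0.5, mu = exp(-9 + 3.9 * z + log(N)))
    cells <- data.frame(y = y, N = N, class_label = "c",
                        is_control = rep(c(FALSE, TRUE), c(n, nc)))
    fit <- em_fit(cells)
    errs[s, ] <- c(fit$beta_act - 3.9, fit$pi - 0.4, fit$beta0 + 9)
  }
  expect_lt(max(abs(errs[, 1])), 0.6)      # per-seed activation coefficient
  expect_lt(abs(mean(errs[, 1])), 0.25)    # near-unbiased across seeds
  expect_lt(max(abs(errs[, 2])), 0.08)     # active-state probability
  expect_lt(max(abs(errs[, 3])), 0.2)      # intercept
})

test_that("estimates match a Poisson mixture EM oracle in the theta limit", {
  # independent two-component Poisson-with-offset EM, written from scratch
  poisson_mix_em <- function(y, N, iters = 400) {
    logN <- log(N)
    r <- as.numeric(y / N > stats::median(y / N))
    pi <- 0.5
    b0 <- log(sum(y * (1 - r)) / sum(N * (1 - r)))
    b1 <- log(sum(y * r) / sum(N * r))
    for (i in seq_len(iters)) {
      l1 <- log(pi) + dpois(y, exp(b1 + logN), log = TRUE)
      l0 <- log1p(-pi) + dpois(y, exp(b0 + logN), log = TRUE)
      r <- 1 / (1 + exp(l0 - l1))
      pi <- mean(r)
      b0 <- log(sum(y * (1 - r)) / sum(N * (1 - r)))
      b1 <- log(sum(y * r) / sum(N * r))
    }
    list(beta0 = b0, beta_act = b1 - b0, pi = pi)
  }
  set.seed(123)
  n <- 2000
  N <- round(rlnorm(n, log(1e4), 0.3))
  z <- runif(n) < 0.4
  y <- rpois(n, exp(-8 + 2.5 * z + log(N)))   # Poisson = NB theta limit
  fit <- em_fit(data.frame(y = y, N = N, class_label = "c"))
  oracle <- poisson_mix_em(y, N)
  expect_gt(unname(fit$theta), 100)  # dispersion at the Poisson limit
  expect_equal(unname(fit$beta0), oracle$beta0, tolerance = 5e-3)
  expect_equal(unname(fit$beta_act), oracle$beta_act, tolerance = 5e-3)
  expect_equal(unname(fit$pi), oracle$pi, tolerance = 5e-3)
})

test_that("all-zero classes floor the intercept with a warning", {
  cells <- data.frame(y = 0, N = rep(1e4, 20), class_label = "c")
  expect_warning(fit <- em_fit(cells), "floor")
  expect_equal(unname(fit$beta0), -30)
})

test_that("class moments combine the two latent components correctly", {
  pars <- list(beta0 = -13.49, beta_act = 3.94, theta = 1, pi = 0)
  m0 <- class_moments(pars, N = 1e4)
  mu_b <- exp(-13.49 + log(1e4))
  expect_equal(unname(m0["mean"]), mu_b)
  expect_equal(unname(m0["variance"]), mu_b + mu_b^2)
  pars$pi <- 1
  m1 <- class_moments(pars, N = 1e4)
  expect_equal(unname(m1["mean"]), exp(-13.49 + 3.94 + log(1e4)))

  # Monte-Carlo oracle at pi = 0.5
  pars$pi <- 0.5
  set.seed(99)
  nsim <- 1e6
  z <- runif(nsim) < 0.5
  draws <- rnbinom(nsim, size = 1, mu = exp(-13.49 + 3.94 * z + log(1e4)))
  mm <- class_moments(pars, N = 1e4)
  expect_lt(abs(mean(draws) - mm["mean"]),
            3 * sqrt(mm[["variance"]] / nsim))
  expect_lt(abs(var(draws) - mm["variance"]) / mm[["variance"]], 0.05)
})

test_that("cell observations pair on-target cells with the control pool", {
  cfg <- sim_config(seed = 5)
  des <- sc_design(n_targets = 3, states = cfg$states[1:3])
  ds <- simulate_sc_dataset(cfg, des, cells_per_target = 50)
  asn <- assign_perturbations(ds)
  obs <- sc_cell_observations(ds, asn$perturbation)
  expect_setequal(unique(obs$target), des$target)
  n_ctrl <- sum(asn$perturbation == "scramble")
  for (t in des$target) {
    sub <- obs[obs$target == t, ]
    expect_equal(sum(sub$is_control), n_ctrl)
    expect_equal(unique(sub$class_label),
                 des$class_label[des$target == t])
  }
  expect_true(all(obs$y <= obs$N))
})

test_that("responsibilities separate active from basal cells", {
  set.seed(77)
  n <- 600; nc <- 300
  N <- round(rlnorm(n + nc, log(1e4), 0.3))
  z <- c(runif(n) < 0.4, rep(FALSE, nc))
  y <- rnbinom(n + nc, size = 0.5, mu = exp(-9 + 3.9 * z + log(N)))
  cells <- data.frame(y = y, N = N, class_label = "c",
                      is_control = rep(c(FALSE, TRUE), c(n, nc)))
  fit <- em_fit(cells)
  r <- fit$responsibilities
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(r[cells$is_control] == 0))
  free <- !cells$is_control
  expect_gt(mean(r[free][z[free]]), mean(r[free][!z[free]]))
})
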