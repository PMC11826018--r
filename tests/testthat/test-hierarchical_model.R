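# Hierarchical model: cell layout, joint density, sampler correctness, and
# convergence diagnostics.

make_design_trials <- function(groups, adaptors, morphs, n_subj = 2,
                               n_per_cell = 3) {
  rows <- list()
  idx <- 0
  for (g in groups) for (s in seq_len(n_subj)) {
    idx <- idx + 1
    for (ad in adaptors) {
      ti <- 0
      for (m in morphs) for (r in seq_len(n_per_cell)) {
        ti <- ti + 1
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = sprintf("S%02d", idx), group = g, adaptor = ad,
          morph_pct = m, trial_index = ti,
          response = if (r %% 2 == 0) "male" else "female",
          rt_ms = 400 + 50 * r, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

test_that("group-level cell count follows the counting formula", {
  tr <- make_design_trials(c("AUT", "NT"), c("androgynous", "male"),
                           c(20, 40, 60, 80))
  expect_equal(build_model(tr)$n_cells, 24L)
  tr1 <- make_design_trials("AUT", "androgynous", 20)
  expect_equal(build_model(tr1)$n_cells, 4L)
  tr3 <- make_design_trials(c("A", "B", "C"), c("androgynous", "male"),
                            c(20, 40, 60, 80))
  expect_equal(build_model(tr3)$n_cells, 36L)  # 3 + 3 + 6 + 24
})

test_that("build_model rejects empty inputs and maps trials to cells", {
  expect_error(build_model(data.frame(participant_id = character(0),
                                      group = character(0),
                                      adaptor = character(0),
                                      morph_pct = numeric(0),
                                      trial_index = integer(0),
                                      response = character(0),
                                      rt_ms = numeric(0))), "respond")
  tr <- make_design_trials(c("AUT", "NT"), c("androgynous", "male"), c(20, 40))
  spec <- build_model(tr)
  expect_equal(spec$K, 4L)
  expect_equal(length(spec$rt_signed), nrow(tr))
  # signed coding: male responses positive
  expect_true(all((spec$rt_signed > 0) == (tr$response == "male")))
})

naive_log_joint <- function(spec, hyper, v) {
  # second implementation: plain loops through the public density API
  ll <- 0
  for (i in seq_along(spec$rt_signed)) {
    s <- spec$subj[i] + 1L
    p <- ddm_params(v$a[s], v$t[s], v$b[s, spec$ad_idx[i]],
                    v$v[s, spec$vcell[i]])
    ll <- ll + wfpt_density(abs(spec$rt_signed[i]),
                            if (spec$rt_signed[i] > 0) "male" else "female",
                            p, log = TRUE)
  }
  for (s in seq_len(spec$S)) {
    g <- spec$subj_group[s]
    ll <- ll + dnorm(v$a[s], v$mu$a[g], 1 / sqrt(v$tau$a[g]), log = TRUE) +
      dnorm(v$t[s], v$mu$t[g], 1 / sqrt(v$tau$t[g]), log = TRUE)
    for (a in seq_len(spec$A)) {
      ll <- ll + dnorm(v$b[s, a], v$mu$b[g, a], 1 / sqrt(v$tau$b[g, a]),
                       log = TRUE)
    }
    for (k in seq_len(spec$K)) {
      ll <- ll + dnorm(v$v[s, k], v$mu$v[g, k], 1 / sqrt(v$tau$v[g, k]),
                       log = TRUE)
    }
  }
  for (ty in c("a", "t", "b", "v")) {
    h <- hyper$mu[[ty]]
    Z <- pnorm(h$upper, h$location, h$scale) - pnorm(h$lower, h$location, h$scale)
    for (x in as.vector(v$mu[[ty]])) {
      ll <- ll + dnorm(x, h$location, h$scale, log = TRUE) - log(Z)
    }
    for (x in as.vector(v$tau[[ty]])) {
      ll <- ll + dgamma(x, hyper$tau$shape, hyper$tau$rate, log = TRUE)
    }
  }
  ll
}

toy_values <- function(spec, seed = 1) {
  set.seed(seed)
  G <- spec$G; A <- spec$A; K <- spec$K; S <- spec$S
  list(mu = list(a = runif(G, 1, 2), t = runif(G, 0.1, 0.3),
                 b = matrix(runif(G * A, 0.4, 0.6), G, A),
                 v = matrix(rnorm(G * K), G, K)),
       tau = list(a = runif(G, 1, 3), t = runif(G, 5, 20),
                  b = matrix(runif(G * A, 5, 20), G, A),
                  v = matrix(runif(G * K, 1, 3), G, K)),
       a = runif(S, 1, 2), t = runif(S, 0.05, 0.2),
       b = matrix(runif(S * A, 0.3, 0.7), S, A),
       v = matrix(rnorm(S * K), S, K))
}

test_that("log joint matches a naive second implementation", {
  tr <- make_design_trials(c("AUT", "NT"), c("androgynous", "male"),
                           c(20, 40), n_subj = 2, n_per_cell = 1)
  tr <- tr[seq_len(5), ]
  spec <- build_model(tr)
  hyper <- default_hyperpriors()
  v <- toy_values(spec)
  expect_equal(log_joint(spec, hyper, v), naive_log_joint(spec, hyper, v),
               tolerance = 1e-10)
})

test_that("log joint is additive in trials and prior-only at zero trials", {
  tr <- make_design_trials("AUT", "androgynous", 20, n_subj = 1,
                           n_per_cell = 2)
  spec1 <- build_model(tr[1, ])
  spec0 <- spec1
  spec0$rt_signed <- numeric(0)
  spec0$subj <- integer(0); spec0$vcell0 <- integer(0)
  spec0$ad_idx <- integer(0); spec0$vcell <- integer(0)
  hyper <- default_hyperpriors()
  v <- toy_values(spec1)
  lik <- log_joint(spec1, hyper, v) - log_joint(spec0, hyper, v)
  p <- ddm_params(v$a[1], v$t[1], v$b[1, 1], v$v[1, 1])
  expect_equal(lik, wfpt_logdens_signed(spec1$rt_signed, p), tolerance = 1e-12)
})

test_that("log joint returns -Inf outside parameter domains", {
  tr <- make_design_trials("AUT", "androgynous", 20, n_subj = 1)
  spec <- build_model(tr)
  hyper <- default_hyperpriors()
  v <- toy_values(spec)
  v_bad <- v; v_bad$a[1] <- -1
  expect_identical(log_joint(spec, hyper, v_bad), -Inf)
  v_bad <- v; v_bad$b[1, 1] <- 1.5
  expect_identical(log_joint(spec, hyper, v_bad), -Inf)
  v_bad <- v; v_bad$t[1] <- 10  # non-decision time above every rt
  expect_identical(log_joint(spec, hyper, v_bad), -Inf)
})

test_that("split R-hat: hand formula, identical chains, and gross divergence", {
  # hand-executed split formula on two chains of four draws
  c1 <- c(1, 2, 3, 4); c2 <- c(2, 3, 4, 5)
  halves <- cbind(c(1, 2), c(3, 4), c(2, 3), c(4, 5))
  W <- mean(apply(halves, 2, var))
  B <- 2 * var(colMeans(halves))
  by_hand <- sqrt(((2 - 1) / 2 * W + B / 2) / W)
  expect_equal(rhat(cbind(c1, c2)), by_hand, tolerance = 1e-12)

  set.seed(1)
  expect_lt(abs(rhat(cbind(rnorm(5000), rnorm(5000))) - 1), 0.01)
  expect_gt(rhat(cbind(rnorm(1000), rnorm(1000, 10))), 1.5)
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "two chains")
})

test_that("the sampler is deterministic given the seed", {
  sim <- small_cohort(seed = 3, n = c(AUT = 2, NT = 2), reps = 4,
                      omission_rate = 0, fast_guess_rate = 0,
                      slow_outlier_rate = 0)
  spec <- build_model(sim$trials)
  cfg <- sampler_config(n_chains = 2, n_iterations = 60, n_burn_in = 20,
                        seed = 5)
  f1 <- suppressWarnings(sample_posterior(spec, config = cfg))
  f2 <- suppressWarnings(sample_posterior(spec, config = cfg))
  expect_identical(f1$draws, f2$draws)
  cfg2 <- cfg; cfg2$seed <- 6L
  f3 <- suppressWarnings(sample_posterior(spec, config = cfg2))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("non-convergence raises a recoverable warning carrying the samples", {
  sim <- small_cohort(seed = 5, n = c(AUT = 2, NT = 2), reps = 4)
  spec <- build_model(preprocess(sim$trials)$model_trials)
  cfg <- sampler_config(n_chains = 2, n_iterations = 30, n_burn_in = 10,
                        seed = 2)
  expect_warning(fit <- sample_posterior(spec, config = cfg),
                 class = "hddm_convergence_warning")
  expect_s3_class(fit, "hddm_fit")
  expect_false(fit$converged)
  expect_equal(dim(fit$draws)[1], 20L)
})

test_that("gaussian-likelihood reduction matches the conjugate closed form", {
  # one group, one adaptor, one morph; observations y ~ N(v_p, 1) with
  # v_p ~ N(mu, 1/tau0) and tau0 effectively fixed by a sharp gamma prior
  set.seed(77)
  S <- 4; n <- 40; tau0 <- 4; mu_true <- 1.1
  vps <- rnorm(S, mu_true, 1 / sqrt(tau0))
  rows <- list()
  for (s in seq_len(S)) {
    y <- rnorm(n, vps[s], 1)
    rows[[s]] <- data.frame(
      participant_id = sprintf("S%02d", s), group = "AUT",
      adaptor = "androgynous", morph_pct = 50, trial_index = seq_len(n),
      response = ifelse(y > 0, "male", "female"),
      rt_ms = abs(y) * 1000, stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  spec <- build_model(trials)
  m0 <- 0; s0 <- 3
  hyper <- default_hyperpriors(
    mu_v = list(location = m0, scale = s0, lower = -Inf, upper = Inf),
    tau = list(shape = 1e8, rate = 1e8 / tau0))
  fit <- suppressWarnings(sample_posterior(
    spec, hyper = hyper,
    config = sampler_config(n_chains = 2, n_iterations = 3000,
                            n_burn_in = 1000, seed = 3),
    likelihood = "gaussian"))
  d <- as.vector(fit$draws[, , "mu_v[AUT,androgynous,50]"])
  # closed form: ybar_p ~ N(mu, 1/tau0 + 1/n), mu ~ N(m0, s0^2)
  ybars <- vapply(rows, function(r) {
    mean(ifelse(r$response == "male", 1, -1) * r$rt_ms / 1000)
  }, numeric(1))
  prec <- 1 / s0^2 + S / (1 / tau0 + 1 / n)
  post_mean <- (m0 / s0^2 + sum(ybars) / (1 / tau0 + 1 / n)) / prec
  post_sd <- 1 / sqrt(prec)
  mcse <- sd(d) / sqrt(200)  # generous effective-sample allowance
  expect_lt(abs(mean(d) - post_mean), 4 * mcse + 0.02)
  expect_lt(abs(sd(d) - post_sd), 0.05)
})

test_that("prior-predictive cell means produce RTs on a behavioral time scale", {
  # subjects placed at hyperprior-drawn cell means (the central subject of
  # each prior draw); the broad default precisions are checked separately
  # for domain safety, not for behavioral realism
  set.seed(9)
  hyper <- default_hyperpriors()
  rtrunc <- function(m, s, lo, hi) {
    qnorm(runif(1, pnorm(lo, m, s), pnorm(hi, m, s)), m, s)
  }
  n_draw <- 40
  med_rt <- numeric(n_draw)
  for (i in seq_len(n_draw)) {
    a <- rtrunc(hyper$mu$a$location, hyper$mu$a$scale, 0, Inf)
    t0 <- rtrunc(hyper$mu$t$location, hyper$mu$t$scale, 0, Inf)
    b <- rtrunc(hyper$mu$b$location, hyper$mu$b$scale, 0, 1)
    v <- rnorm(1, hyper$mu$v$location, hyper$mu$v$scale)
    sim <- simulate_ddm(30, ddm_params(max(a, 1e-3), t0, min(max(b, 1e-3), 1 - 1e-3), v))
    expect_true(all(is.finite(sim$rt)) && all(sim$rt >= t0))
    med_rt[i] <- median(sim$rt)
  }
  expect_lt(median(med_rt), 2.2)  # typical prior draw sits inside the window
})
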