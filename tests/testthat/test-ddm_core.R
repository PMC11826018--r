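# Wiener first-passage kernel: density identities, closed-form choice
# probability, and simulator agreement.

test_that("parameter and rt domain validation", {
  expect_error(ddm_params(a = -1, t = 0.3, b = 0.5, v = 0), "boundary")
  expect_error(ddm_params(a = 2, t = 0.3, b = 1.2, v = 0), "start point")
  expect_error(ddm_params(a = 2, t = -0.1, b = 0.5, v = 0), "non-decision")
  p <- ddm_params(2, 0.3, 0.5, 0)
  expect_error(wfpt_density(-0.5, "male", p), "rt")
  expect_error(wfpt_density(0, "male", p), "rt")
  # below the non-decision time the density is zero, not an error
  expect_equal(wfpt_density(0.2, "male", p), 0)
  expect_equal(wfpt_density(0.2, "female", p), 0)
})

test_that("drift-free symmetric diffusion has equal densities at both boundaries", {
  p <- ddm_params(2, 0.3, 0.5, 0)
  rt <- seq(0.35, 3, by = 0.05)
  expect_equal(wfpt_density(rt, "male", p), wfpt_density(rt, "female", p))
})

param_grid <- list(
  ddm_params(1.5, 0.3, 0.5, 1), ddm_params(1.0, 0.2, 0.5, 0),
  ddm_params(2.0, 0.3, 0.3, -1), ddm_params(0.8, 0.15, 0.6, 2),
  ddm_params(2.5, 0.4, 0.7, 0.5), ddm_params(1.2, 0.25, 0.4, -2),
  ddm_params(1.8, 0.35, 0.55, 3), ddm_params(1.4, 0.3, 0.45, -0.3))

test_that("reflection symmetry: upper density equals lower density of the mirrored process", {
  rt <- seq(0.45, 2.5, by = 0.12)
  for (p in param_grid) {
    mirrored <- ddm_params(p$a, p$t, 1 - p$b, -p$v)
    expect_equal(wfpt_density(rt, "male", p), wfpt_density(rt, "female", mirrored),
                 tolerance = 1e-12)
  }
})

test_that("densities over both boundaries integrate to one", {
  for (p in param_grid) {
    up <- integrate(function(x) wfpt_density(x, "male", p), p$t, 60,
                    rel.tol = 1e-9)$value
    lo <- integrate(function(x) wfpt_density(x, "female", p), p$t, 60,
                    rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-4)
    # and the defective upper mass equals the closed-form choice probability
    expect_equal(up, choice_probability(p), tolerance = 1e-6)
  }
})

test_that("choice probability: drift-free value, monotonicity, and limits", {
  expect_identical(choice_probability(ddm_params(2, 0.3, 0.5, 0)), 0.5)
  expect_identical(choice_probability(ddm_params(1.7, 0.3, 0.23, 0)), 0.23)
  ps <- vapply(seq(-3, 3, by = 0.5),
               function(v) choice_probability(ddm_params(1.5, 0.3, 0.4, v)),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_equal(choice_probability(ddm_params(1.5, 0.3, 0.4, 50)), 1,
               tolerance = 1e-8)
})

test_that("closed-form choice probability matches Euler-simulated absorption fraction", {
  p <- ddm_params(2, 0.3, 0.5, 1)
  set.seed(11)
  n <- 2e4
  sim <- simulate_ddm(n, p, method = "euler", dt = 2e-4)
  frac <- mean(sim$response == "male")
  pr <- choice_probability(p)
  expect_lt(abs(frac - pr), 3 * sqrt(pr * (1 - pr) / n) + 0.005)
})

test_that("density matches the normalized histogram of Euler-simulated trials", {
  p <- ddm_params(1.5, 0.3, 0.5, 1.0)
  set.seed(21)
  n <- 1e5
  sim <- simulate_ddm(n, p, method = "euler", dt = 2e-4)
  up <- sim$rt[sim$response == "male"]
  breaks <- seq(0.3, 3.0, by = 0.15)
  emp <- hist(up[up < 3], breaks = breaks, plot = FALSE)$counts / n
  thr <- vapply(seq_len(length(breaks) - 1), function(i) {
    integrate(function(x) wfpt_density(x, "male", p),
              breaks[i], breaks[i + 1])$value
  }, numeric(1))
  mc <- 3 * sqrt(thr * (1 - thr) / n)
  expect_true(all(abs(emp - thr) < mc + 0.004))  # small Euler discretization margin
})

test_that("inverse-CDF sampler passes a KS check against the integrated density", {
  n <- 1e5
  for (p in param_grid) {
    set.seed(5 + round(100 * p$v))
    sim <- simulate_ddm(n, p)
    expect_true(all(sim$rt >= p$t))
    up <- sort(sim$rt[sim$response == "male"])
    if (length(up) < 1000) next
    pu <- choice_probability(p)
    grid <- seq(p$t + 1e-4, max(up) + 0.5, length.out = 300)
    cdf <- cumsum(c(0, vapply(seq_len(length(grid) - 1), function(i) {
      integrate(function(x) wfpt_density(x, "male", p), grid[i], grid[i + 1],
                rel.tol = 1e-9)$value
    }, numeric(1)))) / pu
    # sup over the grid of |ECDF - CDF|: the oracle CDF is exact (quadrature)
    # at the grid points, so no interpolation error enters
    ks <- max(abs(ecdf(up)(grid) - cdf))
    # alpha = 0.01 KS critical value for the upper-boundary subsample
    expect_lt(ks, 1.63 / sqrt(length(up)) + 2e-3)
  }
})

test_that("exact and Euler samplers agree in distribution", {
  p <- ddm_params(1.4, 0.3, 0.45, -0.5)
  set.seed(3)
  a <- simulate_ddm(3e4, p)
  b <- simulate_ddm(3e4, p, method = "euler", dt = 2e-4)
  expect_lt(abs(mean(a$response == "male") - mean(b$response == "male")), 0.015)
  ks <- suppressWarnings(ks.test(a$rt[a$response == "female"],
                                 b$rt[b$response == "female"]))$statistic
  expect_lt(unname(ks), 0.02)
})

test_that("simulation is reproducible and honors the non-decision floor", {
  p <- ddm_params(1.5, 0.4, 0.5, 0.8)
  set.seed(99); s1 <- simulate_ddm(500, p)
  set.seed(99); s2 <- simulate_ddm(500, p)
  expect_identical(s1, s2)
  expect_true(all(s1$rt >= p$t))
  set.seed(1)
  expect_error(simulate_ddm(10, p, method = "euler", dt = -1), "dt")
  tr <- simulate_trial(p)
  expect_equal(nrow(tr), 1L)
})

test_that("drift-free start-point symmetry in simulation", {
  p <- ddm_params(1.5, 0.3, 0.5, 0)
  set.seed(12)
  n <- 1e5
  sim <- simulate_ddm(n, p)
  expect_lt(abs(mean(sim$response == "male") - 0.5), 3 * sqrt(0.25 / n))
})
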