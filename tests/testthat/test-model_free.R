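# Model-free analysis: proportions, aftereffect curve, and the mixed ANOVA
# against independent oracles.

test_that("response proportions count responded trials only", {
  # 8-trial cell: 5 male, 2 female, 1 omitted -> 5/7
  rts <- c(rep(500, 7), NA)
  resp <- c(rep("male", 5), rep("female", 2), "omitted")
  blk <- make_block("P01", "AUT", "androgynous", rts, resp)
  pt <- response_proportions(blk)
  expect_equal(pt$cells$p_male, 5 / 7)
  expect_equal(pt$cells$n_responded, 7)

  # all-male responder -> 1.0 in every cell
  sim <- small_cohort(seed = 2, n = c(AUT = 1, NT = 1), reps = 4)
  sim$trials$response[sim$trials$response != "omitted"] <- "male"
  pt <- response_proportions(sim$trials)
  expect_true(all(pt$cells$p_male[pt$cells$n_responded > 0] == 1))
})

test_that("strong positive drift at high morphs orders the group means", {
  sim <- small_cohort(seed = 4, n = c(AUT = 4, NT = 4), reps = 16)
  pt <- response_proportions(sim$trials)
  gs <- pt$group_summary
  for (g in c("AUT", "NT")) for (ad in c("androgynous", "male")) {
    hi <- gs$mean[gs$group == g & gs$adaptor == ad & gs$morph_pct == 80]
    lo <- gs$mean[gs$group == g & gs$adaptor == ad & gs$morph_pct == 20]
    expect_gt(hi, lo)
  }
})

test_that("aftereffect curve is zero for identical conditions and antisymmetric", {
  sim <- small_cohort(seed = 6, n = c(AUT = 2, NT = 2), reps = 8)
  tr <- sim$trials
  # clone the androgynous block into the male block -> identical behavior
  andro <- tr[tr$adaptor == "androgynous", ]
  male <- andro; male$adaptor <- "male"
  pt <- response_proportions(rbind(andro, male))
  fc <- fae_curve(pt)
  expect_true(all(fc$participant$fae == 0))

  pt2 <- response_proportions(tr)
  fwd <- fae_curve(pt2)
  rev <- fae_curve(pt2, adaptor_ref = "male", adaptor_adapt = "androgynous")
  m <- merge(fwd$participant, rev$participant,
             by = c("participant_id", "group", "morph_pct"))
  expect_equal(m$fae.x, -m$fae.y)
})

test_that("aftereffect is positive and strongest at interior morphs under adaptation", {
  agg <- 0
  for (seed in 1:5) {
    sim <- generate_experiment(preset_paper_like(
      "adaptor_shift_only", n_per_group = c(AUT = 6, NT = 6),
      trials_per_morph = 16, seed = 100 + seed))
    fc <- fae_curve(response_proportions(sim$trials))
    by_morph <- tapply(fc$group_summary$mean, fc$group_summary$morph_pct, mean)
    agg <- agg + by_morph
  }
  agg <- agg / 5
  expect_true(all(agg > 0))
  expect_gt(mean(agg[c("40", "60")]), mean(agg[c("20", "80")]))
})

test_that("mixed ANOVA matches the brute-force least-squares oracle exactly", {
  set.seed(33)
  for (rep in 1:3) {
    Y <- matrix(runif(6 * 8), 6, 8)   # 3 participants per group
    group <- rep(c("AUT", "NT"), each = 3)
    an <- mixed_anova(prop_table_from_wide(Y, group))
    or <- oracle_mixed_anova(Y, group)
    expect_equal(setNames(an$table$F, an$table$effect), or$F,
                 tolerance = 1e-10)
    # decomposition is complete: component SS add up to the total SS
    expect_equal(sum(or$SS), or$SS_total, tolerance = 1e-8)
    expect_equal(sum(an$table$SS) + sum(unique(an$table$SS_err)),
                 or$SS_total, tolerance = 1e-8)
  }
})

test_that("within-subject effect sums of squares do not depend on group labels", {
  set.seed(44)
  Y <- matrix(runif(8 * 8), 8, 8)
  g1 <- rep(c("AUT", "NT"), each = 4)
  g2 <- sample(g1)
  a1 <- mixed_anova(prop_table_from_wide(Y, g1))$table
  a2 <- mixed_anova(prop_table_from_wide(Y, g2))$table
  for (eff in c("Adaptor", "Morph", "Adaptor:Morph")) {
    expect_equal(a1$SS[a1$effect == eff], a2$SS[a2$effect == eff],
                 tolerance = 1e-10)
  }
})

test_that("sphericity statistics: two-level factors are exactly spherical, epsilon is bounded", {
  set.seed(55)
  Y <- matrix(runif(10 * 8), 10, 8)
  an <- mixed_anova(prop_table_from_wide(Y, rep(c("AUT", "NT"), each = 5)))
  expect_identical(an$mauchly$W[an$mauchly$effect == "Adaptor"], 1)
  expect_identical(an$table$epsilon[an$table$effect == "Adaptor"], 1)
  eps <- an$table$epsilon[an$table$effect == "Morph"]
  expect_gte(eps, 1 / 3)
  expect_lte(eps, 1)
})

test_that("epsilon, corrected p-values, and Mauchly W agree with car::Anova", {
  sim <- generate_experiment(fae_config(n_per_group = c(AUT = 8, NT = 8),
                                        trials_per_morph = 8, seed = 61))
  pt <- response_proportions(sim$trials)
  an <- mixed_anova(pt)

  cells <- pt$cells
  ids <- unique(cells[, c("participant_id", "group")])
  Y <- matrix(NA_real_, nrow(ids), 8, dimnames = list(ids$participant_id, NULL))
  j <- 0
  for (ad in c("androgynous", "male")) for (m in c(20, 40, 60, 80)) {
    j <- j + 1
    sub <- cells[cells$adaptor == ad & cells$morph_pct == m, ]
    Y[sub$participant_id, j] <- sub$p_male
  }
  idata <- expand.grid(morph = factor(c(20, 40, 60, 80)),
                       adaptor = factor(c("androgynous", "male")))[, c(2, 1)]
  ca <- suppressWarnings(
    summary(car::Anova(lm(Y ~ factor(ids$group)), idata = idata,
                       idesign = ~ adaptor * morph, type = 3),
            multivariate = FALSE))
  gg <- ca$pval.adjustments
  expect_equal(an$table$epsilon[an$table$effect == "Morph"],
               unname(gg["morph", "GG eps"]), tolerance = 1e-8)
  expect_equal(an$table$epsilon[an$table$effect == "Adaptor:Morph"],
               unname(gg["adaptor:morph", "GG eps"]), tolerance = 1e-8)
  expect_equal(an$table$p_gg[an$table$effect == "Morph"],
               unname(gg["morph", "Pr(>F[GG])"]), tolerance = 1e-8)
  mw <- ca$sphericity.tests
  expect_equal(an$mauchly$W[an$mauchly$effect == "Morph"],
               unname(mw["morph", "Test statistic"]), tolerance = 1e-8)
})

test_that("group-effect type-I error is nominal under the null scenario", {
  n_rep <- 150
  rejections <- 0
  for (r in seq_len(n_rep)) {
    sim <- generate_experiment(preset_paper_like(
      "null", n_per_group = c(AUT = 6, NT = 6), trials_per_morph = 8,
      seed = 5000 + r))
    an <- mixed_anova(response_proportions(sim$trials))
    p <- an$table$p[an$table$effect == "Group"]
    rejections <- rejections + (p < 0.05)
  }
  band <- qbinom(c(0.025, 0.975), n_rep, 0.05)
  expect_gte(rejections, band[1])
  expect_lte(rejections, band[2])
})

test_that("mixed ANOVA guards small or incomplete designs", {
  Y <- matrix(runif(2 * 8), 2, 8)
  expect_error(mixed_anova(prop_table_from_wide(Y, c("AUT", "NT"))),
               "at least 2")
  # participants with missing cells are dropped and reported
  Y <- matrix(runif(6 * 8), 6, 8)
  pt <- prop_table_from_wide(Y, rep(c("AUT", "NT"), each = 3))
  pt$cells$p_male[1] <- NA
  an <- mixed_anova(pt)
  expect_identical(an$dropped, "P01")
})
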