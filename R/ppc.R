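# Posterior predictive checks and the parameter-recovery harness.

#' Simulate replicate datasets from the posterior
#'
#' For each replicate one posterior iteration is drawn (chain and iteration
#' picked uniformly) and every trial of the observed design is re-simulated
#' from that iteration's subject-level parameters, preserving the
#' per-participant-cell trial counts exactly.
#'
#' @param fit An `hddm_fit`.
#' @param trials The trial table the model was fitted to (responded trials;
#'   defines the design being replicated).
#' @param n_replicates Number of replicate datasets (>= 1).
#' @param seed Integer seed.
#' @return List of `n_replicates` trial data frames (same schema as the
#'   input, `response`/`rt_ms` re-simulated).
#' @export
posterior_predict <- function(fit, trials, n_replicates = 50, seed = 1) {
  if (n_replicates < 1) stop("posterior_predict: n_replicates must be >= 1", call. = FALSE)
  trials <- trials[trials$response != "omitted", , drop = FALSE]
  set.seed(seed)
  d <- dim(fit$draws)
  lapply(seq_len(n_replicates), function(r) {
    it <- sample.int(d[1], 1); ch <- sample.int(d[2], 1)
    draw <- fit$draws[it, ch, ]
    out <- trials
    for (pid in unique(trials$participant_id)) {
      for (ad in fit$adaptors) for (m in fit$morphs) {
        sel <- trials$participant_id == pid & trials$adaptor == ad &
          trials$morph_pct == m
        n <- sum(sel)
        if (n == 0) next
        pars <- ddm_params(a = draw[[paste0("a[", pid, "]")]],
                           t = draw[[paste0("t[", pid, "]")]],
                           b = draw[[paste0("b[", pid, ",", ad, "]")]],
                           v = draw[[paste0("v[", pid, ",", ad, ",", m, "]")]])
        sim <- simulate_ddm(n, pars)
        out$response[sel] <- sim$response
        out$rt_ms[sel] <- sim$rt * 1000
      }
    }
    out
  })
}

cell_key <- function(tr) paste(tr$group, tr$adaptor, tr$morph_pct, sep = "|")

cell_stats <- function(tr, probs) {
  by <- split(seq_len(nrow(tr)), cell_key(tr))
  t(vapply(by, function(i) {
    male <- tr$response[i] == UPPER_RESPONSE
    c(p_male = mean(male),
      setNames(quantile(tr$rt_ms[i], probs, names = FALSE, type = 7),
               paste0("rt_q", probs * 100)))
  }, numeric(1 + length(probs))))
}

#' Summarize posterior predictive checks
#'
#' Per group x adaptor x morph cell: observed male-choice proportion and RT
#' quantiles (10/50/90% by default) against the predictive distribution of
#' the same statistics across replicates, plus an overall coverage summary
#' (fraction of cell statistics inside the central predictive band).
#'
#' @param observed Observed trial table (responded trials).
#' @param replicates List of replicate tables from [posterior_predict()].
#' @param probs RT quantiles to check.
#' @param band Nominal central predictive band (default 0.95).
#' @return A `ppc_result`: list with `cells` (observed value, predictive
#'   band, inside flag for every cell statistic) and `coverage`.
#' @export
ppc_summary <- function(observed, replicates, probs = c(0.1, 0.5, 0.9),
                        band = 0.95) {
  observed <- observed[observed$response != "omitted", , drop = FALSE]
  obs <- cell_stats(observed, probs)
  reps <- lapply(replicates, cell_stats, probs = probs)
  keys <- rownames(obs)
  alpha <- (1 - band) / 2
  rows <- list()
  for (k in keys) {
    pred <- t(vapply(reps, function(r) {
      if (k %in% rownames(r)) r[k, ] else rep(NA_real_, ncol(obs))
    }, numeric(ncol(obs))))
    for (stat in colnames(obs)) {
      lo <- quantile(pred[, stat], alpha, na.rm = TRUE, names = FALSE)
      hi <- quantile(pred[, stat], 1 - alpha, na.rm = TRUE, names = FALSE)
      ov <- obs[k, stat]
      rows[[length(rows) + 1]] <- data.frame(
        cell = k, statistic = stat, observed = ov, lower = lo, upper = hi,
        inside = !is.na(ov) && ov >= lo && ov <= hi)
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  structure(list(cells = cells, band = band,
                 coverage = mean(cells$inside),
                 n_replicates = length(replicates)),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("PPC: %.1f%% of cell statistics inside the central %.0f%% predictive band (%d replicates)\n",
              100 * x$coverage, 100 * x$band, x$n_replicates))
  invisible(x)
}

#' Plot posterior predictive signed-RT distributions
#'
#' Writes one panel per group: the observed signed-RT histogram (negative =
#' female response) with the predictive replicate densities overlaid.
#'
#' @param observed Observed trial table.
#' @param replicates Replicate list from [posterior_predict()].
#' @param file PNG output path.
#' @return `file`, invisibly.
#' @export
plot_ppc <- function(observed, replicates, file) {
  observed <- observed[observed$response != "omitted", , drop = FALSE]
  signed <- function(tr) ifelse(tr$response == UPPER_RESPONSE, 1, -1) * tr$rt_ms / 1000
  groups <- sort(unique(observed$group))
  grDevices::png(file, width = 900, height = 450 * length(groups), res = 100)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(groups), 1))
  for (g in groups) {
    x <- signed(observed[observed$group == g, ])
    graphics::hist(x, breaks = 60, freq = FALSE, col = "grey80", border = NA,
                   main = paste("Group", g), xlab = "signed RT (s)")
    for (r in replicates[seq_len(min(20, length(replicates)))]) {
      xr <- signed(r[r$group == g, ])
      graphics::lines(stats::density(xr), col = grDevices::rgb(0, 0, 0, 0.25))
    }
  }
  invisible(file)
}

mu_cell_names <- function(fit) {
  nm <- character(0)
  for (g in fit$groups) {
    nm <- c(nm, cell_name("mu_a", g), cell_name("mu_t", g))
    for (ad in fit$adaptors) nm <- c(nm, cell_name("mu_b", g, ad))
    for (ad in fit$adaptors) for (m in fit$morphs) {
      nm <- c(nm, cell_name("mu_v", g, ad, m))
    }
  }
  nm
}

truth_of_cell <- function(config, nm) {
  inside <- sub("^[a-z_]+\\[(.*)\\]$", "\\1", nm)
  parts <- strsplit(inside, ",")[[1]]
  tr <- config$truth[[parts[1]]]
  switch(sub("\\[.*$", "", nm),
         mu_a = tr$mu_a, mu_t = tr$mu_t,
         mu_b = tr$mu_b[[parts[2]]],
         mu_v = tr$mu_v[parts[2], parts[3]])
}

#' Parameter-recovery study
#'
#' Loops generate -> preprocess -> fit -> contrast on a preset scenario and
#' reports, per group-level mean cell: bias, RMSE, and central 95% interval
#' coverage of the generative truth; plus the credibility pattern of the
#' drift-rate group contrasts (the 16-cell family) and the sign of the
#' male-morph (60/80%) group drift difference in every replicate.
#'
#' @param scenario Preset name for [preset_paper_like()].
#' @param n_replicates Number of replicates.
#' @param n_per_group Participants per group (named vector).
#' @param trials_per_morph Repetitions per morph per condition.
#' @param sampler An `hddm_sampler_config` (its seed is re-derived per
#'   replicate).
#' @param q FDR level for the contrast family.
#' @param seed Master seed.
#' @return A `recovery_report`: list with `cells` (per-cell recovery
#'   metrics), `replicates` (per-replicate headline results), and summary
#'   fields `coverage` (fraction of cell x replicate intervals covering
#'   truth), `sign_rate` (fraction of replicates with a negative male-morph
#'   group contrast median), and `any_credible_rate`.
#' @export
recovery_study <- function(scenario, n_replicates = 20,
                           n_per_group = c(AUT = 8, NT = 8),
                           trials_per_morph = 16,
                           sampler = sampler_config(n_chains = 2,
                                                    n_iterations = 1200,
                                                    n_burn_in = 600),
                           q = 0.05, seed = 1) {
  cell_rows <- list()
  rep_rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- preset_paper_like(scenario, n_per_group = n_per_group,
                             trials_per_morph = trials_per_morph,
                             seed = seed + 1000L * r)
    sim <- generate_experiment(cfg)
    pp <- preprocess(sim$trials)
    spec <- build_model(pp$model_trials)
    sampler$seed <- as.integer(seed + 17L * r)
    fit <- suppressWarnings(sample_posterior(spec, config = sampler))

    for (nm in mu_cell_names(fit)) {
      d <- draws_of(fit, nm)
      ci <- quantile(d, c(0.025, 0.975), names = FALSE)
      tv <- truth_of_cell(cfg, nm)
      cell_rows[[length(cell_rows) + 1]] <- data.frame(
        replicate = r, cell = nm, truth = tv, estimate = median(d),
        lower = ci[1], upper = ci[2],
        covered = tv >= ci[1] & tv <= ci[2])
    }

    fam <- run_contrast_family(fit, drift_cell_contrasts(fit), q = q)
    male_cells <- fit$morphs[fit$morphs > 50]
    md <- rowMeans(sapply(fit$adaptors, function(ad) {
      rowMeans(sapply(male_cells, function(m) {
        draws_of(fit, cell_name("mu_v", fit$groups[1], ad, m)) -
          draws_of(fit, cell_name("mu_v", fit$groups[2], ad, m))
      }))
    }))
    rep_rows[[length(rep_rows) + 1]] <- data.frame(
      replicate = r, max_rhat = max(fit$rhat),
      n_credible = sum(fam$summary$credible),
      any_credible = any(fam$summary$credible),
      male_contrast_median = median(md),
      sign_negative = median(md) < 0)
  }
  cells <- do.call(rbind, cell_rows)
  reps <- do.call(rbind, rep_rows)
  per_cell <- aggregate(cbind(bias = estimate - truth,
                              sqerr = (estimate - truth)^2,
                              covered = covered) ~ cell, data = cells, FUN = mean)
  per_cell$rmse <- sqrt(per_cell$sqerr)
  per_cell$sqerr <- NULL
  structure(list(scenario = scenario, cells = per_cell, draws = cells,
                 replicates = reps,
                 coverage = mean(cells$covered),
                 sign_rate = mean(reps$sign_negative),
                 any_credible_rate = mean(reps$any_credible)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery study ('%s', %d replicates)\n", x$scenario,
              nrow(x$replicates)))
  cat(sprintf("  truth coverage by 95%% intervals: %.1f%%\n", 100 * x$coverage))
  cat(sprintf("  negative male-morph group contrast in %.0f%% of replicates\n",
              100 * x$sign_rate))
  cat(sprintf("  >=1 credible drift contrast in %.0f%% of replicates\n",
              100 * x$any_credible_rate))
  invisible(x)
}
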