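# Shared fixtures, built in code at test time.

# hand-built trial table: one participant block with explicit RTs
make_block <- function(pid, group, adaptor, rts_ms, responses,
                       morphs = rep(20, length(rts_ms))) {
  data.frame(participant_id = pid, group = group, adaptor = adaptor,
             morph_pct = morphs, trial_index = seq_along(rts_ms),
             response = responses, rt_ms = rts_ms,
             stringsAsFactors = FALSE)
}

# a small but complete synthetic cohort (cheap default)
small_cohort <- function(seed = 7, n = c(AUT = 3, NT = 3), reps = 8, ...) {
  generate_experiment(fae_config(n_per_group = n, trials_per_morph = reps,
                                 seed = seed, ...))
}

# one small hierarchical fit, computed once and shared across test files
shared_fit_env <- new.env()
shared_small_fit <- function() {
  if (is.null(shared_fit_env$fit)) {
    sim <- generate_experiment(preset_paper_like(
      "adaptor_shift_only", n_per_group = c(AUT = 6, NT = 6),
      trials_per_morph = 8, seed = 31))
    pp <- preprocess(sim$trials)
    spec <- build_model(pp$model_trials)
    fit <- suppressWarnings(sample_posterior(
      spec, config = sampler_config(n_chains = 2, n_iterations = 800,
                                    n_burn_in = 400, seed = 32)))
    shared_fit_env$fit <- fit
    shared_fit_env$trials <- pp$model_trials
    shared_fit_env$truth_config <- sim$config
  }
  shared_fit_env
}

# a fake fit with draws fully under test control (documented array layout)
fake_fit <- function(draw_list, n_chains = 2,
                     groups = c("AUT", "NT"),
                     adaptors = c("androgynous", "male"),
                     morphs = c(20, 40, 60, 80)) {
  n <- length(draw_list[[1]])
  stopifnot(n %% n_chains == 0)
  draws <- array(NA_real_, c(n / n_chains, n_chains, length(draw_list)),
                 dimnames = list(NULL, NULL, names(draw_list)))
  for (p in seq_along(draw_list)) {
    draws[, , p] <- matrix(draw_list[[p]], ncol = n_chains)
  }
  structure(list(draws = draws, rhat = rep(1, length(draw_list)),
                 converged = TRUE, groups = groups, adaptors = adaptors,
                 morphs = morphs,
                 config = sampler_config(n_chains, n, n - n / n_chains)),
            class = "hddm_fit")
}
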