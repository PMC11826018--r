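# Synthetic gender face-aftereffect experiments: a two-group, two-adaptor,
# four-morph-level choice/RT design with a hierarchical diffusion-model
# truth, plus omissions and fast/slow contaminant trials.

GROUPS <- c("AUT", "NT")

#' Group-level generative truth for one group
#'
#' Means and precisions (inverse variances) of the normal distributions from
#' which subject-level diffusion parameters are drawn: one (mu, tau) cell for
#' `a` and `t`, one per adaptor for the start point `b`, and one per
#' (adaptor, morph) for the drift `v`.
#'
#' @param mu_a,tau_a Mean and precision of boundary separation.
#' @param mu_t,tau_t Mean and precision of non-decision time (seconds).
#' @param mu_b,tau_b Named vectors over adaptors for the start point.
#' @param mu_v,tau_v Matrices (adaptor x morph) for the drift rate.
#' @return A `group_truth` list.
#' @export
group_truth <- function(mu_a, tau_a, mu_t, tau_t, mu_b, tau_b, mu_v, tau_v) {
  g <- structure(list(mu_a = mu_a, tau_a = tau_a, mu_t = mu_t, tau_t = tau_t,
                      mu_b = mu_b, tau_b = tau_b, mu_v = mu_v, tau_v = tau_v),
                 class = "group_truth")
  taus <- c(tau_a, tau_t, tau_b, tau_v)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    stop("group_truth: all precisions tau must be finite and > 0", call. = FALSE)
  }
  g
}

#' Generator configuration for a synthetic experiment
#'
#' Describes the full design: group sizes, morph levels, adaptor conditions,
#' repetitions, the group-level generative truth, contaminant rates, the
#' response window, and the seed. The default design matches a two-group
#' study with 29 and 39 participants, 32 repetitions of each of four morph
#' levels per adaptor condition (128 trials per condition).
#'
#' @param n_per_group Named integer vector of participants per group.
#' @param trials_per_morph Repetitions per morph level per adaptor condition.
#' @param morph_levels Ordered morph levels (percent male).
#' @param adaptors Ordered adaptor conditions.
#' @param truth Named list of [group_truth] objects, one per group.
#' @param omission_rate Probability a trial has no recorded response.
#' @param fast_guess_rate Probability of a uniform contaminant RT below 250 ms.
#' @param slow_outlier_rate Probability of an inflated RT near the window end.
#' @param response_window_ms Maximum recordable RT (ms); later responses
#'   become omissions.
#' @param seed Integer seed controlling all randomness of the generator.
#' @return A `fae_config` list.
#' @export
#' @examples
#' cfg <- fae_config(n_per_group = c(AUT = 4, NT = 4), trials_per_morph = 8)
#' cfg$trials_per_morph * length(cfg$morph_levels)  # trials per condition
fae_config <- function(n_per_group = c(AUT = 29, NT = 39),
                       trials_per_morph = 32,
                       morph_levels = c(20, 40, 60, 80),
                       adaptors = c("androgynous", "male"),
                       truth = default_truth(names(n_per_group), adaptors,
                                             morph_levels),
                       omission_rate = 0.02,
                       fast_guess_rate = 0.01,
                       slow_outlier_rate = 0.01,
                       response_window_ms = 2200,
                       seed = 1L) {
  cfg <- structure(list(n_per_group = n_per_group,
                        trials_per_morph = as.integer(trials_per_morph),
                        morph_levels = morph_levels, adaptors = adaptors,
                        truth = truth, omission_rate = omission_rate,
                        fast_guess_rate = fast_guess_rate,
                        slow_outlier_rate = slow_outlier_rate,
                        response_window_ms = response_window_ms,
                        seed = as.integer(seed)),
                   class = "fae_config")
  validate_fae_config(cfg)
  cfg
}

validate_fae_config <- function(cfg) {
  if (length(cfg$morph_levels) == 0) stop("fae_config: morph_levels must be non-empty", call. = FALSE)
  if (cfg$trials_per_morph < 1) stop("fae_config: trials_per_morph must be >= 1", call. = FALSE)
  if (is.null(names(cfg$n_per_group)) || any(cfg$n_per_group < 1)) {
    stop("fae_config: n_per_group must be a named vector of positive counts", call. = FALSE)
  }
  rates <- c(cfg$omission_rate, cfg$fast_guess_rate, cfg$slow_outlier_rate)
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop("fae_config: contaminant rates must lie in [0, 1] and sum to at most 1", call. = FALSE)
  }
  if (cfg$response_window_ms <= 250) stop("fae_config: response window must exceed 250 ms", call. = FALSE)
  if (!setequal(names(cfg$truth), names(cfg$n_per_group))) {
    stop("fae_config: truth must have one group_truth per group", call. = FALSE)
  }
  for (g in names(cfg$truth)) {
    tr <- cfg$truth[[g]]
    stopifnot(length(tr$mu_b) == length(cfg$adaptors),
              all(dim(tr$mu_v) == c(length(cfg$adaptors), length(cfg$morph_levels))))
  }
  invisible(cfg)
}

# Shared base truth: drift means ordered negative -> positive across morph
# levels 20 -> 80 (evidence toward "male" grows with the male proportion of
# the test face), male-adaptor cells shifted toward "female" (the
# aftereffect), strongest at the ambiguous interior morphs; start point
# slightly below 0.5 under the male adaptor.
base_group_truth <- function(adaptors, morphs, adaptor_shift = TRUE) {
  A <- length(adaptors); M <- length(morphs)
  v_base <- seq(-1.5, 1.5, length.out = M)
  shift <- if (adaptor_shift) 0.4 + 0.6 * sin(seq(0, pi, length.out = M)) else rep(0, M)
  mu_v <- rbind(v_base, v_base - shift)[seq_len(A), , drop = FALSE]
  dimnames(mu_v) <- list(adaptors, as.character(morphs))
  mu_b <- setNames(c(0.5, if (adaptor_shift) 0.45 else 0.5)[seq_len(A)], adaptors)
  group_truth(mu_a = 1.4, tau_a = 8, mu_t = 0.35, tau_t = 100,
              mu_b = mu_b, tau_b = setNames(rep(100, A), adaptors),
              mu_v = mu_v,
              tau_v = matrix(2, A, M, dimnames = dimnames(mu_v)))
}

default_truth <- function(groups, adaptors, morphs) {
  setNames(lapply(groups, function(g) base_group_truth(adaptors, morphs)), groups)
}

#' Preset generator scenarios
#'
#' Returns a complete [fae_config] encoding one of three generative
#' scenarios: `"null"` (groups identical, no adaptor effect anywhere),
#' `"adaptor_shift_only"` (a genuine aftereffect - male-adaptor drift means
#' shifted toward "female" at every morph, start point shifted toward
#' "female" - identical in both groups), and `"male_drift_reduction"`
#' (additionally, the AUT group's drift means are lowered by 0.5 at the
#' predominantly male 60% and 80% morphs only).
#'
#' @param effect Scenario name.
#' @param ... Further arguments passed to [fae_config()] (e.g. `n_per_group`,
#'   `trials_per_morph`, `seed`).
#' @return A `fae_config`.
#' @export
#' @examples
#' cfg <- preset_paper_like("male_drift_reduction", n_per_group = c(AUT = 8, NT = 8))
preset_paper_like <- function(effect = c("adaptor_shift_only", "null",
                                         "male_drift_reduction"), ...) {
  effect <- match.arg(effect)
  dots <- list(...)
  n_per_group <- dots$n_per_group
  if (is.null(n_per_group)) n_per_group <- c(AUT = 29, NT = 39)
  morphs <- dots$morph_levels
  if (is.null(morphs)) morphs <- c(20, 40, 60, 80)
  adaptors <- dots$adaptors
  if (is.null(adaptors)) adaptors <- c("androgynous", "male")

  shift <- effect != "null"
  truth <- setNames(lapply(names(n_per_group), function(g) {
    tr <- base_group_truth(adaptors, morphs, adaptor_shift = shift)
    if (effect == "male_drift_reduction" && g == "AUT") {
      male_side <- morphs > 50
      tr$mu_v[, male_side] <- tr$mu_v[, male_side] - 0.5
    }
    tr
  }), names(n_per_group))

  args <- dots
  args$n_per_group <- n_per_group
  args$morph_levels <- morphs
  args$adaptors <- adaptors
  args$truth <- truth
  do.call(fae_config, args)
}

# truncated-normal draw by clamping (truncation, not resampling, preserves
# the draw count and hence seed reproducibility); counts clamps
clamp_count <- local({
  n_clamped <- 0L
  function(x, lo, hi, reset = FALSE) {
    if (reset) { n_clamped <<- 0L; return(invisible(n_clamped)) }
    if (is.null(x)) return(n_clamped)
    out <- pmin(pmax(x, lo), hi)
    n_clamped <<- n_clamped + sum(out != x)
    out
  }
})

#' Draw subject-level generative truths
#'
#' Samples each participant's diffusion parameters from the group-level
#' normal cells of their group: one `a` and `t`, one `b` per adaptor, one
#' `v` per (adaptor, morph). Out-of-domain draws are truncated (clamped) to
#' the parameter domain - `a` to a small positive floor, `b` into (0, 1),
#' `t` into [0, 1] s - and the number of clamped draws is recorded in the
#' `n_truncated` attribute.
#'
#' @param config A [fae_config].
#' @param seed Optional seed overriding `config$seed`.
#' @return List of subject truths (one per participant) with fields
#'   `participant_id`, `group`, `a`, `t`, `b` (named by adaptor), and `v`
#'   (adaptor x morph matrix); attribute `n_truncated`.
#' @export
sample_subject_truth <- function(config, seed = config$seed) {
  validate_fae_config(config)
  set.seed(seed)
  clamp_count(NULL, reset = TRUE)
  A <- length(config$adaptors); M <- length(config$morph_levels)
  subjects <- list()
  idx <- 0L
  for (g in names(config$n_per_group)) {
    tr <- config$truth[[g]]
    for (i in seq_len(config$n_per_group[[g]])) {
      idx <- idx + 1L
      a <- clamp_count(rnorm(1, tr$mu_a, 1 / sqrt(tr$tau_a)), 0.05, Inf)
      t0 <- clamp_count(rnorm(1, tr$mu_t, 1 / sqrt(tr$tau_t)), 0, 1)
      b <- clamp_count(rnorm(A, tr$mu_b, 1 / sqrt(tr$tau_b)), 0.01, 0.99)
      v <- matrix(rnorm(A * M, tr$mu_v, 1 / sqrt(tr$tau_v)), A, M,
                  dimnames = dimnames(tr$mu_v))
      subjects[[idx]] <- list(
        participant_id = sprintf("P%03d", idx), group = g,
        a = a, t = t0, b = setNames(b, config$adaptors), v = v)
    }
  }
  attr(subjects, "n_truncated") <- clamp_count(NULL)
  subjects
}

#' Subject-cell diffusion parameters
#'
#' Assemble the [ddm_params] of one (adaptor, morph) cell from a subject
#' truth.
#'
#' @param subject One element of the list returned by
#'   [sample_subject_truth()].
#' @param adaptor,morph Cell labels.
#' @return A [ddm_params] object.
#' @export
subject_cell_params <- function(subject, adaptor, morph) {
  ddm_params(a = subject$a, t = subject$t, b = subject$b[[adaptor]],
             v = subject$v[adaptor, as.character(morph)])
}

#' Generate a complete synthetic experiment
#'
#' Simulates every participant's two adaptor blocks (block order
#' counterbalanced by participant parity), with `trials_per_morph`
#' repetitions of each morph level per block in randomized order. Choices
#' and reaction times come from the subject's cell parameters via the exact
#' diffusion sampler; contaminant trials (omissions, fast guesses uniform on
#' (0, 250) ms, slow outliers near the window end) are then injected, and
#' any RT exceeding the response window becomes an omission.
#'
#' @param config A [fae_config].
#' @return List with `trials` (a data frame with columns `participant_id`,
#'   `group`, `adaptor`, `morph_pct`, `trial_index`, `response`, `rt_ms`),
#'   `truth` (the subject truths), and `config`.
#' @export
#' @examples
#' sim <- generate_experiment(fae_config(n_per_group = c(AUT = 2, NT = 2),
#'                                       trials_per_morph = 4))
#' table(sim$trials$adaptor) / 4  # trials per condition
generate_experiment <- function(config) {
  validate_fae_config(config)
  truth <- sample_subject_truth(config)  # seeds the RNG; trial noise follows
  rows <- vector("list", length(truth))
  for (si in seq_along(truth)) {
    subj <- truth[[si]]
    first_male <- si %% 2L == 0L  # parity counterbalancing
    block_order <- if (first_male) rev(config$adaptors) else config$adaptors
    brows <- list()
    for (ad in block_order) {
      # simulate per cell (shared CDF grid), then shuffle into block order
      cell_rows <- lapply(config$morph_levels, function(m) {
        sim <- simulate_ddm(config$trials_per_morph,
                            subject_cell_params(subj, ad, m))
        data.frame(adaptor = ad, morph_pct = m, response = sim$response,
                   rt_ms = sim$rt * 1000, stringsAsFactors = FALSE)
      })
      blk <- do.call(rbind, cell_rows)
      blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
      blk$trial_index <- seq_len(nrow(blk))
      brows[[ad]] <- blk
    }
    blk <- do.call(rbind, brows)

    # contaminants: at most one mechanism per trial
    u <- runif(nrow(blk))
    om <- u < config$omission_rate
    fast <- !om & u < config$omission_rate + config$fast_guess_rate
    slow <- !om & !fast &
      u < config$omission_rate + config$fast_guess_rate + config$slow_outlier_rate
    if (any(fast)) {
      blk$rt_ms[fast] <- runif(sum(fast), 0, 250)
      blk$response[fast] <- sample(c(UPPER_RESPONSE, LOWER_RESPONSE),
                                   sum(fast), replace = TRUE)
    }
    if (any(slow)) {
      blk$rt_ms[slow] <- runif(sum(slow), 0.75 * config$response_window_ms,
                               config$response_window_ms)
    }
    om <- om | blk$rt_ms > config$response_window_ms
    blk$response[om] <- "omitted"
    blk$rt_ms[om] <- NA_real_
    blk$rt_ms <- round(blk$rt_ms, 3)

    blk$participant_id <- subj$participant_id
    blk$group <- subj$group
    rows[[si]] <- blk[, c("participant_id", "group", "adaptor", "morph_pct",
                          "trial_index", "response", "rt_ms")]
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials, truth = truth, config = config)
}

#' Read and write trial tables
#'
#' CSV schema: `participant_id, group, adaptor, morph_pct, trial_index,
#' response, rt_ms` (omitted trials have an empty `rt_ms`). Writing and
#' re-reading a generated table round-trips exactly.
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return `read_trials` returns the trial data frame; `write_trials`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_columns() %in% names(trials)))
  write.csv(trials[, trial_columns()], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character",
                                group = "character", adaptor = "character",
                                morph_pct = "numeric",
                                trial_index = "integer",
                                response = "character", rt_ms = "numeric"))
  missing <- setdiff(trial_columns(), names(tr))
  if (length(missing)) {
    stop("read_trials: missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tr
}

trial_columns <- function() {
  c("participant_id", "group", "adaptor", "morph_pct", "trial_index",
    "response", "rt_ms")
}
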