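# Trial- and participant-level exclusion rules with a deterministic report.
# Rule attribution order is fixed: first-three -> omission -> fast -> slow,
# so each excluded trial is counted under exactly one rule.

#' Study-level participant exclusion
#'
#' Removes participants who failed to respond in more than a third of their
#' trials.
#'
#' @param trials Trial data frame (see [read_trials()] for the schema).
#' @param max_omission_fraction Omission fraction above which a participant
#'   is removed (default 1/3).
#' @return List with `trials` (retained rows) and `removed` (participant ids
#'   with their omission fractions).
#' @export
exclude_participants_study <- function(trials, max_omission_fraction = 1 / 3) {
  if (nrow(trials) == 0) stop("exclude_participants_study: empty trial table", call. = FALSE)
  om <- tapply(trials$response == "omitted", trials$participant_id, mean)
  bad <- names(om)[om > max_omission_fraction]
  list(trials = trials[!(trials$participant_id %in% bad), , drop = FALSE],
       removed = setNames(as.numeric(om[bad]), bad))
}

#' Trial-level exclusions for the hierarchical model
#'
#' Applies, in order: removal of the first three trials of each participant's
#' condition block (each block is a fresh adaptation context), omitted
#' trials, extremely fast trials (RT < 250 ms), and extremely slow trials
#' (RT above the pooled mean + 3 SD of the trials surviving the earlier
#' rules). The slow threshold is recomputed from the data unless supplied.
#'
#' @param trials Trial data frame, after study-level participant exclusion.
#' @param first_n Leading trials removed per condition block (default 3).
#' @param fast_ms Fast-guess cutoff in ms (default 250).
#' @param slow_sd Number of pooled SDs above the pooled mean defining the
#'   slow cutoff (default 3).
#' @param slow_threshold_ms Optional fixed slow cutoff in ms; when `NULL`
#'   (default) it is computed from the data and recorded in the report.
#' @return List with `trials` (retained rows) and `report` (an
#'   `exclusion_report`: per-rule counts, the slow threshold used, and
#'   per-participant input/retained counts).
#' @export
exclude_trials_hddm <- function(trials, first_n = 3, fast_ms = 250,
                                slow_sd = 3, slow_threshold_ms = NULL) {
  if (nrow(trials) == 0) stop("exclude_trials_hddm: empty trial table", call. = FALSE)
  block <- interaction(trials$participant_id, trials$adaptor, drop = TRUE)
  if (min(table(block)) < first_n + 1) {
    stop("exclude_trials_hddm: every condition block needs more than ",
         first_n, " trials", call. = FALSE)
  }
  n_input <- table(trials$participant_id)

  rule <- rep(NA_character_, nrow(trials))
  rule[trials$trial_index <= first_n] <- "first_trials"
  rule[is.na(rule) & trials$response == "omitted"] <- "omission"
  rule[is.na(rule) & trials$rt_ms < fast_ms] <- "fast"
  if (is.null(slow_threshold_ms)) {
    surviving <- trials$rt_ms[is.na(rule)]
    slow_threshold_ms <- if (length(surviving) < 2) Inf else
      mean(surviving) + slow_sd * sd(surviving)
  }
  rule[is.na(rule) & trials$rt_ms > slow_threshold_ms] <- "slow"

  keep <- is.na(rule)
  retained <- trials[keep, , drop = FALSE]
  n_kept <- table(factor(retained$participant_id, levels = names(n_input)))
  report <- structure(list(
    counts = c(first_trials = sum(rule == "first_trials", na.rm = TRUE),
               omission = sum(rule == "omission", na.rm = TRUE),
               fast = sum(rule == "fast", na.rm = TRUE),
               slow = sum(rule == "slow", na.rm = TRUE)),
    slow_threshold_ms = slow_threshold_ms,
    trials_input = c(n_input), trials_retained = c(n_kept),
    participants_removed_study = character(0),
    participants_removed_model = character(0)),
    class = "exclusion_report")
  list(trials = retained, report = report)
}

#' Model-level participant exclusion
#'
#' Removes participants whose retained-trial fraction (relative to their
#' pre-exclusion trial total) is below 50%; a participant at exactly 50% is
#' kept.
#'
#' @param trials Trial table returned by [exclude_trials_hddm()].
#' @param report The accompanying `exclusion_report`.
#' @param min_valid_fraction Minimum retained fraction (default 0.5).
#' @return List with `trials` and the updated `report`.
#' @export
exclude_participants_hddm <- function(trials, report, min_valid_fraction = 0.5) {
  frac <- report$trials_retained / report$trials_input
  bad <- names(frac)[frac < min_valid_fraction]
  report$participants_removed_model <- bad
  list(trials = trials[!(trials$participant_id %in% bad), , drop = FALSE],
       report = report)
}

#' Full exclusion chain
#'
#' Convenience wrapper running study-level participant exclusion, the
#' trial-level rules, and model-level participant exclusion. `study_trials`
#' (all responded trials of study-retained participants) feed the model-free
#' analysis; `model_trials` feed the hierarchical model.
#'
#' @param trials Raw trial data frame.
#' @param ... Passed to [exclude_trials_hddm()].
#' @return List with `study_trials`, `model_trials`, and `report`.
#' @export
#' @examples
#' sim <- generate_experiment(fae_config(n_per_group = c(AUT = 3, NT = 3),
#'                                       trials_per_morph = 8))
#' pp <- preprocess(sim$trials)
#' pp$report$counts
preprocess <- function(trials, ...) {
  st <- exclude_participants_study(trials)
  tl <- exclude_trials_hddm(st$trials, ...)
  ml <- exclude_participants_hddm(tl$trials, tl$report)
  ml$report$participants_removed_study <- names(st$removed)
  list(study_trials = st$trials, model_trials = ml$trials,
       report = ml$report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat(sprintf("  trials removed: first-three %d, omission %d, fast %d, slow %d\n",
              x$counts[["first_trials"]], x$counts[["omission"]],
              x$counts[["fast"]], x$counts[["slow"]]))
  cat(sprintf("  slow-RT threshold: %.1f ms\n", x$slow_threshold_ms))
  cat(sprintf("  participants removed: %d (study), %d (model)\n",
              length(x$participants_removed_study),
              length(x$participants_removed_model)))
  invisible(x)
}
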