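# Model-free analysis: per-cell male-response proportions, the aftereffect
# difference curve, and the 2 (group) x 2 (adaptor) x 4 (morph) mixed ANOVA
# with sphericity and homogeneity diagnostics.

#' Male-response proportions per participant cell
#'
#' Computes, over responded (non-omitted) trials, the proportion of "male"
#' responses for every participant x adaptor x morph cell, plus group-level
#' means with 95% confidence intervals.
#'
#' @param trials Trial data frame (study-level exclusions applied).
#' @return A `proportion_table`: list with `cells` (participant-level
#'   proportions; cells with no responded trials are `NA`) and
#'   `group_summary` (per group x adaptor x morph mean, t-based 95% CI, n).
#' @export
response_proportions <- function(trials) {
  resp <- trials[trials$response != "omitted", , drop = FALSE]
  resp$male <- as.numeric(resp$response == UPPER_RESPONSE)
  cells <- aggregate(male ~ participant_id + group + adaptor + morph_pct,
                     data = resp, FUN = function(x) c(p = mean(x), n = length(x)))
  cells <- data.frame(cells[, 1:4], p_male = cells$male[, "p"],
                      n_responded = cells$male[, "n"])

  # complete the participant x adaptor x morph lattice; empty cells -> NA
  ids <- unique(trials[, c("participant_id", "group")])
  lattice <- expand.grid(participant_id = ids$participant_id,
                         adaptor = unique(trials$adaptor),
                         morph_pct = sort(unique(trials$morph_pct)),
                         stringsAsFactors = FALSE)
  lattice <- merge(lattice, ids, by = "participant_id")
  cells <- merge(lattice, cells, all.x = TRUE,
                 by = c("participant_id", "group", "adaptor", "morph_pct"))
  cells$n_responded[is.na(cells$n_responded)] <- 0L
  cells <- cells[order(cells$participant_id, cells$adaptor, cells$morph_pct), ]
  rownames(cells) <- NULL

  summ <- aggregate(p_male ~ group + adaptor + morph_pct, data = cells,
                    FUN = function(x) {
                      n <- sum(!is.na(x)); m <- mean(x, na.rm = TRUE)
                      se <- sd(x, na.rm = TRUE) / sqrt(n)
                      hw <- if (n > 1) qt(0.975, n - 1) * se else NA_real_
                      c(mean = m, ci_lo = m - hw, ci_hi = m + hw, n = n)
                    }, na.action = NULL)
  summ <- data.frame(summ[, 1:3], summ$p_male)
  structure(list(cells = cells, group_summary = summ),
            class = "proportion_table")
}

#' Face-aftereffect difference curve
#'
#' The aftereffect is the difference in male-response probability between
#' the reference (androgynous) and the adapting (male) adaptor condition,
#' per participant and morph level, then averaged per group with a 95% CI.
#'
#' @param table A `proportion_table` from [response_proportions()].
#' @param adaptor_ref Reference adaptor (default `"androgynous"`).
#' @param adaptor_adapt Adapting adaptor (default `"male"`).
#' @return List with `participant` (per-participant differences; missing
#'   cells propagate as `NA`) and `group_summary` (group x morph mean, CI).
#' @export
fae_curve <- function(table, adaptor_ref = "androgynous", adaptor_adapt = "male") {
  cells <- table$cells
  ref <- cells[cells$adaptor == adaptor_ref, ]
  adp <- cells[cells$adaptor == adaptor_adapt, ]
  if (nrow(ref) == 0 || nrow(adp) == 0) {
    stop("fae_curve: both adaptor conditions must be present", call. = FALSE)
  }
  m <- merge(ref[, c("participant_id", "group", "morph_pct", "p_male")],
             adp[, c("participant_id", "morph_pct", "p_male")],
             by = c("participant_id", "morph_pct"),
             suffixes = c("_ref", "_adapt"))
  m$fae <- m$p_male_ref - m$p_male_adapt
  summ <- aggregate(fae ~ group + morph_pct, data = m, FUN = function(x) {
    n <- sum(!is.na(x)); mu <- mean(x, na.rm = TRUE)
    se <- sd(x, na.rm = TRUE) / sqrt(n)
    hw <- if (n > 1) qt(0.975, n - 1) * se else NA_real_
    c(mean = mu, ci_lo = mu - hw, ci_hi = mu + hw, n = n)
  }, na.action = NULL)
  summ <- data.frame(summ[, 1:2], summ$fae)
  list(participant = m[, c("participant_id", "group", "morph_pct", "fae")],
       group_summary = summ)
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C %*% diag(1 / sqrt(colSums(C^2)), ncol(C), ncol(C))
}

# pooled within-group covariance of contrast scores; returns the epsilon and
# Mauchly statistics for one within-subject effect
sphericity_stats <- function(scores, group) {
  n <- nrow(scores); g <- length(unique(group)); p <- ncol(scores)
  res <- scores - apply(scores, 2, function(col) ave(col, group))
  S <- crossprod(res) / (n - g)
  eps <- sum(diag(S))^2 / (p * sum(S * S))
  if (p == 1) {
    return(list(epsilon = 1, W = 1, chisq = 0, df = 0, p_value = NA_real_))
  }
  W <- det(S) / (sum(diag(S)) / p)^p
  f <- n - g
  df <- p * (p + 1) / 2 - 1
  if (f <= p || !is.finite(W) || W <= 0) {
    # too few error df to assess sphericity; epsilon is still defined
    return(list(epsilon = eps, W = NA_real_, chisq = NA_real_, df = df,
                p_value = NA_real_))
  }
  d <- 1 - (2 * p^2 + p + 2) / (6 * p * f)
  chisq <- -f * d * log(W)
  list(epsilon = eps, W = W, chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE))
}

#' Mixed three-way ANOVA on response proportions
#'
#' Full decomposition of the 2 (Group, between) x 2 (Adaptor, within) x 4
#' (Morph, within) design on per-cell male-response proportions. Sums of
#' squares, df, and F ratios come from the balanced mixed-design least
#' squares fit; Greenhouse-Geisser epsilon is computed from the pooled
#' covariance of orthonormalized within-subject contrasts and applied
#' (unconditionally) to every within effect involving the morph factor;
#' Mauchly's sphericity test is reported for those effects and Levene's
#' test (absolute deviations from the group mean of participant-mean
#' proportions) for the between factor.
#'
#' @param table A `proportion_table` from [response_proportions()].
#' @return A `fae_anova`: list with `table` (effect, SS, df, F, p, epsilon,
#'   GG-corrected df and p), `mauchly`, `levene`, and `dropped`
#'   (participants removed for incomplete cells).
#' @export
mixed_anova <- function(table) {
  cells <- table$cells
  adaptors <- sort(unique(cells$adaptor))
  morphs <- sort(unique(cells$morph_pct))
  A <- length(adaptors); M <- length(morphs)

  # wide matrix, columns ordered adaptor (outer) x morph (inner)
  Y <- matrix(NA_real_, nrow = length(unique(cells$participant_id)), A * M)
  ids <- unique(cells[, c("participant_id", "group")])
  rownames(Y) <- ids$participant_id
  j <- 0
  for (ad in adaptors) for (m in morphs) {
    j <- j + 1
    sub <- cells[cells$adaptor == ad & cells$morph_pct == m, ]
    Y[sub$participant_id, j] <- sub$p_male
  }
  complete <- stats::complete.cases(Y)
  dropped <- rownames(Y)[!complete]
  Y <- Y[complete, , drop = FALSE]
  ids <- ids[complete, ]
  if (min(table(ids$group)) < 2) {
    stop("mixed_anova: need at least 2 complete participants per group", call. = FALSE)
  }

  long <- data.frame(
    p_male = as.vector(Y),
    participant = factor(rep(ids$participant_id, A * M)),
    group = factor(rep(ids$group, A * M)),
    adaptor = factor(rep(rep(adaptors, each = M), each = nrow(Y))),
    morph = factor(rep(rep(morphs, times = A), each = nrow(Y))))

  fit <- aov(p_male ~ group * adaptor * morph +
               Error(participant / (adaptor * morph)), data = long)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    row <- trimws(rownames(tab)) == effect
    res <- trimws(rownames(tab)) == "Residuals"
    c(SS = tab[row, "Sum Sq"], df1 = tab[row, "Df"],
      df2 = tab[res, "Df"], F = tab[row, "F value"],
      p = tab[row, "Pr(>F)"], SS_err = tab[res, "Sum Sq"])
  }
  rows <- rbind(
    Group = pull("participant", "group"),
    Adaptor = pull("participant:adaptor", "adaptor"),
    `Adaptor:Group` = pull("participant:adaptor", "group:adaptor"),
    Morph = pull("participant:morph", "morph"),
    `Morph:Group` = pull("participant:morph", "group:morph"),
    `Adaptor:Morph` = pull("participant:adaptor:morph", "adaptor:morph"),
    `Adaptor:Morph:Group` = pull("participant:adaptor:morph", "group:adaptor:morph"))

  # sphericity: orthonormal contrast scores per within effect
  CM <- orthonormal_contrasts(M)
  CA <- orthonormal_contrasts(A)
  ones <- function(k) matrix(1 / k, k, 1)
  # columns of Y are adaptor-outer/morph-inner, so the Kronecker order is
  # (adaptor x morph): C_A (x) C_M picks the interaction contrasts directly
  scores_morph <- Y %*% (ones(A) %x% CM)   # averaged over adaptor
  scores_ad <- Y %*% (CA %x% ones(M))      # averaged over morph
  scores_int <- Y %*% (CA %x% CM)
  sph <- list(Adaptor = sphericity_stats(scores_ad, ids$group),
              Morph = sphericity_stats(scores_morph, ids$group),
              `Adaptor:Morph` = sphericity_stats(scores_int, ids$group))

  eps_for <- c(Group = NA, Adaptor = sph$Adaptor$epsilon,
               `Adaptor:Group` = sph$Adaptor$epsilon,
               Morph = sph$Morph$epsilon, `Morph:Group` = sph$Morph$epsilon,
               `Adaptor:Morph` = sph$`Adaptor:Morph`$epsilon,
               `Adaptor:Morph:Group` = sph$`Adaptor:Morph`$epsilon)
  out <- data.frame(effect = rownames(rows), rows, row.names = NULL)
  out$epsilon <- as.numeric(eps_for[out$effect])
  out$df1_gg <- out$df1 * out$epsilon
  out$df2_gg <- out$df2 * out$epsilon
  out$p_gg <- ifelse(is.na(out$epsilon), out$p,
                     pf(out$F, out$df1_gg, out$df2_gg, lower.tail = FALSE))

  # Levene on participant-mean proportions
  pm <- rowMeans(Y)
  lev <- car::leveneTest(pm ~ factor(ids$group), center = mean)

  mauchly <- data.frame(effect = names(sph),
                        W = sapply(sph, `[[`, "W"),
                        chisq = sapply(sph, `[[`, "chisq"),
                        df = sapply(sph, `[[`, "df"),
                        p_value = sapply(sph, `[[`, "p_value"),
                        row.names = NULL)
  structure(list(table = out, mauchly = mauchly,
                 levene = data.frame(F = lev[1, "F value"],
                                     df1 = lev[1, "Df"], df2 = lev[2, "Df"],
                                     p = lev[1, "Pr(>F)"]),
                 dropped = dropped),
            class = "fae_anova")
}

#' @export
print.fae_anova <- function(x, ...) {
  cat("Mixed ANOVA (Greenhouse-Geisser corrected where applicable)\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$epsilon[i])) {
      cat(sprintf("  %-22s F(%g, %g) = %.2f, p = %.4g\n", tab$effect[i],
                  tab$df1[i], tab$df2[i], tab$F[i], tab$p[i]))
    } else {
      cat(sprintf("  %-22s F(%.2f, %.2f) = %.2f, p = %.4g (eps = %.3f)\n",
                  tab$effect[i], tab$df1_gg[i], tab$df2_gg[i], tab$F[i],
                  tab$p_gg[i], tab$epsilon[i]))
    }
  }
  if (length(x$dropped)) {
    cat("  dropped (incomplete cells):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
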