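# Posterior contrast testing: iteration-wise differences, nested
# subtractions, two-sided posterior tail probabilities, a Benjamini-Hochberg
# step-up threshold over the contrast family, and central credible intervals
# at the FDR-adjusted coverage.

draws_of <- function(fit, par) {
  if (!par %in% dimnames(fit$draws)[[3]]) {
    stop("unknown parameter: ", par, call. = FALSE)
  }
  as.vector(fit$draws[, , par])  # chain-major, aligned by (iteration, chain)
}

new_contrast <- function(name, diff) {
  structure(list(name = name, draws = diff, median = median(diff),
                 p = posterior_p(diff), lower = NA_real_, upper = NA_real_,
                 coverage = NA_real_, credible = NA),
            class = "hddm_contrast")
}

#' Posterior contrast between two parameter cells
#'
#' Iteration-wise difference `A - B` of the posterior draws of two
#' parameters, aligned by chain and iteration.
#'
#' @param fit An `hddm_fit`.
#' @param cell_a,cell_b Parameter names (see [cell_name()]).
#' @param name Contrast label.
#' @return An `hddm_contrast` with the difference draws, their median, and
#'   the two-sided posterior tail probability; interval fields are filled by
#'   [adjusted_interval()] or [run_contrast_family()].
#' @export
contrast <- function(fit, cell_a, cell_b,
                     name = paste(cell_a, "-", cell_b)) {
  da <- draws_of(fit, cell_a); db <- draws_of(fit, cell_b)
  if (length(da) != length(db)) stop("contrast: draw-count mismatch", call. = FALSE)
  new_contrast(name, da - db)
}

#' Nested posterior contrast (difference of differences)
#'
#' Iteration-wise `(A1 - A2) - (B1 - B2)`, the construction used for
#' interaction effects such as Group x Adaptor.
#'
#' @param fit An `hddm_fit`.
#' @param pair_a,pair_b Character vectors of two parameter names each.
#' @param name Contrast label.
#' @return An `hddm_contrast`.
#' @export
nested_contrast <- function(fit, pair_a, pair_b,
                            name = sprintf("(%s - %s) - (%s - %s)",
                                           pair_a[1], pair_a[2],
                                           pair_b[1], pair_b[2])) {
  stopifnot(length(pair_a) == 2, length(pair_b) == 2)
  d <- (draws_of(fit, pair_a[1]) - draws_of(fit, pair_a[2])) -
    (draws_of(fit, pair_b[1]) - draws_of(fit, pair_b[2]))
  new_contrast(name, d)
}

#' Two-sided posterior tail probability
#'
#' `p = 2 * min(P(d <= 0), P(d >= 0))` over the difference draws, clipped to
#' `[1/n, 1]` (the draw-resolution floor).
#'
#' @param diff Numeric vector of difference draws (at least 100).
#' @return Scalar in `[1/n, 1]`.
#' @export
posterior_p <- function(diff) {
  n <- length(diff)
  if (n < 100) stop("posterior_p: need at least 100 draws", call. = FALSE)
  p <- 2 * min(mean(diff <= 0), mean(diff >= 0))
  min(max(p, 1 / n), 1)
}

#' Benjamini-Hochberg step-up threshold
#'
#' The largest `p_(k)` with `p_(k) <= k * q / m` (0 if none); contrasts with
#' `p` at or below the threshold pass. Equivalent to BH-adjusted p-values
#' compared against `q`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `threshold` and logical `pass` flags.
#' @export
#' @examples
#' fdr_adjust(c(0.001, 0.01, 0.02, 0.04, 0.2))
fdr_adjust <- function(p, q = 0.05) {
  if (length(p) == 0) stop("fdr_adjust: empty p-value list", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("fdr_adjust: p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  ps <- sort(p)
  ok <- ps <= seq_len(m) * q / m
  threshold <- if (any(ok)) ps[max(which(ok))] else 0
  list(threshold = threshold, pass = p <= threshold & threshold > 0)
}

#' Central credible interval at an adjusted coverage
#'
#' Equal-tailed interval at coverage `(1 - p_star)`: the `p_star/2` and
#' `1 - p_star/2` quantiles of the difference draws (linear interpolation).
#' With the step-up threshold 0.027 this is the 97.3% interval with bounds
#' at the 1.35th and 98.65th percentiles. The contrast is credible when 0
#' lies outside the interval. A highest-density variant is available via
#' `hdi = TRUE`.
#'
#' @param x An `hddm_contrast` or a numeric vector of difference draws.
#' @param p_star Adjusted significance threshold in (0, 1).
#' @param hdi Use the highest-density interval instead of the equal-tailed
#'   central interval?
#' @return The contrast with `lower`, `upper`, `coverage`, and `credible`
#'   filled in (for a numeric input, a list with those fields).
#' @export
adjusted_interval <- function(x, p_star, hdi = FALSE) {
  stopifnot(is.numeric(p_star), p_star > 0, p_star < 1)
  d <- if (inherits(x, "hddm_contrast")) x$draws else x
  if (hdi) {
    n <- length(d)
    ds <- sort(d)
    k <- max(1L, floor((1 - p_star) * n))
    widths <- ds[seq(k, n)] - ds[seq_len(n - k + 1L)]
    i <- which.min(widths)
    bounds <- c(ds[i], ds[i + k - 1L])
  } else {
    bounds <- unname(quantile(d, c(p_star / 2, 1 - p_star / 2), type = 7))
  }
  res <- list(lower = bounds[1], upper = bounds[2],
              coverage = 1 - p_star,
              credible = bounds[1] > 0 || bounds[2] < 0)
  if (inherits(x, "hddm_contrast")) {
    x[names(res)] <- res
    x
  } else {
    res
  }
}

#' Run a family of contrasts with one FDR correction
#'
#' Computes every contrast in the family, their two-sided posterior tail
#' probabilities, one Benjamini-Hochberg threshold over the whole family,
#' and then the adjusted central interval and credibility flag for every
#' member. When no contrast passes the step-up rule the intervals are
#' reported at the unadjusted level `q` and nothing is credible.
#'
#' @param fit An `hddm_fit`.
#' @param contrasts Named list; each element is either a character vector of
#'   two parameter names (simple contrast) or a list of two such pairs
#'   (nested contrast).
#' @param q FDR level (default 0.05).
#' @param hdi Passed to [adjusted_interval()].
#' @return A `contrast_family`: list of `hddm_contrast` objects plus the
#'   family `threshold` and a summary data frame.
#' @export
run_contrast_family <- function(fit, contrasts, q = 0.05, hdi = FALSE) {
  if (length(contrasts) == 0) stop("run_contrast_family: empty family", call. = FALSE)
  if (is.null(names(contrasts)) || any(names(contrasts) == "")) {
    names(contrasts) <- paste0("contrast_", seq_along(contrasts))
  }
  res <- lapply(names(contrasts), function(nm) {
    cc <- contrasts[[nm]]
    if (is.list(cc)) nested_contrast(fit, cc[[1]], cc[[2]], name = nm)
    else contrast(fit, cc[1], cc[2], name = nm)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  bh <- fdr_adjust(p, q)
  p_star <- if (bh$threshold > 0) bh$threshold else q
  res <- lapply(res, adjusted_interval, p_star = p_star, hdi = hdi)
  if (bh$threshold == 0) res <- lapply(res, function(r) { r$credible <- FALSE; r })
  summary <- data.frame(
    name = vapply(res, `[[`, character(1), "name"),
    median = vapply(res, `[[`, numeric(1), "median"),
    p = p,
    lower = vapply(res, `[[`, numeric(1), "lower"),
    upper = vapply(res, `[[`, numeric(1), "upper"),
    coverage = vapply(res, `[[`, numeric(1), "coverage"),
    credible = vapply(res, `[[`, logical(1), "credible"))
  structure(list(contrasts = res, threshold = bh$threshold, q = q,
                 summary = summary),
            class = "contrast_family")
}

#' @export
print.hddm_contrast <- function(x, ...) {
  cat(sprintf("Contrast %s: median %.4g, p %.4g", x$name, x$median, x$p))
  if (!is.na(x$coverage)) {
    cat(sprintf(", %.1f%% interval [%.4g, %.4g]%s", 100 * x$coverage,
                x$lower, x$upper, if (isTRUE(x$credible)) " *credible*" else ""))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.contrast_family <- function(x, ...) {
  cat(sprintf("Contrast family (m = %d, q = %g, BH threshold = %.4g)\n",
              nrow(x$summary), x$q, x$threshold))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Standard drift-rate contrast families
#'
#' `drift_group_contrasts()` builds the AUT - NT group differences in the
#' drift-rate cell means, one per (adaptor, morph) cell (8 for the full
#' design). `drift_adaptor_contrasts()` builds the androgynous - male
#' adaptor differences per group and morph (the aftereffect on the drift;
#' 8 for the full design). `drift_cell_contrasts()` concatenates both into
#' the 16-contrast drift family tested in one analysis run.
#'
#' @param fit An `hddm_fit`.
#' @return Named list usable as the `contrasts` argument of
#'   [run_contrast_family()].
#' @export
drift_group_contrasts <- function(fit) {
  stopifnot(length(fit$groups) == 2)
  out <- list()
  for (ad in fit$adaptors) for (m in fit$morphs) {
    nm <- sprintf("v[%s,%s] %s-%s", ad, m, fit$groups[1], fit$groups[2])
    out[[nm]] <- c(cell_name("mu_v", fit$groups[1], ad, m),
                   cell_name("mu_v", fit$groups[2], ad, m))
  }
  out
}

#' @rdname drift_group_contrasts
#' @export
drift_adaptor_contrasts <- function(fit) {
  stopifnot(length(fit$adaptors) == 2)
  out <- list()
  for (g in fit$groups) for (m in fit$morphs) {
    nm <- sprintf("v[%s,%s] %s-%s", g, m, fit$adaptors[1], fit$adaptors[2])
    out[[nm]] <- c(cell_name("mu_v", g, fit$adaptors[1], m),
                   cell_name("mu_v", g, fit$adaptors[2], m))
  }
  out
}

#' @rdname drift_group_contrasts
#' @export
drift_cell_contrasts <- function(fit) {
  c(drift_group_contrasts(fit), drift_adaptor_contrasts(fit))
}
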