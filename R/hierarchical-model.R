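# Hierarchical drift diffusion model: parameter-cell layout, joint density,
# and a Metropolis-within-Gibbs posterior sampler.
#
# Structure: every participant p has a boundary a_p, non-decision time t_p,
# one start point b_{p,adaptor}, and one drift v_{p,adaptor,morph}. Each
# subject-level parameter is drawn from the normal cell of its group
# (mean mu, precision tau); trials contribute Wiener first-passage terms.
# Group-level mu cells get broad truncated-normal hyperpriors, tau cells
# gamma hyperpriors. The mu and tau conditionals are conjugate and are
# Gibbs-sampled; subject-level parameters move by adaptive random-walk
# Metropolis, blocked so that each proposal only touches the trials it
# affects.

#' Build the hierarchical model specification
#'
#' Enumerates the group-level parameter cells and maps every trial to its
#' participant and cells. With `g` groups, `A` adaptors, and `M` morph
#' levels the group-level cell count is `g + g + g*A + g*A*M` (one `a` and
#' `t` per group, one `b` per group x adaptor, one `v` per group x adaptor x
#' morph).
#'
#' @param trials Trial data frame with the exclusion chain applied; omitted
#'   trials are not allowed.
#' @return An `hddm_spec` list with the factor levels, participant table,
#'   0-based trial index arrays, signed reaction times in seconds, and the
#'   group-level cell names.
#' @export
#' @examples
#' sim <- generate_experiment(fae_config(n_per_group = c(AUT = 2, NT = 2),
#'                                       trials_per_morph = 8,
#'                                       omission_rate = 0))
#' spec <- build_model(sim$trials)
#' spec$n_cells  # 24 for the 2 x 2 x 4 design
build_model <- function(trials) {
  trials <- trials[trials$response != "omitted", , drop = FALSE]
  if (nrow(trials) == 0) stop("build_model: no responded trials", call. = FALSE)
  groups <- sort(unique(trials$group))
  adaptors <- sort(unique(trials$adaptor))
  morphs <- sort(unique(trials$morph_pct))
  G <- length(groups); A <- length(adaptors); M <- length(morphs)
  for (fac in list(trials$group, trials$adaptor, trials$morph_pct)) {
    if (any(table(fac) == 0)) stop("build_model: empty factor level", call. = FALSE)
  }
  parts <- unique(trials[, c("participant_id", "group")])
  parts <- parts[order(parts$participant_id), ]
  rownames(parts) <- NULL
  S <- nrow(parts)

  subj <- match(trials$participant_id, parts$participant_id)
  ad <- match(trials$adaptor, adaptors)
  mo <- match(trials$morph_pct, morphs)
  vcell <- (ad - 1L) * M + mo
  rt_signed <- ifelse(trials$response == UPPER_RESPONSE, 1, -1) *
    trials$rt_ms / 1000

  cellnames <- list(
    a = groups, t = groups,
    b = as.vector(outer(groups, adaptors, paste, sep = ",")),
    v = as.vector(outer(groups, as.vector(outer(adaptors, morphs, paste,
                                                sep = ",")), paste, sep = ",")))
  structure(list(groups = groups, adaptors = adaptors, morphs = morphs,
                 participants = parts,
                 subj_group = match(parts$group, groups),
                 subj = subj - 1L, vcell0 = vcell - 1L,
                 ad_idx = ad, vcell = vcell, rt_signed = rt_signed,
                 S = S, G = G, A = A, M = M, K = A * M,
                 n_cells = as.integer(2 * G + G * A + G * A * M)),
            class = "hddm_spec")
}

#' @export
print.hddm_spec <- function(x, ...) {
  cat(sprintf("hDDM spec: %d participants, %d trials, %d group-level cells\n",
              x$S, length(x$rt_signed), x$n_cells))
  cat(sprintf("  groups: %s; adaptors: %s; morphs: %s\n",
              paste(x$groups, collapse = "/"),
              paste(x$adaptors, collapse = "/"),
              paste(x$morphs, collapse = "/")))
  invisible(x)
}

#' Hyperpriors for the group-level cells
#'
#' Every cell mean mu gets a broad normal prior truncated to the parameter's
#' domain; every cell precision tau gets a gamma prior (defaults: mean 1,
#' variance 10). All settings are plain configuration values.
#'
#' @param mu_a,mu_t,mu_b,mu_v Lists with `location`, `scale`, `lower`,
#'   `upper` for the respective mean cells.
#' @param tau List with gamma `shape` and `rate` shared by all precision
#'   cells.
#' @return An `hddm_hyperpriors` list.
#' @export
default_hyperpriors <- function(
    mu_a = list(location = 1.5, scale = 2, lower = 0, upper = Inf),
    mu_t = list(location = 0.3, scale = 1, lower = 0, upper = Inf),
    mu_b = list(location = 0.5, scale = 1, lower = 0, upper = 1),
    mu_v = list(location = 0, scale = 3, lower = -Inf, upper = Inf),
    tau = list(shape = 0.1, rate = 0.1)) {
  structure(list(mu = list(a = mu_a, t = mu_t, b = mu_b, v = mu_v), tau = tau),
            class = "hddm_hyperpriors")
}

#' Sampler configuration
#'
#' Defaults follow the reference analysis: two independent chains of 20,000
#' iterations each with the first 15,000 discarded as burn-in, leaving 5,000
#' retained draws per chain. Scaled-down values are ordinary configuration.
#'
#' @param n_chains Number of independent chains.
#' @param n_iterations Iterations per chain.
#' @param n_burn_in Burn-in iterations discarded per chain.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param adapt_interval Iterations between step-size adaptations (burn-in
#'   only).
#' @param rhat_threshold Convergence flag threshold for split R-hat.
#' @return An `hddm_sampler_config` list with `n_retained` filled in.
#' @export
sampler_config <- function(n_chains = 2, n_iterations = 20000,
                           n_burn_in = 15000, seed = 1,
                           adapt_interval = 50, rhat_threshold = 1.01) {
  stopifnot(n_chains >= 1, n_burn_in >= 0, n_iterations > n_burn_in)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burn_in = as.integer(n_burn_in),
                 n_retained = as.integer(n_iterations - n_burn_in),
                 seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 rhat_threshold = rhat_threshold),
            class = "hddm_sampler_config")
}

dtruncnorm_log <- function(x, location, scale, lower, upper) {
  ifelse(x < lower | x > upper, -Inf,
         dnorm(x, location, scale, log = TRUE) -
           log(pnorm(upper, location, scale) - pnorm(lower, location, scale)))
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# structured parameter values: list(mu = list(a = G-vec, t = G-vec,
# b = G x A, v = G x K), tau = same shapes, a = S-vec, t = S-vec,
# b = S x A, v = S x K)
per_trial_b <- function(spec, values) values$b[cbind(spec$subj + 1L, spec$ad_idx)]
per_trial_v <- function(spec, values) values$v[cbind(spec$subj + 1L, spec$vcell)]

#' Joint log density of the hierarchical model
#'
#' Sum of the trial log likelihood (Wiener first-passage terms, upper
#' boundary for male responses), the subject-level normal log densities
#' given their group cells, and the hyperprior terms. Returns `-Inf` for
#' out-of-domain parameter values.
#'
#' @param spec An `hddm_spec`.
#' @param hyper An `hddm_hyperpriors`.
#' @param values Structured parameter values (see Details in the vignette):
#'   `mu` and `tau` lists with `a`/`t` group vectors and `b`/`v` group x
#'   cell matrices, plus subject-level `a`, `t` vectors and `b`, `v`
#'   matrices.
#' @param likelihood `"wfpt"`, or `"gaussian"` (unit-variance normal on the
#'   signed rt, a hook used by conjugate-reduction tests).
#' @return Scalar log density.
#' @export
log_joint <- function(spec, hyper, values, likelihood = c("wfpt", "gaussian")) {
  likelihood <- match.arg(likelihood)
  if (any(values$a <= 0) || any(values$t < 0) ||
      any(values$b <= 0) || any(values$b >= 1) ||
      any(unlist(values$tau) <= 0)) {
    return(-Inf)
  }
  lik <- if (likelihood == "wfpt") 0L else 1L
  L <- cell_loglik_cpp(spec$rt_signed, spec$subj, spec$vcell0, spec$S, spec$K,
                       values$a, values$t, per_trial_b(spec, values),
                       per_trial_v(spec, values), lik)
  ll <- sum(L)
  if (!is.finite(ll)) return(-Inf)

  g <- spec$subj_group
  lp <- sum(dnorm(values$a, values$mu$a[g], 1 / sqrt(values$tau$a[g]), log = TRUE)) +
    sum(dnorm(values$t, values$mu$t[g], 1 / sqrt(values$tau$t[g]), log = TRUE)) +
    sum(dnorm(values$b, values$mu$b[g, , drop = FALSE],
              1 / sqrt(values$tau$b[g, , drop = FALSE]), log = TRUE)) +
    sum(dnorm(values$v, values$mu$v[g, , drop = FALSE],
              1 / sqrt(values$tau$v[g, , drop = FALSE]), log = TRUE))

  hp <- 0
  for (ty in c("a", "t", "b", "v")) {
    h <- hyper$mu[[ty]]
    hp <- hp + sum(dtruncnorm_log(values$mu[[ty]], h$location, h$scale,
                                  h$lower, h$upper)) +
      sum(stats::dgamma(values$tau[[ty]], hyper$tau$shape, hyper$tau$rate,
                        log = TRUE))
  }
  ll + lp + hp
}

# data-driven initial values, jittered per chain
init_values <- function(spec, chain) {
  S <- spec$S; A <- spec$A; K <- spec$K; G <- spec$G
  min_rt <- tapply(abs(spec$rt_signed), spec$subj, min)
  jit <- function(x, s) x + rnorm(length(x), 0, s)

  a <- pmax(jit(rep(1.5, S), 0.1), 0.3)
  t0 <- pmin(pmax(jit(0.75 * min_rt, 0.02), 0.01), min_rt * 0.95)
  b <- matrix(pmin(pmax(jit(rep(0.5, S * A), 0.03), 0.2), 0.8), S, A)
  p_male <- matrix(0.5, S, K)
  agg <- tapply(spec$rt_signed > 0,
                list(factor(spec$subj, 0:(S - 1)), factor(spec$vcell, 1:K)),
                mean)
  p_male[!is.na(agg)] <- agg[!is.na(agg)]
  v <- matrix(jit(stats::qlogis(pmin(pmax(p_male, 0.08), 0.92)) / 1.5, 0.15), S, K)

  g <- spec$subj_group
  mu <- list(a = as.numeric(tapply(a, g, mean)),
             t = as.numeric(tapply(t0, g, mean)),
             b = apply(b, 2, function(x) tapply(x, g, mean)),
             v = apply(v, 2, function(x) tapply(x, g, mean)))
  mu$b <- matrix(mu$b, G, A); mu$v <- matrix(mu$v, G, K)
  tau <- list(a = rep(2, G), t = rep(20, G),
              b = matrix(20, G, A), v = matrix(2, G, K))
  list(mu = mu, tau = tau, a = a, t = t0, b = b, v = v, min_rt = min_rt)
}

# flattened parameter names, in storage order; the v-cell index is
# adaptor-major (cell k = (adaptor - 1) * M + morph), matching the S x K
# and G x K matrices flattened column-major
param_names <- function(spec) {
  gn <- spec$groups; adn <- spec$adaptors; mon <- spec$morphs
  pid <- spec$participants$participant_id
  vck <- paste(rep(adn, each = length(mon)), rep(mon, length(adn)), sep = ",")
  bcell <- as.vector(outer(gn, adn, function(g, a) paste0(g, ",", a)))
  vcell <- as.vector(outer(gn, vck, function(g, c) paste0(g, ",", c)))
  c(paste0("mu_a[", gn, "]"), paste0("mu_t[", gn, "]"),
    paste0("mu_b[", bcell, "]"), paste0("mu_v[", vcell, "]"),
    paste0("tau_a[", gn, "]"), paste0("tau_t[", gn, "]"),
    paste0("tau_b[", bcell, "]"), paste0("tau_v[", vcell, "]"),
    paste0("a[", pid, "]"), paste0("t[", pid, "]"),
    as.vector(outer(pid, adn, function(p, a) paste0("b[", p, ",", a, "]"))),
    as.vector(outer(pid, vck, function(p, c) paste0("v[", p, ",", c, "]"))))
}

flatten_values <- function(values) {
  c(values$mu$a, values$mu$t, as.vector(values$mu$b), as.vector(values$mu$v),
    values$tau$a, values$tau$t, as.vector(values$tau$b), as.vector(values$tau$v),
    values$a, values$t, as.vector(values$b), as.vector(values$v))
}

#' Group-level cell parameter name
#'
#' Convenience builder for the flattened parameter names used in
#' `hddm_fit` draws, e.g. `cell_name("mu_v", "AUT", "male", 80)`.
#'
#' @param what Parameter family (`"mu_a"`, `"tau_v"`, ...).
#' @param group,adaptor,morph Cell labels (only those the family needs).
#' @return Character parameter name.
#' @export
cell_name <- function(what, group, adaptor = NULL, morph = NULL) {
  lab <- paste(c(group, adaptor, morph), collapse = ",")
  paste0(what, "[", lab, "]")
}

run_chain <- function(spec, hyper, config, chain, lik, progress = FALSE) {
  set.seed(config$seed + chain - 1L)
  S <- spec$S; A <- spec$A; M <- spec$M; K <- spec$K; G <- spec$G
  v <- init_values(spec, chain)
  min_rt <- v$min_rt
  g <- spec$subj_group

  # per-trial current parameter lookups
  b_tr <- per_trial_b(spec, v)
  v_tr <- per_trial_v(spec, v)

  # trial subsets per adaptor and per v cell
  idx_ad <- lapply(seq_len(A), function(a) which(spec$ad_idx == a))
  idx_vc <- lapply(seq_len(K), function(k) which(spec$vcell == k))
  cols_ad <- lapply(seq_len(A), function(a) (a - 1L) * M + seq_len(M))

  cl <- function(idx, a_s, t_s, b_t, v_t) {
    cell_loglik_cpp(spec$rt_signed[idx], spec$subj[idx], spec$vcell0[idx],
                    S, K, a_s, t_s, b_t, v_t, lik)
  }
  all_idx <- seq_along(spec$rt_signed)
  curL <- cl(all_idx, v$a, v$t, b_tr, v_tr)

  step <- list(a = rep(0.15, S), t = rep(0.03, S),
               b = matrix(0.05, S, A), v = matrix(0.4, S, K))
  acc <- lapply(step, function(x) x * 0)
  n_prop <- 0L

  n_ret <- config$n_retained
  P <- length(param_names(spec))
  draws <- matrix(NA_real_, n_ret, P)

  hmu <- hyper$mu; htau <- hyper$tau
  sd_of <- function(tau) 1 / sqrt(tau)

  for (iter in seq_len(config$n_iterations)) {
    ## --- subject-level Metropolis updates -------------------------------
    # boundary a
    prop <- v$a + step$a * rnorm(S)
    ok <- prop > 0
    propL <- cl(all_idx, ifelse(ok, prop, v$a), v$t, b_tr, v_tr)
    logr <- rowSums(propL) - rowSums(curL) +
      dnorm(prop, v$mu$a[g], sd_of(v$tau$a[g]), log = TRUE) -
      dnorm(v$a, v$mu$a[g], sd_of(v$tau$a[g]), log = TRUE)
    accept <- ok & is.finite(logr) & log(runif(S)) < logr
    v$a[accept] <- prop[accept]
    curL[accept, ] <- propL[accept, , drop = FALSE]
    acc$a <- acc$a + accept

    # non-decision time t
    prop <- v$t + step$t * rnorm(S)
    ok <- prop >= 0 & prop < min_rt
    propL <- cl(all_idx, v$a, ifelse(ok, prop, v$t), b_tr, v_tr)
    logr <- rowSums(propL) - rowSums(curL) +
      dnorm(prop, v$mu$t[g], sd_of(v$tau$t[g]), log = TRUE) -
      dnorm(v$t, v$mu$t[g], sd_of(v$tau$t[g]), log = TRUE)
    accept <- ok & is.finite(logr) & log(runif(S)) < logr
    v$t[accept] <- prop[accept]
    curL[accept, ] <- propL[accept, , drop = FALSE]
    acc$t <- acc$t + accept

    # start point b, one adaptor at a time
    for (a_i in seq_len(A)) {
      idx <- idx_ad[[a_i]]; cols <- cols_ad[[a_i]]
      prop <- v$b[, a_i] + step$b[, a_i] * rnorm(S)
      ok <- prop > 0 & prop < 1
      bp <- ifelse(ok, prop, v$b[, a_i])[spec$subj[idx] + 1L]
      propL <- cl(idx, v$a, v$t, bp, v_tr[idx])
      logr <- rowSums(propL[, cols, drop = FALSE]) -
        rowSums(curL[, cols, drop = FALSE]) +
        dnorm(prop, v$mu$b[g, a_i], sd_of(v$tau$b[g, a_i]), log = TRUE) -
        dnorm(v$b[, a_i], v$mu$b[g, a_i], sd_of(v$tau$b[g, a_i]), log = TRUE)
      accept <- ok & is.finite(logr) & log(runif(S)) < logr
      v$b[accept, a_i] <- prop[accept]
      curL[accept, cols] <- propL[accept, cols, drop = FALSE]
      acc$b[, a_i] <- acc$b[, a_i] + accept
      if (any(accept)) b_tr <- per_trial_b(spec, v)
    }

    # drift v, one (adaptor, morph) cell at a time
    for (k in seq_len(K)) {
      idx <- idx_vc[[k]]
      prop <- v$v[, k] + step$v[, k] * rnorm(S)
      vp <- prop[spec$subj[idx] + 1L]
      propL <- cl(idx, v$a, v$t, b_tr[idx], vp)
      logr <- propL[, k] - curL[, k] +
        dnorm(prop, v$mu$v[g, k], sd_of(v$tau$v[g, k]), log = TRUE) -
        dnorm(v$v[, k], v$mu$v[g, k], sd_of(v$tau$v[g, k]), log = TRUE)
      accept <- is.finite(logr) & log(runif(S)) < logr
      v$v[accept, k] <- prop[accept]
      curL[accept, k] <- propL[accept, k]
      acc$v[, k] <- acc$v[, k] + accept
      if (any(accept)) v_tr[idx] <- v$v[cbind(spec$subj[idx] + 1L, k)]
    }
    n_prop <- n_prop + 1L

    ## --- conjugate Gibbs updates for the group-level cells --------------
    gibbs_cell <- function(x_by_g, mu_vec, tau_vec, hm) {
      for (gi in seq_len(G)) {
        x <- x_by_g[[gi]]; n <- length(x)
        prec0 <- 1 / hm$scale^2
        prec <- prec0 + n * tau_vec[gi]
        m <- (hm$location * prec0 + tau_vec[gi] * sum(x)) / prec
        mu_vec[gi] <- rtruncnorm1(1, m, 1 / sqrt(prec), hm$lower, hm$upper)
        tau_vec[gi] <- rgamma(1, htau$shape + n / 2,
                              htau$rate + sum((x - mu_vec[gi])^2) / 2)
      }
      list(mu = mu_vec, tau = tau_vec)
    }
    xa <- split(v$a, g); xt <- split(v$t, g)
    up <- gibbs_cell(xa, v$mu$a, v$tau$a, hmu$a)
    v$mu$a <- up$mu; v$tau$a <- up$tau
    up <- gibbs_cell(xt, v$mu$t, v$tau$t, hmu$t)
    v$mu$t <- up$mu; v$tau$t <- up$tau
    for (a_i in seq_len(A)) {
      up <- gibbs_cell(split(v$b[, a_i], g), v$mu$b[, a_i], v$tau$b[, a_i], hmu$b)
      v$mu$b[, a_i] <- up$mu; v$tau$b[, a_i] <- up$tau
    }
    for (k in seq_len(K)) {
      up <- gibbs_cell(split(v$v[, k], g), v$mu$v[, k], v$tau$v[, k], hmu$v)
      v$mu$v[, k] <- up$mu; v$tau$v[, k] <- up$tau
    }

    ## --- step-size adaptation during burn-in ----------------------------
    if (iter <= config$n_burn_in && iter %% config$adapt_interval == 0L) {
      tune <- function(st, ac) st * exp((ac / n_prop - 0.44))
      step$a <- tune(step$a, acc$a); step$t <- pmax(tune(step$t, acc$t), 1e-4)
      step$b <- tune(step$b, acc$b); step$v <- tune(step$v, acc$v)
      acc <- lapply(acc, function(x) x * 0)
      n_prop <- 0L
    }

    if (iter > config$n_burn_in) {
      draws[iter - config$n_burn_in, ] <- flatten_values(v)
    }
  }
  draws
}

#' Sample the posterior of the hierarchical model
#'
#' Runs independent Markov chains (Metropolis-within-Gibbs: conjugate Gibbs
#' draws for all group-level means and precisions, adaptive random-walk
#' Metropolis for subject-level parameters), retains the post-burn-in
#' draws, and attaches split-chain R-hat values for every parameter. If any
#' R-hat meets or exceeds the configured threshold a warning (class
#' `hddm_convergence_warning`) is raised, but the samples and diagnostics
#' are returned regardless.
#'
#' @param spec An `hddm_spec` from [build_model()].
#' @param hyper An `hddm_hyperpriors`.
#' @param config An `hddm_sampler_config`.
#' @param likelihood `"wfpt"` or the `"gaussian"` test hook (see
#'   [log_joint()]).
#' @return An `hddm_fit`: list with `draws` (retained-iterations x chains x
#'   parameters array, named), `rhat` (per parameter), `converged`, `spec`
#'   metadata, and `config`.
#' @export
sample_posterior <- function(spec, hyper = default_hyperpriors(),
                             config = sampler_config(),
                             likelihood = c("wfpt", "gaussian")) {
  likelihood <- match.arg(likelihood)
  lik <- if (likelihood == "wfpt") 0L else 1L
  pn <- param_names(spec)
  draws <- array(NA_real_, c(config$n_retained, config$n_chains, length(pn)),
                 dimnames = list(NULL, NULL, pn))
  for (ch in seq_len(config$n_chains)) {
    draws[, ch, ] <- run_chain(spec, hyper, config, ch, lik)
  }
  rh <- if (config$n_chains >= 2) apply(draws, 3, function(m) rhat(m)) else
    setNames(rep(NA_real_, length(pn)), pn)
  fit <- structure(list(draws = draws, rhat = rh,
                        converged = if (all(is.na(rh))) NA else
                          max(rh) < config$rhat_threshold,
                        participants = spec$participants,
                        groups = spec$groups, adaptors = spec$adaptors,
                        morphs = spec$morphs, config = config,
                        likelihood = likelihood),
                   class = "hddm_fit")
  if (isFALSE(fit$converged)) {
    warning(warningCondition(
      sprintf("sample_posterior: max split R-hat %.4f >= %.3f; treat estimates with caution",
              max(rh), config$rhat_threshold),
      class = "hddm_convergence_warning"))
  }
  fit
}

#' @export
print.hddm_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("hDDM fit: %d chains x %d retained draws, %d parameters\n",
              d[2], d[1], d[3]))
  cat(sprintf("  max split R-hat: %.4f (%s)\n", max(x$rhat),
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat on chains split in half (so within-chain drift is
#' detected as well). Values near 1 indicate convergence.
#'
#' @param draws Matrix of draws (iterations x chains), with at least 2
#'   chains of at least 4 draws, or a list of equal-length chain vectors.
#' @return Scalar R-hat.
#' @export
#' @examples
#' set.seed(1)
#' rhat(cbind(rnorm(1000), rnorm(1000)))
rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("rhat: need at least two chains", call. = FALSE)
  if (nrow(draws) < 4) stop("rhat: need at least four draws per chain", call. = FALSE)
  n2 <- floor(nrow(draws) / 2)
  split <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(n2), j], draws[n2 + seq_len(n2), j])
  }))
  m <- ncol(split); n <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
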