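# Diffusion-model kernel: first-passage density, choice probability, and
# trial simulators. Diffusion coefficient is fixed at 1 throughout; all
# parameters are interpreted on that scale.

#' Drift diffusion model parameters
#'
#' Bundle of the four parameters of a single subject-condition diffusion
#' process: boundary separation `a` (evidence units), non-decision time `t`
#' (seconds), relative start point `b` (fraction of `a`, toward the upper
#' "male" boundary), and drift rate `v` (evidence units per second, positive
#' toward "male"). The diffusion coefficient is fixed at 1.
#'
#' @param a Boundary separation, must be > 0.
#' @param t Non-decision time in seconds, must be >= 0.
#' @param b Relative start point in (0, 1).
#' @param v Drift rate (unbounded).
#' @return An object of class `ddm_params`.
#' @export
#' @examples
#' ddm_params(a = 1.4, t = 0.3, b = 0.5, v = 1)
ddm_params <- function(a, t, b, v) {
  p <- structure(list(a = a, t = t, b = b, v = v), class = "ddm_params")
  validate_ddm_params(p)
  p
}

validate_ddm_params <- function(p) {
  stopifnot(is.list(p))
  for (f in c("a", "t", "b", "v")) {
    if (is.null(p[[f]]) || !is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]])) {
      stop("ddm_params: field '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  if (p$a <= 0) stop("ddm_params: boundary separation a must be > 0", call. = FALSE)
  if (p$t < 0) stop("ddm_params: non-decision time t must be >= 0", call. = FALSE)
  if (p$b <= 0 || p$b >= 1) stop("ddm_params: start point b must lie in (0, 1)", call. = FALSE)
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: a = %.4g, t = %.4g s, b = %.4g, v = %.4g\n",
              x$a, x$t, x$b, x$v))
  invisible(x)
}

#' Wiener first-passage-time density
#'
#' Defective density of absorbing at the given boundary at reaction time
#' `rt` (seconds, including non-decision time). Integrating over `rt` for
#' both boundaries sums to one. Evaluated through the two complementary
#' series expansions (small-time / large-time) with an automatic switch at a
#' truncation error of 1e-10 per evaluation.
#'
#' @param rt Vector of reaction times in seconds; all must be > 0. Values at
#'   or below the non-decision time have density 0.
#' @param boundary `"male"` (upper) or `"female"` (lower).
#' @param params A [ddm_params] object.
#' @param log Return the log density?
#' @return Numeric vector of densities (per second).
#' @export
#' @examples
#' p <- ddm_params(1.5, 0.3, 0.5, 1)
#' wfpt_density(seq(0.4, 1.2, by = 0.2), "male", p)
wfpt_density <- function(rt, boundary = c(UPPER_RESPONSE, LOWER_RESPONSE),
                         params, log = FALSE) {
  boundary <- match.arg(boundary)
  validate_ddm_params(params)
  if (!is.numeric(rt) || any(!is.finite(rt)) || any(rt <= 0)) {
    stop("wfpt_density: rt must be finite and > 0", call. = FALSE)
  }
  s <- if (boundary == UPPER_RESPONSE) 1 else -1
  ld <- wfpt_logdens_cpp(s * rt, params$a, params$t, params$b, params$v)
  if (log) ld else exp(ld)
}

#' Signed-reaction-time log density
#'
#' Log of the Wiener first-passage density at signed reaction times
#' (positive = male/upper response, negative = female/lower response).
#'
#' @param rt_signed Vector of signed reaction times in seconds (non-zero).
#' @param params A [ddm_params] object.
#' @return Vector of log densities (`-Inf` where `|rt| <= t`).
#' @export
wfpt_logdens_signed <- function(rt_signed, params) {
  validate_ddm_params(params)
  if (any(rt_signed == 0) || any(!is.finite(rt_signed))) {
    stop("wfpt_logdens_signed: signed rt must be finite and non-zero", call. = FALSE)
  }
  wfpt_logdens_cpp(rt_signed, params$a, params$t, params$b, params$v)
}

#' Probability of an upper-boundary (male) response
#'
#' Closed-form absorption probability at the upper boundary for a Wiener
#' process with absorbing barriers at 0 and `a`, start `b * a`, drift `v`,
#' diffusion coefficient 1. The drift-free limit equals `b` exactly.
#'
#' @param params A [ddm_params] object.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' choice_probability(ddm_params(2, 0.3, 0.5, 1))
choice_probability <- function(params) {
  validate_ddm_params(params)
  v <- params$v
  if (abs(v * params$a) < 1e-12) return(params$b)
  # (1 - exp(-2 v a b)) / (1 - exp(-2 v a)), written via expm1 for stability
  p <- expm1(-2 * v * params$a * params$b) / expm1(-2 * v * params$a)
  min(max(p, 0), 1)
}

# Grid representation of the two defective CDFs, used by the inverse-CDF
# sampler and reusable across trials that share parameters. The grid is
# extended by doubling until the total absorbed mass reaches 1 - 1e-8.
wfpt_cdf_grid <- function(params, n_grid = 8192L, tail_tol = 1e-8, u_cap = 60) {
  a <- params$a; t0 <- params$t; b <- params$b; v <- params$v
  build <- function(u_max) {
    u <- seq(0, u_max, length.out = n_grid + 1L)[-1L]
    f_up <- exp(wfpt_logdens_cpp(t0 + u, a, t0, b, v))
    f_lo <- exp(wfpt_logdens_cpp(-(t0 + u), a, t0, b, v))
    du <- u[2L] - u[1L]
    # trapezoid with an implicit zero at u = 0
    cdf_up <- cumsum((c(0, head(f_up, -1L)) + f_up) / 2) * du
    cdf_lo <- cumsum((c(0, head(f_lo, -1L)) + f_lo) / 2) * du
    list(u = u, cdf_up = cdf_up, cdf_lo = cdf_lo,
         p_up = cdf_up[n_grid], p_lo = cdf_lo[n_grid], t0 = t0,
         total = cdf_up[n_grid] + cdf_lo[n_grid])
  }
  u_max <- max(4 * a^2, 1)
  g <- build(u_max)
  # extend for heavy tails
  while (g$total < 1 - tail_tol && u_max < u_cap) {
    u_max <- u_max * 2
    g <- build(u_max)
  }
  # contract when the mass is concentrated far below the grid resolution
  # (tiny boundaries or extreme drifts); keep contracting only while it helps
  while (g$total < 0.9 && u_max > 1e-4) {
    g2 <- build(u_max / 8)
    if (!is.finite(g2$total) || g2$total <= g$total) break
    u_max <- u_max / 8
    g <- g2
  }
  if (!is.finite(g$total) || g$total <= 0) {
    stop("wfpt_cdf_grid: first-passage mass not representable for a = ",
         signif(a, 3), ", v = ", signif(v, 3), call. = FALSE)
  }
  g
}

# draw n trials from a prepared grid; uses R's RNG
sample_from_grid <- function(grid, n) {
  p_up <- grid$p_up / (grid$p_up + grid$p_lo)
  x <- runif(n)
  upper <- x < p_up
  rt <- numeric(n)
  if (any(upper)) {
    targ <- runif(sum(upper)) * grid$p_up
    rt[upper] <- grid$t0 + approx(grid$cdf_up, grid$u, xout = targ,
                                  ties = "ordered", rule = 2)$y
  }
  if (any(!upper)) {
    targ <- runif(sum(!upper)) * grid$p_lo
    rt[!upper] <- grid$t0 + approx(grid$cdf_lo, grid$u, xout = targ,
                                   ties = "ordered", rule = 2)$y
  }
  data.frame(response = ifelse(upper, UPPER_RESPONSE, LOWER_RESPONSE),
             rt = rt, stringsAsFactors = FALSE)
}

#' Simulate diffusion-model trials
#'
#' Draws choices and reaction times from the Wiener diffusion process. The
#' default method samples exactly from the first-passage distribution by
#' numerical inversion of the (grid-tabulated) defective CDFs; an
#' Euler-Maruyama path simulator is available as `method = "euler"`.
#' Randomness comes from R's global RNG, so results are reproducible with
#' [set.seed()].
#'
#' @param n Number of trials.
#' @param params A [ddm_params] object.
#' @param method `"inverse"` (exact inverse-CDF, default) or `"euler"`.
#' @param dt Euler step size in seconds (used by `method = "euler"`), > 0.
#' @return Data frame with columns `response` (`"male"`/`"female"`) and `rt`
#'   (seconds, always `>= t`).
#' @export
#' @examples
#' set.seed(1)
#' simulate_ddm(5, ddm_params(1.5, 0.3, 0.5, 1))
simulate_ddm <- function(n, params, method = c("inverse", "euler"), dt = 1e-4) {
  method <- match.arg(method)
  validate_ddm_params(params)
  stopifnot(n >= 0)
  if (n == 0) {
    return(data.frame(response = character(0), rt = numeric(0)))
  }
  if (method == "euler") {
    if (!is.numeric(dt) || dt <= 0) {
      stop("simulate_ddm: step size dt must be > 0", call. = FALSE)
    }
    m <- sim_ddm_euler_cpp(as.integer(n), params$a, params$t, params$b,
                           params$v, dt, 60)
    return(data.frame(response = ifelse(m[, 1] == 1, UPPER_RESPONSE, LOWER_RESPONSE),
                      rt = m[, 2], stringsAsFactors = FALSE))
  }
  sample_from_grid(wfpt_cdf_grid(params), n)
}

#' Simulate a single trial
#'
#' @param params A [ddm_params] object.
#' @param method,dt Passed to [simulate_ddm()].
#' @return One-row data frame with `response` and `rt` (seconds).
#' @export
simulate_trial <- function(params, method = c("inverse", "euler"), dt = 1e-4) {
  simulate_ddm(1L, params, method = method, dt = dt)
}
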