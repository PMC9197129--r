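#' Parameter set for the two-boundary Wiener diffusion process
#'
#' Bundles the parameters of a two-boundary drift-diffusion (Wiener) process
#' on the unit-diffusion scale: boundary separation `a`, relative starting
#' point `z` (fraction of `a`), non-decision time `t0` in seconds, mean drift
#' rate `v` (signed; negative values drift toward the lower boundary), and
#' across-trial drift standard deviation `sv`.  Each trial's drift is drawn
#' from `N(v, sv^2)`; `sv = 0` gives the plain Wiener process.  Across-trial
#' variability in starting point and non-decision time is not modelled.
#'
#' @param a boundary separation, `> 0` (evidence units).
#' @param z relative starting point, strictly between 0 and 1.
#' @param t0 non-decision time in seconds, `>= 0`.
#' @param v mean drift rate (evidence/second, signed).
#' @param sv across-trial drift standard deviation, `>= 0`.
#'
#' @return An object of class `ddm_params` (a named list).
#' @examples
#' p <- ddm_params(a = 2, z = 0.5, t0 = 0.3, v = -2)
#' wiener_choice_prob("lower", p)
#' @export
ddm_params <- function(a, z = 0.5, t0 = 0, v = 0, sv = 0) {
  for (nm in c("a", "z", "t0", "v", "sv")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (a <= 0) stop("boundary separation 'a' must be > 0", call. = FALSE)
  if (z <= 0 || z >= 1) stop("relative start 'z' must lie in (0, 1)", call. = FALSE)
  if (t0 < 0) stop("non-decision time 't0' must be >= 0", call. = FALSE)
  if (sv < 0) stop("drift variability 'sv' must be >= 0", call. = FALSE)
  structure(list(a = a, z = z, t0 = t0, v = v, sv = sv),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Wiener diffusion parameters (diffusion coefficient 1):\n")
  cat(sprintf("  a = %.4g, z = %.4g, t0 = %.4g s, v = %.4g, sv = %.4g\n",
              x$a, x$z, x$t0, x$v, x$sv))
  invisible(x)
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(ddm_params(a = x$a, z = x$z %||% 0.5, t0 = x$t0 %||% 0,
                      v = x$v %||% 0, sv = x$sv %||% 0))
  }
  stop("cannot interpret 'params'; use ddm_params()", call. = FALSE)
}

check_boundary <- function(boundary) {
  match.arg(boundary, c("lower", "upper"))
}

#' Defective first-passage-time density of the Wiener process
#'
#' Density (1/seconds) of absorbing at the given boundary at total response
#' time `t` (non-decision time included: the density is zero for
#' `t <= t0`).  The lower boundary is the ingroup-compliant response in this
#' package's coding.  With `sv > 0` the density is marginalised analytically
#' over the Gaussian across-trial drift distribution.  Evaluation switches
#' between the small-time and large-time series expansions with a truncation
#' error bound of `eps` per evaluation.
#'
#' @param t vector of total response times in seconds, all `> 0`.
#' @param boundary `"lower"` or `"upper"`.
#' @param params a [ddm_params] object (or coercible list).
#' @param eps series truncation error bound.
#'
#' @return Numeric vector of non-negative densities.
#' @examples
#' p <- ddm_params(a = 2, z = 0.5, t0 = 0.3, v = -2)
#' wiener_pdf(c(0.4, 0.6, 1), "lower", p)
#' @export
wiener_pdf <- function(t, boundary = c("lower", "upper"), params,
                       eps = 1e-7) {
  boundary <- match.arg(boundary)
  params <- as_ddm_params(params)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be positive and finite", call. = FALSE)
  wiener_pdf_cpp(t, params$a, params$z, params$t0, params$v, params$sv,
                 boundary == "lower", eps)
}

# closed-form absorption probability at the lower boundary for a fixed drift
# (unit diffusion); stable for |v*a| near zero
prob_lower_fixed_v <- function(v, a, z) {
  out <- numeric(length(v))
  small <- abs(v) * a < 1e-8
  out[small] <- 1 - z
  if (any(!small)) {
    vv <- v[!small]
    # (exp(-2va) - exp(-2vza)) / (exp(-2va) - 1), computed via expm1
    num <- exp(-2 * vv * a * z) * expm1(-2 * vv * a * (1 - z))
    den <- expm1(-2 * vv * a)
    out[!small] <- num / den
  }
  pmin(pmax(out, 0), 1)
}

#' Choice probability of the Wiener process
#'
#' Probability that the accumulator is absorbed at the given boundary.  For
#' `sv = 0` the classical closed form is used; for `sv > 0` the closed form
#' is marginalised over the Gaussian drift distribution by adaptive
#' quadrature.
#'
#' @inheritParams wiener_pdf
#' @return A probability; the two boundaries sum to one.
#' @examples
#' wiener_choice_prob("lower", ddm_params(a = 2, z = 0.5, v = -2))
#' @export
wiener_choice_prob <- function(boundary = c("lower", "upper"), params) {
  boundary <- match.arg(boundary)
  params <- as_ddm_params(params)
  p_lower <- if (params$sv > 0) {
    f <- function(u) prob_lower_fixed_v(u, params$a, params$z) *
      dnorm(u, params$v, params$sv)
    integrate(f, params$v - 8 * params$sv, params$v + 8 * params$sv,
              rel.tol = 1e-9)$value
  } else {
    prob_lower_fixed_v(params$v, params$a, params$z)
  }
  if (boundary == "lower") p_lower else 1 - p_lower
}

#' Simulate first passages of the Wiener process
#'
#' Euler-Maruyama simulation of the two-boundary diffusion.  Trials not
#' absorbed within `max_t` (total time, non-decision time included) are
#' flagged censored and carry `rt = max_t` with a missing boundary.  All
#' randomness is governed by the explicit `seed`; the caller's RNG state is
#' left untouched.
#'
#' @param params a [ddm_params] object.
#' @param n number of trials, `>= 1`.
#' @param seed integer seed (required).
#' @param max_t response window in seconds (total time), `> t0`.
#' @param dt Euler step size in seconds.
#'
#' @return A data.frame with columns `boundary` (`"lower"`/`"upper"`/`NA`),
#'   `rt` (seconds) and `censored` (logical).
#' @examples
#' sim <- simulate_wiener(ddm_params(a = 2, v = -2, t0 = 0.3), n = 100,
#'                        seed = 1)
#' mean(sim$boundary == "lower", na.rm = TRUE)
#' @export
simulate_wiener <- function(params, n, seed, max_t = 5, dt = 1e-4) {
  params <- as_ddm_params(params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (max_t <= params$t0)
    stop("'max_t' must exceed the non-decision time", call. = FALSE)
  sim <- with_seed(seed, {
    wiener_sim_cpp(as.integer(n), params$a, params$z, params$t0, params$v,
                   params$sv, dt, max_t)
  })
  data.frame(
    boundary = c("lower", "upper")[sim$boundary + 1L],
    rt = sim$rt,
    censored = sim$censored,
    stringsAsFactors = FALSE
  )
}

# defective CDF of the lower/upper boundary on a time grid, by trapezoidal
# integration of the density; used for quantile diagnostics and KS checks
wiener_cdf_grid <- function(params, boundary = "lower", t_max = 30,
                            n_grid = 4096L, eps = 1e-7) {
  params <- as_ddm_params(params)
  tt <- seq(params$t0 + 1e-9, t_max, length.out = n_grid)
  dd <- wiener_pdf(tt, boundary, params, eps = eps)
  cc <- c(0, cumsum((dd[-1] + dd[-n_grid]) / 2 * diff(tt)))
  list(t = tt, cdf = cc)
}
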