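#' Wiener first-passage-time density
#'
#' Defective density of the decision time (RT with non-decision time
#' already removed) at one response boundary, for a Wiener accumulator
#' with two absorbing boundaries and no inter-trial variabilities.
#' Response coding is fixed package-wide: the upper boundary is the
#' "matching" response, the lower boundary the "nonmatching" response.
#'
#' The density is evaluated with a dual series representation: an
#' image-method small-time expansion and a spectral large-time expansion,
#' with automatic regime selection at the configured truncation tolerance.
#'
#' @param t decision time(s) in seconds; values `<= 0` return 0.
#' @param params a [ddm_params()] object with `sv = st = sz = 0`.
#' @param boundary `"upper"` (matching) or `"lower"` (nonmatching).
#' @param cfg a [density_config()].
#' @return Numeric vector of densities (per second, >= 0).
#' @examples
#' p <- ddm_params(a = 1, v = 1.5, z = 0.5)
#' wiener_fpt_density(c(0.2, 0.5, 1), p, "upper")
#' @export
wiener_fpt_density <- function(t, params, boundary = c("upper", "lower"),
                               cfg = density_config()) {
  boundary <- match.arg(boundary)
  validate_ddm_params(params)
  if (params$sv != 0 || params$st != 0 || params$sz != 0)
    stop("wiener_fpt_density is for sv = st = sz = 0; use marginal_density",
         call. = FALSE)
  stopifnot(is.numeric(t))
  out <- numeric(length(t))
  ok <- is.finite(t) & t > 0
  if (any(ok)) {
    out[ok] <- wiener_fpt_cpp(t[ok], params$a, params$v, params$z,
                              as.integer(boundary == "upper"),
                              cfg$series_tolerance)
  }
  out
}

#' Boundary absorption probability
#'
#' Probability that the accumulator is absorbed at the given boundary,
#' i.e. the marginal choice probability implied by the diffusion process
#' (inter-trial drift and starting-point variabilities must be zero).
#' With diffusion scale 1 and absolute start `z * a`,
#' `P(lower) = (exp(-2 v z a) - exp(-2 v a)) / (1 - exp(-2 v a))`;
#' at `v = 0` the continuous limit `P(upper) = z` is used (a series
#' expansion guards the near-zero regime `|2 v a| < 1e-8`).
#'
#' @inheritParams wiener_fpt_density
#' @return Probability in `[0, 1]`.
#' @examples
#' choice_probability(ddm_params(a = 1, v = 1.5, z = 0.5), "upper")
#' @export
choice_probability <- function(params, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  validate_ddm_params(params)
  if (params$sv != 0 || params$sz != 0)
    stop("choice_probability requires sv = sz = 0", call. = FALSE)
  a <- params$a; v <- params$v; z <- params$z
  if (abs(2 * v * a) < 1e-8) {
    # expand exp(-x) ~ 1 - x + x^2/2 in both numerator and denominator:
    # P(upper) -> z + v*a*z*(1-z) + O((va)^2)
    p_upper <- z + v * a * z * (1 - z)
  } else if (v > 0) {
    # compute via exp of negative arguments only, for numerical safety
    p_upper <- expm1(-2 * v * a * z) / expm1(-2 * v * a)
  } else {
    p_lower <- expm1(2 * v * a * (1 - z)) / expm1(2 * v * a)
    p_upper <- 1 - p_lower
  }
  p_upper <- min(max(p_upper, 0), 1)
  if (boundary == "upper") p_upper else 1 - p_upper
}

#' Marginal trial density with inter-trial variabilities
#'
#' Density of an observed response time at one boundary, marginalised over
#' the inter-trial variabilities: drift `v ~ Normal(v, sv)` (closed form),
#' starting point `z ~ Uniform(z - sz/2, z + sz/2)` and non-decision time
#' `t0 ~ Uniform(t0 - st/2, t0 + st/2)` (Gauss-Legendre quadrature).
#' With all variabilities zero this equals [wiener_fpt_density()] evaluated
#' at `t - t0`.
#'
#' @param t observed response time(s) in seconds (non-decision time
#'   included).
#' @inheritParams wiener_fpt_density
#' @param params a [ddm_params()] object; `sv`, `st`, `sz` may be positive.
#' @return Numeric vector of densities.
#' @export
marginal_density <- function(t, params, boundary = c("upper", "lower"),
                             cfg = density_config()) {
  boundary <- match.arg(boundary)
  validate_ddm_params(params)
  stopifnot(is.numeric(t))
  n <- length(t)
  out <- numeric(n)
  ok <- is.finite(t)
  if (any(ok)) {
    out[ok] <- wiener_marg_cpp(t[ok],
                               rep(as.integer(boundary == "upper"), sum(ok)),
                               rep(params$a, sum(ok)), rep(params$v, sum(ok)),
                               rep(params$z, sum(ok)), rep(params$t0, sum(ok)),
                               params$sv, params$st, params$sz,
                               cfg$qx, cfg$qw, cfg$zqx, cfg$zqw,
                               cfg$series_tolerance)
  }
  out
}

#' Trial log-likelihood
#'
#' Log of the marginal density at a trial's response time and response
#' boundary. Observations that are impossible under the parameters
#' (RT at or below the earliest possible non-decision time) return the
#' configured floor (`cfg$log_floor`, default `log(1e-10)`); set
#' `strict = TRUE` for exact `-Inf`.
#'
#' @param trial a one-row data frame (or list) with fields `rt` (seconds)
#'   and `response` (`"matching"` or `"nonmatching"`).
#' @param params a [ddm_params()].
#' @param cfg a [density_config()].
#' @param strict if `TRUE`, impossible observations yield `-Inf` instead of
#'   the floor.
#' @return A single log density.
#' @export
loglik_trial <- function(trial, params, cfg = density_config(),
                         strict = FALSE) {
  if (is.null(trial$response) || length(trial$response) != 1L ||
      is.na(trial$response))
    stop("trial has no recorded response", call. = FALSE)
  if (is.null(trial$rt) || !is.finite(trial$rt))
    stop("trial has no recorded response time", call. = FALSE)
  validate_ddm_params(params)
  up <- response_is_upper(trial$response)
  floor_ <- if (strict) -Inf else cfg$log_floor
  wiener_logdens_cpp(trial$rt, as.integer(up), params$a, params$v, params$z,
                     params$t0, params$sv, params$st, params$sz,
                     cfg$qx, cfg$qw, cfg$zqx, cfg$zqw,
                     cfg$series_tolerance, floor_)
}

# vectorised over trials with per-trial parameter vectors; the MCMC and
# MLE workhorse
loglik_vec <- function(rt, upper, a, v, z, t0, sv, st, sz, cfg,
                       total = TRUE) {
  floor_ <- cfg$log_floor
  if (total) {
    wiener_logdens_sum_cpp(rt, upper, a, v, z, t0, sv, st, sz,
                           cfg$qx, cfg$qw, cfg$zqx, cfg$zqw,
                           cfg$series_tolerance, floor_)
  } else {
    wiener_logdens_cpp(rt, upper, a, v, z, t0, sv, st, sz,
                       cfg$qx, cfg$qw, cfg$zqx, cfg$zqw,
                       cfg$series_tolerance, floor_)
  }
}

# boundary semantics, fixed package-wide: upper = matching response
response_is_upper <- function(response) {
  if (is.logical(response)) return(response)
  if (is.numeric(response)) return(response != 0)
  r <- as.character(response)
  if (!all(r %in% c("matching", "nonmatching", "upper", "lower")))
    stop("response must be 'matching'/'nonmatching' (or 'upper'/'lower')",
         call. = FALSE)
  r %in% c("matching", "upper")
}
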