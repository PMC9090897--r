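#' Diffusion-model parameter set
#'
#' Bundles the parameters of a response-coded Wiener diffusion process for
#' one condition: boundary separation `a`, drift rate `v`, relative starting
#' point `z`, non-decision time `t0`, and the inter-trial variabilities
#' `sv` (SD of a normal on the drift), `st` and `sz` (full widths of
#' uniforms on the non-decision time and the relative starting point).
#' The within-trial diffusion scale is fixed at s = 1, so printed
#' magnitudes are on the convention where `a` is around 1 and drift rates
#' are a few units per second.
#'
#' Validity requires `a > 0`, `0 < z < 1`, `t0 >= 0`, non-negative
#' variabilities, and containment of the variability ranges:
#' `z - sz/2 > 0`, `z + sz/2 < 1`, and `t0 - st/2 >= 0`.
#'
#' @param a boundary separation (> 0).
#' @param v drift rate (signed; positive drives towards the upper,
#'   "matching", boundary).
#' @param z relative starting point in (0, 1); 0.5 is unbiased.
#' @param t0 non-decision time in seconds (>= 0).
#' @param sv SD of normal inter-trial drift variability (>= 0).
#' @param st full range of uniform inter-trial `t0` variability, seconds.
#' @param sz full range of uniform inter-trial variability of `z`.
#' @return An object of class `ddm_params` (a named list).
#' @examples
#' ddm_params(a = 0.957, v = 1.744, z = 0.544, t0 = 0.437)
#' @export
ddm_params <- function(a, v, z = 0.5, t0 = 0, sv = 0, st = 0, sz = 0) {
  p <- list(a = a, v = v, z = z, t0 = t0, sv = sv, st = st, sz = sz)
  validate_ddm_params(p)
  structure(p, class = "ddm_params")
}

validate_ddm_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("a", "v", "z", "t0", "sv", "st", "sz")) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite number",
                             call. = FALSE)
  }
  if (p$a <= 0) stop("boundary separation 'a' must be > 0", call. = FALSE)
  if (p$z <= 0 || p$z >= 1) stop("relative starting point 'z' must lie in (0, 1)",
                                 call. = FALSE)
  if (p$t0 < 0) stop("non-decision time 't0' must be >= 0", call. = FALSE)
  if (p$sv < 0 || p$st < 0 || p$sz < 0)
    stop("inter-trial variabilities must be >= 0", call. = FALSE)
  if (p$z - p$sz / 2 <= 0 || p$z + p$sz / 2 >= 1)
    stop("starting-point variability range must stay strictly inside (0, 1)",
         call. = FALSE)
  if (p$t0 - p$st / 2 < 0)
    stop("non-decision-time variability range must stay >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Diffusion parameters (s = 1):\n")
  print(unlist(x))
  invisible(x)
}

#' Numerical settings for density evaluation
#'
#' @param series_tolerance truncation tolerance of the dual small/large-time
#'   series for the first-passage density.
#' @param quadrature_nodes number of Gauss-Legendre nodes used to
#'   marginalise over the uniform `st` and `sz` variabilities; odd, >= 3.
#' @param quadrature_nodes_z optional separate node count for the
#'   starting-point (`sz`) dimension; the `sz` integrand is much smoother
#'   than the `st` one, so fewer nodes suffice. Defaults to
#'   `quadrature_nodes`.
#' @param log_floor floor applied to per-trial log densities so that
#'   impossible observations (RT at or below the earliest possible
#'   non-decision time) keep MCMC chains finite; set to `-Inf` for strict
#'   evaluation.
#' @return An object of class `density_config`.
#' @export
density_config <- function(series_tolerance = 1e-7, quadrature_nodes = 11,
                           log_floor = log(1e-10),
                           quadrature_nodes_z = NULL) {
  if (!is.numeric(series_tolerance) || series_tolerance <= 0)
    stop("series_tolerance must be > 0", call. = FALSE)
  qn <- as.integer(quadrature_nodes)
  if (qn < 3L || qn %% 2L == 0L)
    stop("quadrature_nodes must be odd and >= 3", call. = FALSE)
  qnz <- if (is.null(quadrature_nodes_z)) qn else
    as.integer(quadrature_nodes_z)
  if (qnz < 3L || qnz %% 2L == 0L)
    stop("quadrature_nodes_z must be odd and >= 3", call. = FALSE)
  gl <- gauss_legendre(qn)
  glz <- gauss_legendre(qnz)
  structure(list(series_tolerance = series_tolerance,
                 quadrature_nodes = qn,
                 quadrature_nodes_z = qnz,
                 diffusion_scale = 1,
                 log_floor = log_floor,
                 qx = gl$nodes, qw = gl$weights,
                 zqx = glz$nodes, zqw = glz$weights),
            class = "density_config")
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# construction (symmetric tridiagonal Jacobi matrix).
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (2 * e$vectors[1, ]^2)[ord])
}
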