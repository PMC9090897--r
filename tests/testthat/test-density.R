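# The Wiener first-passage density and its analytic companions.

test_that("density is zero at the origin and non-negative everywhere", {
  p <- p_ref()
  expect_identical(wiener_fpt_density(0, p, "upper"), 0)
  expect_identical(wiener_fpt_density(-0.5, p, "lower"), 0)
  tt <- c(1e-4, 0.05, 0.3, 1, 5, 20)
  for (b in c("upper", "lower")) {
    expect_true(all(wiener_fpt_density(tt, p, b) >= 0))
  }
})

test_that("unbiased driftless process is boundary-symmetric", {
  p0 <- ddm_params(a = 1.3, v = 0, z = 0.5)
  tt <- seq(0.01, 3, by = 0.07)
  expect_equal(wiener_fpt_density(tt, p0, "upper"),
               wiener_fpt_density(tt, p0, "lower"), tolerance = 1e-12)
})

test_that("reflection symmetry: upper(v, z) equals lower(-v, 1 - z)", {
  cases <- list(c(1, 0.8, 0.4), c(0.957, 1.744, 0.544), c(1.5, -1.2, 0.3))
  tt <- c(0.05, 0.2, 0.6, 1.5, 4)
  for (cs in cases) {
    pu <- ddm_params(a = cs[1], v = cs[2], z = cs[3])
    pl <- ddm_params(a = cs[1], v = -cs[2], z = 1 - cs[3])
    expect_lt(max(abs(wiener_fpt_density(tt, pu, "upper") -
                        wiener_fpt_density(tt, pl, "lower"))), 1e-10)
  }
})

test_that("choice probability matches the closed-form absorption formula", {
  # independent evaluation of (e^(-2vza) - e^(-2va)) / (1 - e^(-2va))
  p <- p_ref()
  p_lower_expected <- (exp(-1.5) - exp(-3)) / (1 - exp(-3))
  expect_equal(choice_probability(p, "lower"), p_lower_expected,
               tolerance = 1e-12)
  expect_equal(choice_probability(p, "upper"), 1 - p_lower_expected,
               tolerance = 1e-12)
  # frozen value of the upper-boundary probability for a=1, v=1.5, z=0.5
  expect_equal(choice_probability(p, "upper"), 0.8175745, tolerance = 1e-6)
})

test_that("choice probability limits: symmetry, drift dominance, v = 0", {
  expect_equal(choice_probability(ddm_params(1, 0, 0.5), "upper"), 0.5)
  expect_equal(choice_probability(ddm_params(1, 50, 0.5), "upper"), 1,
               tolerance = 1e-10)
  # continuity at v = 0: P(upper) = z, probed from both sides
  for (v in c(-1e-8, 0, 1e-8)) {
    expect_equal(choice_probability(ddm_params(1.2, v, 0.37), "upper"),
                 0.37, tolerance = 1e-7)
  }
})

test_that("density integrates to the absorption probability per boundary", {
  cases <- list(ddm_params(1, 1.5, 0.5), ddm_params(0.957, 0.79, 0.544),
                ddm_params(1.4, -0.9, 0.35))
  for (p in cases) {
    for (b in c("upper", "lower")) {
      mass <- integrate(function(t) wiener_fpt_density(t, p, b), 0, Inf,
                        rel.tol = 1e-9)$value
      expect_equal(mass, choice_probability(p, b), tolerance = 1e-4)
    }
  }
})

test_that("small-time and large-time series agree in the overlap region", {
  # evaluating at coarse vs strict tolerance switches the regime cutover;
  # values must agree to the stated tolerance
  p <- ddm_params(1, 1, 0.45)
  tt <- seq(0.05, 2.5, by = 0.05)
  strict <- wiener_fpt_density(tt, p, "upper", density_config(1e-12))
  loose <- wiener_fpt_density(tt, p, "upper", density_config(1e-7))
  expect_lt(max(abs(strict - loose)), 1e-7)
})

test_that("invalid parameters are rejected", {
  expect_error(ddm_params(a = -1, v = 1), "boundary separation")
  expect_error(ddm_params(a = 1, v = 1, z = 1.2), "starting point")
  expect_error(ddm_params(a = 1, v = 1, z = 0.5, t0 = -0.1), "non-decision")
  expect_error(ddm_params(a = 1, v = 1, z = 0.9, sz = 0.3), "inside")
  expect_error(ddm_params(a = 1, v = 1, z = 0.5, t0 = 0.1, st = 0.3), ">= 0")
})

test_that("sv marginalisation: closed form equals quadrature over drift", {
  # two independent evaluation routes for the drift-variability mixture
  psv <- ddm_params(a = 1, v = 1.2, z = 0.5, t0 = 0, sv = 0.5)
  for (tt in c(0.15, 0.4, 0.9, 2)) {
    closed <- marginal_density(tt, psv, "upper")
    quad <- integrate(function(vv) {
      vapply(vv, function(vi)
        wiener_fpt_density(tt, ddm_params(1, vi, 0.5), "upper"), 0) *
        dnorm(vv, 1.2, 0.5)
    }, -10, 12, rel.tol = 1e-10)$value
    expect_equal(closed, quad, tolerance = 1e-6)
  }
})

test_that("degenerate mixture equals the plain density shifted by t0", {
  p <- ddm_params(a = 0.957, v = 1.744, z = 0.544, t0 = 0.437)
  p0 <- ddm_params(a = 0.957, v = 1.744, z = 0.544)
  tt <- c(0.5, 0.8, 1.4)
  expect_identical(marginal_density(tt, p, "upper"),
                   wiener_fpt_density(tt - 0.437, p0, "upper"))
})

test_that("marginal density with all variabilities stays normalised", {
  # parameters near the group posterior of the equivalent-context study
  pm <- ddm_params(a = 0.957, v = 1.744, z = 0.544, t0 = 0.437,
                   sv = 0.151, st = 0.446, sz = 0.304)
  mass <- integrate(function(t) marginal_density(t, pm, "upper"), 0, Inf,
                    rel.tol = 1e-8)$value +
    integrate(function(t) marginal_density(t, pm, "lower"), 0, Inf,
              rel.tol = 1e-8)$value
  expect_equal(mass, 1, tolerance = 1e-3)
})

test_that("trial log-likelihood floors impossible observations", {
  p <- ddm_params(a = 1, v = 1, z = 0.5, t0 = 0.437)
  tr <- list(rt = 0.10, response = "matching")
  expect_identical(loglik_trial(tr, p, strict = TRUE), -Inf)
  expect_equal(loglik_trial(tr, p), log(1e-10))
  expect_error(loglik_trial(list(rt = 0.5, response = NA), p), "response")
})

test_that("exp(loglik) equals the marginal density on random trials", {
  set.seed(99)
  p <- ddm_params(a = 1.1, v = 0.9, z = 0.48, t0 = 0.3, sv = 0.2,
                  st = 0.2, sz = 0.2)
  for (k in 1:25) {
    rt <- runif(1, 0.35, 2)
    resp <- sample(c("matching", "nonmatching"), 1)
    b <- if (resp == "matching") "upper" else "lower"
    expect_equal(exp(loglik_trial(list(rt = rt, response = resp), p)),
                 marginal_density(rt, p, b), tolerance = 1e-12)
  }
})

test_that("summed log-likelihood peaks near the generating parameters", {
  # coarse grid-search oracle over (a, v, t0) on simulated data
  truth <- ddm_params(a = 1, v = 1.5, z = 0.5, t0 = 0.3)
  set.seed(7)
  n <- 2000
  sim <- ddmatch:::simulate_ddm_cpp(rep(1, n), rep(1.5, n), rep(0.5, n),
                                    rep(0.3, n), 0, 0, 0, 1e-4, 60)
  cfg <- quick_cfg()
  ll_at <- function(a, v, t0) {
    sum(ddmatch:::wiener_logdens_cpp(sim$rt, sim$upper, rep(a, n),
                                     rep(v, n), rep(0.5, n), rep(t0, n),
                                     0, 0, 0, cfg$qx, cfg$qw, cfg$zqx,
                                     cfg$zqw, 1e-7, log(1e-10)))
  }
  grid <- expand.grid(a = c(0.6, 0.8, 1.0, 1.2, 1.5),
                      v = c(0.5, 1.0, 1.5, 2.0, 2.5),
                      t0 = c(0.1, 0.2, 0.3, 0.4, 0.45))
  lls <- mapply(ll_at, grid$a, grid$v, grid$t0)
  best <- grid[which.max(lls), ]
  expect_equal(best$a, 1.0)
  expect_equal(best$v, 1.5)
  expect_equal(best$t0, 0.3)
})
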