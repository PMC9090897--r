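# DIC, the sign-flip convention, directional posterior probabilities and
# recovery reporting.

# minimal fit-like object for draw-level conventions
fake_fit <- function(draws) {
  structure(list(draws = list(draws)), class = "ddm_fit")
}

test_that("DIC components satisfy the quadratic-deviance identity", {
  # Normal likelihood with known SD: for any set of posterior draws
  # {theta_s}, mean_s D(theta_s) = D(theta_bar) + n * Var_s(theta) / sigma^2
  # exactly, so pD has a closed form -- an independent oracle for the
  # draw-averaged computation.
  set.seed(42)
  y <- rnorm(12, 1, 1)
  sigma <- 1.3
  theta <- rnorm(400, mean(y), 0.2)  # stand-in posterior draws
  dev_draws <- vapply(theta, function(th)
    -2 * sum(dnorm(y, th, sigma, log = TRUE)), 0)
  theta_bar <- mean(theta)
  dev_at_mean <- -2 * sum(dnorm(y, theta_bar, sigma, log = TRUE))
  parts <- ddmatch:::dic_parts(dev_draws, dev_at_mean)
  n <- length(y)
  var_s <- mean((theta - theta_bar)^2)  # population variance of draws
  pd_analytic <- n * var_s / sigma^2
  expect_equal(parts$pd, pd_analytic, tolerance = 1e-6)
  expect_equal(parts$dic, parts$dbar + parts$pd, tolerance = 1e-10)
})

test_that("a degenerate posterior has zero effective parameters", {
  dev <- rep(123.4, 50)
  parts <- ddmatch:::dic_parts(dev, 123.4)
  expect_equal(parts$pd, 0)
  expect_equal(parts$dic, 123.4)
})

test_that("DIC identity holds to machine precision on a real fit", {
  sim <- sim_small_expt1(n_participants = 2, seed = 91)
  fit <- fit_hddm(filter_rt(sim$trials)$trials, sim$spec,
                  mcmc = mcmc_config(n_samples = 300, n_burn = 100,
                                     seed = 1),
                  cfg = quick_cfg(), fix = list(st = 0, sz = 0))
  d <- compute_dic(fit)
  expect_equal(d$dic, d$dbar + d$pd, tolerance = 1e-10)
  expect_true(is.finite(d$pd))
})

test_that("sign flip negates nonmatching drifts only and is an involution", {
  draws <- cbind("a" = c(1, 1.1), "v(matching.self)" = c(1.5, 1.6),
                 "v(nonmatching.self)" = c(-1.4, -1.3),
                 "v(nonmatching.friend)" = c(-1.2, -1.1),
                 "z" = c(0.54, 0.55))
  fit <- fake_fit(draws)
  flipped <- flip_nonmatching_drifts(fit)
  expect_equal(flipped$draws[[1]][, "v(nonmatching.self)"], c(1.4, 1.3))
  expect_equal(flipped$draws[[1]][1, "v(nonmatching.friend)"], 1.2,
               ignore_attr = TRUE)
  # matching and non-drift columns bit-identical
  expect_identical(flipped$draws[[1]][, c("a", "v(matching.self)", "z")],
                   draws[, c("a", "v(matching.self)", "z")])
  twice <- flip_nonmatching_drifts(flipped)
  expect_identical(twice$draws, fit$draws)
})

test_that("directional posterior probability follows the fail-fraction rule", {
  draws <- cbind("v(matching.self)" = c(2, 3, 4, 5),
                 "v(matching.friend)" = c(1, 1, 1, 6),
                 "z" = c(0.52, 0.55, 0.60, 0.58))
  fit <- fake_fit(draws)
  # one of four draws fails self > friend
  expect_equal(p_bayes(fit, "v(matching.self)", "v(matching.friend)"), 0.25)
  # every draw satisfies z > 0.5
  expect_equal(p_bayes(fit, "z", 0.5), 0)
  # complement convention: p(H) + p(not H) = 1 (no ties here)
  expect_equal(p_bayes(fit, "v(matching.self)", "v(matching.friend)") +
                 p_bayes(fit, "v(matching.self)", "v(matching.friend)",
                         direction = "<"), 1)
  expect_error(p_bayes(fit, "nope", 0), "unknown parameter")
})

test_that("a symmetric posterior yields an equivocal probability", {
  set.seed(8)
  draws <- cbind("z" = 0.5 + rnorm(20000, 0, 0.01))
  expect_equal(p_bayes(fake_fit(draws), "z", 0.5), 0.5, tolerance = 0.02)
})

test_that("recovery report rows, z-scores and coverage flags", {
  sim <- sim_small_expt1(n_participants = 2, seed = 95)
  fit <- fit_hddm(filter_rt(sim$trials)$trials, sim$spec,
                  mcmc = mcmc_config(n_samples = 250, n_burn = 100,
                                     seed = 2),
                  cfg = quick_cfg())
  rec <- recovery_report(sim$truth, fit)
  expect_equal(nrow(rec), length(spec_labels(sim$spec)))
  expect_equal(rec$z, rec$bias / rec$post_sd, tolerance = 1e-12)
  expect_identical(rec$covered,
                   rec$truth >= rec$ci_lo & rec$truth <= rec$ci_hi)
  # posterior quantile monotonicity
  expect_true(all(rec$ci_lo <= rec$ci_hi))
  ps <- posterior_summary(fit)
  expect_true(all(ps$q2.5 <= ps$q97.5))
})
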