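# MCMC sampler behaviour, the pooled MLE path, and convergence
# diagnostics.

test_that("with the likelihood disabled the sampler returns the prior", {
  sim <- sim_small_expt1(n_participants = 2, seed = 55)
  pri <- ddm_priors()
  fit <- fit_hddm(sim$trials, sim$spec, priors = pri,
                  mcmc = mcmc_config(n_samples = 4000, n_burn = 500,
                                     seed = 3),
                  cfg = quick_cfg(), hierarchical = FALSE,
                  likelihood = "none")
  d <- ddmatch:::combined_draws(fit)
  # truncated-normal prior CDF for the boundary-separation group mean
  tn_cdf <- function(q, loc, scale, lb, ub) {
    (pnorm(q, loc, scale) - pnorm(lb, loc, scale)) /
      (pnorm(ub, loc, scale) - pnorm(lb, loc, scale))
  }
  th <- d[seq(1, nrow(d), by = 8), "a"]  # thin to reduce autocorrelation
  ks <- suppressWarnings(stats::ks.test(th, function(q)
    tn_cdf(q, pri$a$loc, pri$a$scale, pri$a$lb, pri$a$ub)))
  expect_gt(ks$p.value, 0.01)
  # uniform prior on the drift-variability scalar
  ks2 <- suppressWarnings(stats::ks.test(d[seq(1, nrow(d), by = 8), "sv"],
                                         "punif", pri$sv[1], pri$sv[2]))
  expect_gt(ks2$p.value, 0.01)
})

test_that("the default MCMC configuration follows the analysis standard", {
  m <- mcmc_config()
  expect_equal(m$n_samples, 10000L)
  expect_equal(m$n_burn, 1000L)
  expect_error(mcmc_config(n_samples = 100, n_burn = 200))
})

test_that("chains are deterministic given the seed", {
  sim <- sim_small_expt1(n_participants = 2, seed = 60)
  run <- function(s) fit_hddm(sim$trials, sim$spec,
                              mcmc = mcmc_config(n_samples = 120,
                                                 n_burn = 40, seed = s),
                              cfg = quick_cfg(),
                              fix = list(st = 0, sz = 0))
  f1 <- run(4); f2 <- run(4); f3 <- run(5)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("split R-hat flags identical and disjoint chains correctly", {
  fake <- structure(list(draws = list(
    cbind(a = rep(1.5, 100), z = seq(0, 1, length.out = 100)),
    cbind(a = rep(1.5, 100), z = seq(0, 1, length.out = 100)))),
    class = "ddm_fit")
  r <- rhat(fake)
  expect_equal(unname(r["a"]), 1)       # identical constant chains
  fake$draws[[2]][, "z"] <- fake$draws[[2]][, "z"] + 50
  r2 <- rhat(fake)
  expect_gt(r2["z"], 1.1)               # non-overlapping chains detected
  one <- structure(list(draws = fake$draws[1]), class = "ddm_fit")
  expect_warning(r1 <- rhat(one), "two chains")
  expect_true(all(is.na(r1)))
})

test_that("pooled MLE recovers generating parameters at large n", {
  sim <- sim_small_expt1(n_participants = 10, seed = 70, sv = 0)
  trials <- filter_rt(sim$trials)$trials  # 2000 trials, one parameter set
  mle <- fit_pooled_mle(trials, sim$spec, cfg = quick_cfg(),
                        fix = list(sv = 0, st = 0, sz = 0), n_starts = 3,
                        seed = 8)
  est <- mle$estimate
  truth <- sim$truth$group
  expect_lt(abs(est["a"] - truth["a"]) / truth["a"], 0.05)
  expect_lt(abs(est["t0"] - truth["t0"]) / truth["t0"], 0.05)
  for (lab in c("v(matching.self)", "v(nonmatching.self)")) {
    expect_lt(abs(abs(est[lab]) - abs(truth[lab])) / abs(truth[lab]), 0.15)
  }
  # optimality: the estimate cannot be materially worse than the truth
  lay <- ddmatch:::spec_layout(sim$spec, list(sv = 0, st = 0, sz = 0))
  pdat <- ddmatch:::prep_data(transform(trials, participant_id = "all"),
                              sim$spec)
  ll_at <- function(g) ddmatch:::ll_participant(
    pdat[[1]], g[lay$mean_labels], c(g, sv = 0, st = 0, sz = 0), sim$spec,
    lay, quick_cfg(), TRUE)
  expect_gte(mle$loglik, ll_at(truth) - 2)
  # seed determinism
  mle2 <- fit_pooled_mle(trials, sim$spec, cfg = quick_cfg(),
                         fix = list(sv = 0, st = 0, sz = 0), n_starts = 3,
                         seed = 8)
  expect_identical(mle$estimate, mle2$estimate)
})

test_that("pooled MLE and pooled posterior agree without variabilities", {
  sim <- sim_small_expt1(n_participants = 6, seed = 81, sv = 0)
  trials <- filter_rt(sim$trials)$trials
  fx <- list(sv = 0, st = 0, sz = 0)
  fit <- fit_hddm(trials, sim$spec, hierarchical = FALSE, fix = fx,
                  mcmc = mcmc_config(n_samples = 1200, n_burn = 400,
                                     seed = 2),
                  cfg = quick_cfg())
  mle <- fit_pooled_mle(trials, sim$spec, cfg = quick_cfg(), fix = fx,
                        n_starts = 3, seed = 3)
  ps <- posterior_summary(fit)
  for (lab in c("a", "z", "t0", "v(matching.self)")) {
    row <- ps[ps$parameter == lab, ]
    post_sd <- (row$q97.5 - row$q2.5) / (2 * qnorm(0.975))
    expect_lt(abs(row$mean - mle$estimate[lab]), 2 * post_sd + 1e-3)
  }
})

test_that("posterior SDs contract as the trial count doubles", {
  spec <- build_model_ladder(1)$m2
  truth <- make_ground_truth(
    spec, c("a" = 1, "v(matching)" = 1.3, "v(nonmatching)" = -1.3,
            "z" = 0.52, "t0" = 0.3, "sv" = 0, "st" = 0, "sz" = 0),
    participant_sd = c(a = 0, v = 0, z = 0, t0 = 0))
  fx <- list(sv = 0, st = 0, sz = 0)
  post_sd <- function(n_part, seed) {
    tr <- filter_rt(simulate_trials(make_design(1, n_part), truth,
                                    seed = seed))$trials
    fit <- fit_hddm(tr, spec, hierarchical = FALSE, fix = fx,
                    mcmc = mcmc_config(n_samples = 1500, n_burn = 500,
                                       seed = seed),
                    cfg = quick_cfg())
    d <- ddmatch:::combined_draws(fit)
    apply(d[, c("a", "v(matching)", "v(nonmatching)", "z", "t0")], 2, sd)
  }
  s1 <- post_sd(2, 11)
  s2 <- post_sd(4, 12)
  ratio <- stats::median(s1 / s2)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 1.7)
})
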