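# shared fixtures: small parameter sets and quick numerical settings

quick_cfg <- function(nodes = 5) density_config(quadrature_nodes = nodes)

# canonical parameter set used in closed-form checks
p_ref <- function() ddm_params(a = 1, v = 1.5, z = 0.5)

# a small simulated experiment-1 dataset (no participant dispersion, no
# uniform variabilities) for fast estimation checks
sim_small_expt1 <- function(n_participants = 4, seed = 101, sv = 0.151,
                            st = 0, sz = 0, participant_sd = 0) {
  spec <- build_model_ladder(1)$m4
  truth <- make_ground_truth(
    spec,
    c("a" = 0.957, "v(matching.self)" = 1.744, "v(matching.friend)" = 0.79,
      "v(nonmatching.self)" = -1.372, "v(nonmatching.friend)" = -1.399,
      "z" = 0.544, "t0" = 0.437, "sv" = sv, "st" = st, "sz" = sz),
    participant_sd = c(a = participant_sd, v = participant_sd,
                       z = participant_sd / 10, t0 = participant_sd / 2))
  list(truth = truth, spec = spec,
       trials = simulate_trials(make_design(1, n_participants), truth,
                                seed = seed))
}

# numeric CDF of the decision-time distribution at one boundary,
# normalised by the absorption probability (independent oracle for
# distributional checks)
numeric_cdf <- function(params, boundary) {
  pb <- choice_probability(params, boundary)
  function(q) vapply(q, function(qq) {
    if (qq <= 0) return(0)
    stats::integrate(function(t) wiener_fpt_density(t, params, boundary),
                     0, qq, rel.tol = 1e-8)$value / pb
  }, 0)
}
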