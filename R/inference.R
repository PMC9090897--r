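# Hierarchical Bayesian estimation of a model specification by adaptive
# Metropolis-within-Gibbs, plus a fast pooled maximum-likelihood path.
#
# Hierarchy: participant-level values of every free a/v/z/t0 cell are
# normal around group means (one group SD per parameter type, shared
# across cells of that type), with domain truncation by proposal
# rejection.  The inter-trial variabilities sv/st/sz and any trial-number
# slopes are group-level scalars shared across participants.

#' Prior specification
#'
#' Package-default priors (weakly informative on the scale of the s = 1
#' parameter convention): truncated normals on the group means of `a`,
#' `z`, `t0`, a normal on drift means, uniforms on the inter-trial
#' variabilities, half-normal group SDs and a zero-centred normal on
#' trial-number slopes.
#'
#' @param slope_scale SD of the normal prior on trial-number slopes.
#' @return A list of class `ddm_priors`.
#' @export
ddm_priors <- function(slope_scale = 0.02) {
  structure(list(
    a  = list(loc = 1.5, scale = 1.0, lb = 0.1, ub = 5),
    v  = list(loc = 0.0, scale = 3.0, lb = -15, ub = 15),
    z  = list(loc = 0.5, scale = 0.25, lb = 0.05, ub = 0.95),
    t0 = list(loc = 0.4, scale = 0.3, lb = 0.05, ub = 1),
    sv = c(0, 2), st = c(0, 0.6), sz = c(0, 0.7),
    sigma_scale = 0.5,
    slope = list(loc = 0, scale = slope_scale)
  ), class = "ddm_priors")
}

#' MCMC configuration
#'
#' Defaults follow the package's standard analysis settings: 10,000
#' samples with a 1,000-sample burn-in, one chain. Recovery studies use
#' two chains for convergence diagnostics.
#'
#' @param n_samples total iterations per chain (including burn-in).
#' @param n_burn burn-in iterations discarded from every chain; proposal
#'   scales adapt only during burn-in.
#' @param n_chains number of independent chains.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param adapt_window iterations between proposal-scale updates during
#'   burn-in.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 10000, n_burn = 1000, n_chains = 1,
                        seed = 1, adapt_window = 25) {
  stopifnot(n_samples > n_burn, n_burn >= 0, n_chains >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_burn = as.integer(n_burn),
                 n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 adapt_window = as.integer(adapt_window)),
            class = "mcmc_config")
}

# per-parameter-type domains for sampled values (participant or group)
sample_domain <- function(priors, p) {
  pr <- priors[[p]]
  c(pr$lb, pr$ub)
}

# log prior density of a group mean (truncated normal; bounds enforced by
# rejection so the normalising constant is a fixed offset)
log_prior_mean <- function(priors, p, value) {
  pr <- priors[[p]]
  dnorm(value, pr$loc, pr$scale, log = TRUE)
}

# precompute per-participant data blocks and resolution indices
prep_data <- function(trials, spec) {
  ids <- unique(trials$participant_id)
  lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    idx <- lapply(c(a = "a", v = "v", z = "z", t0 = "t0"), function(p) {
      if (is.null(spec$par[[p]]$fixed)) cell_index(spec, p, tr) else NULL
    })
    list(id = id, n = nrow(tr), rt = tr$rt,
         upper = as.integer(response_is_upper(tr$response)),
         idx = idx, tn = tr$trial_number)
  })
}

# layout of sampled quantities for one spec
spec_layout <- function(spec, fix) {
  mean_labels <- character(); mean_type <- character()
  for (p in c("a", "v", "z", "t0")) {
    pp <- spec$par[[p]]
    if (!is.null(pp$fixed)) next
    labs <- vapply(pp$cells, function(cl) param_label(p, cl), "")
    mean_labels <- c(mean_labels, labs)
    mean_type <- c(mean_type, rep(p, length(labs)))
  }
  slope_labels <- character(); slope_type <- character()
  for (p in c("a", "v", "z")) {
    pp <- spec$par[[p]]
    if (isTRUE(pp$slope)) {
      labs <- vapply(pp$cells, function(cl) slope_label(p, cl), "")
      slope_labels <- c(slope_labels, labs)
      slope_type <- c(slope_type, rep(p, length(labs)))
    }
  }
  var_labels <- setdiff(c("sv", "st", "sz"), names(fix))
  types <- unique(mean_type)
  list(mean_labels = mean_labels, mean_type = mean_type,
       slope_labels = slope_labels, slope_type = slope_type,
       var_labels = var_labels, types = types,
       sigma_labels = paste0("sigma_", types))
}

# resolve per-trial parameter vectors for one participant from a named
# value vector `means` (their a/v/z/t0 cell values), slopes/variabilities
# taken from the group vector `g`
ll_participant <- function(pd, means, g, spec, lay, cfg, use_lik) {
  if (!use_lik) return(0)
  n <- pd$n
  get_vec <- function(p) {
    pp <- spec$par[[p]]
    if (!is.null(pp$fixed)) return(rep(pp$fixed, n))
    labs <- vapply(pp$cells, function(cl) param_label(p, cl), "")
    val <- unname(means[labs])[pd$idx[[p]]]
    if (isTRUE(pp$slope)) {
      sl <- unname(g[vapply(pp$cells, function(cl) slope_label(p, cl), "")])
      val <- val + sl[pd$idx[[p]]] * pd$tn
    }
    pmin(pmax(val, CLIP[[p]][1]), CLIP[[p]][2])
  }
  loglik_vec(pd$rt, pd$upper, get_vec("a"), get_vec("v"), get_vec("z"),
             get_vec("t0"),
             unname(g["sv"]), unname(g["st"]), unname(g["sz"]), cfg)
}

#' Fit a model by hierarchical Bayesian MCMC
#'
#' Samples the posterior of a model specification on trial data with an
#' adaptive Metropolis-within-Gibbs sampler: per-parameter Gaussian
#' random-walk proposals, tuned towards 20-50% acceptance during
#' burn-in. Participant-level parameters (every free `a`/`v`/`z`/`t0`
#' cell) are drawn around group means with one group SD per parameter
#' type; `sv`, `st`, `sz` and trial-number slopes are group-level
#' scalars. With `hierarchical = FALSE` the participant level is dropped
#' and the group-level parameters carry the full-data likelihood (pooled
#' Bayesian fit).
#'
#' @param trials trial data frame (run [filter_rt()] first).
#' @param spec a [model_spec()].
#' @param priors a [ddm_priors()].
#' @param mcmc a [mcmc_config()].
#' @param cfg a [density_config()].
#' @param hierarchical participant-level random effects (default) or a
#'   pooled fit.
#' @param fix named list fixing variability parameters, e.g.
#'   `list(st = 0, sz = 0)`; fixed values are not sampled.
#' @param likelihood `"wiener"` (default) or `"none"`, which replaces the
#'   likelihood by a constant so the sampler returns the prior.
#' @return An object of class `ddm_fit`: per-chain draws of all
#'   group-level quantities (means, slopes, variabilities, group SDs),
#'   per-draw deviance, posterior means of participant-level parameters,
#'   and sampler metadata.
#' @export
fit_hddm <- function(trials, spec, priors = ddm_priors(),
                     mcmc = mcmc_config(), cfg = density_config(),
                     hierarchical = TRUE, fix = list(),
                     likelihood = c("wiener", "none")) {
  likelihood <- match.arg(likelihood)
  use_lik <- likelihood == "wiener"
  stopifnot(inherits(spec, "ddm_model_spec"), nrow(trials) > 0)
  if (length(fix) && !all(names(fix) %in% c("sv", "st", "sz")))
    stop("only sv, st, sz can be fixed", call. = FALSE)
  lay <- spec_layout(spec, fix)
  pdat <- prep_data(trials, spec)
  n_part <- length(pdat)
  if (!hierarchical && n_part > 1L) {
    # pooled: all trials treated as one block
    all_tr <- trials
    all_tr$participant_id <- "pooled"
    pdat <- prep_data(all_tr, spec)
    n_part <- 1L
  }

  chains <- vector("list", mcmc$n_chains)
  dev_chains <- vector("list", mcmc$n_chains)
  xmeans <- vector("list", mcmc$n_chains)
  accept <- NULL
  for (ch in seq_len(mcmc$n_chains)) {
    res <- run_chain(pdat, spec, priors, mcmc, cfg, lay, hierarchical,
                     fix, use_lik, seed = mcmc$seed + ch - 1L)
    chains[[ch]] <- res$draws
    dev_chains[[ch]] <- res$deviance
    xmeans[[ch]] <- res$x_mean
    accept <- res$accept
  }
  x_mean <- Reduce(`+`, xmeans) / length(xmeans)
  structure(list(draws = chains, deviance = dev_chains, x_mean = x_mean,
                 spec = spec, layout = lay, trials = trials,
                 priors = priors, mcmc = mcmc, cfg = cfg, fix = fix,
                 hierarchical = hierarchical, likelihood = likelihood,
                 accept = accept, n_participants = n_part),
            class = "ddm_fit")
}

# One MCMC chain.  The likelihood factorises over trials, so the sampler
# caches per-trial log densities and, for each proposal, recomputes only
# the trials whose resolved parameters change: a cell-level mean touches
# only its cell's trials, while sv/st/sz and trial-number slopes touch
# everything.
run_chain <- function(pdat, spec, priors, mcmc, cfg, lay, hierarchical,
                      fix, use_lik, seed) {
  set.seed(seed)
  n_part <- length(pdat)
  nm <- length(lay$mean_labels)
  labs_by_p <- lapply(stats::setNames(nm = lay$types), function(p)
    lay$mean_labels[lay$mean_type == p])
  cols_by_p <- lapply(labs_by_p, function(l) match(l, lay$mean_labels))
  slope_labs_by_p <- lapply(stats::setNames(nm = c("a", "v", "z")),
                            function(p) lay$slope_labels[lay$slope_type == p])

  # --- initial values (prior-guided, data-informed t0, seed-jittered) ---
  all_rt <- unlist(lapply(pdat, `[[`, "rt"))
  t0_init <- min(max(0.5 * min(all_rt), 0.08), 0.6)
  init_mean <- function(lab, p) {
    switch(p,
           a = 1 + 0.05 * rnorm(1),
           v = (if (grepl("nonmatching", lab)) -1 else 1) + 0.1 * rnorm(1),
           z = 0.5 + 0.01 * rnorm(1),
           t0 = t0_init + 0.01 * abs(rnorm(1)))
  }
  gm <- vapply(seq_len(nm),
               function(j) init_mean(lay$mean_labels[j], lay$mean_type[j]), 0)
  names(gm) <- lay$mean_labels
  gs <- rep(0, length(lay$slope_labels)); names(gs) <- lay$slope_labels
  gv <- c(sv = 0.2, st = 0.1, sz = 0.1)
  for (nmf in names(fix)) gv[nmf] <- fix[[nmf]]
  g <- c(gm, gs, gv)

  sig_init <- c(a = 0.1, v = 0.3, z = 0.03, t0 = 0.05)
  sigma <- sig_init[lay$types]; names(sigma) <- lay$types

  dom <- lapply(c(a = "a", v = "v", z = "z", t0 = "t0"),
                function(p) sample_domain(priors, p))
  clampdom <- function(val, p) min(max(val, dom[[p]][1] + 1e-6),
                                   dom[[p]][2] - 1e-6)
  x <- NULL
  if (hierarchical) {
    x <- matrix(0, n_part, nm, dimnames = list(NULL, lay$mean_labels))
    for (j in seq_len(nm)) {
      p <- lay$mean_type[j]
      x[, j] <- vapply(rnorm(n_part, g[j], 0.5 * sigma[p]), clampdom, 0,
                       p = p)
    }
  }

  # trials affected by each cell of each free parameter
  aff <- lapply(pdat, function(pd) {
    lapply(stats::setNames(nm = c("a", "v", "z", "t0")), function(p) {
      if (is.null(spec$par[[p]]$fixed))
        lapply(seq_along(spec$par[[p]]$cells),
               function(j) which(pd$idx[[p]] == j))
      else NULL
    })
  })

  # resolved parameter vector for participant i, parameter p
  pvec_full <- function(pd, p, vals) {
    pp <- spec$par[[p]]
    if (!is.null(pp$fixed)) return(rep(pp$fixed, pd$n))
    val <- unname(vals)[pd$idx[[p]]]
    if (isTRUE(pp$slope)) {
      sl <- unname(g[slope_labs_by_p[[p]]])
      val <- val + sl[pd$idx[[p]]] * pd$tn
    }
    pmin(pmax(val, CLIP[[p]][1]), CLIP[[p]][2])
  }
  means_of <- function(i) if (hierarchical) x[i, ] else g[lay$mean_labels]
  vals_p <- function(i, p) {
    if (hierarchical) x[i, cols_by_p[[p]]] else g[labs_by_p[[p]]]
  }
  ld_full <- function(pd, vec) {
    if (!use_lik) return(rep(0, pd$n))
    wiener_logdens_cpp(pd$rt, pd$upper, vec$a, vec$v, vec$z, vec$t0,
                       unname(g["sv"]), unname(g["st"]), unname(g["sz"]),
                       cfg$qx, cfg$qw, cfg$zqx, cfg$zqw,
                       cfg$series_tolerance, cfg$log_floor)
  }
  ld_sub <- function(pd, vec, sub, p, newp_sub, sv, st, sz) {
    if (!use_lik) return(rep(0, length(sub)))
    av <- vec$a[sub]; vv <- vec$v[sub]; zv <- vec$z[sub]; tv <- vec$t0[sub]
    if (p == "a") av <- newp_sub else if (p == "v") vv <- newp_sub
    else if (p == "z") zv <- newp_sub else tv <- newp_sub
    wiener_logdens_cpp(pd$rt[sub], pd$upper[sub], av, vv, zv, tv,
                       sv, st, sz, cfg$qx, cfg$qw, cfg$zqx, cfg$zqw,
                       cfg$series_tolerance, cfg$log_floor)
  }

  refresh_all <- function() {
    vecs <- lapply(seq_len(n_part), function(i) {
      pd <- pdat[[i]]
      list(a = pvec_full(pd, "a", vals_p_ofmeans(i, "a")),
           v = pvec_full(pd, "v", vals_p_ofmeans(i, "v")),
           z = pvec_full(pd, "z", vals_p_ofmeans(i, "z")),
           t0 = pvec_full(pd, "t0", vals_p_ofmeans(i, "t0")))
    })
    vecs
  }
  vals_p_ofmeans <- function(i, p) {
    if (!p %in% lay$types) return(NULL)
    vals_p(i, p)
  }
  vecs <- refresh_all()
  ld <- lapply(seq_len(n_part), function(i) ld_full(pdat[[i]], vecs[[i]]))
  cur_ll <- vapply(ld, sum, 0)

  # bounded re-initialisation if the start is degenerate
  tries <- 0L
  while (any(!is.finite(cur_ll)) && tries < 20L) {
    gm <- vapply(seq_len(nm),
                 function(j) init_mean(lay$mean_labels[j], lay$mean_type[j]), 0)
    g[lay$mean_labels] <- gm
    if (hierarchical) for (j in seq_len(nm))
      x[, j] <- vapply(rnorm(n_part, g[j], 0.5 * sigma[lay$mean_type[j]]),
                       clampdom, 0, p = lay$mean_type[j])
    vecs <- refresh_all()
    ld <- lapply(seq_len(n_part), function(i) ld_full(pdat[[i]], vecs[[i]]))
    cur_ll <- vapply(ld, sum, 0)
    tries <- tries + 1L
  }
  if (any(!is.finite(cur_ll)))
    stop("could not find a finite-likelihood starting point", call. = FALSE)

  # --- proposal scales and adaptation state ---
  sc_mean_init <- c(a = 0.06, v = 0.15, z = 0.012, t0 = 0.012)
  sc_x <- if (hierarchical)
    matrix(rep(c(a = 0.08, v = 0.25, z = 0.02, t0 = 0.02)[lay$mean_type],
               each = n_part), n_part, nm) else NULL
  sc_g <- sc_mean_init[lay$mean_type]
  if (!hierarchical) sc_g <- sc_g / 2
  sc_slope <- rep(8e-4, length(lay$slope_labels))
  sc_var <- c(sv = 0.08, st = 0.03, sz = 0.08)[lay$var_labels]
  sc_sigma <- rep(0.03, length(lay$types))

  n_units <- (if (hierarchical) n_part * nm else 0) + nm +
    (if (hierarchical) length(lay$types) else 0) +
    length(lay$slope_labels) + length(lay$var_labels)
  acc_n <- numeric(n_units); try_n <- numeric(n_units)

  keep_labels <- c(lay$mean_labels, lay$slope_labels, lay$var_labels,
                   if (hierarchical) lay$sigma_labels)
  n_keep <- mcmc$n_samples - mcmc$n_burn
  draws <- matrix(NA_real_, n_keep, length(keep_labels),
                  dimnames = list(NULL, keep_labels))
  deviance <- numeric(n_keep)
  x_sum <- if (hierarchical) matrix(0, n_part, nm) else NULL

  for (it in seq_len(mcmc$n_samples)) {
    u <- 0L
    adapting <- it <= mcmc$n_burn

    if (hierarchical) {
      # participant-level cell values
      for (i in seq_len(n_part)) {
        pd <- pdat[[i]]
        for (j in seq_len(nm)) {
          u <- u + 1L
          p <- lay$mean_type[j]
          cur <- x[i, j]
          prop <- cur + sc_x[i, j] * rnorm(1)
          try_n[u] <- try_n[u] + 1
          if (prop <= dom[[p]][1] || prop >= dom[[p]][2]) next
          jc <- match(j, cols_by_p[[p]])  # cell index within p
          sub <- aff[[i]][[p]][[jc]]
          delta_lik <- 0
          if (length(sub) && use_lik) {
            if (isTRUE(spec$par[[p]]$slope)) {
              sl <- unname(g[slope_labs_by_p[[p]]])[jc]
              newp_sub <- prop + sl * pd$tn[sub]
            } else newp_sub <- rep(prop, length(sub))
            newp_sub <- pmin(pmax(newp_sub, CLIP[[p]][1]), CLIP[[p]][2])
            new_ld_sub <- ld_sub(pd, vecs[[i]], sub, p, newp_sub,
                                 unname(g["sv"]), unname(g["st"]),
                                 unname(g["sz"]))
            delta_lik <- sum(new_ld_sub) - sum(ld[[i]][sub])
          }
          logr <- delta_lik +
            dnorm(prop, g[j], sigma[p], log = TRUE) -
            dnorm(cur, g[j], sigma[p], log = TRUE)
          if (is.finite(logr) && log(runif(1)) < logr) {
            x[i, j] <- prop
            if (length(sub) && use_lik) {
              vecs[[i]][[p]][sub] <- newp_sub
              ld[[i]][sub] <- new_ld_sub
              cur_ll[i] <- cur_ll[i] + delta_lik
            }
            acc_n[u] <- acc_n[u] + 1
          }
        }
      }
      # group means: participant values are the "data"
      for (j in seq_len(nm)) {
        u <- u + 1L
        p <- lay$mean_type[j]
        prop <- g[j] + sc_g[j] * rnorm(1)
        try_n[u] <- try_n[u] + 1
        if (prop <= dom[[p]][1] || prop >= dom[[p]][2]) next
        logr <- sum(dnorm(x[, j], prop, sigma[p], log = TRUE)) -
          sum(dnorm(x[, j], g[j], sigma[p], log = TRUE)) +
          log_prior_mean(priors, p, prop) - log_prior_mean(priors, p, g[j])
        if (is.finite(logr) && log(runif(1)) < logr) {
          g[j] <- prop; acc_n[u] <- acc_n[u] + 1
        }
      }
      # group SDs (half-normal prior)
      for (k in seq_along(lay$types)) {
        u <- u + 1L
        p <- lay$types[k]
        prop <- sigma[p] + sc_sigma[k] * rnorm(1)
        try_n[u] <- try_n[u] + 1
        if (prop <= 1e-4 || prop > 5) next
        jj <- cols_by_p[[p]]
        logr <- sum(dnorm(x[, jj, drop = FALSE],
                          rep(g[jj], each = n_part), prop, log = TRUE)) -
          sum(dnorm(x[, jj, drop = FALSE],
                    rep(g[jj], each = n_part), sigma[p], log = TRUE)) +
          dnorm(prop, 0, priors$sigma_scale, log = TRUE) -
          dnorm(sigma[p], 0, priors$sigma_scale, log = TRUE)
        if (is.finite(logr) && log(runif(1)) < logr) {
          sigma[p] <- prop; acc_n[u] <- acc_n[u] + 1
        }
      }
    } else {
      # pooled: the group-level means carry the full-data likelihood
      pd <- pdat[[1]]
      for (j in seq_len(nm)) {
        u <- u + 1L
        p <- lay$mean_type[j]
        cur <- g[j]
        prop <- cur + sc_g[j] * rnorm(1)
        try_n[u] <- try_n[u] + 1
        if (prop <= dom[[p]][1] || prop >= dom[[p]][2]) next
        jc <- match(j, match(labs_by_p[[p]], lay$mean_labels))
        sub <- aff[[1]][[p]][[jc]]
        delta_lik <- 0
        if (length(sub) && use_lik) {
          if (isTRUE(spec$par[[p]]$slope)) {
            sl <- unname(g[slope_labs_by_p[[p]]])[jc]
            newp_sub <- prop + sl * pd$tn[sub]
          } else newp_sub <- rep(prop, length(sub))
          newp_sub <- pmin(pmax(newp_sub, CLIP[[p]][1]), CLIP[[p]][2])
          new_ld_sub <- ld_sub(pd, vecs[[1]], sub, p, newp_sub,
                               unname(g["sv"]), unname(g["st"]),
                               unname(g["sz"]))
          delta_lik <- sum(new_ld_sub) - sum(ld[[1]][sub])
        }
        logr <- delta_lik +
          log_prior_mean(priors, p, prop) - log_prior_mean(priors, p, cur)
        if (is.finite(logr) && log(runif(1)) < logr) {
          g[j] <- prop
          if (length(sub) && use_lik) {
            vecs[[1]][[p]][sub] <- newp_sub
            ld[[1]][sub] <- new_ld_sub
            cur_ll[1] <- cur_ll[1] + delta_lik
          }
          acc_n[u] <- acc_n[u] + 1
        }
      }
    }

    # trial-number slopes: group-level, touch every trial of their cell
    for (k in seq_along(lay$slope_labels)) {
      u <- u + 1L
      lab <- lay$slope_labels[k]
      p <- lay$slope_type[k]
      jc <- match(lab, slope_labs_by_p[[p]])
      prop <- g[lab] + sc_slope[k] * rnorm(1)
      try_n[u] <- try_n[u] + 1
      new_subs <- vector("list", n_part)
      new_lds <- vector("list", n_part)
      delta <- 0
      for (i in seq_len(n_part)) {
        pd <- pdat[[i]]
        sub <- aff[[i]][[p]][[jc]]
        if (!length(sub)) next
        base <- unname(vals_p(i, p))[jc]
        newp_sub <- pmin(pmax(base + prop * pd$tn[sub],
                              CLIP[[p]][1]), CLIP[[p]][2])
        nl <- ld_sub(pd, vecs[[i]], sub, p, newp_sub,
                     unname(g["sv"]), unname(g["st"]), unname(g["sz"]))
        new_subs[[i]] <- newp_sub
        new_lds[[i]] <- nl
        delta <- delta + sum(nl) - sum(ld[[i]][sub])
      }
      logr <- delta +
        dnorm(prop, priors$slope$loc, priors$slope$scale, log = TRUE) -
        dnorm(g[lab], priors$slope$loc, priors$slope$scale, log = TRUE)
      if (is.finite(logr) && log(runif(1)) < logr) {
        g[lab] <- prop
        for (i in seq_len(n_part)) {
          sub <- aff[[i]][[p]][[jc]]
          if (!length(sub)) next
          vecs[[i]][[p]][sub] <- new_subs[[i]]
          dl <- sum(new_lds[[i]]) - sum(ld[[i]][sub])
          ld[[i]][sub] <- new_lds[[i]]
          cur_ll[i] <- cur_ll[i] + dl
        }
        acc_n[u] <- acc_n[u] + 1
      }
    }

    # inter-trial variabilities: group-level, touch every trial
    for (k in seq_along(lay$var_labels)) {
      u <- u + 1L
      lab <- lay$var_labels[k]
      bounds <- priors[[lab]]
      prop <- g[lab] + sc_var[k] * rnorm(1)
      try_n[u] <- try_n[u] + 1
      if (prop < bounds[1] || prop > bounds[2]) next
      gc <- g; gc[lab] <- prop
      new_lds <- vector("list", n_part)
      delta <- 0
      for (i in seq_len(n_part)) {
        nl <- if (use_lik) {
          wiener_logdens_cpp(pdat[[i]]$rt, pdat[[i]]$upper,
                             vecs[[i]]$a, vecs[[i]]$v, vecs[[i]]$z,
                             vecs[[i]]$t0, unname(gc["sv"]),
                             unname(gc["st"]), unname(gc["sz"]),
                             cfg$qx, cfg$qw, cfg$zqx, cfg$zqw,
                             cfg$series_tolerance, cfg$log_floor)
        } else rep(0, pdat[[i]]$n)
        new_lds[[i]] <- nl
        delta <- delta + sum(nl) - cur_ll[i]
      }
      if (is.finite(delta) && log(runif(1)) < delta) {
        g <- gc
        ld <- new_lds
        cur_ll <- vapply(ld, sum, 0)
        acc_n[u] <- acc_n[u] + 1
      }
    }

    # proposal-scale adaptation towards 20-50% acceptance (burn-in only)
    if (adapting && it %% mcmc$adapt_window == 0L) {
      rate <- ifelse(try_n > 0, acc_n / pmax(try_n, 1), 0.3)
      fac <- exp(rate - 0.3)
      u2 <- 0L
      if (hierarchical) {
        for (i in seq_len(n_part)) for (j in seq_len(nm)) {
          u2 <- u2 + 1L
          sc_x[i, j] <- min(max(sc_x[i, j] * fac[u2], 1e-5), 5)
        }
      }
      for (j in seq_len(nm)) {
        u2 <- u2 + 1L; sc_g[j] <- min(max(sc_g[j] * fac[u2], 1e-5), 5)
      }
      if (hierarchical) for (k in seq_along(lay$types)) {
        u2 <- u2 + 1L; sc_sigma[k] <- min(max(sc_sigma[k] * fac[u2], 1e-5), 5)
      }
      for (k in seq_along(lay$slope_labels)) {
        u2 <- u2 + 1L; sc_slope[k] <- min(max(sc_slope[k] * fac[u2], 1e-6), 1)
      }
      for (k in seq_along(lay$var_labels)) {
        u2 <- u2 + 1L; sc_var[k] <- min(max(sc_var[k] * fac[u2], 1e-5), 5)
      }
      acc_n[] <- 0; try_n[] <- 0
    }

    if (it > mcmc$n_burn) {
      row <- it - mcmc$n_burn
      draws[row, lay$mean_labels] <- g[lay$mean_labels]
      if (length(lay$slope_labels))
        draws[row, lay$slope_labels] <- g[lay$slope_labels]
      if (length(lay$var_labels))
        draws[row, lay$var_labels] <- g[lay$var_labels]
      if (hierarchical) draws[row, lay$sigma_labels] <- sigma
      deviance[row] <- -2 * sum(cur_ll)
      if (hierarchical) x_sum <- x_sum + x
    }
  }

  rate <- ifelse(try_n > 0, acc_n / pmax(try_n, 1), NA_real_)
  x_mean <- if (hierarchical) {
    xm <- x_sum / n_keep
    dimnames(xm) <- list(vapply(pdat, `[[`, "", "id"), lay$mean_labels)
    xm
  } else {
    matrix(colMeans(draws[, lay$mean_labels, drop = FALSE]), 1,
           dimnames = list("pooled", lay$mean_labels))
  }
  list(draws = draws, deviance = deviance, x_mean = x_mean,
       accept = mean(rate, na.rm = TRUE))
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Diffusion-model fit:", x$spec$label,
      if (x$hierarchical) "(hierarchical)" else "(pooled)", "\n")
  cat(" ", x$mcmc$n_chains, "chain(s) x",
      x$mcmc$n_samples - x$mcmc$n_burn, "retained draws;",
      x$n_participants, "participant block(s)\n")
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

# combined draws across chains
combined_draws <- function(fit) do.call(rbind, fit$draws)

#' Posterior summary table
#'
#' Mean and central 95% interval (2.5% / 97.5% quantiles) of every
#' group-level quantity.
#'
#' @param fit a [fit_hddm()] result.
#' @return A data frame with columns `parameter`, `mean`, `q2.5`,
#'   `q97.5`.
#' @export
posterior_summary <- function(fit) {
  d <- combined_draws(fit)
  data.frame(parameter = colnames(d),
             mean = colMeans(d),
             q2.5 = apply(d, 2, quantile, 0.025),
             q97.5 = apply(d, 2, quantile, 0.975),
             row.names = NULL)
}

#' Export posterior draws as CSV
#'
#' One row per retained draw (chains stacked), one column per group-level
#' quantity, plus a `chain` column.
#'
#' @param fit a [fit_hddm()] result.
#' @param path output file path.
#' @export
write_draws <- function(fit, path) {
  d <- as.data.frame(combined_draws(fit))
  d$chain <- rep(seq_along(fit$draws),
                 vapply(fit$draws, nrow, 0L))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Split-chain potential scale reduction factor per group-level
#' parameter. Requires at least two chains (each chain is additionally
#' split in half).
#'
#' @param fit a [fit_hddm()] result.
#' @return Named numeric vector of split-R-hat values, or `NA` with a
#'   warning for single-chain fits.
#' @export
rhat <- function(fit) {
  if (length(fit$draws) < 2L) {
    warning("R-hat needs at least two chains; returning NA", call. = FALSE)
    return(stats::setNames(rep(NA_real_, ncol(fit$draws[[1]])),
                           colnames(fit$draws[[1]])))
  }
  halves <- list()
  for (d in fit$draws) {
    n <- nrow(d); h <- n %/% 2L
    halves <- c(halves, list(d[seq_len(h), , drop = FALSE],
                             d[(h + 1L):(2L * h), , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  vapply(colnames(halves[[1]]), function(p) {
    seqs <- vapply(halves, function(h) h[, p], numeric(n))
    mu <- colMeans(seqs)
    s2 <- apply(seqs, 2, var)
    W <- mean(s2)
    B <- n * var(mu)
    if (W <= 0) return(if (B <= 1e-300) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

#' Pooled maximum-likelihood fit
#'
#' Fast non-Bayesian companion of [fit_hddm()]: maximises the summed
#' trial log-likelihood over the group-level parameters, ignoring
#' participant structure, with L-BFGS-B from several seeded starting
#' points.
#'
#' @param trials trial data frame.
#' @param spec a [model_spec()].
#' @param cfg a [density_config()].
#' @param fix named list fixing variability parameters (see
#'   [fit_hddm()]).
#' @param n_starts number of seeded multi-start initial points.
#' @param seed integer seed for the start jitter.
#' @param priors a [ddm_priors()] (used only for box bounds).
#' @return List with `estimate` (named vector), `loglik`, `converged`,
#'   and the per-start objective values.
#' @export
fit_pooled_mle <- function(trials, spec, cfg = density_config(),
                           fix = list(), n_starts = 5, seed = 1,
                           priors = ddm_priors()) {
  lay <- spec_layout(spec, fix)
  all_tr <- trials
  all_tr$participant_id <- "pooled"
  pdat <- prep_data(all_tr, spec)
  labels <- c(lay$mean_labels, lay$slope_labels, lay$var_labels)
  lower <- upper <- numeric(length(labels))
  for (k in seq_along(labels)) {
    lab <- labels[k]
    if (lab %in% lay$mean_labels) {
      p <- lay$mean_type[match(lab, lay$mean_labels)]
      lower[k] <- sample_domain(priors, p)[1] + 1e-6
      upper[k] <- sample_domain(priors, p)[2] - 1e-6
    } else if (lab %in% lay$slope_labels) {
      lower[k] <- -0.1; upper[k] <- 0.1
    } else {
      lower[k] <- priors[[lab]][1]; upper[k] <- priors[[lab]][2]
    }
  }
  fixed_g <- c(sv = 0, st = 0, sz = 0)
  for (nmf in names(fix)) fixed_g[nmf] <- fix[[nmf]]

  negll <- function(par) {
    g <- stats::setNames(par, labels)
    g <- c(g, fixed_g[setdiff(names(fixed_g), names(g))])
    -ll_participant(pdat[[1]], g[lay$mean_labels], g, spec, lay, cfg, TRUE)
  }
  set.seed(as.integer(seed))
  init0 <- vapply(seq_along(labels), function(k) {
    lab <- labels[k]
    if (lab %in% lay$mean_labels) {
      p <- lay$mean_type[match(lab, lay$mean_labels)]
      switch(p, a = 1, v = if (grepl("nonmatching", lab)) -1 else 1,
             z = 0.5, t0 = min(max(0.5 * min(pdat[[1]]$rt), 0.08), 0.6))
    } else if (lab %in% lay$slope_labels) 0 else
      c(sv = 0.2, st = 0.1, sz = 0.1)[lab]
  }, 0)
  best <- NULL; vals <- numeric(n_starts); conv <- logical(n_starts)
  for (s in seq_len(n_starts)) {
    init <- init0
    if (s > 1) init <- pmin(pmax(init + 0.15 * abs(init0 + 0.2) * rnorm(length(init)),
                                 lower), upper)
    o <- tryCatch(
      optim(init, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) list(value = Inf, par = init, convergence = 99L))
    vals[s] <- o$value
    conv[s] <- identical(o$convergence, 0L)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!any(conv))
    warning("optimizer did not report convergence from any start; ",
            "returning the best iterate", call. = FALSE)
  list(estimate = stats::setNames(best$par, labels),
       loglik = -best$value,
       converged = any(conv),
       start_values = vals)
}
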