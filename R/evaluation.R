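# Model comparison and posterior evaluation: DIC, directional posterior
# probability tests, the sign-flip convention for nonmatching drifts, and
# parameter-recovery reports.

# DIC components from a deviance trace and the deviance at the posterior
# mean (classic Spiegelhalter plug-in): Dbar = mean deviance,
# pD = Dbar - D(theta_bar), DIC = Dbar + pD.
dic_parts <- function(deviance_draws, deviance_at_mean) {
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_mean
  list(dbar = dbar, pd = pd, dic = dbar + pd)
}

#' Deviance information criterion of a fit
#'
#' Computes `Dbar` (posterior mean of `-2 log L`), the plug-in deviance
#' at the posterior means of all sampled parameters (group- and
#' participant-level), the effective parameter count `pD = Dbar - D(mean)`
#' and `DIC = Dbar + pD`. Lower DIC indicates better fit. A negative
#' `pD` is reported with a warning, not clamped.
#'
#' @param fit a [fit_hddm()] result.
#' @return An object of class `ddm_dic`: `model`, `dic`, `dbar`, `pd`,
#'   and the posterior summary table.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  dev <- unlist(fit$deviance)
  if (mean(!is.finite(dev)) > 0.01)
    stop("log-likelihood non-finite on more than 1% of draws", call. = FALSE)
  post <- colMeans(combined_draws(fit))
  lay <- fit$layout
  g_hat <- post[c(lay$mean_labels, lay$slope_labels, lay$var_labels)]
  fixed_g <- c(sv = 0, st = 0, sz = 0)
  for (nmf in names(fit$fix)) fixed_g[nmf] <- fit$fix[[nmf]]
  g_hat <- c(g_hat, fixed_g[setdiff(names(fixed_g), names(g_hat))])
  pdat <- if (fit$hierarchical) {
    prep_data(fit$trials, fit$spec)
  } else {
    tr <- fit$trials; tr$participant_id <- "pooled"
    prep_data(tr, fit$spec)
  }
  ll_hat <- sum(vapply(seq_along(pdat), function(i) {
    means <- if (fit$hierarchical) fit$x_mean[i, ] else g_hat[lay$mean_labels]
    ll_participant(pdat[[i]], means, g_hat, fit$spec, lay, fit$cfg, TRUE)
  }, 0))
  parts <- dic_parts(dev, -2 * ll_hat)
  if (parts$pd < 0)
    warning("negative effective parameter count (pD = ",
            format(parts$pd, digits = 3), "); reported as is", call. = FALSE)
  structure(list(model = fit$spec$label, dic = parts$dic, dbar = parts$dbar,
                 pd = parts$pd, summary = posterior_summary(fit)),
            class = "ddm_dic")
}

#' @export
print.ddm_dic <- function(x, ...) {
  cat(sprintf("Model %s: DIC = %.1f (Dbar = %.1f, pD = %.1f)\n",
              x$model, x$dic, x$dbar, x$pd))
  invisible(x)
}

#' DIC comparison table for a model ladder
#'
#' @param dics list of [compute_dic()] results.
#' @return Data frame (model, DIC, Dbar, pD) ordered as supplied, plus a
#'   `best` flag on the lowest-DIC row.
#' @export
dic_table <- function(dics) {
  out <- data.frame(model = vapply(dics, `[[`, "", "model"),
                    dic = vapply(dics, `[[`, 0, "dic"),
                    dbar = vapply(dics, `[[`, 0, "dbar"),
                    pd = vapply(dics, `[[`, 0, "pd"))
  out$best <- seq_len(nrow(out)) == which.min(out$dic)
  out
}

#' Flip nonmatching drift rates
#'
#' Negates the posterior draws of every drift-rate cell belonging to the
#' nonmatching condition (which are negative under response coding), so
#' that drift magnitudes can be compared across matching conditions.
#' All other draws are untouched. The transformation is an involution:
#' applying it twice restores the original fit. Flipped fits are for
#' directional contrasts; model comparison uses the unflipped fit.
#'
#' @param fit a [fit_hddm()] result.
#' @return The fit with nonmatching drift draws negated.
#' @export
flip_nonmatching_drifts <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  cols <- grep("^v\\(.*nonmatching", colnames(fit$draws[[1]]), value = TRUE)
  for (ch in seq_along(fit$draws)) {
    fit$draws[[ch]][, cols] <- -fit$draws[[ch]][, cols]
  }
  attr(fit, "flipped") <- !isTRUE(attr(fit, "flipped"))
  fit
}

#' Directional posterior probability
#'
#' Evidence index for a directional hypothesis about group-level
#' parameters: the fraction of posterior draws in which the stated
#' direction FAILS, so small values indicate strong evidence for the
#' direction (e.g. a value below 0.001 for `left > right` means nearly
#' every draw satisfied `left > right`). For contrasts between drift
#' magnitudes on nonmatching trials, apply [flip_nonmatching_drifts()]
#' first.
#'
#' @param fit a [fit_hddm()] result.
#' @param left parameter label (e.g. `"v(matching.self)"`).
#' @param right parameter label, or a number (e.g. `0.5` to test a
#'   starting-point bias against the unbiased value).
#' @param direction `">"` (default) or `"<"`: the stated hypothesis is
#'   `left <direction> right`.
#' @return Probability in `[0, 1]`.
#' @export
p_bayes <- function(fit, left, right, direction = c(">", "<")) {
  direction <- match.arg(direction)
  d <- combined_draws(fit)
  get_side <- function(s) {
    if (is.numeric(s)) return(rep(s, nrow(d)))
    if (!s %in% colnames(d))
      stop("unknown parameter label: ", s, call. = FALSE)
    d[, s]
  }
  dl <- get_side(left); dr <- get_side(right)
  holds <- if (direction == ">") dl > dr else dl < dr
  mean(!holds)
}

#' Parameter-recovery report
#'
#' One row per group-level parameter of the generating configuration:
#' truth, posterior mean and SD, bias, z-score
#' (`(posterior mean - truth) / posterior SD`) and whether the central
#' 95% interval covers the truth.
#'
#' @param truth a [make_ground_truth()] / [ddm_ground_truth()] object.
#' @param fit a [fit_hddm()] result for the same model specification.
#' @return A data frame of class `ddm_recovery`.
#' @export
recovery_report <- function(truth, fit) {
  stopifnot(inherits(truth, "ddm_truth"), inherits(fit, "ddm_fit"))
  if (!identical(spec_labels(truth$spec), spec_labels(fit$spec)))
    stop("ground truth and fit use different model specifications",
         call. = FALSE)
  d <- combined_draws(fit)
  labs <- intersect(names(truth$group), colnames(d))
  out <- data.frame(parameter = labs,
                    truth = unname(truth$group[labs]),
                    post_mean = colMeans(d[, labs, drop = FALSE]),
                    post_sd = apply(d[, labs, drop = FALSE], 2, sd),
                    row.names = NULL)
  out$bias <- out$post_mean - out$truth
  out$z <- ifelse(out$post_sd > 0, out$bias / out$post_sd,
                  ifelse(out$bias == 0, 0, Inf))
  out$ci_lo <- apply(d[, labs, drop = FALSE], 2, quantile, 0.025)
  out$ci_hi <- apply(d[, labs, drop = FALSE], 2, quantile, 0.975)
  out$covered <- out$truth >= out$ci_lo & out$truth <= out$ci_hi
  class(out) <- c("ddm_recovery", "data.frame")
  out
}
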