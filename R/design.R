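# Experimental designs of the three shape-label matching studies and the
# trial-level simulator that stands in for raw data.

#' Build an experimental design
#'
#' Experiment 1 (equivalent context): one block of 200 trials, 50 per
#' Shape Association x Matching Condition cell. Experiments 2 and 3
#' (confirmatory / dis-confirmatory contexts): two 200-trial blocks with a
#' 75%/25% frequency split -- in each block the frequent target
#' contributes 150 trials (75 matching, 75 nonmatching) and the infrequent
#' target 50 (25/25), keeping every block at 100 matching and 100
#' nonmatching trials. Block order alternates across participants.
#'
#' @param experiment 1, 2 or 3.
#' @param n_participants number of simulated participants (>= 1).
#' @return An object of class `ddm_design`: experiment id, participant
#'   count, and a per-block cell table (`stimulus_frequency`,
#'   `shape_association`, `matching_condition`, `n_trials`).
#' @export
make_design <- function(experiment, n_participants) {
  if (!experiment %in% 1:3) stop("unknown experiment id", call. = FALSE)
  if (n_participants < 1) stop("need at least one participant", call. = FALSE)
  if (experiment == 1) {
    cells <- expand.grid(shape_association = c("self", "friend"),
                         matching_condition = c("matching", "nonmatching"),
                         stringsAsFactors = FALSE)
    cells$stimulus_frequency <- "equal"
    cells$block <- 1L
    cells$n_trials <- 50L
  } else {
    one_block <- function(block, freq) {
      frequent_shape <- if (freq == "self_frequent") "self" else "friend"
      g <- expand.grid(shape_association = c("self", "friend"),
                       matching_condition = c("matching", "nonmatching"),
                       stringsAsFactors = FALSE)
      g$stimulus_frequency <- freq
      g$block <- block
      g$n_trials <- ifelse(g$shape_association == frequent_shape, 75L, 25L)
      g
    }
    cells <- rbind(one_block(1L, "self_frequent"),
                   one_block(2L, "friend_frequent"))
  }
  cells <- cells[, c("block", "stimulus_frequency", "shape_association",
                     "matching_condition", "n_trials")]
  structure(list(experiment = experiment, n_participants = n_participants,
                 cells = cells),
            class = "ddm_design")
}

#' @export
print.ddm_design <- function(x, ...) {
  cat("Experiment", x$experiment, "design,", x$n_participants,
      "participants,", sum(x$cells$n_trials), "trials each\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Ground truth for synthetic data generation
#'
#' Bundles a model specification, group-level parameter values and
#' participant-level dispersion SDs into a generating configuration for
#' [simulate_trials()]. `ddm_ground_truth()` returns the canonical
#' configurations used throughout the package: the group posterior means
#' of the best-fitting model of each experiment (`"expt1"`,
#' `"expt2"`, `"expt3"`).
#'
#' The participant-level dispersion SDs (defaults `a` 0.1, `v` 0.3, `z`
#' 0.03, `t0` 0.05; truncated-normal sampling within the valid domain) are
#' package defaults for realistic between-participant heterogeneity -- no
#' dispersion estimates are available to pin them down.
#'
#' @param source one of `"expt1"`, `"expt2"`, `"expt3"`.
#' @return An object of class `ddm_truth`.
#' @export
ddm_ground_truth <- function(source = c("expt1", "expt2", "expt3")) {
  source <- match.arg(source)
  if (source == "expt1") {
    spec <- build_model_ladder(1)$m4
    group <- c("a" = 0.957,
               "v(matching.self)" = 1.744, "v(matching.friend)" = 0.790,
               "v(nonmatching.self)" = -1.372, "v(nonmatching.friend)" = -1.399,
               "z" = 0.544, "t0" = 0.437,
               "sv" = 0.151, "st" = 0.446, "sz" = 0.304)
  } else if (source == "expt2") {
    spec <- build_model_ladder(2)$m3
    group <- c("a(self_frequent)" = 1.033, "a(friend_frequent)" = 0.995,
               "v(self_frequent.matching.self)" = 2.274,
               "v(self_frequent.matching.friend)" = 0.325,
               "v(self_frequent.nonmatching.self)" = -1.966,
               "v(self_frequent.nonmatching.friend)" = -0.831,
               "v(friend_frequent.matching.self)" = 1.123,
               "v(friend_frequent.matching.friend)" = 1.484,
               "v(friend_frequent.nonmatching.self)" = -1.136,
               "v(friend_frequent.nonmatching.friend)" = -1.915,
               "z" = 0.543, "t0" = 0.412,
               "sv" = 0.087, "st" = 0.365, "sz" = 0.406)
  } else {
    spec <- build_model_ladder(3)$m3
    group <- c("a(self_frequent)" = 0.960, "a(friend_frequent)" = 1.046,
               "v(self_frequent.matching.self)" = 2.521,
               "v(self_frequent.matching.friend)" = 0.672,
               "v(self_frequent.nonmatching.self)" = -1.857,
               "v(self_frequent.nonmatching.friend)" = -1.346,
               "v(friend_frequent.matching.self)" = 1.987,
               "v(friend_frequent.matching.friend)" = 0.954,
               "v(friend_frequent.nonmatching.self)" = -1.632,
               "v(friend_frequent.nonmatching.friend)" = -1.515,
               "z" = 0.505, "t0" = 0.415,
               "slope_a(self_frequent)" = 2.65e-05,
               "slope_a(friend_frequent)" = -4.44e-04,
               "slope_v(self_frequent.matching.self)" = -0.001,
               "slope_v(self_frequent.matching.friend)" = -0.001,
               "slope_v(self_frequent.nonmatching.self)" = -0.001,
               "slope_v(self_frequent.nonmatching.friend)" = 0.005,
               "slope_v(friend_frequent.matching.self)" = -0.002,
               "slope_v(friend_frequent.matching.friend)" = 0.005,
               "slope_v(friend_frequent.nonmatching.self)" = 0.002,
               "slope_v(friend_frequent.nonmatching.friend)" = -0.003,
               "slope_z" = -5.80e-05,
               "sv" = 0.102, "st" = 0.440, "sz" = 0.787)
  }
  make_ground_truth(spec, group)
}

#' @rdname ddm_ground_truth
#' @param spec a [model_spec()].
#' @param group named numeric vector with one value per label in
#'   [spec_labels()] (trial-number slopes default to 0 if omitted).
#' @param participant_sd named numeric vector of between-participant SDs
#'   for `a`, `v`, `z`, `t0` (0 disables hierarchical dispersion).
#' @export
make_ground_truth <- function(spec, group,
                              participant_sd = c(a = 0.1, v = 0.3,
                                                 z = 0.03, t0 = 0.05)) {
  need <- spec_labels(spec)
  miss <- setdiff(need, names(group))
  slope_miss <- grepl("^slope_", miss)
  if (any(slope_miss)) {
    group[miss[slope_miss]] <- 0
    miss <- miss[!slope_miss]
  }
  if (length(miss))
    stop("ground truth does not cover: ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(all(c("a", "v", "z", "t0") %in% names(participant_sd)))
  structure(list(spec = spec, group = group[need],
                 participant_sd = participant_sd),
            class = "ddm_truth")
}

# draw one participant's cell-level parameter values around the group
# means, truncated to the valid domain
draw_participant <- function(truth) {
  draw <- truth$group
  for (p in c("a", "v", "z", "t0")) {
    pp <- truth$spec$par[[p]]
    if (!is.null(pp$fixed)) next
    sdv <- truth$participant_sd[[p]]
    if (sdv <= 0) next
    labs <- vapply(pp$cells, function(cl) param_label(p, cl), "")
    lo <- CLIP[[p]][1]; hi <- CLIP[[p]][2]
    for (lb in labs) {
      val <- rnorm(1, truth$group[[lb]], sdv)
      tries <- 0L
      while ((val <= lo || val >= hi) && tries < 100L) {
        val <- rnorm(1, truth$group[[lb]], sdv)
        tries <- tries + 1L
      }
      draw[[lb]] <- min(max(val, lo + 1e-6), hi - 1e-6)
    }
  }
  draw
}

#' Simulate trial data from a design and ground truth
#'
#' Per participant, cell-level diffusion parameters are drawn from normal
#' distributions around the group means (truncated to the valid domain),
#' the trial order is randomised within block, and each trial's response
#' and response time are sampled from the diffusion process at the
#' trial-resolved parameters by Euler-Maruyama integration (step `dt`)
#' with linear boundary-crossing interpolation. Inter-trial
#' variabilities `sv`, `st`, `sz` are applied per trial inside the
#' simulator; `rt` is the non-decision-time draw plus the first-passage
#' time. Block order alternates across participants.
#'
#' @param design a [make_design()] object.
#' @param truth a [ddm_ground_truth()] / [make_ground_truth()] object
#'   covering the design.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param dt Euler-Maruyama time step in seconds.
#' @return A data frame of trials with columns `participant_id`,
#'   `experiment`, `block`, `stimulus_frequency`, `shape_association`,
#'   `matching_condition`, `trial_number`, `response`, `rt`, `correct`.
#' @export
simulate_trials <- function(design, truth, seed, dt = 1e-4) {
  stopifnot(inherits(design, "ddm_design"), inherits(truth, "ddm_truth"))
  if (truth$spec$experiment != design$experiment)
    stop("ground truth does not cover this design (experiment mismatch)",
         call. = FALSE)
  set.seed(as.integer(seed))
  out <- vector("list", design$n_participants)
  blocks <- unique(design$cells$block)
  for (i in seq_len(design$n_participants)) {
    draw <- draw_participant(truth)
    border <- if (i %% 2L == 1L) blocks else rev(blocks)
    btabs <- vector("list", length(border))
    for (bi in seq_along(border)) {
      b <- border[bi]
      cells <- design$cells[design$cells$block == b, ]
      rows <- cells[rep(seq_len(nrow(cells)), cells$n_trials), ]
      rows <- rows[sample.int(nrow(rows)), ]
      rows$trial_number <- seq_len(nrow(rows))
      rows$block <- bi  # presentation order
      btabs[[bi]] <- rows
    }
    trials <- do.call(rbind, btabs)
    trials$participant_id <- sprintf("p%02d", i)
    trials$experiment <- design$experiment
    r <- resolve_params(truth$spec, draw, trials)
    sim <- simulate_ddm_cpp(r$a, r$v, r$z, r$t0, r$sv, r$st, r$sz,
                            dt, 60)
    trials$response <- ifelse(sim$upper == 1L, "matching", "nonmatching")
    trials$rt <- sim$rt
    # response coding: upper = matching response, so a trial is correct
    # exactly when the response label equals the matching condition
    trials$correct <- trials$response == trials$matching_condition
    rownames(trials) <- NULL
    out[[i]] <- trials[, c("participant_id", "experiment", "block",
                           "stimulus_frequency", "shape_association",
                           "matching_condition", "trial_number",
                           "response", "rt", "correct")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exclude anticipatory responses
#'
#' Removes trials with response times strictly below the floor (default
#' 200 ms; responses at exactly the floor are retained).
#'
#' @param trials trial data frame with an `rt` column (seconds).
#' @param floor exclusion threshold in seconds.
#' @return A list with `trials` (kept rows), `n_excluded`, `n_input` and
#'   `fraction_excluded`.
#' @export
filter_rt <- function(trials, floor = 0.200) {
  if (!"rt" %in% names(trials) || anyNA(trials$rt))
    stop("every trial needs a response time", call. = FALSE)
  drop <- trials$rt < floor
  list(trials = trials[!drop, , drop = FALSE],
       n_excluded = sum(drop),
       n_input = nrow(trials),
       fraction_excluded = if (nrow(trials)) mean(drop) else 0)
}

#' Per-cell behavioural summary
#'
#' Mean correct response time, accuracy and trial count per design cell
#' (stimulus frequency x shape association x matching condition). RT means
#' are over correct trials only; accuracy is over all trials. Cells with
#' no trials are kept in the table and flagged.
#'
#' @param trials trial data frame.
#' @return A data frame with one row per cell: `n`, `accuracy`,
#'   `mean_rt_correct`, `empty`.
#' @export
summarize_behavior <- function(trials) {
  if (!nrow(trials)) stop("no trials to summarise", call. = FALSE)
  f <- interaction(trials$stimulus_frequency, trials$shape_association,
                   trials$matching_condition, sep = "|", drop = FALSE)
  lv <- levels(f)
  parts <- do.call(rbind, strsplit(lv, "|", fixed = TRUE))
  out <- data.frame(stimulus_frequency = parts[, 1],
                    shape_association = parts[, 2],
                    matching_condition = parts[, 3],
                    stringsAsFactors = FALSE)
  out$n <- as.integer(table(f)[lv])
  out$accuracy <- vapply(lv, function(l) {
    s <- f == l
    if (!any(s)) NA_real_ else mean(trials$correct[s])
  }, 0)
  out$mean_rt_correct <- vapply(lv, function(l) {
    s <- f == l & trials$correct
    if (!any(s)) NA_real_ else mean(trials$rt[s])
  }, 0)
  out$empty <- out$n == 0L
  rownames(out) <- NULL
  out
}
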