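# Designs, the trial simulator, RT filtering, descriptives and CSV I/O.

test_that("designs reproduce the three experimental structures", {
  d1 <- make_design(1, 20)
  expect_equal(nrow(d1$cells), 4)
  expect_true(all(d1$cells$n_trials == 50))
  expect_equal(sum(d1$cells$n_trials), 200)
  expect_true(all(d1$cells$stimulus_frequency == "equal"))

  for (e in 2:3) {
    d <- make_design(e, 24)
    expect_equal(sum(d$cells$n_trials), 400)
    for (b in 1:2) {
      blk <- d$cells[d$cells$block == b, ]
      expect_equal(sum(blk$n_trials), 200)
      # each block: 100 matching / 100 nonmatching
      expect_equal(sum(blk$n_trials[blk$matching_condition == "matching"]),
                   100)
      # frequent target 75/75, infrequent 25/25
      freq_shape <- if (blk$stimulus_frequency[1] == "self_frequent")
        "self" else "friend"
      expect_true(all(blk$n_trials[blk$shape_association == freq_shape] == 75))
      expect_true(all(blk$n_trials[blk$shape_association != freq_shape] == 25))
    }
  }
  expect_error(make_design(4, 10), "unknown experiment")
})

test_that("simulated trials conserve the design cell counts exactly", {
  truth <- ddm_ground_truth("expt2")
  tr <- simulate_trials(make_design(2, 3), truth, seed = 5)
  expect_equal(nrow(tr), 3 * 400)
  counts <- with(tr, table(participant_id, stimulus_frequency,
                           shape_association, matching_condition))
  expect_true(all(counts[, "self_frequent", "self", ] == 75))
  expect_true(all(counts[, "self_frequent", "friend", ] == 25))
  expect_true(all(counts[, "friend_frequent", "friend", ] == 75))
  expect_true(all(counts[, "friend_frequent", "self", ] == 25))
  # trial numbering is 1-based within block
  expect_true(all(tapply(tr$trial_number,
                         interaction(tr$participant_id, tr$block),
                         function(x) identical(sort(x), 1:200))))
})

test_that("identical seeds give byte-identical datasets", {
  truth <- ddm_ground_truth("expt1")
  d <- make_design(1, 3)
  t1 <- simulate_trials(d, truth, seed = 77)
  t2 <- simulate_trials(d, truth, seed = 77)
  t3 <- simulate_trials(d, truth, seed = 78)
  expect_identical(t1, t2)
  expect_false(identical(t1$rt, t3$rt))
})

test_that("overwhelming drift produces near-exclusive matching responses", {
  spec <- build_model_ladder(1)$m1
  truth <- make_ground_truth(spec, c("v(matching)" = 50, "v(nonmatching)" = 50,
                                     "a" = 1, "t0" = 0.3, "sv" = 0, "st" = 0,
                                     "sz" = 0),
                             participant_sd = c(a = 0, v = 0, z = 0, t0 = 0))
  tr <- simulate_trials(make_design(1, 5), truth, seed = 9)
  expect_gte(mean(tr$response == "matching"), 0.999)
})

test_that("simulated choice fractions match the absorption probability", {
  # analytic absorption probability as the oracle, 3 Monte-Carlo SEs
  set.seed(31)
  n <- 10000
  for (cs in list(c(a = 1, v = 1.5, z = 0.5), c(a = 0.96, v = 0.8, z = 0.544))) {
    sim <- ddmatch:::simulate_ddm_cpp(rep(cs["a"], n), rep(cs["v"], n),
                                      rep(cs["z"], n), rep(0.3, n),
                                      0, 0, 0, 1e-4, 60)
    pu <- choice_probability(ddm_params(cs["a"], cs["v"], cs["z"]), "upper")
    se <- sqrt(pu * (1 - pu) / n)
    expect_lt(abs(mean(sim$upper) - pu), 3 * se)
  }
})

test_that("simulated decision times follow the first-passage distribution", {
  set.seed(13)
  n <- 7000
  p <- ddm_params(a = 1, v = 1.2, z = 0.45)
  sim <- ddmatch:::simulate_ddm_cpp(rep(1, n), rep(1.2, n), rep(0.45, n),
                                    rep(0, n), 0, 0, 0, 1e-4, 60)
  for (b in c("upper", "lower")) {
    rts <- sim$rt[sim$upper == as.integer(b == "upper")]
    rts <- rts[seq_len(min(5000, length(rts)))]
    ks <- suppressWarnings(stats::ks.test(rts, numeric_cdf(p, b)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("anticipation filter uses a strict 200 ms cutoff and is idempotent", {
  tr <- data.frame(rt = c(0.150, 0.199, 0.200, 0.201, 0.650),
                   response = "matching")
  f <- filter_rt(tr)
  expect_equal(f$n_excluded, 2)
  expect_equal(f$fraction_excluded, 0.4)
  expect_true(all(f$trials$rt >= 0.200))
  expect_true(0.200 %in% f$trials$rt)  # ties at the floor retained
  f2 <- filter_rt(f$trials)
  expect_identical(f2$trials, f$trials)
  expect_equal(f$n_excluded + nrow(f$trials), nrow(tr))
})

test_that("behavioural summary computes correct-trial RT means per cell", {
  tr <- data.frame(
    stimulus_frequency = "equal",
    shape_association = c("self", "self", "self", "friend"),
    matching_condition = "matching",
    rt = c(0.5, 0.7, 0.9, 0.6),
    correct = c(TRUE, TRUE, FALSE, TRUE))
  s <- summarize_behavior(tr)
  self_row <- s[s$shape_association == "self" & !s$empty, ]
  expect_equal(self_row$mean_rt_correct, 0.6)  # mean of 0.5, 0.7
  expect_equal(self_row$accuracy, 2 / 3)
  expect_equal(self_row$n, 3L)
})

test_that("empty design cells are flagged rather than dropped", {
  tr <- data.frame(
    stimulus_frequency = "equal",
    shape_association = factor(c("self", "self"), c("self", "friend")),
    matching_condition = "matching",
    rt = c(0.5, 0.6), correct = TRUE)
  s <- summarize_behavior(tr)
  expect_true(any(s$empty))
  expect_true(all(is.na(s$mean_rt_correct[s$empty])))
})

test_that("trial tables round-trip through CSV losslessly", {
  tr <- simulate_trials(make_design(1, 2), ddm_ground_truth("expt1"),
                        seed = 21)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$rt, tr$rt, tolerance = 1e-12)
  expect_identical(back$response, tr$response)
  expect_identical(back$correct, tr$correct)
  expect_identical(back$trial_number, tr$trial_number)
})

test_that("millisecond ingestion converts to seconds", {
  tr <- data.frame(participant_id = "p01", experiment = 1L, block = 1L,
                   stimulus_frequency = "equal", shape_association = "self",
                   matching_condition = "matching", trial_number = 1L,
                   response = "matching", rt = 650, correct = TRUE)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path, rt_unit = "ms")
  expect_equal(back$rt, 0.650)
})

test_that("malformed trial files are reported with row numbers", {
  tr <- data.frame(participant_id = "p01", experiment = 1L, block = 1L,
                   stimulus_frequency = "equal", shape_association = "self",
                   matching_condition = "matching", trial_number = 1:3,
                   response = c("matching", NA, "matching"),
                   rt = c(0.5, 0.6, 0.7), correct = TRUE)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tr, path, row.names = FALSE)
  expect_error(read_trials(path), "row.*2")
  tr$response <- "matching"
  tr$extra_column <- 1
  utils::write.csv(tr, path, row.names = FALSE)
  expect_warning(back <- read_trials(path), "extra_column")
  expect_true("extra_column" %in% names(back))
})
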