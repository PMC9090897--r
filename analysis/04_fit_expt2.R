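#!/usr/bin/env Rscript
# Hierarchical model comparison for the confirmatory-context study: the
# three-model ladder (default drift model; + frequency-dependent starting
# point; + frequency-dependent boundary separation), DIC comparison and
# the frequency contrasts on drift rates.
#
# Usage: Rscript analysis/04_fit_expt2.R [n_samples] [n_burn]

suppressPackageStartupMessages(library(ddmatch))

args <- commandArgs(trailingOnly = TRUE)
n_samples <- if (length(args) >= 1) as.integer(args[[1]]) else 2000L
n_burn <- if (length(args) >= 2) as.integer(args[[2]]) else 500L

data_dir <- file.path("results", "data")
out_dir <- file.path("results", "expt2")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

trials <- filter_rt(read_trials(file.path(data_dir, "expt2_trials.csv")))$trials
cfg <- density_config(quadrature_nodes = 3)

dics <- list(); fits <- list()
for (spec in build_model_ladder(2)) {
  cat("fitting", spec$label, "...\n")
  fit <- fit_hddm(trials, spec,
                  mcmc = mcmc_config(n_samples = n_samples, n_burn = n_burn,
                                     seed = 2345),
                  cfg = cfg)
  fits[[spec$label]] <- fit
  dics[[spec$label]] <- compute_dic(fit)
}
tab <- dic_table(dics)
write.csv(tab, file.path(out_dir, "dic_table.csv"), row.names = FALSE)
cat("\nDIC comparison (lower is better):\n")
print(tab, digits = 1)

best <- fits[[tab$model[tab$best]]]
summ <- posterior_summary(best)
write.csv(summ, file.path(out_dir, "posterior_summary.csv"),
          row.names = FALSE)
print(summ, digits = 3)

flipped <- flip_nonmatching_drifts(best)
contrasts <- data.frame(
  contrast = c("self-frequent: self > friend | matching",
               "self-frequent: self > friend | nonmatching",
               "friend-frequent: friend > self | matching",
               "friend-frequent: friend > self | nonmatching",
               "bias > 0.50"),
  p_bayes = c(
    p_bayes(best, "v(self_frequent.matching.self)",
            "v(self_frequent.matching.friend)"),
    p_bayes(flipped, "v(self_frequent.nonmatching.self)",
            "v(self_frequent.nonmatching.friend)"),
    p_bayes(best, "v(friend_frequent.matching.friend)",
            "v(friend_frequent.matching.self)"),
    p_bayes(flipped, "v(friend_frequent.nonmatching.friend)",
            "v(friend_frequent.nonmatching.self)"),
    p_bayes(best, "z", 0.5)))
write.csv(contrasts, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
cat("\ndirectional posterior tests (small = strong evidence):\n")
print(contrasts, digits = 3)
cat("done.\n")
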