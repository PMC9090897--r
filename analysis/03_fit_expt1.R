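#!/usr/bin/env Rscript
# Hierarchical model comparison for the equivalent-context study: fit the
# four-model ladder, compare by DIC, summarise the winning model's
# posterior and run the directional contrasts (self vs friend drift on
# matching and nonmatching trials, starting point vs no bias).
#
# Usage: Rscript analysis/03_fit_expt1.R [n_samples] [n_burn]
# Defaults are a reduced chain (2500/500); pass 10000 1000 for the
# full-length analysis configuration.

suppressPackageStartupMessages(library(ddmatch))

args <- commandArgs(trailingOnly = TRUE)
n_samples <- if (length(args) >= 1) as.integer(args[[1]]) else 2500L
n_burn <- if (length(args) >= 2) as.integer(args[[2]]) else 500L

data_dir <- file.path("results", "data")
out_dir <- file.path("results", "expt1")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

trials <- filter_rt(read_trials(file.path(data_dir, "expt1_trials.csv")))$trials
cfg <- density_config(quadrature_nodes = 5)

dics <- list()
fits <- list()
for (spec in build_model_ladder(1)) {
  cat("fitting", spec$label, "...\n")
  fit <- fit_hddm(trials, spec,
                  mcmc = mcmc_config(n_samples = n_samples, n_burn = n_burn,
                                     seed = 1234),
                  cfg = cfg)
  fits[[spec$label]] <- fit
  dics[[spec$label]] <- compute_dic(fit)
  write_draws(fit, file.path(out_dir, paste0("draws_", spec$label, ".csv")))
}

tab <- dic_table(dics)
write.csv(tab, file.path(out_dir, "dic_table.csv"), row.names = FALSE)
cat("\nDIC comparison (lower is better):\n")
print(tab, digits = 1)

best <- fits[[tab$model[tab$best]]]
cat("\nbest model:", best$spec$label, "\n")
summ <- posterior_summary(best)
write.csv(summ, file.path(out_dir, "posterior_summary.csv"),
          row.names = FALSE)
print(summ, digits = 3)

# directional contrasts; drift magnitudes on nonmatching trials are
# compared after flipping their (negative) signs
flipped <- flip_nonmatching_drifts(best)
contrasts <- data.frame(
  contrast = c("self > friend | matching", "self > friend | nonmatching",
               "bias > 0.50"),
  p_bayes = c(
    p_bayes(best, "v(matching.self)", "v(matching.friend)"),
    p_bayes(flipped, "v(nonmatching.self)", "v(nonmatching.friend)"),
    p_bayes(best, "z", 0.5)))
write.csv(contrasts, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
cat("\ndirectional posterior tests (small = strong evidence):\n")
print(contrasts, digits = 3)
cat("done.\n")
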