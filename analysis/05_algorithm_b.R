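#!/usr/bin/env Rscript
# Stage 5: Algorithm B. Over a metadata-only population of 1,000,000
# subjects, tabulate the mean number of cohort-pair draws needed until a
# pair of trial cohorts differs significantly (p < 0.05) and relevantly
# (|Cohen's d| >= threshold), for trial sizes 10-60 and thresholds
# 0.5-0.9, 100 repeats per cell. Runs that exceed the per-run iteration
# cap are reported as censored rather than extrapolated.

suppressPackageStartupMessages(library(gapmech))

dir.create("results", showWarnings = FALSE)
cfg <- default_config()

cat("Generating the metadata population (n = 1,000,000)...\n")
meta <- generate_population(cfg, n = 1e6)

curves <- list()
for (par in c("bmi", "tibia_length")) {
  col <- c(bmi = "bmi", tibia_length = "tibia_length_mm")[[par]]
  cat(sprintf("Algorithm B on %s...\n", par))
  curves[[par]] <- algorithm_b(
    meta[[col]],
    trial_sizes = seq(10L, 60L, by = 10L),
    d_grid = seq(0.5, 0.9, by = 0.1),
    repeats = 100, max_iter = 20000,
    parameter = par, seed = cfg$seed + match(par, c("bmi", "tibia_length")))
}
res <- do.call(rbind, curves)
rownames(res) <- NULL

cat("\nMean iterations to find a differing cohort pair (BMI):\n")
bmi <- subset(res, parameter == "bmi")
print(reshape(bmi[, c("trial_size", "d_threshold", "mean_iterations")],
              idvar = "trial_size", timevar = "d_threshold",
              direction = "wide"), digits = 4, row.names = FALSE)
cens <- sum(res$censored_runs)
if (cens > 0) {
  cat(sprintf("\n%d of %d runs censored at the %d-iteration cap\n",
              cens, nrow(res) * 100, 20000))
}
cat("\nMean iterations grow roughly exponentially with trial size once\n")
cat("the effect-size condition binds (see log-scale column ratios).\n")

write.csv(res, "results/algob_iterations.csv", row.names = FALSE,
          quote = FALSE)
cat("\nwrote results/algob_iterations.csv\n")
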