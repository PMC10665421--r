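#!/usr/bin/env Rscript
# Stage 3: anthropometry vs gap micromechanics. Reports, per
# anthropometric parameter, the landmark with the strongest correlation
# to the median invariants, and fits the linear regressions of median
# hydrostatic and octahedral shear strain in the gap on each parameter.
# Expects stage 2 outputs under results/pipeline/.

suppressPackageStartupMessages(library(gapmech))

avatars <- read.csv("results/pipeline/avatars.csv")
summaries <- read.csv("results/pipeline/strain_summary.csv")
co <- correlation_battery(summaries, avatars)

cat(sprintf("Correlation battery: %d rows, %d significant at 0.01\n",
            nrow(co), sum(co$significant_0p01)))

cat("\nStrongest |r| per parameter (gap, median invariants):\n")
gap <- subset(co, region == "gap")
for (par in unique(gap$parameter)) {
  sub <- gap[gap$parameter == par, ]
  best <- sub[which.max(abs(sub$r)), ]
  cat(sprintf("  %-12s r = %+.3f at %s (%s)\n",
              par, best$r, best$landmark, best$quantity))
}

# regression of the two leading invariants on each parameter at S4
params <- c(weight = "weight_kg", height = "height_m", bmi = "bmi",
            tibia_length = "tibia_length_mm")
rows <- list()
for (qt in c("hydrostatic", "oct_shear")) {
  sub <- subset(summaries, landmark == "S4" & region == "gap" &
                  quantity == qt)
  y <- sub$median[match(avatars$id, sub$avatar_id)]
  for (par in names(params)) {
    fit <- linear_regression(avatars[[params[[par]]]], y)
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = qt, parameter = par, slope = fit$slope,
      intercept = fit$intercept, r_squared = fit$r_squared)
  }
}
reg <- do.call(rbind, rows)
cat("\nLinear regressions at S4 (gap, median invariant ~ parameter):\n")
print(reg, digits = 3)

write.csv(co, "results/correlations.csv", row.names = FALSE, quote = FALSE)
write.csv(reg, "results/regressions_s4.csv", row.names = FALSE, quote = FALSE)
cat("\nwrote results/correlations.csv and results/regressions_s4.csv\n")
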