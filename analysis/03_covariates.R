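#!/usr/bin/env Rscript
# Stage 3 — association indices and per-hunt covariates.
#
# Dyadic simple-ratio association (SRI) per calendar year from the party
# scans, intergroup-encounter classification, and the seven-predictor
# covariate table for the prey-type model, with a collinearity screen.
suppressMessages(library(huntniche))

scans <- read_scans("results/data/scans.csv")
ind <- read_individuals("results/data/individuals.csv")
hunts <- read_hunts("results/data/hunts.csv")
scores <- read.csv("results/ranging/usage_scores.csv")
dir.create("results/covariates", recursive = TRUE, showWarnings = FALSE)

years <- sort(unique(format(scans$timestamp, "%Y")))
sri_by_year <- lapply(setNames(years, years), function(y)
  compute_sri(scans, y, ind))
for (y in years) {
  long <- sri_long(sri_by_year[[y]])
  write.csv(long, sprintf("results/covariates/sri_%s.csv", y),
            row.names = FALSE)
  cat(sprintf("SRI %s: %d dyads, median %.2f\n", y,
              sum(!is.na(long$sri)), median(long$sri, na.rm = TRUE)))
}

cov <- hunt_party_covariates(hunts, scans, ind, sri_by_year, scores)
write.csv(cov, "results/covariates/hunt_covariates.csv", row.names = FALSE)
cat(sprintf("\n%d hunts, %d flagged with missing covariates, %d intergroup\n",
            nrow(cov), attr(cov, "n_flagged"),
            sum(cov$is_intergroup, na.rm = TRUE)))
cat("\nparty association by group (mean +/- sd):\n")
for (g in sort(unique(cov$group)))
  cat(sprintf("  %-11s %.2f +/- %.2f\n", g,
              mean(cov$mean_association[cov$group == g], na.rm = TRUE),
              sd(cov$mean_association[cov$group == g], na.rm = TRUE)))
cat("\nvariance inflation factors:\n")
print(round(vif(cov[complete.cases(cov), ],
                c("n_available_males", "n_available_females",
                  "mean_association", "usage_difference",
                  "sin_date", "cos_date")), 2))
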