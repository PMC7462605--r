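#!/usr/bin/env Rscript
# Stage 5 — summary report.
#
# Tallies successful hunts by group and prey type, compares the recovered
# group effects with the generative truth, and records the run summary.
suppressMessages(library(huntniche))

hunts <- read_hunts("results/data/hunts.csv")
fitsum <- read.csv("results/model/fit_summary.csv")
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)

tal <- tally_hunts(hunts)
print(tal)

grp <- fitsum[fitsum$term == "group", ]
cat("\nGroup (Kokoalongo) effects, posterior mean [95% CI] vs truth:\n")
for (i in seq_len(nrow(grp))) {
  tru <- truth$true_coefficients$group[
    match(grp$category[i], rownames(truth$true_coefficients))]
  if (is.null(tru) || !length(tru))
    tru <- truth$true_coefficients$group[i]
  cat(sprintf("  %-9s %5.2f [%5.2f, %5.2f]  (truth %.2f)\n",
              grp$category[i], grp$estimate[i], grp$ci_low[i],
              grp$ci_high[i], tru))
}
cat(sprintf("\nmax split-Rhat: %.3f\n", max(fitsum$rhat)))

sink("results/report.txt")
print(tal)
cat("\n")
print(grp, digits = 3)
sink()
cat("report written to results/report.txt\n")
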