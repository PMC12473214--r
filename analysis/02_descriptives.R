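#!/usr/bin/env Rscript
# Descriptive statistics of the simulated populations: per-group trait means
# and SDs, parental-line t-tests, and the F1 trait correlation matrix.

suppressPackageStartupMessages(library(alfaselect))

tab <- read_trait_table("results/simulation/population.csv")
dir.create("results/descriptives", recursive = TRUE, showWarnings = FALSE)

summ <- summarize_groups(tab)
write.csv(transform(summ, mean = round(mean, 2), sd = round(sd, 2)),
          "results/descriptives/group_summaries.csv", row.names = FALSE)
cat("Group summaries -> results/descriptives/group_summaries.csv\n")

cat("\nParental-line t-tests (pooled, two-sided):\n")
pat <- tab[tab$generation == "P_paternal", ]
mat <- tab[tab$generation == "P_maternal", ]
ttests <- do.call(rbind, lapply(trait_names(), function(tr) {
  r <- two_sample_ttest(pat[[tr]], mat[[tr]])
  data.frame(trait = tr, t = round(r$statistic, 3),
             p_value = round(r$p_value, 4))
}))
print(ttests, row.names = FALSE)
write.csv(ttests, "results/descriptives/parental_ttests.csv", row.names = FALSE)

f1 <- tab[tab$generation == "F1", ]
corr <- pearson_correlations(f1)
write.csv(data.frame(trait = trait_names(), round(corr$r, 3)),
          "results/descriptives/f1_correlations.csv", row.names = FALSE)
cat(sprintf("\nF1 correlations (n = %d) -> results/descriptives/f1_correlations.csv\n",
            corr$n))
cat(sprintf("  dry weight vs height: %.2f   height vs branches: %.2f\n",
            corr$r["dry_weight_g", "height_cm"],
            corr$r["height_cm", "branches"]))
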