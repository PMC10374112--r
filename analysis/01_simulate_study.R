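#!/usr/bin/env Rscript
# Generate the synthetic comparative study: ten species spanning the
# observed range of cell-size dimorphism (D = 0 to 1.70), 40 comb images in
# total, and run the full per-comb measurement pipeline on each.
# Writes results/study_features.csv (one row per comb) and one example
# annotated comb with its per-cell metrics.

suppressPackageStartupMessages(library(hexcomb))
dir.create("results", showWarnings = FALSE)

study <- simulate_study(seed = 1)
write.csv(study, "results/study_features.csv", row.names = FALSE)

cat(sprintf("simulated %d combs across %d species (D %.2f-%.2f)\n",
            nrow(study), length(unique(study$species)),
            min(study$D_true), max(study$D_true)))
cat(sprintf("measured dimorphism tracks the generated values: r = %.3f\n",
            cor(study$D, study$D_true)))
agg <- aggregate(cbind(D, prop_nonhex) ~ species, study, mean)
agg <- agg[order(agg$D), ]
print(agg, digits = 3)
cat("proportion of non-hexagonal cells rises with dimorphism (Spearman r =",
    round(cor(agg$D, agg$prop_nonhex, method = "spearman"), 2), ")\n")

# one worked example comb: sudden transition at the highest dimorphism
cb <- one_step_merge(L = 10, alpha = dimorphism_to_scale(1.70),
                     jitter_sigma = 0.02, seed = 7)
write_comb(cb, "results/example_comb.json")
write_metrics(cb, "results", name = "example")
det <- detect_57_pairs(cb)
cat(sprintf("example comb (D = 1.70, L = 10): %d 5-7 pairs, %d/%d oriented with growth\n",
            det$summary$n_pairs, sum(det$pairs$oriented_correctly),
            nrow(det$pairs)))
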