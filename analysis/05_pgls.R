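#!/usr/bin/env Rscript
# Species-level comparative analysis: does cell-size dimorphism predict the
# proportion of non-hexagonal cells once shared phylogenetic history is
# accounted for?  PGLS with maximum-likelihood Pagel's lambda on the
# example time tree.  Writes results/pgls_fit.csv and the lambda profile.

suppressPackageStartupMessages(library(hexcomb))
dir.create("results", showWarnings = FALSE)

path <- "results/study_features.csv"
study <- if (file.exists(path)) read.csv(path) else simulate_study(seed = 1)

agg <- aggregate(cbind(D, prop_nonhex) ~ species, study, mean)
tr <- study_timetree()
x <- setNames(agg$D, agg$species)
y <- setNames(agg$prop_nonhex, agg$species)
fit <- pgls_fit(x, y, tr)
print(fit)

write.csv(data.frame(lambda = fit$lambda, slope = fit$slope,
                     intercept = fit$intercept, F_stat = fit$F_stat,
                     df1 = fit$df[1], df2 = fit$df[2],
                     p_value = fit$p_value, adj_R2 = fit$adj_R2),
          "results/pgls_fit.csv", row.names = FALSE)
write.csv(fit$lambda_profile, "results/pgls_lambda_profile.csv",
          row.names = FALSE)

cat(sprintf("\ndimorphism predicts the non-hexagonal proportion (F(1, %d) = %.1f, p = %.3g)\n",
            fit$df[2], fit$F_stat, fit$p_value))
cat("after phylogenetic correction; the divergence dates beyond the printed\n")
cat("179-My and 8-My anchors are example values, so the tree is illustrative.\n")
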