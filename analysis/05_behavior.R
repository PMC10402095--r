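#!/usr/bin/env Rscript
# Stage 5: behavioral summaries and the brain-behavior linkage: accuracy vs
# chance, per-participant RT slopes over steps-into-the-future, and the
# Spearman correlation between fitted asymptotes and RT slopes.

suppressPackageStartupMessages(library(seqgauss))
study <- readRDS("scratch/study.rds")

acc <- accuracy_vs_chance(study$behavior)
cat(sprintf("accuracy: %.2f%% (sd %.2f), vs 50%%: t(%d) = %.2f, p = %.2g\n",
            100 * acc$mean, 100 * acc$sd, acc$df, acc$t, acc$p))

slopes <- rt_slopes(study$behavior)
write.table(slopes, "results/rt_slopes.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("RT cost: %.1f ms per step into the future (group mean)\n",
            1000 * mean(slopes$slope, na.rm = TRUE)))

rel <- environment_reliability(study$localizer)
roi <- conjunction_roi(rel)
fits <- fit_participants(study_profiles(study, roi = roi)$profiles)
link <- brain_behavior_correlation(fits$b, slopes$slope)
cat(sprintf("asymptote ~ RT slope: Spearman rho = %.3f, p = %.3f (n = %d)\n",
            link$rho, link$p, link$n))
for (w in c("sigma_f", "sigma_b")) {
  lw <- brain_behavior_correlation(fits[[w]], slopes$slope)
  cat(sprintf("%s ~ RT slope: rho = %.3f, p = %.3f\n", w, lw$rho, lw$p))
}
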