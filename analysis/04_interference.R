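#!/usr/bin/env Rscript
# Stage 4: crossover interference.
#
# For each cohort: inter-crossover distances on chromosomes with exactly two
# called crossovers, a 500-permutation test of whether those distances exceed
# a random-placement null (positions resampled from the cohort's own
# midpoint pool per chromosome), and coefficient-of-coincidence curves over
# 1-15 Mb inter-interval distances with a LOESS fit. Wild-type cohorts
# (nu = 5) should reject the null and dip well below CoC = 1 at short
# distances; mutant cohorts (nu = 1) should not.

suppressMessages(library(meiocross))

out <- "results/analysis"
cohorts <- read.delim(file.path(out, "cohorts.tsv"))
specs <- tair10_chromosomes()
seed <- 20260931

perm_rows <- NULL
all_dist <- NULL
for (lab in cohorts$cohort) {
  gm <- read_vcf(file.path(out, paste0(lab, "_filtered.vcf")))
  events <- read_events_bed(file.path(out, paste0(lab, "_events.bed")))
  dists <- inter_co_distances(events)
  all_dist <- rbind(all_dist, cbind(cohort = lab, dists))
  perm <- permutation_null(dists, events, n_perm = 500, seed = seed)
  perm_rows <- rbind(perm_rows, data.frame(
    cohort = lab, n_double_co_chromosomes = perm$n_instances,
    observed_mean_mb = perm$observed_mean / 1e6,
    null_mean_mb = mean(perm$null_means) / 1e6,
    p_value = perm$p_value, n_perm = perm$n_perm, scheme = perm$scheme))
  coc <- coc_curve(events, specs, length(gm$samples))
  write.table(coc$points, file.path(out, paste0(lab, "_coc.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(coc$pooled) >= 4) {
    fit <- loess_fit(coc$pooled$d_mb, coc$pooled$coc)
    write.table(cbind(coc$pooled, loess = fit$fit$fitted),
                file.path(out, paste0(lab, "_coc_pooled.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cat(sprintf(
    "%-10s %3d double-CO chromosomes, mean distance %.1f Mb (null %.1f), p = %.3g\n",
    lab, perm$n_instances, perm$observed_mean / 1e6,
    mean(perm$null_means) / 1e6, perm$p_value))
}
write.table(perm_rows, file.path(out, "permutation_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(all_dist, file.path(out, "inter_co_distances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("interference tables written; wild-type p-values should be small,",
    "mutant p-values should not.\n")
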