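#' Marker and sample quality-control filters
#'
#' The QC chain mirrors the standard filtering of a shallow-coverage BC1
#' genotyping-by-sequencing variant matrix, applied in this order:
#' site filters ([filter_sites()]) -> removal of high-missingness samples
#' ([remove_high_missing_samples()]) -> removal of impossible
#' homozygous-Ler calls ([remove_impossible_homozygotes()]) -> removal of
#' samples with extreme marker numbers ([percentile_sample_filter()]).
#' Each step appends rows to a QC report recording what was removed.
#'
#' @name marker_qc
NULL

qc_row <- function(step, unit, n_removed, n_remaining, thresholds = "") {
  data.frame(step = step, unit = unit, n_removed = n_removed,
             n_remaining = n_remaining, thresholds = thresholds,
             stringsAsFactors = FALSE)
}

#' Site-level filters: depth bounds, mean depth, minor allele frequency
#'
#' Three filters applied in order: (i) genotype calls with depth outside
#' `[min_dp, max_dp]` are set missing (with `depth_scope = "site"` the
#' bounds apply to the per-site mean depth and remove whole markers
#' instead); (ii) markers whose mean raw depth across all samples lies
#' outside `mean_dp_range` are removed; (iii) markers whose minor allele
#' frequency -- `min(f, 1 - f)` with `f` the Ler allele frequency
#' `(2 * n_HOM_LER + n_HET) / (2 * n_non-missing)` computed on
#' post-depth-mask calls -- lies outside `maf_range` (inclusive) are
#' removed, as are markers with no remaining calls.
#'
#' @param gm A [geno_matrix()]; markers are assumed biallelic (asserted).
#' @param maf_range Length-2 inclusive MAF bounds.
#' @param min_dp,max_dp Per-genotype depth bounds.
#' @param mean_dp_range Length-2 bounds on per-site mean depth.
#' @param depth_scope `"genotype"` (default: mask individual calls) or
#'   `"site"` (remove markers whose mean depth violates `[min_dp, max_dp]`).
#' @return List with `matrix` (filtered) and `report` (QC rows).
#' @export
filter_sites <- function(gm, maf_range = c(0.2, 0.3), min_dp = 4,
                         max_dp = 100, mean_dp_range = c(1, 1.5),
                         depth_scope = c("genotype", "site")) {
  depth_scope <- match.arg(depth_scope)
  if (maf_range[1] > maf_range[2] || min_dp > max_dp ||
      mean_dp_range[1] > mean_dp_range[2])
    stop("inverted filter range")
  if (nrow(gm$markers) == 0L) stop("empty genotype matrix")
  stopifnot(all(nchar(gm$markers$ref) == 1L),
            all(nchar(gm$markers$alt) == 1L))
  report <- NULL
  mean_dp <- colMeans(gm$depth)

  if (depth_scope == "genotype") {
    mask <- !is.na(gm$calls) & (gm$depth < min_dp | gm$depth > max_dp)
    gm$calls[mask] <- NA
    report <- rbind(report, qc_row(
      "genotype_depth", "calls", sum(mask), sum(!is.na(gm$calls)),
      sprintf("DP in [%g, %g]", min_dp, max_dp)))
  } else {
    drop <- mean_dp < min_dp | mean_dp > max_dp
    gm <- subset_markers(gm, !drop)
    mean_dp <- mean_dp[!drop]
    report <- rbind(report, qc_row(
      "site_depth", "markers", sum(drop), nrow(gm$markers),
      sprintf("site mean DP in [%g, %g]", min_dp, max_dp)))
  }

  drop <- mean_dp < mean_dp_range[1] | mean_dp > mean_dp_range[2]
  gm <- subset_markers(gm, !drop)
  report <- rbind(report, qc_row(
    "mean_depth", "markers", sum(drop), nrow(gm$markers),
    sprintf("mean DP in [%g, %g]", mean_dp_range[1], mean_dp_range[2])))

  n_het <- colSums(gm$calls == GENO[["HET"]], na.rm = TRUE)
  n_ler <- colSums(gm$calls == GENO[["HOM_LER"]], na.rm = TRUE)
  n_obs <- colSums(!is.na(gm$calls))
  f_ler <- (2 * n_ler + n_het) / (2 * n_obs)
  maf <- pmin(f_ler, 1 - f_ler)
  drop <- n_obs == 0 | maf < maf_range[1] | maf > maf_range[2]
  gm <- subset_markers(gm, !drop)
  report <- rbind(report, qc_row(
    "maf", "markers", sum(drop), nrow(gm$markers),
    sprintf("MAF in [%g, %g]", maf_range[1], maf_range[2])))

  list(matrix = gm, report = report)
}

#' Remove samples with excessive missing data
#'
#' A sample is removed iff its fraction of missing calls is strictly greater
#' than `max_missing`.
#'
#' @param gm A [geno_matrix()].
#' @param max_missing Missingness threshold (default 0.75).
#' @return List with `matrix` and `report`.
#' @export
remove_high_missing_samples <- function(gm, max_missing = 0.75) {
  frac <- rowMeans(is.na(gm$calls))
  keep <- frac <= max_missing
  out <- subset_samples(gm, keep)
  list(matrix = out,
       report = qc_row("high_missing_samples", "samples", sum(!keep),
                       sum(keep), sprintf("missing > %g%%", 100 * max_missing)))
}

#' Remove impossible homozygous-Ler genotype calls
#'
#' In a Col-0 backcross the offspring can only be Col-homozygous or
#' heterozygous at a Col/Ler marker; homozygous-Ler calls are genotyping
#' artifacts (typically single-Ler-read calls at shallow depth) and are set
#' missing. The report records the mean per-sample removed fraction
#' (HOM_LER calls over non-missing calls).
#'
#' @param gm A [geno_matrix()].
#' @return List with `matrix`, `report`, and `mean_removed_fraction`.
#' @export
remove_impossible_homozygotes <- function(gm) {
  is_ler <- !is.na(gm$calls) & gm$calls == GENO[["HOM_LER"]]
  n_obs <- rowSums(!is.na(gm$calls))
  frac <- ifelse(n_obs > 0, rowSums(is_ler) / n_obs, 0)
  gm$calls[is_ler] <- NA
  list(matrix = gm,
       report = qc_row("impossible_hom_ler", "calls", sum(is_ler),
                       sum(!is.na(gm$calls)),
                       sprintf("mean per-sample removed %.2f%%",
                               100 * mean(frac))),
       mean_removed_fraction = mean(frac))
}

#' Remove samples with extreme marker numbers
#'
#' Per-sample SNV number is the count of non-missing calls; samples strictly
#' below the `lo` quantile or strictly above the `hi` quantile of that
#' distribution are removed. Quantiles use linear interpolation between
#' order statistics (R type 7).
#'
#' @param gm A [geno_matrix()] with at least 3 samples.
#' @param lo,hi Quantile bounds (defaults 0.05 and 0.95).
#' @return List with `matrix` and `report`.
#' @export
percentile_sample_filter <- function(gm, lo = 0.05, hi = 0.95) {
  if (length(gm$samples) < 3L) stop("need at least 3 samples")
  n_snv <- rowSums(!is.na(gm$calls))
  q <- stats::quantile(n_snv, c(lo, hi), type = 7, names = FALSE)
  keep <- n_snv >= q[1] & n_snv <= q[2]
  out <- subset_samples(gm, keep)
  list(matrix = out,
       report = qc_row("percentile_samples", "samples", sum(!keep),
                       sum(keep),
                       sprintf("SNV count in [%.6g, %.6g] (q%g-q%g)",
                               q[1], q[2], 100 * lo, 100 * hi)))
}

#' Run the full QC chain
#'
#' Applies [filter_sites()], [remove_high_missing_samples()],
#' [remove_impossible_homozygotes()] and [percentile_sample_filter()] in
#' order and concatenates their reports.
#'
#' @param gm A [geno_matrix()].
#' @param maf_range,min_dp,max_dp,mean_dp_range,depth_scope Passed to
#'   [filter_sites()].
#' @param max_missing Passed to [remove_high_missing_samples()].
#' @param percentiles Length-2 vector passed to
#'   [percentile_sample_filter()] as `(lo, hi)`.
#' @return List with `matrix` (post-QC) and `report` (all QC rows in order).
#' @export
run_qc <- function(gm, maf_range = c(0.2, 0.3), min_dp = 4, max_dp = 100,
                   mean_dp_range = c(1, 1.5),
                   depth_scope = c("genotype", "site"),
                   max_missing = 0.75, percentiles = c(0.05, 0.95)) {
  s1 <- filter_sites(gm, maf_range, min_dp, max_dp, mean_dp_range,
                     depth_scope)
  s2 <- remove_high_missing_samples(s1$matrix, max_missing)
  s3 <- remove_impossible_homozygotes(s2$matrix)
  s4 <- percentile_sample_filter(s3$matrix, percentiles[1], percentiles[2])
  list(matrix = s4$matrix,
       report = rbind(s1$report, s2$report, s3$report, s4$report))
}
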