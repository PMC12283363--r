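#' Nested ANOVA with Tukey HSD for sex/genotype comparisons
#'
#' Fits the nested model `y ~ sex / genotype` (sequential sums of squares:
#' sex, then genotype within sex) and follows it with Tukey's honestly
#' significant difference test over the sex x genotype cell means, using the
#' Tukey-Kramer correction for unbalanced cells (via the Studentized range
#' distribution on the equivalent cell-means fit, which shares the nested
#' model's residuals).
#'
#' @param y Numeric response (e.g. crossover count per offspring, or
#'   inter-crossover distance).
#' @param sex Factor or character vector.
#' @param genotype Factor or character vector (nested within sex).
#' @return List with `table` (term, Df, Sum Sq, Mean Sq, F value, Pr(>F)),
#'   `tukey` (data frame: pair, diff, lwr, upr, p_adj) and the fitted `aov`
#'   objects.
#' @export
nested_anova <- function(y, sex, genotype) {
  sex <- droplevels(as.factor(sex))
  genotype <- droplevels(as.factor(genotype))
  stopifnot(length(y) == length(sex), length(y) == length(genotype))
  if (nlevels(sex) < 2 || nlevels(genotype) < 2)
    stop("need at least 2 levels of sex and of genotype")
  if (any(table(sex, genotype) == 0))
    stop("singular design: empty sex x genotype cell")
  dat <- data.frame(y = y, sex = sex, genotype = genotype)
  fit <- stats::aov(y ~ sex / genotype, data = dat)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  cell <- interaction(sex, genotype, sep = ":", drop = TRUE)
  fit_cells <- stats::aov(y ~ cell, data = data.frame(y = y, cell = cell))
  tk <- stats::TukeyHSD(fit_cells)$cell
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(table = tab, tukey = tukey, fit = fit, fit_cells = fit_cells)
}

#' Per-window chi-square comparison of two recombination landscapes
#'
#' For each 1-Mb window, a 2x2 contingency table of (crossovers in the
#' window vs crossovers elsewhere) x (group A vs group B) is tested with
#' Pearson's chi-square (df = 1, no continuity correction). Windows where
#' both groups have zero crossovers are skipped. Benjamini-Hochberg adjusted
#' p-values are reported alongside the raw ones, since the multiplicity
#' procedure is an analysis choice.
#'
#' @param landscape_a,landscape_b Landscapes from [bin_landscape()], with
#'   identical `(chrom, bin)` rows.
#' @return Data frame `chrom`, `bin`, `count_a`, `count_b`, `chisq`, `df`,
#'   `p`, `p_adj`.
#' @export
landscape_chisq <- function(landscape_a, landscape_b) {
  if (!identical(landscape_a[c("chrom", "bin")],
                 landscape_b[c("chrom", "bin")]))
    stop("landscapes have mismatched bins")
  tot_a <- sum(landscape_a$count); tot_b <- sum(landscape_b$count)
  n <- nrow(landscape_a)
  chisq <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- landscape_a$count[i]; b <- landscape_b$count[i]
    if (a + b == 0) next
    m <- matrix(c(a, tot_a - a, b, tot_b - b), nrow = 2)
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    chisq[i] <- unname(ct$statistic)
    p[i] <- ct$p.value
  }
  out <- data.frame(chrom = landscape_a$chrom, bin = landscape_a$bin,
                    count_a = landscape_a$count, count_b = landscape_b$count,
                    chisq = chisq, df = 1L, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percent change between two means
#'
#' @param mean_ref Reference mean (> 0).
#' @param mean_alt Alternative mean.
#' @return `100 * (mean_alt - mean_ref) / mean_ref`.
#' @export
percent_change <- function(mean_ref, mean_alt) {
  if (any(mean_ref <= 0)) stop("reference mean must be > 0")
  100 * (mean_alt - mean_ref) / mean_ref
}

#' Class I focus to offspring crossover ratio
#'
#' Relates the mean number of cytological class I crossover foci per
#' meiocyte (e.g. HEI10 foci) to the mean crossover count per sequenced
#' offspring. A transmitted gamete carries on average half of its
#' meiocyte's crossovers (no chromatid interference), so the offspring
#' count is compared against `transmission_factor * co_mean` meiocyte
#' crossovers.
#'
#' @param foci_mean Mean foci per meiocyte.
#' @param co_mean Mean crossovers per offspring (> 0).
#' @param transmission_factor Meiocyte-to-gamete crossover ratio (default 2;
#'   set to 1 to compare on the raw scale).
#' @return Percentage `100 * foci_mean / (transmission_factor * co_mean)`.
#' @export
foci_to_offspring_co_ratio <- function(foci_mean, co_mean,
                                       transmission_factor = 2) {
  if (any(co_mean <= 0)) stop("crossover mean must be > 0")
  100 * foci_mean / (transmission_factor * co_mean)
}

#' Minimum chiasma count from bivalent shapes
#'
#' Rod-shaped bivalents are scored as one chiasma and ring-shaped bivalents
#' as two.
#'
#' @param rod_count,ring_count Non-negative integer counts.
#' @return `rod_count + 2 * ring_count`.
#' @export
min_chiasmata <- function(rod_count, ring_count) {
  stopifnot(all(rod_count >= 0), all(ring_count >= 0))
  rod_count + 2L * ring_count
}
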