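#' Inter-crossover distances on double-crossover chromosomes
#'
#' For interference analysis only chromosomes carrying exactly two called
#' crossovers are used; each qualifying (sample, chromosome) contributes one
#' distance between the two crossover midpoints.
#'
#' @param events Crossover event data frame (`sample`, `chrom`, `mid_bp`).
#' @return Data frame `sample`, `chrom`, `mid1`, `mid2`, `distance_bp`.
#' @export
inter_co_distances <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(sample = character(0), chrom = character(0),
                      mid1 = numeric(0), mid2 = numeric(0),
                      distance_bp = numeric(0)))
  empty <- data.frame(sample = character(0), chrom = character(0),
                      mid1 = numeric(0), mid2 = numeric(0),
                      distance_bp = numeric(0))
  key <- interaction(events$sample, events$chrom, drop = TRUE)
  cnt <- table(key)
  keep <- names(cnt)[cnt == 2L]
  if (length(keep) == 0L) return(empty)
  rows <- lapply(keep, function(k) {
    e <- events[key == k, , drop = FALSE]
    m <- sort(e$mid_bp)
    data.frame(sample = e$sample[1], chrom = e$chrom[1],
               mid1 = m[1], mid2 = m[2], distance_bp = m[2] - m[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation test for crossover interference
#'
#' Compares the observed mean inter-crossover distance (over chromosomes
#' with exactly two crossovers) against a null in which, for each
#' permutation, every qualifying chromosome-instance receives two positions
#' drawn independently, with replacement, from the empirical distribution of
#' all crossover midpoints on that chromosome in the same dataset
#' (`scheme = "resample"`, default). This preserves each chromosome's
#' crossover landscape while destroying within-gamete pairing. The
#' alternative `scheme = "shuffle"` deals observed midpoints (without
#' replacement within a permutation) across the qualifying instances of the
#' same chromosome. One-sided p-value: interference pushes crossovers apart,
#' so `p = (1 + #{null mean >= observed mean}) / (n_perm + 1)`.
#'
#' @param distances Output of [inter_co_distances()].
#' @param events All crossover events of the same dataset (midpoint pools).
#' @param n_perm Number of permutations (default 500).
#' @param seed Optional integer seed.
#' @param scheme `"resample"` or `"shuffle"`.
#' @return List `observed_mean`, `null_means`, `p_value`, `n_perm`,
#'   `direction`, `scheme`, `n_instances`, `n_skipped`.
#' @export
permutation_null <- function(distances, events, n_perm = 500, seed = NULL,
                             scheme = c("resample", "shuffle")) {
  scheme <- match.arg(scheme)
  if (nrow(distances) == 0L) stop("no qualifying double-crossover chromosomes")
  if (!is.null(seed)) set.seed(seed)
  pools <- split(events$mid_bp, events$chrom)
  inst_chrom <- distances$chrom
  have_pool <- inst_chrom %in% names(pools)
  n_skipped <- sum(!have_pool)
  if (n_skipped > 0) {
    warning(n_skipped, " instance(s) skipped: empty midpoint pool")
    distances <- distances[have_pool, , drop = FALSE]
    inst_chrom <- distances$chrom
  }
  observed <- mean(distances$distance_bp)
  k <- nrow(distances)
  null_means <- numeric(n_perm)
  chrom_idx <- split(seq_len(k), inst_chrom)
  for (b in seq_len(n_perm)) {
    d <- numeric(k)
    for (ch in names(chrom_idx)) {
      idx <- chrom_idx[[ch]]
      pool <- pools[[ch]]
      if (scheme == "resample") {
        p1 <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
        p2 <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
      } else {
        need <- 2L * length(idx)
        perm <- pool[sample.int(length(pool), min(need, length(pool)))]
        if (need > length(pool)) # top up with replacement if pool too small
          perm <- c(perm, pool[sample.int(length(pool), need - length(pool),
                                          replace = TRUE)])
        p1 <- perm[seq_len(length(idx))]
        p2 <- perm[length(idx) + seq_len(length(idx))]
      }
      d[idx] <- abs(p2 - p1)
    }
    null_means[b] <- mean(d)
  }
  list(observed_mean = observed, null_means = null_means,
       p_value = (1 + sum(null_means >= observed)) / (n_perm + 1),
       n_perm = n_perm, direction = "greater (interference => larger distances)",
       scheme = scheme, n_instances = k, n_skipped = n_skipped)
}

#' Coefficient of coincidence curve
#'
#' For each chromosome and each inter-interval distance `d` (in bins), over
#' all ordered bin pairs `(i, i + d)`:
#' `CoC(d) = sum(f_ij) / sum(f_i * f_j)` where `f_i` is the fraction of
#' gametes with at least one crossover midpoint in bin `i` and `f_ij` the
#' fraction with crossovers in both bins (pooled-ratio estimator). Pairs
#' with `f_i * f_j = 0` contribute to neither sum; a distance whose
#' denominator is zero is omitted. A pooled curve across chromosomes (sums
#' over all chromosomes' pairs) is also returned.
#'
#' @param events Crossover event data frame (`sample`, `chrom`, `mid_bp`).
#' @param specs List of [chromosome_spec()].
#' @param n_samples Number of gametes in the dataset.
#' @param d_range Integer vector of inter-interval distances in bins
#'   (default `1:15`, i.e. 1-15 Mb at the default bin size).
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return List with `points` (per chromosome: `chrom`, `d_mb`, `coc`,
#'   `n_pairs`, `num`, `den`) and `pooled` (`d_mb`, `coc`).
#' @export
coc_curve <- function(events, specs, n_samples, d_range = 1:15,
                      bin_size = 1e6) {
  stopifnot(n_samples > 0)
  samples <- unique(events$sample)
  pts <- list(); kk <- 0L
  pooled_num <- stats::setNames(numeric(length(d_range)),
                                as.character(d_range))
  pooled_den <- pooled_num
  for (spec in specs) {
    nb <- ceiling(spec$length_bp / bin_size)
    ev <- events[events$chrom == spec$name, , drop = FALSE]
    H <- matrix(FALSE, n_samples, nb)
    if (nrow(ev) > 0) {
      si <- match(ev$sample, samples)
      bi <- pmax(1L, ceiling(ev$mid_bp / bin_size))
      H[cbind(si, bi)] <- TRUE
    }
    f <- colMeans(H)
    for (d in d_range) {
      if (nb - d < 1L) next
      i <- seq_len(nb - d); j <- i + d
      den_pair <- f[i] * f[j]
      use <- den_pair > 0
      if (!any(use)) next
      num_pair <- colMeans(H[, i, drop = FALSE] & H[, j, drop = FALSE])
      num <- sum(num_pair[use]); den <- sum(den_pair[use])
      kk <- kk + 1L
      pts[[kk]] <- data.frame(chrom = spec$name, d_mb = d * bin_size / 1e6,
                              coc = num / den, n_pairs = sum(use),
                              num = num, den = den, stringsAsFactors = FALSE)
      pooled_num[as.character(d)] <- pooled_num[as.character(d)] + num
      pooled_den[as.character(d)] <- pooled_den[as.character(d)] + den
    }
  }
  points <- if (kk > 0) do.call(rbind, pts) else
    data.frame(chrom = character(0), d_mb = numeric(0), coc = numeric(0),
               n_pairs = integer(0), num = numeric(0), den = numeric(0))
  rownames(points) <- NULL
  ok <- pooled_den > 0
  pooled <- data.frame(d_mb = d_range[ok] * bin_size / 1e6,
                       coc = pooled_num[ok] / pooled_den[ok])
  rownames(pooled) <- NULL
  list(points = points, pooled = pooled)
}

#' LOESS fit of a CoC (or any x-y) curve
#'
#' Local polynomial regression with tricube weights, evaluated exactly
#' (`surface = "direct"`), on a grid (default: the sorted unique `x`).
#'
#' @param x,y Numeric vectors.
#' @param span LOESS span (default 0.75).
#' @param degree Local polynomial degree (default 2).
#' @param grid Evaluation grid (default sorted unique `x`).
#' @return List `fit` (data frame `x`, `fitted`), `span`, `degree`.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2, grid = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < degree + 2)
    stop("need at least degree + 2 points for a LOESS fit")
  if (is.null(grid)) grid <- sort(unique(x))
  m <- stats::loess(y ~ x, data = data.frame(x = x, y = y), span = span,
                    degree = degree, family = "gaussian",
                    surface = "direct")
  list(fit = data.frame(x = grid,
                        fitted = stats::predict(m, data.frame(x = grid))),
       span = span, degree = degree)
}
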