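#' Sliding-window modal genotype smoothing
#'
#' Denoises one sample-chromosome genotype sequence by aggregating
#' consecutive non-missing SNV calls in sliding windows of `w` markers
#' (step 1) and assigning each window its modal genotype. Ties (possible
#' when `w` is even) inherit the previous window's value; a run of leading
#' ties takes the value of the first subsequent untied window; if every
#' window is tied the whole sequence takes the first marker's genotype.
#' Marker `m` takes the value of the window centred on it (the window
#' starting at `m - floor((w - 1) / 2)`, clamped to the valid range), so
#' that on clean data the smoothed transition falls exactly between the two
#' markers flanking the true crossover; markers within half a window of
#' either end take the first/last window's value. If fewer than `w` markers
#' are present, a single window over all of them is used.
#'
#' @param calls Integer vector of non-missing calls, each `GENO[["HOM_COL"]]`
#'   or `GENO[["HET"]]`.
#' @param w Window size in markers (default 20).
#' @param s Step size; only `s = 1` is supported.
#' @return Integer vector of smoothed calls, same length as `calls`.
#' @export
smooth_genotypes <- function(calls, w = 20, s = 1) {
  if (s != 1) stop("only step size 1 is supported")
  if (w < 1) stop("w must be >= 1")
  M <- length(calls)
  if (M == 0L) return(integer(0))
  if (anyNA(calls)) stop("calls must be non-missing (drop missing first)")
  if (!all(calls %in% c(GENO[["HOM_COL"]], GENO[["HET"]])))
    stop("calls must be HOM_COL or HET")
  if (M < w) {
    n_het <- sum(calls == GENO[["HET"]])
    val <- if (2 * n_het > M) GENO[["HET"]]
           else if (2 * n_het < M) GENO[["HOM_COL"]]
           else calls[1L]
    return(rep(val, M))
  }
  nw <- M - w + 1L
  cs <- c(0L, cumsum(calls == GENO[["HET"]]))
  n_het <- cs[(w + 1L):(M + 1L)] - cs[1L:nw]
  win <- rep(NA_integer_, nw)
  win[2L * n_het > w] <- GENO[["HET"]]
  win[2L * n_het < w] <- GENO[["HOM_COL"]]
  if (anyNA(win)) {
    if (all(is.na(win))) {
      win[] <- calls[1L]
    } else {
      first_ok <- which(!is.na(win))[1L]
      if (first_ok > 1L) win[seq_len(first_ok - 1L)] <- win[first_ok]
      for (i in seq.int(first_ok + 1L, length.out = nw - first_ok)) {
        if (is.na(win[i])) win[i] <- win[i - 1L]
      }
    }
  }
  idx <- pmin(pmax(seq_len(M) - (w - 1L) %/% 2L, 1L), nw)
  win[idx]
}

#' Call crossovers from a smoothed genotype sequence
#'
#' Collapses the smoothed marker values into maximal genotype runs; runs
#' shorter than `min_run_markers` are merged into their flanks (interior
#' short runs vanish between two runs of the shared flanking genotype; edge
#' short runs are absorbed by their single neighbour). Each boundary between
#' adjacent runs of different genotype yields one crossover event with
#' breakpoint interval spanning the flanking run-end markers and midpoint
#' `floor((left_bp + right_bp) / 2)`.
#'
#' @param positions bp positions of the (non-missing) markers.
#' @param smoothed Smoothed calls from [smooth_genotypes()], same length.
#' @param min_run_markers Minimum run length retained (default 1, i.e. no
#'   run merging beyond the modal smoothing itself).
#' @return Data frame with columns `left_bp`, `right_bp`, `mid_bp`,
#'   `left_genotype`, `right_genotype` (genotype code strings).
#' @export
call_crossovers <- function(positions, smoothed, min_run_markers = 1) {
  stopifnot(length(positions) == length(smoothed))
  empty <- data.frame(left_bp = numeric(0), right_bp = numeric(0),
                      mid_bp = numeric(0), left_genotype = character(0),
                      right_genotype = character(0))
  if (length(smoothed) == 0L) return(empty)
  r <- rle(smoothed)
  if (min_run_markers > 1) {
    repeat {
      short <- which(r$lengths < min_run_markers)
      if (length(short) == 0L || length(r$lengths) == 1L) break
      i <- short[1L]
      if (i == 1L) {
        r$values[1L] <- r$values[2L]
      } else if (i == length(r$lengths)) {
        r$values[i] <- r$values[i - 1L]
      } else {
        r$values[i] <- r$values[i - 1L] # flanks share a genotype
      }
      merged <- rle(inverse.rle(r))
      r <- merged
    }
  }
  if (length(r$values) < 2L) return(empty)
  ends <- cumsum(r$lengths)
  left_idx <- ends[-length(ends)]
  right_idx <- left_idx + 1L
  left_bp <- positions[left_idx]
  right_bp <- positions[right_idx]
  data.frame(
    left_bp = left_bp, right_bp = right_bp,
    mid_bp = floor((left_bp + right_bp) / 2),
    left_genotype = names(GENO)[match(r$values[-length(r$values)], GENO)],
    right_genotype = names(GENO)[match(r$values[-1L], GENO)],
    stringsAsFactors = FALSE
  )
}

#' Call crossovers across a whole population
#'
#' Runs [smooth_genotypes()] and [call_crossovers()] on every
#' (sample, chromosome) of a genotype matrix. Missing calls are dropped
#' before windowing (windows span `w` non-missing SNVs); any residual
#' HOM_LER calls are dropped with a warning (the QC chain should have
#' removed them).
#'
#' @param gm A post-QC [geno_matrix()].
#' @param w Smoothing window size.
#' @param min_run_markers Passed to [call_crossovers()].
#' @return Data frame of crossover events: `sample`, `chrom`, `left_bp`,
#'   `right_bp`, `mid_bp`, `left_genotype`, `right_genotype`.
#' @export
call_population_crossovers <- function(gm, w = 20, min_run_markers = 1) {
  if (any(gm$calls == GENO[["HOM_LER"]], na.rm = TRUE)) {
    warning("HOM_LER calls present; dropping them (run QC first)")
    gm$calls[!is.na(gm$calls) & gm$calls == GENO[["HOM_LER"]]] <- NA
  }
  chroms <- unique(gm$markers$chrom)
  out <- list()
  k <- 0L
  for (ch in chroms) {
    idx <- which(gm$markers$chrom == ch)
    pos <- gm$markers$pos[idx]
    for (i in seq_along(gm$samples)) {
      calls <- gm$calls[i, idx]
      ok <- !is.na(calls)
      if (sum(ok) == 0L) next
      sm <- smooth_genotypes(calls[ok], w = w)
      ev <- call_crossovers(pos[ok], sm, min_run_markers)
      if (nrow(ev) == 0L) next
      k <- k + 1L
      out[[k]] <- cbind(sample = gm$samples[i], chrom = ch, ev,
                        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(sample = character(0), chrom = character(0),
                      left_bp = numeric(0), right_bp = numeric(0),
                      mid_bp = numeric(0), left_genotype = character(0),
                      right_genotype = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate crossover events into a 1-Mb landscape
#'
#' Each event is assigned to the non-overlapping bin containing its
#' midpoint: bin `b` covers `(b - 1) * bin_size < pos <= b * bin_size`
#' (1-based). The last, possibly partial, bin is retained and flagged.
#'
#' @param events Event data frame from [call_population_crossovers()].
#' @param specs List of [chromosome_spec()].
#' @param n_samples Number of gametes, for per-gamete rates.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return Data frame `chrom`, `bin`, `start_bp`, `end_bp`, `count`,
#'   `per_gamete`, `partial`.
#' @export
bin_landscape <- function(events, specs, n_samples, bin_size = 1e6) {
  stopifnot(n_samples > 0)
  out <- do.call(rbind, lapply(specs, function(spec) {
    nb <- ceiling(spec$length_bp / bin_size)
    ev <- events[events$chrom == spec$name, , drop = FALSE]
    if (any(ev$mid_bp > spec$length_bp))
      stop("event midpoint beyond end of ", spec$name, " (sample ",
           ev$sample[which(ev$mid_bp > spec$length_bp)[1]], ")")
    b <- ceiling(ev$mid_bp / bin_size) # pos <= b * bin_size
    b[ev$mid_bp <= 0] <- 1L
    cnt <- tabulate(b, nbins = nb)
    data.frame(chrom = spec$name, bin = seq_len(nb),
               start_bp = (seq_len(nb) - 1) * bin_size + 1,
               end_bp = pmin(seq_len(nb) * bin_size, spec$length_bp),
               count = cnt, per_gamete = cnt / n_samples,
               partial = seq_len(nb) * bin_size > spec$length_bp,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-offspring crossover counts
#'
#' @param events Event data frame.
#' @param samples Character vector of all sample ids (samples without any
#'   event get count 0).
#' @param chroms Optional chromosome names for per-chromosome columns.
#' @return Data frame with `sample`, `total`, and one column per chromosome.
#' @export
per_sample_counts <- function(events, samples, chroms = NULL) {
  if (is.null(chroms)) chroms <- unique(events$chrom)
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  out$total <- as.integer(table(factor(events$sample, levels = samples)))
  for (ch in chroms) {
    e <- events[events$chrom == ch, , drop = FALSE]
    out[[ch]] <- as.integer(table(factor(e$sample, levels = samples)))
  }
  out
}
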