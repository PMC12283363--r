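#' Genotype codes
#'
#' Calls in a BC1 genotype matrix are stored as integers:
#' `0` = HOM_COL (homozygous Col, the recurrent parent), `1` = HET
#' (Col/Ler), `2` = HOM_LER (homozygous Ler -- impossible in a Col
#' backcross, an artifact class kept representable so the QC chain can
#' remove it explicitly), `NA` = missing.
#'
#' @format Named integer vector.
#' @export
GENO <- c(HOM_COL = 0L, HET = 1L, HOM_LER = 2L)

#' Construct a genotype matrix
#'
#' The central container of the pipeline: samples x ordered markers with
#' genotype calls and per-call read depth.
#'
#' @param calls Integer matrix (samples x markers) with values in
#'   `GENO` or `NA` for missing.
#' @param depth Non-negative integer matrix, same dimensions as `calls`.
#' @param markers Data frame with columns `chrom`, `pos` (1-based bp,
#'   strictly increasing within each chromosome), and optionally `ref`,
#'   `alt` single-base allele labels (Col reference, Ler alternate).
#' @param samples Character vector of sample labels (rownames of `calls`).
#'
#' @return An object of class `geno_matrix` with elements `calls`, `depth`,
#'   `markers`, `samples`.
#' @export
geno_matrix <- function(calls, depth, markers, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  depth <- as.matrix(depth)
  stopifnot(identical(dim(calls), dim(depth)))
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  stopifnot(length(samples) == nrow(calls))
  markers <- as.data.frame(markers)
  stopifnot(all(c("chrom", "pos") %in% names(markers)),
            nrow(markers) == ncol(calls))
  if (is.null(markers$ref)) markers$ref <- "A"
  if (is.null(markers$alt)) markers$alt <- "T"
  bad <- !is.na(calls) & !(calls %in% GENO)
  if (any(bad)) stop("calls must be in {0 (HOM_COL), 1 (HET), 2 (HOM_LER), NA}")
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within ", ch)
  }
  rownames(calls) <- rownames(depth) <- samples
  structure(list(calls = calls, depth = depth,
                 markers = markers, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_mis <- mean(is.na(x$calls))
  cat("geno_matrix:", length(x$samples), "samples x",
      nrow(x$markers), "markers on",
      length(unique(x$markers$chrom)), "chromosomes\n")
  cat(sprintf("  missing calls: %.1f%%; mean depth: %.2f\n",
              100 * n_mis, mean(x$depth)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

# subset helpers used by the QC chain
subset_markers <- function(gm, keep) {
  geno_matrix(gm$calls[, keep, drop = FALSE], gm$depth[, keep, drop = FALSE],
              gm$markers[keep, , drop = FALSE], gm$samples)
}

subset_samples <- function(gm, keep) {
  geno_matrix(gm$calls[keep, , drop = FALSE], gm$depth[keep, , drop = FALSE],
              gm$markers, gm$samples[keep])
}

#' Long-format export of a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @return Data frame with columns `sample`, `chrom`, `pos`, `call`
#'   (character code or `NA`) and `depth`, one row per (sample, marker).
#' @export
geno_long <- function(gm) {
  code <- names(GENO)[match(as.vector(t(gm$calls)), GENO)]
  data.frame(
    sample = rep(gm$samples, each = nrow(gm$markers)),
    chrom = rep(gm$markers$chrom, times = length(gm$samples)),
    pos = rep(gm$markers$pos, times = length(gm$samples)),
    call = code,
    depth = as.vector(t(gm$depth)),
    stringsAsFactors = FALSE
  )
}
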