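#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT and DP per genotype. Only biallelic single-nucleotide variants
#' are kept (others are counted and skipped). Genotype mapping:
#' `0/0` -> HOM_COL, `0/1` or `1/0` -> HET, `1/1` -> HOM_LER,
#' `./.` or absent -> missing. A missing DP is stored as 0.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [geno_matrix()]; the number of skipped non-biallelic-SNV
#'   records is attached as attribute `"n_skipped"`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("no biallelic SNV records in ", path)
  for (ch in unique(chrom[keep])) {
    if (is.unsorted(pos[keep & chrom == ch], strictly = TRUE))
      stop("positions not strictly increasing on ", ch)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE])
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt))
  calls[gt_clean == "0/0"] <- GENO[["HOM_COL"]]
  calls[gt_clean %in% c("0/1", "1/0")] <- GENO[["HET"]]
  calls[gt_clean == "1/1"] <- GENO[["HOM_LER"]]
  dp[is.na(dp)] <- 0
  gm <- geno_matrix(t(calls), t(dp),
                    data.frame(chrom = chrom[keep], pos = pos[keep],
                               ref = ref[keep], alt = alt[keep],
                               stringsAsFactors = FALSE),
                    samples = colnames(gt))
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as a multi-sample VCF
#'
#' GT:DP per genotype, 1-based positions, one contig line per chromosome.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @param specs Optional list of [chromosome_spec()] for contig lengths
#'   (defaults to the maximum marker position per chromosome).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, specs = NULL) {
  chroms <- unique(gm$markers$chrom)
  lens <- if (!is.null(specs)) {
    vapply(specs, function(s) s$length_bp, numeric(1))[chroms]
  } else {
    vapply(chroms, function(ch) max(gm$markers$pos[gm$markers$chrom == ch]),
           numeric(1))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=meiocross",
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(lens)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
  ok <- !is.na(gm$calls)
  gt[ok] <- gt_codes[gm$calls[ok] + 1L]
  cells <- matrix(paste0(gt, ":", gm$depth), nrow(gm$calls))
  body <- vapply(seq_len(nrow(gm$markers)), function(j) {
    paste(c(gm$markers$chrom[j], format(gm$markers$pos[j], scientific = FALSE),
            ".", gm$markers$ref[j], gm$markers$alt[j], ".", "PASS", ".",
            "GT:DP", cells[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write simulated crossover truth as TSV
#'
#' @param truth Truth data frame from [simulate_gametes()] /
#'   [build_population()] (`sample`, `chrom`, `pos`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write crossover events as BED-like TSV
#'
#' Columns `chrom`, `start` (= left_bp - 1), `end` (= right_bp), `sample`,
#' `mid_bp`: 0-based half-open intervals in the BED columns, 1-based
#' midpoint, as stated in the header line.
#'
#' @param events Event data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  lines <- c("# crossover breakpoint intervals; start/end 0-based half-open (BED), mid_bp 1-based",
             paste(c("chrom", "start", "end", "sample", "mid_bp"),
                   collapse = "\t"))
  if (nrow(events) > 0) {
    lines <- c(lines, paste(events$chrom,
                            format(events$left_bp - 1, scientific = FALSE, trim = TRUE),
                            format(events$right_bp, scientific = FALSE, trim = TRUE),
                            events$sample,
                            format(events$mid_bp, scientific = FALSE, trim = TRUE),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events_bed
#' @export
read_events_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  data.frame(sample = df$sample, chrom = df$chrom,
             left_bp = df$start + 1, right_bp = df$end, mid_bp = df$mid_bp,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
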