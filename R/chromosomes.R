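#' Chromosome specification
#'
#' Describes one chromosome for simulation and landscape binning: its
#' physical length, a piecewise-linear physical-to-genetic map, and an
#' optional pericentromeric interval used for annotation.
#'
#' @param name Chromosome label (e.g. `"Chr1"`).
#' @param length_bp Physical length in base pairs (> 0).
#' @param map_points Two-column matrix or data.frame of (bp, cM) anchors,
#'   strictly increasing in both coordinates, starting at (1, 0) and ending
#'   at `(length_bp, G)` where `G` is the genetic length in centimorgans.
#'   If `NULL`, a uniform map at `cm_per_mb` is built, with the recombination
#'   rate inside `pericentromere_bp` multiplied by `peri_factor`.
#' @param pericentromere_bp Optional length-2 vector `(start, end)` in bp.
#' @param cm_per_mb Base recombination rate used when `map_points` is `NULL`.
#' @param peri_factor Multiplier applied to `cm_per_mb` inside the
#'   pericentromere when building a default map (default 0.1, i.e. a
#'   10-fold suppression).
#'
#' @return An object of class `chromosome_spec`.
#' @export
chromosome_spec <- function(name, length_bp, map_points = NULL,
                            pericentromere_bp = NULL,
                            cm_per_mb = 1, peri_factor = 0.1) {
  stopifnot(length(name) == 1L, length(length_bp) == 1L, length_bp > 0)
  length_bp <- as.numeric(length_bp)
  if (!is.null(pericentromere_bp)) {
    stopifnot(length(pericentromere_bp) == 2L,
              pericentromere_bp[1] < pericentromere_bp[2],
              pericentromere_bp[1] >= 1, pericentromere_bp[2] <= length_bp)
  }
  if (is.null(map_points)) {
    map_points <- build_linear_map(length_bp, pericentromere_bp,
                                   cm_per_mb, peri_factor)
  }
  map_points <- as.matrix(map_points)
  if (ncol(map_points) != 2L) stop("map_points must have two columns (bp, cM)")
  colnames(map_points) <- c("bp", "cM")
  if (nrow(map_points) < 2L) stop("map_points needs at least two anchors")
  if (any(diff(map_points[, 1]) <= 0) || any(diff(map_points[, 2]) <= 0))
    stop("map_points must be strictly increasing in both coordinates")
  if (map_points[1, 1] != 1 || map_points[1, 2] != 0)
    stop("first map anchor must be (1, 0)")
  if (map_points[nrow(map_points), 1] != length_bp)
    stop("last map anchor must sit at length_bp")
  structure(
    list(name = as.character(name), length_bp = length_bp,
         map_points = map_points, pericentromere_bp = pericentromere_bp),
    class = "chromosome_spec"
  )
}

# uniform cM/Mb map with a rate-suppressed pericentromere
build_linear_map <- function(length_bp, peri, cm_per_mb, peri_factor) {
  r <- cm_per_mb / 1e6
  if (is.null(peri)) {
    return(cbind(bp = c(1, length_bp), cM = c(0, (length_bp - 1) * r)))
  }
  g1 <- (peri[1] - 1) * r
  g2 <- g1 + (peri[2] - peri[1]) * r * peri_factor
  g3 <- g2 + (length_bp - peri[2]) * r
  cbind(bp = c(1, peri[1], peri[2], length_bp), cM = c(0, g1, g2, g3))
}

#' Genetic length of a chromosome in cM
#' @param spec A [chromosome_spec()].
#' @return Genetic length (cM of the last map anchor).
#' @export
genetic_length <- function(spec) {
  spec$map_points[nrow(spec$map_points), "cM"]
}

#' Convert genetic positions to physical positions
#'
#' Piecewise-linear interpolation between the chromosome's map anchors,
#' rounded to integer bp. Inverse of [physical_to_genetic()] up to rounding.
#'
#' @param pos_cm Numeric vector of positions in cM, each in `[0, G]`.
#' @param spec A [chromosome_spec()].
#' @return Integer-valued bp positions in `[1, length_bp]`.
#' @export
genetic_to_physical <- function(pos_cm, spec) {
  G <- genetic_length(spec)
  if (length(pos_cm) == 0L) return(numeric(0))
  if (any(pos_cm < 0 | pos_cm > G))
    stop("genetic position outside [0, ", format(G), "] cM on ", spec$name)
  out <- stats::approx(spec$map_points[, "cM"], spec$map_points[, "bp"],
                       xout = pos_cm, ties = "ordered")$y
  round(out)
}

#' Convert physical positions to genetic positions
#' @param pos_bp Numeric vector of bp positions in `[1, length_bp]`.
#' @param spec A [chromosome_spec()].
#' @return Positions in cM.
#' @export
physical_to_genetic <- function(pos_bp, spec) {
  if (length(pos_bp) == 0L) return(numeric(0))
  if (any(pos_bp < 1 | pos_bp > spec$length_bp))
    stop("physical position outside [1, ", spec$length_bp, "] on ", spec$name)
  stats::approx(spec$map_points[, "bp"], spec$map_points[, "cM"],
                xout = pos_bp, ties = "ordered")$y
}

#' TAIR10-like Arabidopsis chromosome set
#'
#' Five chromosomes with the TAIR10 assembly lengths and approximate
#' pericentromeric intervals. Default genetic maps are uniform at
#' `cm_per_mb` with a 10-fold rate suppression inside the pericentromere,
#' qualitatively matching observed recombination landscapes.
#'
#' @inheritParams chromosome_spec
#' @return Named list of five [chromosome_spec()] objects.
#' @export
tair10_chromosomes <- function(cm_per_mb = 1, peri_factor = 0.1) {
  lens <- c(Chr1 = 30427671, Chr2 = 19698289, Chr3 = 23459830,
            Chr4 = 18585056, Chr5 = 26975502)
  peri <- list(Chr1 = c(12e6, 18e6), Chr2 = c(2e6, 8e6),
               Chr3 = c(11e6, 17e6), Chr4 = c(2e6, 7e6),
               Chr5 = c(10e6, 16e6))
  out <- lapply(names(lens), function(nm) {
    chromosome_spec(nm, lens[[nm]], pericentromere_bp = peri[[nm]],
                    cm_per_mb = cm_per_mb, peri_factor = peri_factor)
  })
  names(out) <- names(lens)
  out
}
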