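#' Construct a cytological point set
#'
#' A set of detected focus centroids (2D or 3D, coordinates in micrometres)
#' within a rectangular field of view.
#'
#' @param coords Matrix or data frame with columns `x`, `y` and optionally
#'   `z`, in micrometres.
#' @param bounds Field bounds: numeric vector `(xmin, xmax, ymin, ymax)`
#'   (and `zmin, zmax` for 3D). Defaults to the coordinate ranges.
#' @param label Channel label (e.g. `"red"`, `"green"`).
#' @return Object of class `point_set`.
#' @export
point_set <- function(coords, bounds = NULL, label = "") {
  coords <- as.matrix(as.data.frame(coords))
  stopifnot(ncol(coords) %in% c(2L, 3L), all(is.finite(coords)) || nrow(coords) == 0L)
  colnames(coords) <- c("x", "y", "z")[seq_len(ncol(coords))]
  if (is.null(bounds)) {
    bounds <- as.vector(rbind(apply(coords, 2, min), apply(coords, 2, max)))
    if (nrow(coords) == 0L) bounds <- rep(c(0, 1), ncol(coords))
  }
  stopifnot(length(bounds) == 2L * ncol(coords))
  structure(list(coords = coords, bounds = bounds, label = label),
            class = "point_set")
}

#' Read / write point sets as CSV
#'
#' CSV columns: `x`, `y` (optionally `z`) in micrometres and `channel`.
#'
#' @param path CSV file path.
#' @param bounds Optional field bounds passed to [point_set()].
#' @return Named list of [point_set()] objects, one per channel.
#' @export
read_point_sets <- function(path, bounds = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "channel") %in% names(df)))
  cols <- intersect(c("x", "y", "z"), names(df))
  sets <- lapply(split(df, df$channel), function(d)
    point_set(d[, cols, drop = FALSE], bounds = bounds,
              label = d$channel[1]))
  sets
}

#' @rdname read_point_sets
#' @param sets Named list of [point_set()] objects.
#' @export
write_point_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s) {
    d <- as.data.frame(s$coords)
    d$channel <- s$label
    d
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Focus colocalization by distance threshold
#'
#' A red focus overlaps if any green focus lies within `max_dist`
#' (Euclidean), and symmetrically for green; the reported percentages are
#' `100 * n_overlapping / n_total` per channel. A greedy one-to-one
#' nearest-pair matching (closest available pair first, within `max_dist`)
#' is reported for pair counts.
#'
#' @param red,green [point_set()] objects.
#' @param max_dist Maximum centroid distance in micrometres (default 0.33).
#' @return List `pct_red_overlapping`, `pct_green_overlapping` (`NA` when
#'   the respective set is empty), `n_red`, `n_green`, `pairs` (data frame
#'   `red_idx`, `green_idx`, `dist`).
#' @export
overlap_fraction <- function(red, green, max_dist = 0.33) {
  stopifnot(max_dist > 0)
  nr <- nrow(red$coords); ng <- nrow(green$coords)
  if (nr == 0L || ng == 0L) {
    # undefined against an empty partner: missing, never 0
    return(list(pct_red_overlapping = NA_real_,
                pct_green_overlapping = NA_real_,
                n_red = nr, n_green = ng,
                pairs = data.frame(red_idx = integer(0),
                                   green_idx = integer(0),
                                   dist = numeric(0))))
  }
  stopifnot(ncol(red$coords) == ncol(green$coords))
  d2 <- outer(rowSums(red$coords^2), rowSums(green$coords^2), "+") -
    2 * red$coords %*% t(green$coords)
  dm <- sqrt(pmax(d2, 0))
  red_hit <- apply(dm, 1, min) <= max_dist
  green_hit <- apply(dm, 2, min) <= max_dist
  pairs <- greedy_match(dm, max_dist)
  list(pct_red_overlapping = 100 * mean(red_hit),
       pct_green_overlapping = 100 * mean(green_hit),
       n_red = nr, n_green = ng, pairs = pairs)
}

greedy_match <- function(dm, max_dist) {
  pairs <- data.frame(red_idx = integer(0), green_idx = integer(0),
                      dist = numeric(0))
  dm <- as.matrix(dm)
  repeat {
    m <- which.min(dm)
    if (length(m) == 0L || dm[m] > max_dist) break
    i <- (m - 1) %% nrow(dm) + 1
    j <- (m - 1) %/% nrow(dm) + 1
    pairs <- rbind(pairs, data.frame(red_idx = i, green_idx = j,
                                     dist = dm[m]))
    dm[i, ] <- Inf
    dm[, j] <- Inf
    if (all(!is.finite(dm))) break
  }
  pairs
}

#' 90-degree rotation randomness control
#'
#' Recomputes the overlap statistic after rotating the green channel 90
#' degrees about the field centre. The rotation acts on field-normalized
#' coordinates (so points stay within a non-square field); for a square
#' field it is the rigid rotation, and four applications restore the
#' original set. The z coordinate (if any) is unchanged.
#'
#' @param red,green [point_set()] objects (green must carry field bounds).
#' @param max_dist Distance threshold in micrometres.
#' @return [overlap_fraction()] result against the rotated green set, with
#'   the rotated set attached as `rotated_green`.
#' @export
rotation_control <- function(red, green, max_dist = 0.33) {
  rg <- rotate_point_set(green)
  out <- overlap_fraction(red, rg, max_dist)
  out$rotated_green <- rg
  out
}

#' @rdname rotation_control
#' @param s A [point_set()].
#' @export
rotate_point_set <- function(s) {
  if (nrow(s$coords) == 0L) return(s)
  b <- s$bounds
  u <- (s$coords[, "x"] - b[1]) / (b[2] - b[1])
  v <- (s$coords[, "y"] - b[3]) / (b[4] - b[3])
  # (u, v) -> (1 - v, u): 90-degree rotation of the unit square
  coords <- s$coords
  coords[, "x"] <- b[1] + (1 - v) * (b[2] - b[1])
  coords[, "y"] <- b[3] + u * (b[4] - b[3])
  point_set(coords, bounds = b, label = paste0(s$label, "_rot90"))
}
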