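# Independent brute-force oracles and small fixture builders shared by the
# unit tests. These deliberately avoid the package's optimized code paths.

# brute-force sliding-window modal smoothing: enumerate every window,
# majority vote by explicit counting, same tie semantics as documented
brute_smooth <- function(calls, w) {
  M <- length(calls)
  if (M == 0L) return(integer(0))
  vote <- function(x) {
    n1 <- sum(x == 1L)
    n0 <- length(x) - n1
    if (n1 > n0) 1L else if (n0 > n1) 0L else NA_integer_
  }
  if (M < w) {
    v <- vote(calls)
    if (is.na(v)) v <- calls[1L]
    return(rep(v, M))
  }
  nw <- M - w + 1L
  win <- vapply(seq_len(nw), function(i) vote(calls[i:(i + w - 1L)]),
                integer(1))
  if (all(is.na(win))) {
    win[] <- calls[1L]
  } else {
    for (i in seq_len(nw)) {
      if (is.na(win[i])) next
      if (i > 1L && any(is.na(win[seq_len(i - 1L)]))) {
        win[seq_len(i - 1L)][is.na(win[seq_len(i - 1L)])] <- win[i]
      }
      break
    }
    for (i in seq_len(nw)) if (is.na(win[i])) win[i] <- win[i - 1L]
  }
  # marker m takes the window centred on it, clamped at the ends
  vapply(seq_len(M), function(m)
    win[min(max(m - (w - 1L) %/% 2L, 1L), nw)], integer(1))
}

# naive run scan: crossover count from a smoothed sequence
brute_events <- function(positions, smoothed) {
  if (length(smoothed) < 2L) return(NULL)
  out <- NULL
  for (i in seq_len(length(smoothed) - 1L)) {
    if (smoothed[i] != smoothed[i + 1L]) {
      out <- rbind(out, data.frame(left_bp = positions[i],
                                   right_bp = positions[i + 1L],
                                   mid_bp = floor((positions[i] +
                                                     positions[i + 1L]) / 2)))
    }
  }
  out
}

# naive tricube-weighted local polynomial regression (LOESS oracle)
brute_loess <- function(x, y, x0, span = 0.75, degree = 2) {
  n <- length(x)
  q <- min(n, floor(n * span + 1e-9))
  vapply(x0, function(xx) {
    d <- abs(x - xx)
    dq <- sort(d)[q]
    wts <- pmax(0, (1 - pmin(d / dq, 1)^3))^3
    use <- wts > 0
    X <- outer(x[use] - xx, 0:degree, "^")
    fit <- stats::lm.wfit(X, y[use], wts[use])
    fit$coefficients[1]
  }, numeric(1))
}

# sequential (type I) sums of squares for y ~ sex/genotype by explicit
# projection onto nested column spaces
brute_nested_ss <- function(y, sex, genotype) {
  proj <- function(X, y) X %*% qr.solve(crossprod(X), crossprod(X, y))
  n <- length(y)
  X0 <- matrix(1, n, 1)
  X1 <- stats::model.matrix(~sex)
  X2 <- stats::model.matrix(~ sex / genotype)
  f0 <- proj(X0, y); f1 <- proj(X1, y); f2 <- proj(X2, y)
  c(ss_sex = sum((f1 - f0)^2),
    ss_geno_in_sex = sum((f2 - f1)^2),
    ss_resid = sum((y - f2)^2))
}

# small genotype matrix straight from call/depth matrices on one chromosome
toy_gm <- function(calls, depth = NULL, pos = NULL, chrom = "Chr1") {
  calls <- as.matrix(calls)
  if (is.null(depth)) depth <- matrix(10L, nrow(calls), ncol(calls))
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000
  geno_matrix(calls, depth, data.frame(chrom = chrom, pos = pos),
              samples = paste0("S", seq_len(nrow(calls))))
}

# two tiny chromosomes for fast simulator-based tests
small_specs <- function() {
  list(ChrA = chromosome_spec("ChrA", 10e6),
       ChrB = chromosome_spec("ChrB", 8e6))
}

# per-gamete transmitted genome-wide CO count, truth-only (fast)
sim_transmitted_counts <- function(n, specs, model) {
  vapply(seq_len(n), function(i) {
    tot <- 0L
    for (spec in specs) {
      lam <- model$lambda_biv
      l <- if (length(lam) == 1L) lam else lam[[spec$name]]
      biv <- simulate_bivalent_crossovers(spec, l, model$nu,
                                          model$obligate_co)
      tot <- tot + length(thin_to_chromatid(biv))
    }
    tot
  }, integer(1))
}
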