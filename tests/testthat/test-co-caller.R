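HOM <- GENO[["HOM_COL"]]; HET <- GENO[["HET"]]

test_that("modal smoothing absorbs isolated errors and respects tie rules", {
  # constant sequence: unchanged
  expect_identical(smooth_genotypes(rep(HET, 25), w = 20), rep(HET, 25))

  # 40 markers: 1-20 HOM except marker 5 HET, 21-40 HET -> the isolated HET
  # is absorbed and the transition lands between markers 20 and 21
  calls <- c(rep(HOM, 20), rep(HET, 20))
  calls[5] <- HET
  sm <- smooth_genotypes(calls, w = 20)
  expect_identical(sm, c(rep(HOM, 20), rep(HET, 20)))
  expect_identical(sm, brute_smooth(calls, 20))

  # strictly alternating: every window tied -> whole sequence constant
  alt <- rep(c(HOM, HET), 20)
  sm2 <- smooth_genotypes(alt, w = 20)
  expect_true(length(unique(sm2)) == 1)
  expect_identical(sm2, brute_smooth(alt, 20))

  # fewer markers than the window: one window over all markers
  expect_identical(smooth_genotypes(c(HET, HET, HOM), w = 20),
                   rep(HET, 3))
  expect_identical(smooth_genotypes(integer(0), w = 20), integer(0))
  expect_error(smooth_genotypes(c(HET, NA), w = 20), "missing")
  expect_error(smooth_genotypes(rep(HET, 5), w = 20, s = 2), "step")
})

test_that("optimized smoothing and run scan agree exactly with the brute-force oracle", {
  set.seed(55)
  for (rep in seq_len(1000)) {
    M <- sample(1:200, 1)
    w <- sample(c(2, 3, 5, 10, 20, 21), 1)
    # block-structured sequences with noise: the realistic regime
    n_blocks <- sample(1:4, 1)
    bounds <- sort(sample(0:M, n_blocks - 1))
    lens <- diff(c(0, bounds, M))
    g <- unlist(mapply(rep, sample(c(HOM, HET), n_blocks, replace = TRUE),
                       lens, SIMPLIFY = FALSE))
    flip <- runif(M) < 0.1
    g[flip] <- 1L - g[flip]
    pos <- sort(sample.int(1e6, M))

    sm_fast <- smooth_genotypes(g, w = w)
    sm_brute <- brute_smooth(g, w)
    expect_identical(sm_fast, sm_brute)

    ev_fast <- call_crossovers(pos, sm_fast)
    ev_brute <- brute_events(pos, sm_brute)
    if (is.null(ev_brute)) {
      expect_equal(nrow(ev_fast), 0)
    } else {
      expect_equal(nrow(ev_fast), nrow(ev_brute))
      expect_equal(ev_fast$left_bp, ev_brute$left_bp)
      expect_equal(ev_fast$right_bp, ev_brute$right_bp)
      expect_equal(ev_fast$mid_bp, ev_brute$mid_bp)
    }
  }
})

test_that("crossover events carry flanking markers and floor midpoints", {
  calls <- c(rep(HOM, 20), rep(HET, 20))
  calls[5] <- HET
  pos <- seq(10000, by = 10000, length.out = 40) # marker 20 at 200000
  sm <- smooth_genotypes(calls, w = 20)
  ev <- call_crossovers(pos, sm)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$left_bp, 200000)
  expect_equal(ev$right_bp, 210000)
  expect_equal(ev$mid_bp, 205000)
  expect_equal(ev$left_genotype, "HOM_COL")
  expect_equal(ev$right_genotype, "HET")
  # constant sequence: no events
  expect_equal(nrow(call_crossovers(pos, rep(HET, 40))), 0)
  # odd bp sum floors the midpoint
  ev2 <- call_crossovers(c(100, 201), c(HOM, HET))
  expect_equal(ev2$mid_bp, 150)
})

test_that("short runs merge into their flanks under min_run_markers", {
  sm <- c(rep(HOM, 10), rep(HET, 2), rep(HOM, 10))
  pos <- seq_len(22) * 100
  expect_equal(nrow(call_crossovers(pos, sm, min_run_markers = 1)), 2)
  expect_equal(nrow(call_crossovers(pos, sm, min_run_markers = 3)), 0)
  # edge short run is absorbed by its single neighbour
  sm2 <- c(HET, rep(HOM, 15))
  expect_equal(nrow(call_crossovers(seq_len(16) * 10, sm2,
                                    min_run_markers = 2)), 0)
})

test_that("larger windows reduce the number of called events in aggregate", {
  # modal smoothing is not strictly monotone in w on every single input
  # (window-scale aliasing can occasionally split a run), but over noisy
  # sequences the event count decreases steeply with w
  set.seed(66)
  totals <- c(`5` = 0L, `10` = 0L, `20` = 0L, `40` = 0L)
  for (rep in seq_len(50)) {
    M <- sample(50:200, 1)
    g <- as.integer(runif(M) < 0.5)
    # make it blocky so events exist
    g <- stats::filter(g, rep(1, 5), sides = 1)
    g <- as.integer(!is.na(g) & g >= 3)
    pos <- sort(sample.int(1e6, M))
    totals <- totals + vapply(c(5, 10, 20, 40), function(w)
      nrow(call_crossovers(pos, smooth_genotypes(g, w = w))), integer(1))
  }
  expect_true(all(diff(totals) < 0))
})

test_that("noise-free calls recover every true crossover when spacing exceeds the window", {
  specs <- small_specs()
  m <- recombination_model("male", lambda_for_transmitted(specs, 3), nu = 1)
  obs <- observation_model(depth_mean = 50, depth_dropout = FALSE)
  mk <- marker_panel(specs, 1000) # ~1 marker / 18 kb
  pop <- build_population(60, specs, m, mk, obs, seed = 71)
  ev <- call_population_crossovers(pop$matrix, w = 20)
  w <- 20
  for (s in pop$matrix$samples) {
    for (ch in names(specs)) {
      true_co <- sort(pop$truth$pos[pop$truth$sample == s &
                                      pop$truth$chrom == ch])
      mpos <- mk$pos[mk$chrom == ch]
      # qualifying sample-chromosomes: every crossover > w markers from its
      # neighbours and from both chromosome ends
      ranks <- findInterval(true_co, mpos)
      qualifies <- length(true_co) == 0 ||
        (all(diff(c(0, ranks, length(mpos))) > w))
      if (!qualifies) next
      e <- ev[ev$sample == s & ev$chrom == ch, , drop = FALSE]
      expect_equal(nrow(e), length(true_co))
      if (length(true_co)) {
        expect_true(all(e$left_bp <= true_co & true_co <= e$right_bp))
      }
    }
  }
})

test_that("1-Mb binning uses (b-1)Mb < pos <= bMb and keeps partial bins", {
  specs <- list(c15 = chromosome_spec("c15", 15e6),
                c2 = chromosome_spec("c2", 2.5e6))
  none <- bin_landscape(data.frame(sample = character(0),
                                   chrom = character(0),
                                   mid_bp = numeric(0)), specs, 10)
  expect_true(all(none$count == 0))
  expect_equal(sum(none$chrom == "c2"), 3)
  expect_true(none$partial[none$chrom == "c2"][3])

  ev <- data.frame(sample = "a", chrom = "c15",
                   mid_bp = c(0.5e6, 1e6, 1.5e6, 14.9e6))
  l <- bin_landscape(ev, specs, 10)
  l15 <- l[l$chrom == "c15", ]
  expect_equal(l15$count[1], 2) # 0.5 Mb and the boundary point 1 Mb
  expect_equal(l15$count[2], 1)
  expect_equal(l15$count[15], 1)
  expect_equal(sum(l15$count), 4)
  expect_equal(l15$per_gamete, l15$count / 10)

  bad <- data.frame(sample = "a", chrom = "c2", mid_bp = 3e6)
  expect_error(bin_landscape(bad, specs, 10), "beyond")
})

test_that("per-sample counts include zero-event offspring", {
  ev <- data.frame(sample = c("A", "A", "A"),
                   chrom = c("Chr1", "Chr1", "Chr3"),
                   mid_bp = c(1, 2, 3))
  out <- per_sample_counts(ev, c("A", "B", "C"), c("Chr1", "Chr3"))
  expect_equal(out$total, c(3, 0, 0))
  expect_equal(out$Chr1, c(2, 0, 0))
  expect_equal(out$Chr3, c(1, 0, 0))
  empty <- per_sample_counts(ev[0, ], c("A", "B", "C"))
  expect_equal(empty$total, c(0, 0, 0))
})

test_that("population crossover counts recover simulated truth on clean dense data", {
  specs <- small_specs()
  m <- recombination_model("male", lambda_for_transmitted(specs, 4.8), nu = 5)
  obs <- observation_model(depth_mean = 50, depth_dropout = FALSE)
  pop <- build_population(200, specs, m, marker_panel(specs, 4000), obs,
                          seed = 83)
  ev <- call_population_crossovers(pop$matrix, w = 20)
  true_mean <- nrow(pop$truth) / 200
  called_mean <- nrow(ev) / 200
  # dense error-free markers: recovery within 3 s.e. of the truth
  se <- sd(table(factor(pop$truth$sample,
                        levels = pop$matrix$samples))) / sqrt(200)
  expect_lt(abs(called_mean - true_mean), 3 * se)
})
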