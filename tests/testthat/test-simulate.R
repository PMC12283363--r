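spec1 <- chromosome_spec("ChrA", 10e6) # 10 Mb, ~10 cM uniform map

test_that("zero-rate process yields no crossovers; bad nu rejected", {
  expect_identical(simulate_bivalent_crossovers(spec1, 0, 1), numeric(0))
  expect_identical(simulate_bivalent_crossovers(spec1, 0, 7), numeric(0))
  expect_error(simulate_bivalent_crossovers(spec1, 2, 1.5), "integer")
  expect_error(simulate_bivalent_crossovers(spec1, 2, 0), "integer")
  expect_error(recombination_model("male", 1, nu = 2.5), "integer")
})

test_that("nu = 1 counts are Poisson; nu = 5 counts are sub-Poisson", {
  set.seed(101)
  n <- 10000
  cnt1 <- vapply(seq_len(n), function(i)
    length(simulate_bivalent_crossovers(spec1, 2, 1)), integer(1))
  # mean within 3 s.e. of 2; index of dispersion within 3 s.e. of 1
  expect_lt(abs(mean(cnt1) - 2), 3 * sqrt(2 / n))
  disp1 <- var(cnt1) / mean(cnt1)
  expect_lt(abs(disp1 - 1), 3 * sqrt(2 / (n - 1)))
  # chi-square goodness of fit against Poisson(2), alpha = 0.01
  brk <- c(0:6, Inf)
  obs <- table(cut(cnt1, breaks = c(-1, 0:5, Inf)))
  p_exp <- diff(c(0, ppois(0:5, 2), 1))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = p_exp))
  expect_gt(gof$p.value, 0.01)

  cnt5 <- vapply(seq_len(n), function(i)
    length(simulate_bivalent_crossovers(spec1, 2, 5)), integer(1))
  expect_lt(abs(mean(cnt5) - 2), 3 * sqrt(var(cnt5) / n))
  expect_lt(var(cnt5) / mean(cnt5), 1)
})

test_that("chromatid thinning halves counts and keeps order and sign", {
  expect_identical(thin_to_chromatid(numeric(0)), numeric(0))
  set.seed(7)
  # single crossover retained with probability 1/2
  kept <- vapply(seq_len(10000), function(i)
    length(thin_to_chromatid(5)), integer(1))
  expect_true(all(kept %in% 0:1))
  expect_lt(abs(mean(kept) - 0.5), 3 * sqrt(0.25 / 10000))
  # genome-wide bivalent mean 9.6 -> transmitted mean 4.8
  trans <- vapply(seq_len(10000), function(i)
    length(thin_to_chromatid(sort(runif(rpois(1, 9.6), 0, 100)))), integer(1))
  expect_lt(abs(mean(trans) - 4.8), 3 * sd(trans) / sqrt(10000))
  # order preserved, output subset of input
  x <- sort(runif(50))
  y <- thin_to_chromatid(x)
  expect_true(all(y %in% x) && !is.unsorted(y))
  # sub-Poisson stays sub-Poisson after thinning
  t5 <- vapply(seq_len(10000), function(i)
    length(thin_to_chromatid(simulate_bivalent_crossovers(spec1, 4, 5))),
    integer(1))
  expect_lt(var(t5) / mean(t5), 1)
})

test_that("obligate crossover never emits empty bivalents and inflates mean", {
  set.seed(21)
  lens <- vapply(seq_len(2000), function(i)
    length(simulate_bivalent_crossovers(spec1, 0.5, 1, obligate_co = TRUE)),
    integer(1))
  expect_true(all(lens >= 1))
  expect_gt(mean(lens), 0.5)
  expect_error(simulate_bivalent_crossovers(spec1, 0, 1, obligate_co = TRUE))
})

test_that("meiocyte summaries count univalent pairs; zero-class matches Poisson", {
  expect_equal(summarize_meiocyte(c(2, 1, 1, 3, 2)),
               list(n_univalent_pairs = 0L, n_bivalents = 5L))
  expect_equal(summarize_meiocyte(c(0, 0, 1, 2, 1)),
               list(n_univalent_pairs = 2L, n_bivalents = 3L))
  set.seed(31)
  # nu = 1, per-chromosome lambda 2.4: P(>=1 univalent pair over 5 chrom)
  # has closed form 1 - (1 - exp(-2.4))^5
  n <- 10000
  any_uni <- vapply(seq_len(n), function(i) {
    cnt <- rpois(5, 2.4) # Poisson counts are the nu = 1 law
    summarize_meiocyte(cnt)$n_univalent_pairs >= 1
  }, logical(1))
  p_theory <- 1 - (1 - exp(-2.4))^5
  expect_lt(abs(mean(any_uni) - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / n))
  # and the simulator's own nu = 1 counts agree with that closed form
  m <- recombination_model("male", rep(2.4, 2), nu = 1)
  g <- simulate_gametes(3000, small_specs(), m)
  p_uni <- mean(apply(g$biv_counts, 1, function(x) any(x == 0)))
  p_th2 <- 1 - (1 - exp(-2.4))^2
  expect_lt(abs(p_uni - p_th2), 3 * sqrt(p_th2 * (1 - p_th2) / 3000))
})

test_that("noise-free observation reproduces the true genotype matrix", {
  specs <- small_specs()
  m <- recombination_model("male", lambda_for_transmitted(specs, 2), nu = 1)
  obs <- observation_model(depth_mean = 50, depth_dropout = FALSE)
  mk <- marker_panel(specs, 150)
  pop <- build_population(20, specs, m, mk, obs, seed = 5)
  expect_identical(pop$matrix$calls, pop$true_matrix$calls)
  expect_false(anyNA(pop$matrix$calls))
})

test_that("BC1 marker heterozygosity is ~25% Ler-allele frequency", {
  specs <- small_specs()
  m <- recombination_model("male", lambda_for_transmitted(specs, 2), nu = 1)
  obs <- observation_model(depth_mean = 50, depth_dropout = FALSE)
  mk <- marker_panel(specs, 100)
  pop <- build_population(1000, specs, m, mk, obs, seed = 9)
  het <- colMeans(pop$matrix$calls == GENO[["HET"]])
  # Ler allele frequency = het / 2; mean across markers ~ 0.25
  f_ler <- mean(het) / 2
  expect_lt(abs(f_ler - 0.25), 3 * sqrt(0.25 * 0.75 / (2 * 1000)))
  # and most markers fall inside the MAF (0.2, 0.3) acceptance window
  expect_gt(mean(het / 2 >= 0.2 & het / 2 <= 0.3), 0.9)
})

test_that("transmitted crossover mean matches the model target", {
  specs <- small_specs()
  m <- recombination_model("male", lambda_for_transmitted(specs, 4.8), nu = 1)
  set.seed(13)
  g <- simulate_gametes(1000, specs, m)
  per_sample <- table(factor(g$truth$sample, levels = g$samples))
  expect_lt(abs(mean(per_sample) - 4.8), 3 * sd(per_sample) / sqrt(1000))
})

test_that("populations are fully reproducible from the seed", {
  specs <- small_specs()
  m <- recombination_model("female", lambda_for_transmitted(specs, 3), nu = 2)
  obs <- observation_model(p_missing = 0.2, e_hom_ler = 0.05,
                           depth_mean = 1.3)
  mk <- marker_panel(specs, 200)
  a <- build_population(15, specs, m, mk, obs, seed = 77)
  b <- build_population(15, specs, m, mk, obs, seed = 77)
  expect_identical(a$matrix$calls, b$matrix$calls)
  expect_identical(a$matrix$depth, b$matrix$depth)
  expect_identical(a$truth, b$truth)
  expect_error(build_population(5, specs, m, mk[0, ], obs, seed = 1),
               "empty")
})

test_that("shallow-depth dropout converts depth-1 HETs to homozygous calls", {
  specs <- small_specs()[1]
  m <- recombination_model("male", 0, nu = 1) # no COs: start parent decides
  obs <- observation_model(depth_mean = 1, depth_dropout = TRUE)
  mk <- marker_panel(specs, 300)
  pop <- build_population(200, specs, m, mk, obs, seed = 19)
  # in LER-start samples every true call is HET; at depth 1 half should
  # drop to HOM_COL and half rise to the impossible HOM_LER call
  ler_rows <- pop$start_parent[, 1] == "LER"
  d1 <- pop$matrix$depth == 1 & matrix(ler_rows, nrow(pop$matrix$depth),
                                       ncol(pop$matrix$depth))
  calls_d1 <- pop$matrix$calls[d1]
  n <- sum(!is.na(calls_d1))
  f_col <- mean(calls_d1 == GENO[["HOM_COL"]], na.rm = TRUE)
  f_ler <- mean(calls_d1 == GENO[["HOM_LER"]], na.rm = TRUE)
  expect_lt(abs(f_col - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(f_ler - 0.5), 3 * sqrt(0.25 / n))
})
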