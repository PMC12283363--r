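#' Recombination model for one cohort
#'
#' Parameters of the gamma-renewal crossover process used by the simulator.
#' `nu = 1` gives a Poisson process (no interference); larger integer `nu`
#' gives increasingly regular, sub-Poisson crossover placement (stronger
#' interference).
#'
#' @param sex `"male"` or `"female"` (label only; rates are set via
#'   `lambda_biv`).
#' @param lambda_biv Named numeric vector of expected bivalent (meiocyte)
#'   crossover counts per chromosome. The mean count transmitted to a gamete
#'   is half of this (no chromatid interference). See
#'   [lambda_for_transmitted()].
#' @param nu Interference shape; integer >= 1.
#' @param obligate_co If `TRUE`, zero-crossover bivalents are redrawn until
#'   at least one crossover occurs. This conditioning inflates the realized
#'   mean above `lambda_biv`.
#' @param genotype Free-text cohort label (e.g. `"WT"`, `"mutant"`).
#'
#' @return An object of class `recombination_model`.
#' @export
recombination_model <- function(sex = c("male", "female"), lambda_biv,
                                nu = 1L, obligate_co = FALSE,
                                genotype = "WT") {
  sex <- match.arg(sex)
  if (length(nu) != 1L || is.na(nu) || nu != as.integer(nu) || nu < 1)
    stop("nu must be a single integer >= 1")
  if (any(lambda_biv < 0)) stop("lambda_biv must be >= 0")
  structure(list(sex = sex, genotype = genotype,
                 lambda_biv = lambda_biv, nu = as.integer(nu),
                 obligate_co = isTRUE(obligate_co)),
            class = "recombination_model")
}

#' Per-chromosome bivalent rates for a target transmitted mean
#'
#' Distributes a genome-wide transmitted (per-gamete) crossover mean over
#' chromosomes proportionally to genetic length, returning bivalent-scale
#' expectations (twice the transmitted values, since each crossover is
#' transmitted to a given chromatid with probability 1/2).
#'
#' @param specs List of [chromosome_spec()].
#' @param transmitted_mean Target genome-wide mean crossovers per gamete.
#' @return Named numeric vector of per-chromosome `lambda_biv`.
#' @export
lambda_for_transmitted <- function(specs, transmitted_mean) {
  g <- vapply(specs, genetic_length, numeric(1))
  2 * transmitted_mean * g / sum(g)
}

#' Sequencing observation model
#'
#' Error and missingness processes applied to true genotypes to emulate
#' shallow genotyping-by-sequencing of a BC1 population.
#'
#' @param p_missing Probability a call with non-zero depth is still missing.
#' @param e_het_to_hom Probability a HET call is miscalled HOM_COL.
#' @param e_hom_to_het Probability a HOM_COL call is miscalled HET.
#' @param e_hom_ler Probability any non-missing call is replaced by HOM_LER
#'   (the impossible-genotype artifact class).
#' @param depth_mean Expected reads per marker per sample (Poisson).
#' @param depth_dropout If `TRUE`, allele dropout is simulated from the
#'   depth: a true HET with depth `d` has its Ler read count drawn
#'   Binomial(d, 1/2); zero Ler reads are observed as HOM_COL and all-Ler
#'   reads as HOM_LER (so a depth-1 HET is observed HOM_COL or HOM_LER with
#'   equal probability). This is the dominant error mode at ~1-1.5x depth.
#'
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(p_missing = 0, e_het_to_hom = 0,
                              e_hom_to_het = 0, e_hom_ler = 0,
                              depth_mean = 1.25, depth_dropout = TRUE) {
  p <- c(p_missing, e_het_to_hom, e_hom_to_het, e_hom_ler)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  structure(list(p_missing = p_missing, e_het_to_hom = e_het_to_hom,
                 e_hom_to_het = e_hom_to_het, e_hom_ler = e_hom_ler,
                 depth_mean = depth_mean,
                 depth_dropout = isTRUE(depth_dropout)),
            class = "observation_model")
}

#' Simulate crossover positions on one bivalent
#'
#' Stationary gamma-renewal construction: a homogeneous Poisson process of
#' rate `nu * lambda / G` per cM is drawn on `[0, G]` and every `nu`-th
#' point is retained, with a uniformly random phase offset, so the expected
#' retained count is `lambda` and inter-crossover spacings follow a gamma
#' (Erlang) law with shape `nu`. `nu = 1` reduces to a Poisson process.
#'
#' @param spec A [chromosome_spec()].
#' @param lambda Expected bivalent crossover count on this chromosome.
#' @param nu Interference shape, integer >= 1.
#' @param obligate_co Redraw until at least one crossover (conditioning that
#'   inflates the realized mean).
#' @return Sorted numeric vector of crossover positions in cM.
#' @export
simulate_bivalent_crossovers <- function(spec, lambda, nu = 1L,
                                         obligate_co = FALSE) {
  if (length(nu) != 1L || is.na(nu) || nu != as.integer(nu) || nu < 1)
    stop("nu must be a single integer >= 1")
  if (lambda < 0) stop("lambda must be >= 0")
  G <- genetic_length(spec)
  if (lambda == 0) {
    if (obligate_co) stop("obligate_co with lambda = 0 cannot be satisfied")
    return(numeric(0))
  }
  repeat {
    n_pois <- stats::rpois(1L, nu * lambda)
    pts <- sort(stats::runif(n_pois, 0, G))
    phase <- sample.int(nu, 1L) - 1L # offset in {0, ..., nu-1}
    idx <- seq_len(n_pois)
    out <- pts[(idx - 1L) %% nu == phase]
    if (!obligate_co || length(out) >= 1L) return(out)
  }
}

#' Thin bivalent crossovers to one chromatid
#'
#' Each crossover involves two of the four chromatids, so a given transmitted
#' chromatid carries each crossover independently with probability 1/2 (no
#' chromatid interference). Order is preserved.
#'
#' @param positions Sorted numeric vector of bivalent crossover positions.
#' @return Subset of `positions` retained on the transmitted chromatid.
#' @export
thin_to_chromatid <- function(positions) {
  if (length(positions) == 0L) return(positions)
  positions[stats::runif(length(positions)) < 0.5]
}

#' Summarize a meiocyte's bivalent crossover counts
#'
#' @param counts Integer vector, one bivalent crossover count per chromosome.
#' @return List with `n_univalent_pairs` (chromosomes with zero crossovers,
#'   i.e. failure of the obligate crossover) and `n_bivalents`
#'   (`length(counts) - n_univalent_pairs`).
#' @export
summarize_meiocyte <- function(counts) {
  stopifnot(all(counts >= 0))
  n_uni <- sum(counts == 0)
  list(n_univalent_pairs = n_uni, n_bivalents = length(counts) - n_uni)
}

#' Simulate transmitted gametes (truth only)
#'
#' Runs the meiosis model without the genotype observation layer; used for
#' interference analyses and as ground truth for recovery tests.
#'
#' @param n_samples Number of gametes (BC1 offspring).
#' @param specs List of [chromosome_spec()].
#' @param model A [recombination_model()]; `model$lambda_biv` may be a named
#'   vector (matched to `specs` names) or a single value recycled.
#' @param sample_prefix Prefix for generated sample ids.
#' @return List with `truth` (data.frame `sample`, `chrom`, `pos` of
#'   transmitted crossovers in bp), `start_parent` (samples x chromosomes
#'   matrix, `"COL"`/`"LER"` at the chromosome start), `biv_counts`
#'   (samples x chromosomes matrix of meiocyte bivalent crossover counts)
#'   and `samples`.
#' @export
simulate_gametes <- function(n_samples, specs, model,
                             sample_prefix = "S") {
  stopifnot(n_samples > 0)
  lam <- model$lambda_biv
  if (length(lam) == 1L) lam <- stats::setNames(rep(lam, length(specs)),
                                                names(specs))
  if (is.null(names(lam))) names(lam) <- names(specs)
  samples <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))
  nch <- length(specs)
  biv_counts <- matrix(0L, n_samples, nch,
                       dimnames = list(samples, names(specs)))
  start_parent <- matrix("COL", n_samples, nch,
                         dimnames = list(samples, names(specs)))
  rows <- vector("list", n_samples * nch)
  k <- 0L
  for (i in seq_len(n_samples)) {
    for (j in seq_len(nch)) {
      spec <- specs[[j]]
      biv <- simulate_bivalent_crossovers(spec, lam[[spec$name]],
                                          model$nu, model$obligate_co)
      biv_counts[i, j] <- length(biv)
      trans_cm <- thin_to_chromatid(biv)
      start_parent[i, j] <- if (stats::runif(1) < 0.5) "COL" else "LER"
      k <- k + 1L
      if (length(trans_cm)) {
        rows[[k]] <- data.frame(sample = samples[i], chrom = spec$name,
                                pos = genetic_to_physical(trans_cm, spec),
                                stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(truth))
    truth <- data.frame(sample = character(0), chrom = character(0),
                        pos = numeric(0))
  rownames(truth) <- NULL
  list(truth = truth, start_parent = start_parent,
       biv_counts = biv_counts, samples = samples)
}

#' Convert simulated truth to a crossover event table
#'
#' Treats each true transmitted crossover position as an exactly localized
#' event (left = right = midpoint), so truth can be fed to the landscape and
#' interference routines directly.
#'
#' @param truth Data frame `sample`, `chrom`, `pos` from
#'   [simulate_gametes()].
#' @return Event data frame compatible with
#'   [call_population_crossovers()] output.
#' @export
events_from_truth <- function(truth) {
  data.frame(sample = truth$sample, chrom = truth$chrom,
             left_bp = truth$pos, right_bp = truth$pos, mid_bp = truth$pos,
             left_genotype = NA_character_, right_genotype = NA_character_,
             stringsAsFactors = FALSE)
}

#' Build an evenly spaced marker panel
#'
#' @param specs List of [chromosome_spec()].
#' @param n_markers Total marker count, apportioned to chromosomes in
#'   proportion to physical length and spaced evenly.
#' @return Data frame `chrom`, `pos`, `ref`, `alt`.
#' @export
marker_panel <- function(specs, n_markers = 10000) {
  lens <- vapply(specs, function(s) s$length_bp, numeric(1))
  n_per <- pmax(2L, round(n_markers * lens / sum(lens)))
  out <- do.call(rbind, lapply(seq_along(specs), function(j) {
    pos <- unique(round(seq(1, lens[j], length.out = n_per[j])))
    data.frame(chrom = specs[[j]]$name, pos = pos, stringsAsFactors = FALSE)
  }))
  out$ref <- "A"
  out$alt <- "T"
  rownames(out) <- NULL
  out
}

# true BC1 genotype at each marker given transmitted crossovers:
# segment parent flips at every crossover; Ler segments are HET in a Col
# backcross, Col segments HOM_COL.
true_calls_chrom <- function(marker_pos, co_pos, start_parent) {
  flips <- findInterval(marker_pos, sort(co_pos))
  parent_is_ler <- xor(start_parent == "LER", flips %% 2L == 1L)
  ifelse(parent_is_ler, GENO[["HET"]], GENO[["HOM_COL"]])
}

#' Simulate a BC1 population with observed genotypes
#'
#' Full generative model for one cohort: meiosis (gamma-renewal bivalent
#' crossovers, chromatid thinning), true marker genotypes, and the
#' sequencing observation layer (Poisson depth, optional allele dropout,
#' genotyping errors, missingness).
#'
#' @param n_samples Number of BC1 offspring.
#' @param specs List of [chromosome_spec()].
#' @param model A [recombination_model()].
#' @param markers Marker panel data frame (`chrom`, `pos`), e.g. from
#'   [marker_panel()].
#' @param obs An [observation_model()].
#' @param seed Optional integer; if given, `set.seed(seed)` is called so the
#'   population is fully reproducible.
#' @param sample_prefix Prefix for sample ids.
#' @return List with `matrix` (observed [geno_matrix()]), `truth`
#'   (transmitted crossover positions), `true_matrix` (error-free
#'   [geno_matrix()] at full depth), `biv_counts`, `start_parent`,
#'   `summaries` (per-sample [summarize_meiocyte()] results) and `model`,
#'   `obs` echoes.
#' @export
build_population <- function(n_samples, specs, model, markers, obs,
                             seed = NULL, sample_prefix = "S") {
  if (nrow(markers) == 0L) stop("marker panel is empty")
  if (!is.null(seed)) set.seed(seed)
  gam <- simulate_gametes(n_samples, specs, model, sample_prefix)
  samples <- gam$samples
  M <- nrow(markers)
  true_calls <- matrix(GENO[["HOM_COL"]], n_samples, M)
  for (j in seq_along(specs)) {
    nm <- specs[[j]]$name
    idx <- which(markers$chrom == nm)
    if (!length(idx)) next
    mpos <- markers$pos[idx]
    for (i in seq_len(n_samples)) {
      co <- gam$truth$pos[gam$truth$sample == samples[i] &
                            gam$truth$chrom == nm]
      true_calls[i, idx] <- true_calls_chrom(mpos, co, gam$start_parent[i, j])
    }
  }

  depth <- matrix(stats::rpois(n_samples * M, obs$depth_mean), n_samples, M)
  calls <- true_calls
  if (obs$depth_dropout) {
    het <- which(calls == GENO[["HET"]] & depth > 0)
    if (length(het)) {
      ler_reads <- stats::rbinom(length(het), depth[het], 0.5)
      calls[het[ler_reads == 0]] <- GENO[["HOM_COL"]]
      calls[het[ler_reads == depth[het]]] <- GENO[["HOM_LER"]]
    }
  }
  u <- matrix(stats::runif(n_samples * M), n_samples, M)
  flip_het <- calls == GENO[["HET"]] & u < obs$e_het_to_hom
  flip_hom <- calls == GENO[["HOM_COL"]] & u < obs$e_hom_to_het
  calls[flip_het] <- GENO[["HOM_COL"]]
  calls[flip_hom] <- GENO[["HET"]]
  if (obs$e_hom_ler > 0) {
    ler <- matrix(stats::runif(n_samples * M), n_samples, M) < obs$e_hom_ler
    calls[ler] <- GENO[["HOM_LER"]]
  }
  calls[depth == 0] <- NA
  if (obs$p_missing > 0) {
    mis <- matrix(stats::runif(n_samples * M), n_samples, M) < obs$p_missing
    calls[mis] <- NA
  }
  depth_true <- matrix(pmax(depth, 1L), n_samples, M)
  list(
    matrix = geno_matrix(calls, depth, markers, samples),
    true_matrix = geno_matrix(true_calls, depth_true, markers, samples),
    truth = gam$truth,
    biv_counts = gam$biv_counts,
    start_parent = gam$start_parent,
    summaries = apply(gam$biv_counts, 1, summarize_meiocyte),
    model = model, obs = obs
  )
}
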