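#' Load a run configuration
#'
#' Configurations are YAML (or an equivalent R list) with blocks:
#' `seed`, `output_dir`, either `simulation` (with `cohorts`, `markers`,
#' `observation`) or `input` (`vcf` path with a single cohort label),
#' `qc`, `smoothing`, `binning`, `interference`. Missing keys fall back to
#' the documented defaults. See `inst/extdata/demo_config.yaml`.
#'
#' @param config Path to a YAML file, or a list.
#' @return Normalized configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L, output_dir = NULL,
    qc = list(maf_range = c(0.2, 0.3), min_dp = 4, max_dp = 100,
              mean_dp_range = c(1, 1.5), depth_scope = "genotype",
              max_missing = 0.75, percentiles = c(0.05, 0.95)),
    smoothing = list(w = 20, min_run_markers = 1),
    binning = list(bin_size = 1e6),
    interference = list(n_perm = 500, d_max_mb = 15, span = 0.75,
                        degree = 2, scheme = "resample")
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (kk in names(defaults[[k]]))
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- defaults[[k]][[kk]]
  }
  if (is.null(config$simulation) && is.null(config$input))
    stop("config error: need a 'simulation' or an 'input' block")
  config
}

cohort_population <- function(cohort, specs, obs, markers, seed) {
  # YAML 1.1 readers coerce a bare `n:` key to FALSE; accept n_samples too
  n <- cohort$n_samples
  if (is.null(n)) n <- cohort$n
  if (is.null(n)) n <- cohort[["FALSE"]]
  if (is.null(n)) stop("cohort '", cohort$label, "' needs n_samples")
  lam <- if (!is.null(cohort$transmitted_mean)) {
    lambda_for_transmitted(specs, cohort$transmitted_mean)
  } else cohort$lambda_biv
  model <- recombination_model(
    sex = cohort$sex, lambda_biv = lam,
    nu = if (is.null(cohort$nu)) 1L else cohort$nu,
    obligate_co = isTRUE(cohort$obligate_co),
    genotype = if (is.null(cohort$genotype)) "WT" else cohort$genotype)
  build_population(n, specs, model, markers, obs, seed = seed,
                   sample_prefix = paste0(cohort$label, "_"))
}

#' Run the full crossover-mapping pipeline
#'
#' Executes: simulate (or read a VCF) -> QC -> smoothing + crossover calling
#' -> per-sample counts and 1-Mb landscapes -> interference statistics
#' (inter-crossover distances, permutation test, CoC curve with LOESS fit)
#' -> cross-cohort nested ANOVA when both sex and genotype vary. When
#' `config$output_dir` is set, all tables are written as TSV/BED, the
#' summary as JSON, and a log with versions, seed and thresholds.
#'
#' @param config Path to a YAML config or a list; see [load_config()].
#' @return Result bundle: per-cohort list (`population`, `qc`, `events`,
#'   `counts`, `landscape`, `distances`, `permutation`, `coc`, `coc_fit`)
#'   plus `anova`, `summary`, `config`.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  set.seed(config$seed)
  specs <- tair10_chromosomes()

  stage <- "simulate"
  cohorts <- tryCatch({
    if (!is.null(config$simulation)) {
      obs_cfg <- config$simulation$observation
      obs <- do.call(observation_model, if (is.null(obs_cfg)) list() else obs_cfg)
      n_mark <- if (is.null(config$simulation$markers)) 10000 else
        config$simulation$markers
      markers <- marker_panel(specs, n_mark)
      lapply(seq_along(config$simulation$cohorts), function(i) {
        co <- config$simulation$cohorts[[i]]
        pop <- cohort_population(co, specs, obs, markers,
                                 seed = config$seed + i)
        list(label = co$label, sex = co$sex,
             genotype = if (is.null(co$genotype)) "WT" else co$genotype,
             population = pop, matrix = pop$matrix)
      })
    } else {
      gm <- read_vcf(config$input$vcf)
      lab <- if (is.null(config$input$label)) "all" else config$input$label
      list(list(label = lab,
                sex = if (is.null(config$input$sex)) "male" else config$input$sex,
                genotype = if (is.null(config$input$genotype)) "WT" else
                  config$input$genotype,
                population = NULL, matrix = gm))
    }
  }, error = function(e) stop("[", stage, "] ", conditionMessage(e), call. = FALSE))

  qc_cfg <- config$qc
  res <- lapply(cohorts, function(co) {
    stage <- paste0("qc:", co$label)
    q <- tryCatch(
      run_qc(co$matrix, maf_range = qc_cfg$maf_range, min_dp = qc_cfg$min_dp,
             max_dp = qc_cfg$max_dp, mean_dp_range = qc_cfg$mean_dp_range,
             depth_scope = qc_cfg$depth_scope,
             max_missing = qc_cfg$max_missing,
             percentiles = qc_cfg$percentiles),
      error = function(e) stop("[", stage, "] ", conditionMessage(e),
                               call. = FALSE))
    stage <- paste0("call:", co$label)
    tryCatch({
      events <- call_population_crossovers(
        q$matrix, w = config$smoothing$w,
        min_run_markers = config$smoothing$min_run_markers)
      counts <- per_sample_counts(events, q$matrix$samples, names(specs))
      landscape <- bin_landscape(events, specs, length(q$matrix$samples),
                                 config$binning$bin_size)
      dists <- inter_co_distances(events)
      perm <- if (nrow(dists) > 0) {
        permutation_null(dists, events, n_perm = config$interference$n_perm,
                         seed = config$seed, scheme = config$interference$scheme)
      } else NULL
      coc <- coc_curve(events, specs, length(q$matrix$samples),
                       d_range = seq_len(config$interference$d_max_mb),
                       bin_size = config$binning$bin_size)
      coc_fit <- if (nrow(coc$pooled) >= config$interference$degree + 2) {
        loess_fit(coc$pooled$d_mb, coc$pooled$coc,
                  span = config$interference$span,
                  degree = config$interference$degree)
      } else NULL
      c(co, list(qc = q, events = events, counts = counts,
                 landscape = landscape, distances = dists,
                 permutation = perm, coc = coc, coc_fit = coc_fit))
    }, error = function(e) stop("[", stage, "] ", conditionMessage(e),
                                call. = FALSE))
  })
  names(res) <- vapply(res, `[[`, character(1), "label")

  sexes <- vapply(res, `[[`, character(1), "sex")
  genos <- vapply(res, `[[`, character(1), "genotype")
  anova <- NULL
  if (length(unique(sexes)) >= 2 && length(unique(genos)) >= 2) {
    y <- unlist(lapply(res, function(r) r$counts$total))
    sx <- rep(sexes, vapply(res, function(r) nrow(r$counts), integer(1)))
    gt <- rep(genos, vapply(res, function(r) nrow(r$counts), integer(1)))
    anova <- tryCatch(nested_anova(y, sx, gt), error = function(e) NULL)
  }

  summary <- list(
    seed = config$seed,
    cohorts = lapply(res, function(r) list(
      label = r$label, sex = r$sex, genotype = r$genotype,
      n_samples = length(r$qc$matrix$samples),
      n_markers = nrow(r$qc$matrix$markers),
      mean_co = mean(r$counts$total),
      permutation_p = if (is.null(r$permutation)) NA else r$permutation$p_value,
      n_double_co_chromosomes = nrow(r$distances),
      mean_inter_co_distance_mb = if (nrow(r$distances)) {
        mean(r$distances$distance_bp) / 1e6
      } else NA
    )),
    coc = lapply(res, function(r) r$coc$pooled),
    thresholds = config[c("qc", "smoothing", "binning", "interference")]
  )

  bundle <- list(cohorts = res, anova = anova, summary = summary,
                 config = config, specs = specs)
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in bundle$cohorts) {
    pre <- file.path(dir, r$label)
    write_tsv(r$qc$report, paste0(pre, "_qc_report.tsv"))
    write_events_bed(r$events, paste0(pre, "_events.bed"))
    write_tsv(r$counts, paste0(pre, "_counts.tsv"))
    write_tsv(r$landscape, paste0(pre, "_landscape.tsv"))
    write_tsv(r$distances, paste0(pre, "_inter_co_distances.tsv"))
    write_tsv(r$coc$points, paste0(pre, "_coc.tsv"))
    if (!is.null(r$permutation)) {
      write_tsv(data.frame(
        observed_mean = r$permutation$observed_mean,
        p_value = r$permutation$p_value, n_perm = r$permutation$n_perm,
        scheme = r$permutation$scheme,
        n_instances = r$permutation$n_instances,
        direction = r$permutation$direction),
        paste0(pre, "_permutation.tsv"))
    }
    if (!is.null(r$population)) {
      write_vcf(r$matrix, paste0(pre, "_simulated.vcf"), bundle$specs)
      write_truth_tsv(r$population$truth, paste0(pre, "_truth.tsv"))
    }
  }
  if (!is.null(bundle$anova)) {
    tab <- as.data.frame(bundle$anova$table)
    tab <- cbind(term = trimws(rownames(tab)), tab)
    write_tsv(tab, file.path(dir, "anova_table.tsv"))
    write_tsv(bundle$anova$tukey, file.path(dir, "tukey.tsv"))
  }
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  writeLines(c(
    paste("meiocross", as.character(utils::packageVersion("meiocross"))),
    R.version.string,
    paste("seed:", bundle$config$seed),
    paste("config:", jsonlite::toJSON(
      bundle$config[c("qc", "smoothing", "binning", "interference")],
      auto_unbox = TRUE))
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Plot a recombination landscape
#'
#' Crossovers per gamete in 1-Mb windows along each chromosome, with
#' pericentromeric intervals shaded.
#'
#' @param landscape Output of [bin_landscape()].
#' @param specs List of [chromosome_spec()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_landscape <- function(landscape, specs, ...) {
  op <- graphics::par(mfrow = c(length(specs), 1),
                      mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (spec in specs) {
    l <- landscape[landscape$chrom == spec$name, ]
    graphics::plot((l$start_bp + l$end_bp) / 2e6, l$per_gamete, type = "h",
                   xlab = "position (Mb)", ylab = "COs per gamete",
                   main = spec$name, ...)
    if (!is.null(spec$pericentromere_bp)) {
      graphics::rect(spec$pericentromere_bp[1] / 1e6, 0,
                     spec$pericentromere_bp[2] / 1e6,
                     max(l$per_gamete, 0.01),
                     col = grDevices::adjustcolor("blue", 0.1), border = NA)
    }
  }
  invisible(NULL)
}

#' Plot coefficient of coincidence curves
#'
#' Per-chromosome CoC points with the pooled LOESS fit; the horizontal line
#' at 1 marks absence of interference.
#'
#' @param coc Output of [coc_curve()].
#' @param fit Optional [loess_fit()] result to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_coc <- function(coc, fit = NULL, ...) {
  graphics::plot(coc$points$d_mb, coc$points$coc,
                 col = as.integer(factor(coc$points$chrom)),
                 xlab = "inter-interval distance (Mb)", ylab = "CoC", ...)
  graphics::abline(h = 1, lty = 2, col = "grey")
  if (!is.null(fit))
    graphics::lines(fit$fit$x, fit$fit$fitted, lwd = 2)
  invisible(NULL)
}
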