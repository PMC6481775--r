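#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Either
#' `synthetic = TRUE` (with a [synthetic_config()]) or a phenotype
#' table path must be supplied; SNPs, coordinates and SNP weights are
#' optional and enable the distance stage.
#'
#' @param phenotypes path to a phenotype CSV/TSV, or `NULL` in
#'   synthetic mode.
#' @param snps optional path to a SNP TSV (see [read_snp_table()]).
#' @param coords optional path to a coordinates CSV.
#' @param snp_weights optional path to a two-column CSV
#'   (`marker_id, effect`) of per-marker effect sizes for the top-SNP
#'   subset.
#' @param synthetic use the synthetic-data generator instead of input
#'   files.
#' @param synthetic_config a [synthetic_config()] (synthetic mode).
#' @param n_boot bootstrap resamples for heterosis classification.
#' @param seed integer seed recorded in every output and governing the
#'   bootstrap (and the generator in synthetic mode).
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phenotypes = NULL, snps = NULL, coords = NULL,
                            snp_weights = NULL, synthetic = is.null(phenotypes),
                            synthetic_config = NULL, n_boot = 1000,
                            seed = 1L, out_dir = NULL) {
  if (!synthetic && is.null(phenotypes))
    stop("either a phenotype table or synthetic mode is required")
  if (synthetic && is.null(synthetic_config))
    synthetic_config <- allohet::synthetic_config(seed = seed)
  structure(list(phenotypes = phenotypes, snps = snps, coords = coords,
                 snp_weights = snp_weights, synthetic = synthetic,
                 synthetic_config = synthetic_config,
                 n_boot = n_boot, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `synthetic_config` mapping is passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic_config))
    y$synthetic_config <- do.call(synthetic_config, y$synthetic_config)
  do.call(pipeline_config, y)
}

#' Run the full heterosis-from-allometry analysis
#'
#' Stages, mirroring the analysis flow: (1) load or simulate replicate
#' phenotypes and validate them; (2) aggregate to genotype means; (3)
#' fit the growth and fruit allometries separately on accessions and
#' hybrids, with AIC comparison against the simpler alternative form
#' and SMA regression of log10 growth on log10 mass; (4) measure
#' per-hybrid MPH/BPH, classify hybrids by bootstrap against parental
#' values, and estimate broad-sense heritability per trait; (5) predict
#' heterosis from parental masses via NLDev (accession-fitted models)
#' and compare predictions with observations; (6) if genotype and/or
#' coordinate data are available, compute distance matrices and regress
#' heterosis on parental distances. A structured report (list / JSON)
#' plus CSV tables are produced; the seed is recorded in the report.
#'
#' @param config a `pipeline_config` (or YAML path).
#' @return The report, a nested list with elements `meta`, `data`,
#'   `allometry`, `heterosis`, `nldev`, and optionally `distances`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(meta = list(package_version = as.character(
    utils::packageVersion("allohet")), seed = config$seed,
    mode = if (config$synthetic) "synthetic" else "files"))

  ## stage: io ---------------------------------------------------------
  if (config$synthetic) {
    cohort <- simulate_cohort(config$synthetic_config,
                              genotypes = is.null(config$snps))
    records <- validate_phenotypes(cohort$phenotypes)
    snps <- cohort$snps
    coords <- cohort$coords
  } else {
    records <- read_phenotypes(config$phenotypes)
    snps <- if (!is.null(config$snps)) read_snp_table(config$snps) else NULL
    coords <- if (!is.null(config$coords)) read.csv(config$coords) else NULL
  }
  val <- attr(records, "validation")
  report$data <- list(n_records = nrow(records),
                      n_excluded = val$n_read - val$n_kept,
                      n_accessions = length(unique(
                        records$genotype_id[records$type == "accession"])),
                      n_hybrids = length(unique(
                        records$genotype_id[records$type == "hybrid"])))
  summaries <- summarize_genotypes(records)
  acc <- summaries[summaries$type == "accession", ]
  hyb <- summaries[summaries$type == "hybrid", ]

  ## stage: allometry --------------------------------------------------
  fit_set <- function(d, label) {
    okg <- is.finite(d$mass_mg) & is.finite(d$growth_mg_per_d)
    okf <- is.finite(d$mass_mg) & is.finite(d$fruit_n)
    growth <- fit_growth_allometry(d$mass_mg[okg], d$growth_mg_per_d[okg],
                                   fitted_on = label)
    growth_fixed <- fit_growth_allometry(d$mass_mg[okg], d$growth_mg_per_d[okg],
                                         form = "power_fixed", fitted_on = label)
    fruit <- fit_fruit_allometry(d$mass_mg[okf], d$fruit_n[okf],
                                 fitted_on = label)
    ricker <- tryCatch(fit_fruit_allometry(d$mass_mg[okf], d$fruit_n[okf],
                                           form = "ricker", fitted_on = label),
                       error = function(e) NULL)
    sma <- fit_sma(log10(d$mass_mg[okg]), log10(d$growth_mg_per_d[okg]))
    slope_test <- test_sma_slope(sma, 0.75, log10(d$mass_mg[okg]),
                                 log10(d$growth_mg_per_d[okg]))
    list(growth = growth, growth_fixed = growth_fixed,
         fruit = fruit, ricker = ricker, sma = sma,
         summary = list(
           growth_coefficients = as.list(growth$coefficients),
           fruit_coefficients = as.list(fruit$coefficients),
           delta_aic_growth = compare_models_aic(growth, growth_fixed),
           delta_aic_fruit = if (!is.null(ricker))
             compare_models_aic(fruit, ricker) else NA,
           sma_slope = sma$slope, sma_r2 = sma$r2,
           sma_p_vs_three_quarters = slope_test$p_value))
  }
  fits <- list(accessions = fit_set(acc, "accessions"),
               hybrids = fit_set(hyb, "hybrids"))
  report$allometry <- lapply(fits, `[[`, "summary")

  ## stage: heterosis --------------------------------------------------
  het <- heterosis_table(summaries)
  cls <- classify_heterosis(records, n_boot = config$n_boot,
                            seed = config$seed)
  cls_sum <- summarize_classification(cls)
  herit <- lapply(c("mass_mg", "age_d", "growth_mg_per_d", "fruit_n"),
                  function(tr) heritability(records, tr))
  report$heterosis <- list(
    classification_percent = cls_sum,
    heritability = setNames(lapply(herit, function(h)
      list(h2 = h$h2, var_genotype = h$var_genotype,
           var_residual = h$var_residual)),
      vapply(herit, `[[`, "", "trait")))

  ## stage: nldev ------------------------------------------------------
  nld <- list(
    growth_mg_per_d = nldev_table(fits$accessions$growth, summaries),
    fruit_n = nldev_table(fits$accessions$fruit, summaries))
  cmp <- lapply(names(nld), function(tr) {
    obs <- setNames(hyb[[tr]], hyb$genotype_id)
    compare_predictions(nld[[tr]], het[het$trait == tr, ], obs)
  })
  names(cmp) <- names(nld)
  report$nldev <- lapply(cmp, function(d)
    setNames(as.list(d$r2), d$comparison))

  ## stage: distances --------------------------------------------------
  dist_out <- NULL
  if (!is.null(snps) || !is.null(coords)) {
    dist_out <- list()
    het_growth <- het[het$trait == "growth_mg_per_d", ]
    par_ids <- cbind(hyb$parent1, hyb$parent2)[
      match(het_growth$hybrid_id, hyb$genotype_id), , drop = FALSE]
    if (!is.null(snps)) {
      filt <- filter_snps(snps)
      gd <- genetic_distance_matrix(filt)
      dist_out$genetic <- gd
      report$distances$snp_filter <- attr(filt, "filter_report")
      have <- par_ids[, 1] %in% rownames(gd) & par_ids[, 2] %in% rownames(gd)
      dvec <- rep(NA_real_, nrow(par_ids))
      dvec[have] <- gd[par_ids[have, , drop = FALSE]]
      ld <- ifelse(dvec > 0, log10(dvec), NA)
      reg <- tryCatch(regress_heterosis_on_distance(ld, het_growth$mph),
                      error = function(e) NULL)
      if (!is.null(reg))
        report$distances$genetic_vs_growth_mph <-
          list(r2 = reg$r2, r2_linear = reg$linear$r2,
               p_quadratic = unname(reg$p_values["quadratic"]))
    }
    if (!is.null(coords)) {
      gg <- geographic_distance_matrix(coords)
      dist_out$geographic <- gg
      if (!is.null(snps) && !is.null(dist_out$genetic)) {
        common <- intersect(rownames(dist_out$genetic), rownames(gg))
        ut <- upper.tri(gg[common, common])
        report$distances$cor_genetic_geographic <-
          cor(dist_out$genetic[common, common][ut], gg[common, common][ut])
      }
    }
    dist_out$phenotypic_mass <- phenotypic_distance_matrix(acc, mode = "mass")
  }

  ## outputs -----------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
    write.csv(het, file.path(config$out_dir, "heterosis.csv"),
              row.names = FALSE)
    write.csv(cls, file.path(config$out_dir, "heterosis_classes.csv"),
              row.names = FALSE)
    for (tr in names(nld))
      write.csv(nld[[tr]], file.path(config$out_dir,
                                     paste0("nldev_", tr, ".csv")),
                row.names = FALSE)
    write_allometric_model(fits$accessions$growth,
                           file.path(config$out_dir, "growth_model.json"))
    write_allometric_model(fits$accessions$fruit,
                           file.path(config$out_dir, "fruit_model.json"))
    if (!is.null(dist_out))
      for (k in names(dist_out))
        write_distance_matrix(dist_out[[k]],
                              file.path(config$out_dir,
                                        paste0("distance_", k, ".csv")))
  }
  invisible(structure(c(report, list(
    fits = fits, heterosis_values = het, classification = cls,
    nldev_tables = nld, comparisons = cmp, distance_matrices = dist_out)),
    class = "allohet_report"))
}

#' @export
print.allohet_report <- function(x, ...) {
  cat("allohet pipeline report (seed ", x$meta$seed, ", ",
      x$meta$mode, " mode)\n", sep = "")
  cat(sprintf("  %d records: %d accessions, %d hybrids\n",
              x$data$n_records, x$data$n_accessions, x$data$n_hybrids))
  ga <- x$allometry$accessions
  cat(sprintf("  accession growth allometry: a %.3g, b %.3g, c %.3g (dAIC %.1f vs fixed exponent)\n",
              ga$growth_coefficients$a, ga$growth_coefficients$b,
              ga$growth_coefficients$c, ga$delta_aic_growth))
  cat(sprintf("  SMA slope %.3f (r2 %.3f)\n", ga$sma_slope, ga$sma_r2))
  for (tr in names(x$nldev))
    cat(sprintf("  NLDev (%s): r2 pred %.2f, MP %.2f, BP %.2f\n", tr,
                x$nldev[[tr]]$pred_vs_obs, x$nldev[[tr]]$nldev_mp_vs_mph,
                x$nldev[[tr]]$nldev_bp_vs_bph))
  invisible(x)
}
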