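#' Configuration for the synthetic phenotyping design
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate a two-experiment design: inbred accessions phenotyped with two
#' replicates and F1 hybrids (crosses among those accessions) with four
#' replicates. Vegetative dry mass is lognormal, spanning roughly 1 to
#' 2,000 mg; growth rate follows a power law with mass-corrected exponent
#' with tight multiplicative noise; fruit number follows an inverse
#' quadratic (hump-shaped) allometry with much looser noise. Hybrid mass
#' is near-additive: mid-parent mass times `1 + delta`, with `delta`
#' drawn from a Normal whose default mean is negative, so that negative
#' mass heterosis predominates.
#'
#' @param n_accessions number of inbred accessions.
#' @param n_hybrids number of hybrids (distinct parent pairs).
#' @param replicates_accession,replicates_hybrid replicate plants per
#'   genotype in each experiment.
#' @param mass_log10_mean,mass_log10_sd mean and sd of log10 vegetative
#'   dry mass (mg) across genotypes.
#' @param growth_coeffs named numeric `c(a, b, c)` of the generative
#'   growth allometry `g(M) = a * M^(b + c*log10(M))` (mg/d vs mg).
#' @param fruit_coeffs named numeric `c(a, b, c)` of the generative fruit
#'   allometry `f(M) = M / (a + b*M + c*M^2)` (count vs mg).
#' @param growth_noise_sd,fruit_noise_sd sd of the multiplicative
#'   lognormal trait noise on the log10 scale.
#' @param hybrid_mass_dev_mean,hybrid_mass_dev_sd distribution of the
#'   fractional deviation of hybrid mass from the mid-parent mass.
#' @param hybrid_trait_dev_sd optional extra log10-scale deviation applied
#'   to hybrid growth/fruit on top of the shared allometry (default 0;
#'   useful for null experiments).
#' @param replicate_cv within-genotype coefficient of variation of the
#'   replicate-level measurements.
#' @param n_markers number of biallelic SNP markers.
#' @param snp_gradient strength of the latent spatial allele-frequency
#'   gradient (0 = no isolation-by-distance structure).
#' @param snp_missing_rate per-call missingness probability.
#' @param seed integer seed governing all draws; deterministic sub-streams
#'   are derived per stage.
#' @return An object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_accessions = 20, n_hybrids = 10, seed = 1)
#' acc <- simulate_accessions(cfg)
#' @export
synthetic_config <- function(n_accessions = 451,
                             n_hybrids = 450,
                             replicates_accession = 2,
                             replicates_hybrid = 4,
                             mass_log10_mean = 1.6,
                             mass_log10_sd = 0.7,
                             growth_coeffs = c(a = 0.022, b = 1.483, c = -0.164),
                             fruit_coeffs = c(a = 0.155, b = 0.0022, c = 1.292e-5),
                             growth_noise_sd = 0.05,
                             fruit_noise_sd = 0.3,
                             hybrid_mass_dev_mean = -0.05,
                             hybrid_mass_dev_sd = 0.15,
                             hybrid_trait_dev_sd = 0,
                             replicate_cv = 0.1,
                             n_markers = 500,
                             snp_gradient = 2,
                             snp_missing_rate = 0,
                             seed = 1L) {
  counts <- c(n_accessions = n_accessions, n_hybrids = n_hybrids,
              replicates_accession = replicates_accession,
              replicates_hybrid = replicates_hybrid, n_markers = n_markers)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  nonneg <- c(mass_log10_sd = mass_log10_sd, growth_noise_sd = growth_noise_sd,
              fruit_noise_sd = fruit_noise_sd, replicate_cv = replicate_cv,
              hybrid_mass_dev_sd = hybrid_mass_dev_sd,
              hybrid_trait_dev_sd = hybrid_trait_dev_sd)
  if (any(nonneg < 0)) stop("sd and cv parameters must be >= 0")
  growth_coeffs <- .coerce_coeffs(growth_coeffs)
  fruit_coeffs <- .coerce_coeffs(fruit_coeffs)
  if (growth_coeffs[["a"]] <= 0 || fruit_coeffs[["a"]] <= 0)
    stop("coefficient 'a' of both allometries must be > 0")
  if (snp_missing_rate < 0 || snp_missing_rate >= 1)
    stop("snp_missing_rate must be in [0, 1)")
  if (abs(seed) >= 2^31) stop("seed must be a 32-bit integer")
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_hybrids = as.integer(n_hybrids),
              replicates_accession = as.integer(replicates_accession),
              replicates_hybrid = as.integer(replicates_hybrid),
              mass_log10_mean = mass_log10_mean,
              mass_log10_sd = mass_log10_sd,
              growth_coeffs = growth_coeffs,
              fruit_coeffs = fruit_coeffs,
              growth_noise_sd = growth_noise_sd,
              fruit_noise_sd = fruit_noise_sd,
              hybrid_mass_dev_mean = hybrid_mass_dev_mean,
              hybrid_mass_dev_sd = hybrid_mass_dev_sd,
              hybrid_trait_dev_sd = hybrid_trait_dev_sd,
              replicate_cv = replicate_cv,
              n_markers = as.integer(n_markers),
              snp_gradient = snp_gradient,
              snp_missing_rate = snp_missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

.coerce_coeffs <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3 || any(!is.finite(x)))
    stop("allometry coefficients must be three finite numbers (a, b, c)")
  names(x) <- c("a", "b", "c")
  x
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic phenotyping design\n")
  cat(sprintf("  %d accessions x %d reps, %d hybrids x %d reps, seed %d\n",
              x$n_accessions, x$replicates_accession,
              x$n_hybrids, x$replicates_hybrid, x$seed))
  cat(sprintf("  M ~ 10^N(%.2f, %.2f) mg; noise sd (log10): growth %.3g, fruit %.3g\n",
              x$mass_log10_mean, x$mass_log10_sd,
              x$growth_noise_sd, x$fruit_noise_sd))
  invisible(x)
}

# deterministic per-stage sub-seeds, kept inside 32-bit integer range
.stage_seed <- function(seed, stage) {
  offsets <- c(accessions = 101L, hybrids = 211L, snps = 307L,
               coords = 401L, series = 503L)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

.growth_curve <- function(coeffs) {
  force(coeffs)
  function(M) coeffs[["a"]] * M^(coeffs[["b"]] + coeffs[["c"]] * log10(M))
}

.fruit_curve <- function(coeffs) {
  force(coeffs)
  function(M) M / (coeffs[["a"]] + coeffs[["b"]] * M + coeffs[["c"]] * M^2)
}

# lognormal replicate jitter with a given coefficient of variation
.rep_jitter <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

# genotype-level true trait values; resamples non-finite/nonpositive draws
.draw_genotype_traits <- function(M, cfg, max_retry = 50L) {
  g <- .growth_curve(cfg$growth_coeffs)
  f <- .fruit_curve(cfg$fruit_coeffs)
  n <- length(M)
  growth <- g(M) * 10^rnorm(n, 0, cfg$growth_noise_sd)
  fruit <- f(M) * 10^rnorm(n, 0, cfg$fruit_noise_sd)
  bad <- which(!is.finite(growth) | growth <= 0 |
               !is.finite(fruit))
  tries <- 0L
  while (length(bad) && tries < max_retry) {
    growth[bad] <- g(M[bad]) * 10^rnorm(length(bad), 0, cfg$growth_noise_sd)
    fruit[bad] <- f(M[bad]) * 10^rnorm(length(bad), 0, cfg$fruit_noise_sd)
    bad <- which(!is.finite(growth) | growth <= 0 | !is.finite(fruit))
    tries <- tries + 1L
  }
  if (length(bad))
    stop("could not draw finite positive traits after ", max_retry,
         " retries; check growth_coeffs/fruit_coeffs at M = ",
         paste(signif(M[bad[1]], 4)))
  fruit <- pmax(fruit, 1)  # floor guards degenerate tails only
  list(growth = growth, fruit = fruit)
}

# expand genotype-level truth into replicate rows
.make_replicates <- function(ids, type, parent1, parent2, experiment,
                             M, growth, fruit, n_rep, cv) {
  idx <- rep(seq_along(ids), each = n_rep)
  n <- length(idx)
  mass_r <- M[idx] * .rep_jitter(n, cv)
  growth_r <- growth[idx] * .rep_jitter(n, cv)
  fruit_r <- pmax(round(fruit[idx] * .rep_jitter(n, cv)), 1)
  data.frame(genotype_id = ids[idx],
             type = type,
             parent1 = parent1[idx],
             parent2 = parent2[idx],
             experiment = experiment,
             replicate = rep(seq_len(n_rep), times = length(ids)),
             mass_mg = mass_r,
             age_d = mass_r / growth_r,  # definitional: growth = M / age
             growth_mg_per_d = growth_r,
             fruit_n = fruit_r,
             stringsAsFactors = FALSE)
}

#' Simulate replicate-level accession phenotypes
#'
#' Draws a genotype-level true vegetative dry mass
#' `M = 10^Normal(mass_log10_mean, mass_log10_sd)` per accession, then
#' growth rate and fruit number from the generative allometries with
#' multiplicative lognormal noise. Age at reproduction is derived as
#' `M / growth`, so the definitional identity `growth = M / age` holds
#' exactly for true values (and for replicates, whose age is recomputed
#' from the jittered mass and growth). Fruit counts are floored at 1.
#'
#' @param config a [synthetic_config()].
#' @return A `data.frame` of replicate records with columns
#'   `genotype_id, type, parent1, parent2, experiment, replicate,
#'   mass_mg, age_d, growth_mg_per_d, fruit_n`, with the genotype-level
#'   truth attached as attribute `"truth"`.
#' @export
simulate_accessions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.stage_seed(config$seed, "accessions"))
  n <- config$n_accessions
  ids <- sprintf("acc%03d", seq_len(n))
  M <- 10^rnorm(n, config$mass_log10_mean, config$mass_log10_sd)
  tr <- .draw_genotype_traits(M, config)
  rec <- .make_replicates(ids, "accession", rep(NA_character_, n),
                          rep(NA_character_, n), "Exp1",
                          M, tr$growth, tr$fruit,
                          config$replicates_accession, config$replicate_cv)
  attr(rec, "truth") <- data.frame(genotype_id = ids, mass_mg = M,
                                   growth_mg_per_d = tr$growth,
                                   fruit_n = tr$fruit,
                                   stringsAsFactors = FALSE)
  rec
}

#' Simulate replicate-level hybrid phenotypes from accession parents
#'
#' Samples `n_hybrids` distinct parent pairs without replacement, sets
#' each hybrid's true mass to the mid-parent mass times `1 + delta`,
#' `delta ~ Normal(hybrid_mass_dev_mean, hybrid_mass_dev_sd)`, and draws
#' growth rate and fruit number from the *same* allometric curves and
#' noise as the accessions — the structural assumption under test: any
#' heterosis of growth or fruit then emerges from the curvature of the
#' shared allometry, not from trait-level hybrid effects. An optional
#' `hybrid_trait_dev_sd` adds trait-level deviations for null
#' experiments.
#'
#' @param parents accession records from [simulate_accessions()] (the
#'   genotype-level truth attribute is used when present, otherwise
#'   replicate means).
#' @param config a [synthetic_config()].
#' @return Replicate records as in [simulate_accessions()], `type`
#'   `"hybrid"`, with parent ids filled and a `"truth"` attribute.
#' @export
simulate_hybrids <- function(parents, config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- attr(parents, "truth")
  if (is.null(truth)) {
    truth <- aggregate(mass_mg ~ genotype_id, data = parents, FUN = mean)
  }
  ids <- truth$genotype_id
  if (length(ids) < 2) stop("need at least 2 accessions to cross")
  n_pairs_avail <- choose(length(ids), 2)
  if (config$n_hybrids > n_pairs_avail)
    stop("n_hybrids (", config$n_hybrids, ") exceeds available distinct pairs (",
         n_pairs_avail, ")")
  set.seed(.stage_seed(config$seed, "hybrids"))
  pairs <- .sample_pairs(length(ids), config$n_hybrids)
  p1 <- ids[pairs[, 1]]; p2 <- ids[pairs[, 2]]
  mass <- setNames(truth$mass_mg, truth$genotype_id)
  delta <- rnorm(config$n_hybrids, config$hybrid_mass_dev_mean,
                 config$hybrid_mass_dev_sd)
  delta <- pmax(delta, -0.95)  # keep masses positive
  M12 <- (mass[p1] + mass[p2]) / 2 * (1 + delta)
  tr <- .draw_genotype_traits(M12, config)
  if (config$hybrid_trait_dev_sd > 0) {
    tr$growth <- tr$growth * 10^rnorm(length(M12), 0, config$hybrid_trait_dev_sd)
    tr$fruit <- pmax(tr$fruit * 10^rnorm(length(M12), 0, config$hybrid_trait_dev_sd), 1)
  }
  hid <- sprintf("hyb%03d", seq_len(config$n_hybrids))
  rec <- .make_replicates(hid, "hybrid", p1, p2, "Exp2",
                          M12, tr$growth, tr$fruit,
                          config$replicates_hybrid, config$replicate_cv)
  attr(rec, "truth") <- data.frame(genotype_id = hid, parent1 = p1, parent2 = p2,
                                   delta = delta, mass_mg = unname(M12),
                                   growth_mg_per_d = unname(tr$growth),
                                   fruit_n = unname(tr$fruit),
                                   stringsAsFactors = FALSE)
  rec
}

# sample k unordered distinct pairs from n items without replacement
.sample_pairs <- function(n, k) {
  total <- choose(n, 2)
  if (total <= 5e5) {
    all_pairs <- t(utils::combn(n, 2))
    all_pairs[sample.int(total, k), , drop = FALSE]
  } else {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, k, 2); got <- 0L
    while (got < k) {
      p <- sort(sample.int(n, 2))
      key <- paste(p, collapse = "-")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        out[got, ] <- p
      }
    }
    out
  }
}

#' Simulate genotype coordinates
#'
#' Uniform longitude/latitude over a Eurasian-like window; used as the
#' latent spatial positions for the SNP generator and as input to the
#' geographic distance functions.
#'
#' @param config a [synthetic_config()].
#' @param ids genotype ids (defaults to the accession ids of `config`).
#' @return `data.frame(genotype_id, longitude, latitude)`.
#' @export
simulate_coordinates <- function(config, ids = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(ids)) ids <- sprintf("acc%03d", seq_len(config$n_accessions))
  set.seed(.stage_seed(config$seed, "coords"))
  data.frame(genotype_id = ids,
             longitude = runif(length(ids), -10, 60),
             latitude = runif(length(ids), 35, 65),
             stringsAsFactors = FALSE)
}

#' Simulate a biallelic SNP matrix with isolation-by-distance structure
#'
#' Homozygous inbred genotypes are coded 0/1. Each marker's allele
#' frequency follows a logistic function of the genotypes' projection on
#' a random geographic direction, scaled by `snp_gradient`; with a
#' nonzero gradient, pairwise genetic distance correlates positively
#' with geographic distance, and with `snp_gradient = 0` the expected
#' correlation is zero. Optional missingness (`NA`) exercises the
#' call-rate filter downstream.
#'
#' @param config a [synthetic_config()].
#' @param coords coordinates as returned by [simulate_coordinates()].
#' @return Integer matrix (genotypes x markers, dimnames set) with
#'   values 0/1/NA.
#' @export
simulate_snp_matrix <- function(config, coords) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.stage_seed(config$seed, "snps"))
  n <- nrow(coords); m <- config$n_markers
  xy <- scale(as.matrix(coords[, c("longitude", "latitude")]))
  theta <- runif(m, 0, 2 * pi)
  proj <- xy %*% rbind(cos(theta), sin(theta))       # n x m projections
  alpha <- rnorm(m, 0, 0.5)
  p <- 1 / (1 + exp(-(alpha + config$snp_gradient *
                        sweep(proj, 2, runif(m, 0.2, 1), `*`))))
  calls <- matrix(rbinom(n * m, 1L, p), n, m)
  if (config$snp_missing_rate > 0) {
    calls[runif(n * m) < config$snp_missing_rate] <- NA_integer_
  }
  dimnames(calls) <- list(coords$genotype_id, sprintf("m%05d", seq_len(m)))
  calls
}

#' Simulate a logistic growth trajectory
#'
#' Rosette mass over time follows `K / (1 + exp(-r * (t - t0)))` plus
#' additive Gaussian measurement noise; the inflection at `t = t0` has
#' mass `K/2`.
#'
#' @param true_K asymptotic mass (mg), > 0.
#' @param true_t0 inflection time (d).
#' @param true_r growth rate constant (per d), > 0.
#' @param times at least 5 measurement times (d).
#' @param noise_sd sd of additive measurement noise (mg).
#' @param seed optional integer seed.
#' @return `data.frame(time_d, mass_mg)`.
#' @export
simulate_growth_series <- function(true_K, true_t0, true_r, times,
                                   noise_sd = 0, seed = NULL) {
  if (true_K <= 0 || true_r <= 0) stop("K and r must be > 0")
  if (length(times) < 5) stop("need at least 5 time points")
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  mu <- true_K / (1 + exp(-true_r * (times - true_t0)))
  data.frame(time_d = times, mass_mg = mu + rnorm(length(times), 0, noise_sd))
}

#' Simulate a full accession + hybrid cohort
#'
#' Convenience wrapper running [simulate_accessions()] and
#' [simulate_hybrids()] (and optionally coordinates and SNPs) under one
#' seed. The same seed and config always yield identical tables.
#'
#' @param config a [synthetic_config()].
#' @param genotypes if `TRUE`, also simulate coordinates and a SNP
#'   matrix for the accessions.
#' @return list with `phenotypes` (row-bound accession + hybrid
#'   records), `accessions`, `hybrids`, and optionally `coords`, `snps`.
#' @export
simulate_cohort <- function(config, genotypes = FALSE) {
  acc <- simulate_accessions(config)
  hyb <- simulate_hybrids(acc, config)
  out <- list(phenotypes = rbind(acc, hyb), accessions = acc, hybrids = hyb)
  if (genotypes) {
    out$coords <- simulate_coordinates(config)
    out$snps <- simulate_snp_matrix(config, out$coords)
  }
  out
}

#' Write synthetic genotype tables to disk
#'
#' Writes the SNP matrix as TSV (`genotype_id` then one 0/1/NA column
#' per marker) and coordinates as CSV.
#'
#' @param snps matrix from [simulate_snp_matrix()].
#' @param coords data frame from [simulate_coordinates()].
#' @param snp_path,coords_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_genotype_tables <- function(snps, coords, snp_path, coords_path) {
  df <- data.frame(genotype_id = rownames(snps), snps, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(coords, coords_path, row.names = FALSE)
  invisible(c(snp_path, coords_path))
}

#' Read a SNP table written by [write_genotype_tables()]
#' @param path TSV path with `genotype_id` then marker columns.
#' @return integer matrix with genotype rownames.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$genotype_id
  m
}
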