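test_that("config validation rejects bad parameters", {
  expect_error(synthetic_config(n_accessions = 0), "counts")
  expect_error(synthetic_config(growth_noise_sd = -1), ">= 0")
  expect_error(synthetic_config(growth_coeffs = c(a = -1, b = 1, c = 0)), "'a'")
  expect_s3_class(synthetic_config(n_accessions = 5, n_hybrids = 2), "synthetic_config")
})

test_that("same seed and config give byte-identical tables", {
  cfg <- synthetic_config(n_accessions = 30, n_hybrids = 20, seed = 5)
  a <- simulate_cohort(cfg, genotypes = TRUE)
  b <- simulate_cohort(cfg, genotypes = TRUE)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$snps, b$snps)
  expect_identical(a$coords, b$coords)
  # a different seed changes the draw
  c2 <- simulate_accessions(synthetic_config(n_accessions = 30,
                                             n_hybrids = 20, seed = 6))
  expect_false(identical(a$accessions$mass_mg, c2$mass_mg))
})

test_that("noise-free accessions lie exactly on the generative curves", {
  cfg <- synthetic_config(n_accessions = 120, n_hybrids = 10,
                          growth_noise_sd = 0, fruit_noise_sd = 0,
                          replicate_cv = 0, seed = 2)
  acc <- simulate_accessions(cfg)
  expect_equal(acc$growth_mg_per_d, g_ref(acc$mass_mg), tolerance = 1e-12)
  # definitional identity growth * age = M, exact with replicate_cv = 0
  expect_equal(acc$growth_mg_per_d * acc$age_d, acc$mass_mg, tolerance = 1e-12)
  # refitting recovers the generative coefficients
  m <- fit_growth_allometry(acc$mass_mg, acc$growth_mg_per_d)
  expect_equal(unname(coef(m)), unname(ACC_GROWTH), tolerance = 1e-6)
  tr <- attr(acc, "truth")
  f <- fit_fruit_allometry(tr$mass_mg, tr$fruit_n)
  expect_equal(unname(coef(f)), unname(ACC_FRUIT), tolerance = 1e-6)
})

test_that("sampled masses span the observed biological range", {
  cfg <- synthetic_config(n_accessions = 400, n_hybrids = 10, seed = 9)
  M <- attr(simulate_accessions(cfg), "truth")$mass_mg
  # plausibility band around the observed 1.3-2,218 mg span
  expect_gt(min(M), 0.1)
  expect_lt(min(M), 15)
  expect_gt(max(M), 500)
  expect_lt(max(M), 50000)
})

test_that("hybrid mass is exactly mid-parent when deviation and noise are off", {
  cfg <- synthetic_config(n_accessions = 20, n_hybrids = 15,
                          hybrid_mass_dev_mean = 0, hybrid_mass_dev_sd = 0,
                          growth_noise_sd = 0, fruit_noise_sd = 0,
                          replicate_cv = 0, seed = 3)
  acc <- simulate_accessions(cfg)
  hyb <- simulate_hybrids(acc, cfg)
  ta <- attr(acc, "truth"); th <- attr(hyb, "truth")
  mass <- setNames(ta$mass_mg, ta$genotype_id)
  expect_equal(th$mass_mg, (mass[th$parent1] + mass[th$parent2]) / 2,
               ignore_attr = TRUE, tolerance = 1e-12)
  # downstream MPH of mass is zero for every hybrid
  s <- summarize_genotypes(rbind(acc, hyb))
  ht <- heterosis_table(s, "mass_mg")
  expect_equal(ht$mph, rep(0, nrow(ht)), tolerance = 1e-12)
  expect_error(simulate_hybrids(acc, synthetic_config(n_accessions = 20,
                                                      n_hybrids = 1000)),
               "exceeds")
})

test_that("negative mass-deviation mean yields mostly negative mass MPH", {
  cfg <- synthetic_config(n_accessions = 200, n_hybrids = 1200, seed = 11)
  stopifnot(cfg$hybrid_mass_dev_mean < 0)
  acc <- simulate_accessions(cfg)
  hyb <- simulate_hybrids(acc, cfg)
  s <- summarize_genotypes(validate_phenotypes(rbind(acc, hyb)))
  ht <- heterosis_table(s, "mass_mg")
  expect_gt(mean(ht$mph < 0, na.rm = TRUE), 0.5)
})

test_that("accessions and hybrids share the conditional trait law given mass", {
  cfg <- synthetic_config(n_accessions = 400, n_hybrids = 400,
                          hybrid_mass_dev_mean = 0, seed = 7)
  acc <- simulate_accessions(cfg); hyb <- simulate_hybrids(acc, cfg)
  ta <- attr(acc, "truth"); th <- attr(hyb, "truth")
  # trait residuals around the shared curve are identically distributed
  ra <- log10(ta$growth_mg_per_d / g_ref(ta$mass_mg))
  rh <- log10(th$growth_mg_per_d / g_ref(th$mass_mg))
  expect_gt(suppressWarnings(stats::ks.test(ra, rh)$p.value), 0.01)
  fa <- log10(ta$fruit_n / f_ref(ta$mass_mg))
  fh <- log10(th$fruit_n / f_ref(th$mass_mg))
  expect_gt(suppressWarnings(stats::ks.test(fa, fh)$p.value), 0.01)
  # hybrid trait values occupy the accession phenotypic range
  expect_gt(mean(th$growth_mg_per_d >= min(ta$growth_mg_per_d) &
                   th$growth_mg_per_d <= max(ta$growth_mg_per_d)), 0.95)
})

test_that("trait noise defaults give tight growth and loose fruit scatter", {
  cfg <- synthetic_config(n_accessions = 400, n_hybrids = 10, seed = 13)
  tr <- attr(simulate_accessions(cfg), "truth")
  r2 <- function(obs, fit) cor(log10(obs), log10(fit))^2
  expect_gt(r2(tr$growth_mg_per_d, g_ref(tr$mass_mg)), 0.9)
  expect_lt(r2(tr$fruit_n, f_ref(tr$mass_mg)),
            r2(tr$growth_mg_per_d, g_ref(tr$mass_mg)))
})

test_that("SNP generator produces isolation-by-distance structure", {
  cfg <- synthetic_config(n_accessions = 200, n_hybrids = 10,
                          n_markers = 2000, seed = 17)
  coords <- simulate_coordinates(cfg)
  snps <- simulate_snp_matrix(cfg, coords)
  expect_true(all(snps %in% c(0L, 1L)))
  gd <- genetic_distance_matrix(snps)
  gg <- geographic_distance_matrix(coords)
  ut <- upper.tri(gd)
  ct <- cor.test(gd[ut], gg[ut])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # no spatial structure -> negligible correlation
  cfg0 <- synthetic_config(n_accessions = 120, n_hybrids = 10,
                           n_markers = 800, snp_gradient = 0, seed = 19)
  coords0 <- simulate_coordinates(cfg0)
  gd0 <- genetic_distance_matrix(simulate_snp_matrix(cfg0, coords0))
  gg0 <- geographic_distance_matrix(coords0)
  expect_lt(abs(cor(gd0[upper.tri(gd0)], gg0[upper.tri(gg0)])), 0.1)
})

test_that("SNP missingness lowers call rates as configured", {
  cfg <- synthetic_config(n_accessions = 300, n_hybrids = 10, n_markers = 200,
                          snp_missing_rate = 0.2, seed = 23)
  snps <- simulate_snp_matrix(cfg, simulate_coordinates(cfg))
  expect_equal(mean(is.na(snps)), 0.2, tolerance = 0.02)
})

test_that("logistic growth series has the right midpoint, asymptote and refit", {
  t <- seq(0, 60, by = 2)
  s <- simulate_growth_series(100, 20, 0.3, t, noise_sd = 0)
  expect_equal(s$mass_mg[s$time_d == 20], 50)
  expect_equal(s$mass_mg[s$time_d == 60], 100, tolerance = 1e-4)
  fit <- fit_sigmoid_growth(s$time_d, s$mass_mg)
  expect_equal(c(fit$K, fit$t0, fit$r), c(100, 20, 0.3), tolerance = 1e-6)
  expect_equal(fit$mass_at_inflection, 50, tolerance = 1e-6)
  expect_error(simulate_growth_series(100, 20, 0.3, c(1, 2)), "5 time points")
  expect_error(simulate_growth_series(-1, 20, 0.3, t), "> 0")
})

test_that("genotype tables round-trip through TSV/CSV", {
  cfg <- synthetic_config(n_accessions = 10, n_hybrids = 5, n_markers = 20,
                          snp_missing_rate = 0.1, seed = 29)
  coords <- simulate_coordinates(cfg)
  snps <- simulate_snp_matrix(cfg, coords)
  tsv <- tempfile(fileext = ".tsv"); csv <- tempfile(fileext = ".csv")
  write_genotype_tables(snps, coords, tsv, csv)
  back <- read_snp_table(tsv)
  expect_identical(unname(back), unname(snps))
  expect_identical(rownames(back), rownames(snps))
})
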