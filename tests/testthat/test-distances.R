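test_that("SNP filter removes designed failures from a toy matrix", {
  set.seed(1)
  m <- matrix(rep(c(0L, 1L), each = 5), nrow = 10, ncol = 10)  # MAF 0.5
  rownames(m) <- sprintf("g%02d", 1:10)
  colnames(m) <- sprintf("mk%02d", 1:10)
  m[, 2] <- 0L                       # monomorphic: MAF 0
  m[, 5] <- c(rep(0L, 9), 1L)        # MAF 0.1 -> passes at 0.05
  m[1:2, 7] <- NA                    # call rate 0.8 < 0.85
  m[9:10, 9] <- c(NA, NA)            # call rate 0.8 < 0.85
  m[, 3] <- c(1L, rep(0L, 9))        # MAF 0.1, passes; 3 designed failures
  out <- filter_snps(m)
  expect_equal(ncol(out), 7)
  expect_false(any(c("mk02", "mk07", "mk09") %in% colnames(out)))
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_before, 10)
  expect_equal(rep$n_after, 7)
  # marker exactly at the call-rate threshold is retained
  m2 <- matrix(rep(c(0L, 1L), 10), nrow = 20, ncol = 2,
               dimnames = list(sprintf("a%02d", 1:20), c("x", "y")))
  m2[1:3, 2] <- NA  # call rate 0.85 exactly
  expect_equal(ncol(filter_snps(m2)), 2)
  m2[4, 2] <- NA    # 0.80 < 0.85
  expect_equal(colnames(filter_snps(m2)), "x")
  expect_warning(filter_snps(m2, maf_min = 0.9), "no markers")
})

test_that("genetic distance counts two alleles per differing homozygous site", {
  m <- rbind(g1 = c(0L, 1L, 1L), g2 = c(0L, 1L, 0L), g3 = c(0L, 1L, 1L))
  colnames(m) <- c("s1", "s2", "s3")
  expect_equal(genetic_distance(m, "g1", "g2"), 2)  # 1 differing site
  expect_equal(genetic_distance(m, "g1", "g3"), 0)  # identical rows
  expect_equal(genetic_distance(m, "g1", "g2", per_site = TRUE), 1)
  expect_error(genetic_distance(m, "g1", "nope"), "not present")
  # missing calls are skipped pairwise-complete
  m2 <- rbind(a = c(0L, NA, 1L, 1L), b = c(1L, 0L, NA, 0L))
  expect_equal(genetic_distance(m2, "a", "b"), 2 * 2)  # sites 1 and 4 differ
})

test_that("matrix form matches the brute-force per-site oracle", {
  set.seed(5)
  for (i in 1:5) {
    n <- sample(4:10, 1); p <- sample(20:50, 1)
    m <- matrix(sample(c(0L, 1L, NA), n * p, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), n, p,
                dimnames = list(sprintf("g%d", 1:n), sprintf("s%d", 1:p)))
    d <- genetic_distance_matrix(m)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
    for (j in 1:(n - 1)) for (k in (j + 1):n) {
      a <- m[j, ]; b <- m[k, ]
      ok <- !is.na(a) & !is.na(b)
      expect_equal(d[j, k], 2 * sum(a[ok] != b[ok]))
      expect_equal(d[j, k], genetic_distance(m, rownames(m)[j], rownames(m)[k]))
    }
  }
})

test_that("top-SNP subset ranks by absolute effect with deterministic ties", {
  w <- setNames(c(-5, 4, 3, rep(0.1, 97)), sprintf("snp%03d", 1:100))
  expect_equal(top_snp_subset(w, 0.01), "snp001")
  expect_equal(sort(top_snp_subset(w, 0.02)), c("snp001", "snp002"))
  # all-equal weights: ties broken by marker id
  weq <- setNames(rep(1, 100), sprintf("snp%03d", 100:1))
  expect_equal(top_snp_subset(weq, 0.01), "snp001")
  expect_error(top_snp_subset(w, 0), "fraction")
  expect_error(top_snp_subset(w, 1.5), "fraction")
})

test_that("geographic distance is a great circle on the mean-radius sphere", {
  co <- data.frame(genotype_id = c("a", "b", "c"),
                   longitude = c(0, 1, 0), latitude = c(0, 0, 0))
  expect_equal(geographic_distance(co, "a", "c"), 0)
  # one degree of longitude at the equator: 2*pi*6371/360
  expect_equal(geographic_distance(co, "a", "b"), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_equal(geographic_distance(co, "a", "b"),
               geographic_distance(co, "b", "a"))
  d <- geographic_distance_matrix(co)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  bad <- data.frame(genotype_id = "x", longitude = 200, latitude = 0)
  expect_error(geographic_distance_matrix(bad), "out of range")
})

test_that("phenotypic distances behave as metrics in both modes", {
  cfg <- synthetic_config(n_accessions = 30, n_hybrids = 5, seed = 53)
  s <- summarize_genotypes(simulate_accessions(cfg))
  d <- phenotypic_distance_matrix(s)
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0) && all(diag(d) == 0))
  # triangle inequality on random triples
  set.seed(5)
  for (i in 1:50) {
    ijk <- sample(rownames(d), 3)
    expect_lte(d[ijk[1], ijk[2]],
               d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-12)
  }
  # mass mode is the absolute mass difference
  dm <- phenotypic_distance_matrix(s, mode = "mass")
  i <- rownames(dm)[1]; j <- rownames(dm)[2]
  mi <- s$mass_mg[s$genotype_id == i]; mj <- s$mass_mg[s$genotype_id == j]
  expect_equal(dm[i, j], abs(mi - mj))
  # identical trait vectors -> zero distance
  s2 <- rbind(s[1, ], s[1, ]); s2$genotype_id <- c("u", "v")
  expect_equal(phenotypic_distance(rbind(s, s2), "u", "v"), 0,
               tolerance = 1e-12)
})

test_that("quadratic heterosis-distance regression detects curvature and its absence", {
  set.seed(8)
  d <- runif(300, 0, 10)
  # exactly linear response: quadratic term is null
  lin <- suppressWarnings(regress_heterosis_on_distance(d, 0.5 + 0.2 * d))
  expect_equal(unname(lin$coefficients["quadratic"]), 0, tolerance = 1e-9)
  expect_equal(unname(lin$linear$coefficients["linear"]), 0.2, tolerance = 1e-9)
  # hump with an optimum at d0 = 6
  h <- -(d - 6)^2 + rnorm(300, 0, 1)
  hump <- regress_heterosis_on_distance(d, h)
  expect_lt(unname(hump$coefficients["quadratic"]), 0)
  expect_lt(unname(hump$p_values["quadratic"]), 0.01)
  d0_hat <- -hump$coefficients["linear"] / (2 * hump$coefficients["quadratic"])
  expect_equal(unname(d0_hat), 6, tolerance = 0.1)
  expect_error(regress_heterosis_on_distance(d[1:5], h[1:5]), "10 matched")
  expect_error(regress_heterosis_on_distance(rep(1, 20), rnorm(20)),
               "degenerate")
})

test_that("distance matrices export to long-format CSV", {
  m <- rbind(g1 = c(0L, 1L), g2 = c(1L, 1L), g3 = c(0L, 0L))
  colnames(m) <- c("s1", "s2")
  d <- genetic_distance_matrix(m)
  path <- tempfile(fileext = ".csv")
  write_distance_matrix(d, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$value[back$id1 == "g1" & back$id2 == "g2"], 2)
})
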