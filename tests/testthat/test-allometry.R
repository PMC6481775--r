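test_that("noise-free data refit to the generative coefficients", {
  M <- mass_grid(200)
  gm <- fit_growth_allometry(M, g_ref(M))
  expect_equal(unname(coef(gm)), unname(ACC_GROWTH), tolerance = 1e-6)
  fm <- fit_fruit_allometry(M, f_ref(M))
  expect_equal(unname(coef(fm)), unname(ACC_FRUIT), tolerance = 1e-6)
  # fixed-exponent and Ricker forms also recover their own truth
  pf <- fit_growth_allometry(M, 0.05 * M^0.8, form = "power_fixed")
  expect_equal(unname(coef(pf)), c(0.05, 0.8), tolerance = 1e-6)
  rk <- fit_fruit_allometry(M, 2 * M * exp(-0.004 * M), form = "ricker")
  expect_equal(unname(coef(rk)), c(2, 0.004), tolerance = 1e-6)
  # CIs bracket the estimates
  expect_true(all(gm$ci95[, "lower"] < coef(gm) & coef(gm) < gm$ci95[, "upper"]))
})

test_that("fitting validates its inputs", {
  M <- mass_grid(20)
  expect_error(fit_growth_allometry(M[1:5], g_ref(M[1:5])), "10 observations")
  expect_error(fit_growth_allometry(-M, g_ref(M)), "positive")
  expect_error(fit_growth_allometry(rep(10, 20), rep(2, 20)), "variance|distinct")
  expect_error(evaluate_allometry(growth_model_ref(), -5), "positive")
})

test_that("model evaluation matches direct arithmetic", {
  gm <- growth_model_ref()
  # at M = 1 the exponent is irrelevant (log10 1 = 0): value = a
  expect_equal(evaluate_allometry(gm, 1), 0.022)
  expect_equal(evaluate_allometry(gm, 100), 0.022 * 100^(1.483 - 0.328),
               tolerance = 1e-12)
  expect_equal(evaluate_allometry(gm, 100), 4.4918, tolerance = 1e-4)
  fmod <- fruit_model_ref()
  expect_equal(evaluate_allometry(fmod, 100), 100 / (0.155 + 0.22 + 0.1292),
               tolerance = 1e-12)
  expect_equal(evaluate_allometry(fmod, 100), 198.3, tolerance = 1e-3)
})

test_that("AIC comparison favours the generative model and is convention-free", {
  M <- mass_grid(300)
  set.seed(4)
  G <- g_ref(M) * 10^rnorm(300, 0, 0.1)
  full <- fit_growth_allometry(M, G)
  fixed <- fit_growth_allometry(M, G, form = "power_fixed")
  expect_equal(compare_models_aic(full, full), 0)
  expect_gt(compare_models_aic(full, fixed), 0)  # curvature is real
  # invariance to the additive constant: recompute with a shifted constant
  d1 <- compare_models_aic(full, fixed)
  shift <- function(m, k) { m$aic <- m$aic + k; m }
  expect_equal(compare_models_aic(shift(full, 7), shift(fixed, 7)), d1)
  expect_error(compare_models_aic(full, fit_growth_allometry(M[-1], G[-1])),
               "different numbers")
})

test_that("fitted fruit curve is hump-shaped with its peak at sqrt(a/c)", {
  peak <- allometry_peak_mass(fruit_model_ref())
  expect_equal(peak, sqrt(0.155 / 1.292e-5), tolerance = 1e-12)
  expect_equal(peak, 109.5, tolerance = 1e-3)
  # grid search confirms the interior maximum
  M <- seq(1, 2218, by = 0.5)
  fv <- evaluate_allometry(fruit_model_ref(), M)
  expect_equal(M[which.max(fv)], peak, tolerance = 1e-2)
  expect_true(all(diff(fv[M < peak - 1]) > 0))
  expect_true(all(diff(fv[M > peak + 1]) < 0))
})

test_that("growth curve is concave above its raw-scale inflection", {
  thr <- concavity_threshold(growth_model_ref())
  expect_equal(thr, 12.22, tolerance = 1e-3)
  M <- seq(13, 2218, length.out = 4000)
  g <- evaluate_allometry(growth_model_ref(), M)
  expect_true(all(diff(g, differences = 2) <= 0))
  # below the inflection the curve is convex
  Ml <- seq(1.3, 11.5, length.out = 500)
  gl <- evaluate_allometry(growth_model_ref(), Ml)
  expect_true(all(diff(gl, differences = 2) >= 0))
  # log-log the curve is concave everywhere (c < 0)
  x <- seq(0.1, 3.4, length.out = 1000)
  expect_true(all(diff(log10(evaluate_allometry(growth_model_ref(), 10^x)),
                       differences = 2) <= 0))
})

test_that("models round-trip through JSON", {
  M <- mass_grid(50)
  set.seed(8)
  m <- fit_growth_allometry(M, g_ref(M) * 10^rnorm(50, 0, 0.05))
  path <- tempfile(fileext = ".json")
  write_allometric_model(m, path)
  back <- read_allometric_model(path)
  expect_equal(coef(back), coef(m), tolerance = 1e-12)
  expect_equal(back$aic, m$aic, tolerance = 1e-12)
  expect_equal(evaluate_allometry(back, 100), evaluate_allometry(m, 100))
})

test_that("SMA closed form matches its definition and a brute-force oracle", {
  x <- runif(40, 0, 2)
  y <- 0.75 * x + 1
  fit <- fit_sma(x, y)
  expect_equal(fit$slope, 0.75, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  set.seed(15)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    xx <- rnorm(n); yy <- sample(c(-1, 1), 1) * xx + rnorm(n, 0, 0.7)
    f <- fit_sma(xx, yy)
    # SMA identity
    expect_equal(abs(f$slope), sd(yy) / sd(xx), tolerance = 1e-9)
    # oracle: first principal axis of the standardized data, mapped back
    ev <- eigen(cov(cbind(scale(xx), scale(yy))))$vectors[, 1]
    oracle <- (ev[2] / ev[1]) * sd(yy) / sd(xx)
    expect_equal(f$slope, oracle, tolerance = 1e-9)
  }
  expect_error(fit_sma(rep(1, 10), rnorm(10)), "variance")
})

test_that("SMA slope test behaves at and away from the null", {
  x <- runif(60, 0, 2)
  y <- 0.75 * x + 1
  fit <- fit_sma(x, y)
  expect_equal(test_sma_slope(fit, 0.75, x, y)$p_value, 1)
  # tight scatter around slope 0.9 rejects 3/4 at n = 400
  set.seed(21)
  xs <- rnorm(400, 0, 0.5)
  ys <- 0.9 * xs + rnorm(400, 0, 0.1)
  fs <- fit_sma(xs, ys)
  expect_lt(test_sma_slope(fs, 0.75, xs, ys)$p_value, 0.01)
  expect_gt(test_sma_slope(fs, fs$slope, xs, ys)$p_value, 0.9)
  # symmetry: testing slope b on (x, y) = testing 1/b on (y, x)
  p_xy <- test_sma_slope(fs, 0.75, xs, ys)$p_value
  p_yx <- test_sma_slope(fit_sma(ys, xs), 1 / 0.75, ys, xs)$p_value
  expect_equal(p_xy, p_yx, tolerance = 1e-9)
  # two-group comparison flags clearly different slopes
  y2 <- 1.4 * xs + rnorm(400, 0, 0.1)
  cmp <- compare_sma_slopes(fs, fit_sma(xs, y2))
  expect_lt(cmp$p_value, 0.01)
})

test_that("logistic fits are exact, time-equivariant, and robust to noise", {
  t <- seq(2, 50, by = 2)
  mass <- 100 / (1 + exp(-0.3 * (t - 20)))
  fit <- fit_sigmoid_growth(t, mass)
  expect_equal(c(fit$K, fit$t0, fit$r), c(100, 20, 0.3), tolerance = 1e-6)
  expect_equal(fit$mass_at_inflection, fit$K / 2)
  # translation in time shifts t0 only
  fit5 <- fit_sigmoid_growth(t + 5, mass)
  expect_equal(fit5$t0, fit$t0 + 5, tolerance = 1e-6)
  expect_equal(c(fit5$K, fit5$r), c(fit$K, fit$r), tolerance = 1e-6)
  # noisy replicates: median K within 2% of truth
  set.seed(33)
  Ks <- vapply(1:60, function(i) {
    s <- simulate_growth_series(100, 20, 0.3, t, noise_sd = 2)
    fit_sigmoid_growth(s$time_d, s$mass_mg)$K
  }, numeric(1))
  expect_lt(abs(median(Ks) - 100) / 100, 0.02)
  expect_error(fit_sigmoid_growth(1:3, c(1, 2, 3)), "5 time points")
})
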