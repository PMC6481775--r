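#' Allometric model forms
#'
#' Four nonlinear trait-vs-mass model forms are supported, all fitted by
#' least squares on the untransformed trait:
#'
#' * `power_mass_corrected`: `g(M) = a * M^(b + c*log10(M))` — a power
#'   law whose exponent declines linearly with log10 mass; equivalently
#'   a quadratic in log10-log10 space, concave for `c < 0`.
#' * `power_fixed`: `g(M) = a * M^b`.
#' * `inverse_quadratic`: `f(M) = M / (a + b*M + c*M^2)` — hump-shaped
#'   with an interior maximum at `M = sqrt(a/c)`.
#' * `ricker`: `f(M) = a * M * exp(-b*M)`.
#'
#' @name allometry-forms
#' @keywords internal
NULL

.allometry_fun <- function(form) {
  switch(form,
    power_mass_corrected = function(M, p) p[1] * M^(p[2] + p[3] * log10(M)),
    power_fixed = function(M, p) p[1] * M^p[2],
    inverse_quadratic = function(M, p) M / (p[1] + p[2] * M + p[3] * M^2),
    ricker = function(M, p) p[1] * M * exp(-p[2] * M),
    stop("unknown allometric form: ", form))
}

.allometry_npar <- function(form) {
  switch(form, power_mass_corrected = 3L, power_fixed = 2L,
         inverse_quadratic = 3L, ricker = 2L)
}

# Gaussian-likelihood AIC up to an additive constant shared across models
# fitted on the same data: n*log(rss/n) + 2k, k = npar + 1 (sigma).
.aic_rss <- function(rss, n, npar) n * log(rss / n) + 2 * (npar + 1)

.new_allometric_model <- function(form, coef, vcov_m, n, rss, fitted_on) {
  npar <- length(coef)
  se <- sqrt(pmax(diag(vcov_m), 0))
  ci <- cbind(lower = coef - qt(0.975, n - npar) * se,
              upper = coef + qt(0.975, n - npar) * se)
  rownames(ci) <- names(coef)
  structure(list(form = form, coefficients = coef, se = se, ci95 = ci,
                 n = n, rss = rss, aic = .aic_rss(rss, n, npar),
                 fitted_on = fitted_on),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("Allometric model (%s), fitted on %s, n = %d\n",
              x$form, x$fitted_on, x$n))
  tab <- cbind(estimate = x$coefficients, x$ci95)
  print(signif(tab, 4))
  cat(sprintf("rss = %.4g, AIC = %.2f\n", x$rss, x$aic))
  invisible(x)
}

#' @export
coef.allometric_model <- function(object, ...) object$coefficients

# nonlinear LS with analytic start + multi-start fallback
.fit_allometry <- function(M, Y, form, start, fitted_on, label) {
  if (length(M) != length(Y)) stop("M and Y lengths differ")
  ok <- is.finite(M) & is.finite(Y)
  if (any(!ok)) { M <- M[ok]; Y <- Y[ok] }
  if (any(M <= 0) || any(Y <= 0))
    stop(label, ": all masses and trait values must be positive")
  npar <- .allometry_npar(form)
  if (length(M) < 10) stop(label, ": need at least 10 observations")
  if (length(unique(M)) < 3) stop(label, ": need at least 3 distinct masses")
  fun <- .allometry_fun(form)
  df <- data.frame(M = M, Y = Y)
  fml <- switch(form,
    power_mass_corrected = Y ~ a * M^(b + c * log10(M)),
    power_fixed = Y ~ a * M^b,
    inverse_quadratic = Y ~ M / (a + b * M + c * M^2),
    ricker = Y ~ a * M * exp(-b * M))
  # analytic start first; the multi-start grid is a fallback only
  starts <- c(list(start), .extra_starts(form, start))
  best <- NULL
  diag_msgs <- character()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = df, start = as.list(s),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { diag_msgs <- c(diag_msgs, conditionMessage(fit)); next }
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    if (identical(s, start) && !is.null(best)) break
  }
  if (is.null(best))
    stop(label, ": nonlinear least squares did not converge from any start (",
         paste(unique(diag_msgs), collapse = "; "), ")")
  fit <- best$fit
  cf <- coef(fit)
  if (form == "inverse_quadratic") {
    dd <- cf[1] + cf[2] * M + cf[3] * M^2
    if (any(dd <= 0))
      stop(label, ": fitted inverse-quadratic denominator crosses zero ",
           "inside the data range")
  }
  if (cf[1] <= 0)
    stop(label, ": fitted coefficient a is nonpositive")
  .new_allometric_model(form, cf, vcov(fit), length(M), best$rss, fitted_on)
}

.extra_starts <- function(form, start) {
  grid <- switch(form,
    power_mass_corrected = expand.grid(a = start[["a"]] * c(0.25, 1, 4),
                                       b = start[["b"]] + c(-0.5, 0, 0.5),
                                       c = start[["c"]] + c(-0.1, 0, 0.1)),
    power_fixed = expand.grid(a = start[["a"]] * c(0.25, 1, 4),
                              b = start[["b"]] + c(-0.5, 0, 0.5)),
    inverse_quadratic = expand.grid(a = start[["a"]] * c(0.5, 1, 2),
                                    b = start[["b"]] * c(0.5, 1, 2),
                                    c = start[["c"]] * c(0.5, 1, 2)),
    ricker = expand.grid(a = start[["a"]] * c(0.5, 1, 2),
                         b = start[["b"]] * c(0.5, 1, 2)))
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = TRUE]))
}

#' Fit the growth-rate allometry
#'
#' Fits growth rate (mg/d) against vegetative dry mass (mg) by nonlinear
#' least squares on the untransformed trait. The default form is the
#' power law with mass-corrected exponent, `g(M) = a*M^(b + c*log10 M)`
#' (the exponent is the derivative of the quadratic obtained after
#' log10 transformation); `power_fixed` fits a plain power law for AIC
#' comparison. Starting values come from the linearized fit of
#' `log10 G` on `log10 M` (and its square), refined by a small
#' multi-start grid.
#'
#' @param M vegetative dry mass (mg), positive.
#' @param G growth rate (mg/d), positive, same length.
#' @param form `"power_mass_corrected"` (default) or `"power_fixed"`.
#' @param fitted_on label recording the data subset
#'   (`"accessions"`, `"hybrids"` or `"pooled"`).
#' @return An `allometric_model`: coefficients with asymptotic (Wald)
#'   95% CIs, `n`, `rss` and Gaussian-likelihood `aic`.
#' @examples
#' M <- 10^seq(0.3, 3, length.out = 50)
#' G <- 0.022 * M^(1.483 - 0.164 * log10(M))
#' fit_growth_allometry(M, G)
#' @export
fit_growth_allometry <- function(M, G, form = c("power_mass_corrected",
                                                "power_fixed"),
                                 fitted_on = "accessions") {
  form <- match.arg(form)
  ok <- is.finite(M) & is.finite(G)
  if (any(M[ok] <= 0) || any(G[ok] <= 0))
    stop("growth allometry: masses and growth rates must be positive")
  x <- log10(M[ok]); y <- log10(G[ok])
  start <- if (form == "power_mass_corrected") {
    cf <- coef(lm(y ~ x + I(x^2)))
    c(a = 10^unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]))
  } else {
    cf <- coef(lm(y ~ x))
    c(a = 10^unname(cf[1]), b = unname(cf[2]))
  }
  .fit_allometry(M, G, form, start, fitted_on, "growth allometry")
}

#' Fit the fruit-number allometry
#'
#' Fits fruit number against vegetative dry mass (mg) by nonlinear least
#' squares. The default inverse-quadratic form
#' `f(M) = M / (a + b*M + c*M^2)` is hump-shaped (source/sink
#' competition depresses fruit production in very large plants), with
#' its maximum at `M = sqrt(a/c)`; the Ricker form
#' `f(M) = a*M*exp(-b*M)` is the alternative compared by AIC. Inverse-
#' quadratic starts come from the linear regression of `M/F` on
#' `(1, M, M^2)`.
#'
#' @param M vegetative dry mass (mg), positive.
#' @param F fruit count, positive, same length.
#' @param form `"inverse_quadratic"` (default) or `"ricker"`.
#' @param fitted_on label recording the data subset.
#' @return An `allometric_model`.
#' @export
fit_fruit_allometry <- function(M, F, form = c("inverse_quadratic", "ricker"),
                                fitted_on = "accessions") {
  form <- match.arg(form)
  ok <- is.finite(M) & is.finite(F)
  if (any(M[ok] <= 0) || any(F[ok] <= 0))
    stop("fruit allometry: masses and fruit counts must be positive")
  Mk <- M[ok]; Fk <- F[ok]
  start <- if (form == "inverse_quadratic") {
    cf <- coef(lm(I(Mk / Fk) ~ Mk + I(Mk^2)))
    s <- c(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]))
    s[!is.finite(s)] <- 1e-6
    if (s[["a"]] <= 0) s[["a"]] <- 0.1
    if (s[["c"]] <= 0) s[["c"]] <- 1e-6
    s
  } else {
    cf <- coef(lm(log(Fk / Mk) ~ Mk))
    c(a = exp(unname(cf[1])), b = -unname(cf[2]))
  }
  .fit_allometry(M, F, form, start, fitted_on, "fruit allometry")
}

#' Evaluate a fitted allometric model
#'
#' Closed-form evaluation of the model curve at new masses. The log in
#' the mass-corrected exponent is base 10.
#'
#' @param model an `allometric_model` (or a list with `form` and
#'   `coefficients`).
#' @param M positive masses (mg).
#' @return Predicted trait values.
#' @export
evaluate_allometry <- function(model, M) {
  if (any(!is.finite(M)) || any(M <= 0)) stop("M must be positive and finite")
  .allometry_fun(model$form)(M, unname(model$coefficients))
}

#' @export
predict.allometric_model <- function(object, newdata, ...) {
  M <- if (is.data.frame(newdata)) newdata$M else newdata
  evaluate_allometry(object, M)
}

#' Compare two allometric models by AIC
#'
#' `delta_aic = AIC(alternative) - AIC(retained)`: positive values
#' favour the `retained` model. Both models must be fitted on the same
#' data (equal `n`); the additive AIC constant cancels.
#'
#' @param retained,alternative `allometric_model`s fitted on identical
#'   observations.
#' @return `delta_aic` (numeric scalar).
#' @export
compare_models_aic <- function(retained, alternative) {
  if (retained$n != alternative$n)
    stop("models were fitted on different numbers of observations (",
         retained$n, " vs ", alternative$n, ")")
  alternative$aic - retained$aic
}

#' Interior maximum of a hump-shaped allometry
#'
#' For the inverse-quadratic form the fitted curve has a unique interior
#' maximum at `M = sqrt(a/c)`; for the Ricker form at `M = 1/b`.
#'
#' @param model an `allometric_model` of form `inverse_quadratic` or
#'   `ricker`.
#' @return Mass (mg) at the curve's maximum.
#' @export
allometry_peak_mass <- function(model) {
  cf <- model$coefficients
  switch(model$form,
         inverse_quadratic = sqrt(cf[["a"]] / cf[["c"]]),
         ricker = 1 / cf[["b"]],
         stop("peak is defined for hump-shaped forms only"))
}

#' Save / load an allometric model as JSON
#'
#' @param model an `allometric_model`.
#' @param path JSON file path.
#' @return `write_allometric_model` invisibly returns `path`;
#'   `read_allometric_model` returns the model.
#' @export
write_allometric_model <- function(model, path) {
  obj <- list(form = model$form,
              coefficients = as.list(model$coefficients),
              se = as.list(setNames(model$se, names(model$coefficients))),
              ci95 = list(lower = as.list(setNames(model$ci95[, "lower"],
                                                   names(model$coefficients))),
                          upper = as.list(setNames(model$ci95[, "upper"],
                                                   names(model$coefficients)))),
              n = model$n, rss = model$rss, aic = model$aic,
              fitted_on = model$fitted_on)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_allometric_model
#' @export
read_allometric_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- unlist(obj$coefficients)
  ci <- cbind(lower = unlist(obj$ci95$lower), upper = unlist(obj$ci95$upper))
  rownames(ci) <- names(coef)
  structure(list(form = obj$form, coefficients = coef, se = unlist(obj$se),
                 ci95 = ci, n = obj$n, rss = obj$rss, aic = obj$aic,
                 fitted_on = obj$fitted_on),
            class = "allometric_model")
}

#' Logistic growth-curve fit
#'
#' Fits the 3-parameter logistic `m(t) = K / (1 + exp(-r*(t - t0)))` by
#' least squares. The inflection point — the day at which daily growth
#' is maximal and starts to decrease — is `t0`, with mass `K/2`; the
#' mass at the inflection is the vegetative dry mass M used throughout
#' the allometric analysis.
#'
#' @param times measurement times (d), at least 5, spanning the
#'   inflection.
#' @param masses rosette masses (mg).
#' @return A `sigmoid_fit`: `K`, `t0`, `r`, `mass_at_inflection = K/2`,
#'   `rss`.
#' @export
fit_sigmoid_growth <- function(times, masses) {
  if (length(times) < 5) stop("need at least 5 time points")
  if (length(times) != length(masses)) stop("times and masses lengths differ")
  K0 <- max(masses) * 1.05
  y <- pmin(pmax(masses / K0, 1e-6), 1 - 1e-6)
  lf <- coef(lm(qlogis(y) ~ times))
  start <- list(K = K0, r = max(unname(lf[2]), 1e-3),
                t0 = -unname(lf[1]) / max(unname(lf[2]), 1e-3))
  fit <- tryCatch(
    minpack.lm::nlsLM(masses ~ K / (1 + exp(-r * (times - t0))),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("logistic growth fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  structure(list(K = unname(cf["K"]), t0 = unname(cf["t0"]),
                 r = unname(cf["r"]),
                 mass_at_inflection = unname(cf["K"]) / 2,
                 rss = sum(resid(fit)^2), n = length(times)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Logistic growth fit: K = %.4g mg, t0 = %.4g d, r = %.4g /d\n",
              x$K, x$t0, x$r))
  cat(sprintf("mass at inflection = K/2 = %.4g mg (rss %.4g, n %d)\n",
              x$mass_at_inflection, x$rss, x$n))
  invisible(x)
}
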