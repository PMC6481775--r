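#' Predicted mid- and best-parent trait values from parental masses
#'
#' Evaluates the accession-fitted allometry at both parental masses:
#' `MP_pred = (g(M1) + g(M2)) / 2` and
#' `BP_pred = max(g(M1), g(M2))`. Parents are labelled worst/best by
#' their *predicted* trait value, not by mass (relevant on the
#' descending limb of a hump-shaped allometry).
#'
#' @param model an `allometric_model` fitted on accessions.
#' @param m1,m2 parental vegetative dry masses (mg), positive
#'   (vectorized).
#' @return list with `mp_pred` and `bp_pred`.
#' @export
predict_parent_values <- function(model, m1, m2) {
  if (any(!is.finite(c(m1, m2))) || any(m1 <= 0) || any(m2 <= 0))
    stop("parental masses must be positive and finite")
  g1 <- evaluate_allometry(model, m1)
  g2 <- evaluate_allometry(model, m2)
  list(mp_pred = (g1 + g2) / 2, bp_pred = pmax(g1, g2))
}

#' Nonlinear deviation (NLDev): curvature-predicted heterosis
#'
#' Predicts heterosis from masses alone, using the allometry fitted on
#' the parents' population:
#' `NLDev_MP = (g(M12) - MP_pred) / MP_pred` and
#' `NLDev_BP = (g(M12) - BP_pred) / BP_pred`, with `M12` the hybrid's
#' observed mass. Where the curve is concave and the hybrid mass is
#' mid-parent, Jensen's inequality makes `NLDev_MP > 0`: curvature
#' alone generates mid-parent heterosis. NLDev is invariant to swapping
#' the parent labels.
#'
#' @param model an `allometric_model` fitted on accessions.
#' @param m1,m2 parental masses (mg), positive (vectorized).
#' @param m12 hybrid mass (mg), positive.
#' @return Data frame: `m1, m2, m12, pred, mp_pred, bp_pred, nldev_mp,
#'   nldev_bp` (`pred = g(M12)`).
#' @examples
#' M <- 10^seq(0.3, 3, length.out = 60)
#' mod <- fit_growth_allometry(M, 0.022 * M^(1.483 - 0.164 * log10(M)))
#' nldev(mod, 10, 100, 55)
#' @export
nldev <- function(model, m1, m2, m12) {
  if (any(!is.finite(m12)) || any(m12 <= 0))
    stop("hybrid masses must be positive and finite")
  pv <- predict_parent_values(model, m1, m2)
  if (any(pv$mp_pred <= 0)) stop("predicted mid-parent value is nonpositive")
  pred <- evaluate_allometry(model, m12)
  data.frame(m1 = m1, m2 = m2, m12 = m12, pred = pred,
             mp_pred = pv$mp_pred, bp_pred = pv$bp_pred,
             nldev_mp = (pred - pv$mp_pred) / pv$mp_pred,
             nldev_bp = (pred - pv$bp_pred) / pv$bp_pred)
}

#' Per-hybrid NLDev table from genotype summaries
#'
#' Looks up parental and hybrid masses in a genotype summary table and
#' computes NLDev of the model's trait for every hybrid with complete
#' mass data.
#'
#' @param model accession-fitted `allometric_model` for the trait of
#'   interest.
#' @param summaries genotype summaries (accessions and hybrids) from
#'   [summarize_genotypes()].
#' @return Data frame keyed by `hybrid_id` with the columns of
#'   [nldev()].
#' @export
nldev_table <- function(model, summaries) {
  rownames(summaries) <- summaries$genotype_id
  hyb <- summaries[summaries$type == "hybrid", , drop = FALSE]
  m1 <- summaries[hyb$parent1, "mass_mg"]
  m2 <- summaries[hyb$parent2, "mass_mg"]
  m12 <- hyb$mass_mg
  ok <- is.finite(m1) & is.finite(m2) & is.finite(m12) &
    m1 > 0 & m2 > 0 & m12 > 0
  res <- nldev(model, m1[ok], m2[ok], m12[ok])
  cbind(data.frame(hybrid_id = hyb$genotype_id[ok], stringsAsFactors = FALSE),
        res)
}

#' Compare curvature predictions with observed heterosis
#'
#' Pearson r-squared (and least-squares slope and p value) for three
#' comparisons over matched hybrids: (i) predicted `g(M12)` vs the
#' observed hybrid trait, (ii) `NLDev_MP` vs observed MPH, (iii)
#' `NLDev_BP` vs observed BPH.
#'
#' @param nldev_results output of [nldev_table()].
#' @param heterosis_measures output of [heterosis_table()] filtered to
#'   one trait.
#' @param observed named vector of observed hybrid genotype-mean trait
#'   values (names = hybrid ids).
#' @return Data frame: `comparison, n, r2, slope, p_value`.
#' @export
compare_predictions <- function(nldev_results, heterosis_measures, observed) {
  het <- heterosis_measures
  ids <- intersect(nldev_results$hybrid_id, het$hybrid_id)
  ids <- intersect(ids, names(observed)[is.finite(observed)])
  if (length(ids) < 3) stop("need at least 3 matched hybrids")
  nd <- nldev_results[match(ids, nldev_results$hybrid_id), ]
  ht <- het[match(ids, het$hybrid_id), ]
  one <- function(x, y, label) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || sd(x) == 0)
      return(data.frame(comparison = label, n = length(x), r2 = NA_real_,
                        slope = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    fit <- summary(lm(y ~ x))
    data.frame(comparison = label, n = length(x), r2 = cor(x, y)^2,
               slope = fit$coefficients["x", "Estimate"],
               p_value = fit$coefficients["x", "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  }
  rbind(one(nd$pred, unname(observed[ids]), "pred_vs_obs"),
        one(nd$nldev_mp, ht$mph, "nldev_mp_vs_mph"),
        one(nd$nldev_bp, ht$bph, "nldev_bp_vs_bph"))
}

#' Raw-scale inflection mass of a mass-corrected power law
#'
#' The curve `g(M) = a*M^(b + c*log10 M)` with `c < 0` is concave
#' everywhere on the log-log scale, but on the raw scale it is convex
#' below and concave above the mass at which
#' `phi^2 - phi + 2c/ln(10) = 0`, with `phi = b + 2c*log10(M)` the
#' local log-log slope. Jensen-type mid-parent heterosis of the
#' predicted trait is guaranteed only for parent pairs inside the
#' concave region.
#'
#' @param model an `allometric_model` of form `power_mass_corrected`.
#' @return Mass (mg) at the raw-scale inflection (or 0 if the curve is
#'   concave over all positive masses).
#' @export
concavity_threshold <- function(model) {
  if (model$form != "power_mass_corrected")
    stop("defined for the mass-corrected power law only")
  cf <- model$coefficients
  b <- cf[["b"]]; cc <- cf[["c"]]
  if (cc >= 0) stop("curve is not log-log concave (c >= 0)")
  disc <- 1 - 4 * (2 * cc / log(10))
  phi_hi <- (1 + sqrt(disc)) / 2  # g'' < 0 requires local slope below this
  x <- (phi_hi - b) / (2 * cc)    # log10 M where phi crosses phi_hi
  10^x
}
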