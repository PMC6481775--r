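#' Mid-parent heterosis
#'
#' `MPH = (y12 - mean(y1, y2)) / mean(y1, y2)`: the deviation of the
#' observed hybrid value scaled to the observed mean parental value.
#' Scale-invariant; for positive traits `MPH >= -1`.
#'
#' @param y1,y2 parental genotype means (positive).
#' @param y12 hybrid genotype mean.
#' @return MPH as a fraction (vectorized).
#' @examples
#' mph(10, 20, 18)  # 0.2
#' @export
mph <- function(y1, y2, y12) {
  mp <- (y1 + y2) / 2
  if (any(!is.finite(mp)) || any(mp <= 0))
    stop("parental mean must be positive and finite")
  (y12 - mp) / mp
}

#' Best-parent heterosis
#'
#' `BPH = (y12 - max(y1, y2)) / max(y1, y2)`: the deviation of the
#' observed hybrid value scaled to the observed best parental value.
#' For positive parental values `BPH <= MPH` always (the best parent is
#' at least the mid-parent).
#'
#' @inheritParams mph
#' @return BPH as a fraction (vectorized).
#' @examples
#' bph(10, 20, 25)  # 0.25
#' @export
bph <- function(y1, y2, y12) {
  if (any(!is.finite(c(y1, y2))) || any(y1 <= 0) || any(y2 <= 0))
    stop("parental values must be positive and finite")
  bp <- pmax(y1, y2)
  (y12 - bp) / bp
}

#' Per-hybrid heterosis table
#'
#' Computes MPH and BPH for every hybrid and trait from genotype-level
#' summaries (see [summarize_genotypes()]). Hybrids whose parents lack
#' a trait are reported with `NA` for that trait.
#'
#' @param summaries genotype summary data frame containing accessions
#'   and hybrids.
#' @param traits trait columns.
#' @return Long data frame: `hybrid_id, trait, y1, y2, y12, mph, bph`.
#' @export
heterosis_table <- function(summaries,
                            traits = c("mass_mg", "age_d",
                                       "growth_mg_per_d", "fruit_n")) {
  hyb <- summaries[summaries$type == "hybrid", , drop = FALSE]
  rownames(summaries) <- summaries$genotype_id
  out <- lapply(traits, function(tr) {
    y1 <- summaries[hyb$parent1, tr]
    y2 <- summaries[hyb$parent2, tr]
    y12 <- hyb[[tr]]
    ok <- is.finite(y1) & is.finite(y2) & is.finite(y12) & y1 > 0 & y2 > 0
    mp <- (y1 + y2) / 2
    bp <- pmax(y1, y2)
    data.frame(hybrid_id = hyb$genotype_id, trait = tr,
               y1 = y1, y2 = y2, y12 = y12,
               mph = ifelse(ok, (y12 - mp) / mp, NA_real_),
               bph = ifelse(ok, (y12 - bp) / bp, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.classify_one <- function(reps, mid, best, worst, n_boot, alpha, family_size) {
  reps <- reps[is.finite(reps)]
  n <- length(reps)
  if (n < 2)
    return(list(category = "unclassifiable",
                p_mid = NA_real_, p_best = NA_real_, p_worst = NA_real_))
  boot_means <- vapply(seq_len(n_boot), function(i)
    mean(reps[sample.int(n, n, replace = TRUE)]), numeric(1))
  m <- mean(boot_means)
  se <- sd(boot_means)  # bootstrap sd of the mean estimates its SE
  df <- n_boot - 1
  if (se == 0) {
    # degenerate: all replicates identical; exact comparison
    p_mid <- if (m == mid) 1 else 0
    p_best <- if (m > best) 0 else 1
    p_worst <- if (m < worst) 0 else 1
  } else {
    p_mid <- 2 * pt(-abs((m - mid) / se), df)          # two-sided vs mid
    p_best <- pt((m - best) / se, df, lower.tail = FALSE)  # one-sided: > best
    p_worst <- pt((m - worst) / se, df)                    # one-sided: < worst
  }
  adj <- pmin(c(p_mid, p_best, p_worst) * family_size, 1)
  category <- if (adj[2] < alpha && m > best) "above_best"
    else if (adj[3] < alpha && m < worst) "below_worst"
    else if (adj[1] < alpha && m > mid) "positive"
    else if (adj[1] < alpha && m < mid) "negative"
    else "additive"
  list(category = category, p_mid = adj[1], p_best = adj[2], p_worst = adj[3])
}

#' Bootstrap classification of hybrids against parental values
#'
#' For each hybrid and trait, the F1 trait distribution is estimated by
#' bootstrap resampling (with replacement) of the hybrid's replicate
#' measurements; parents enter as fixed genotype means. The bootstrap
#' mean is compared to the mid-parent value (two-sided), the best
#' parent (one-sided, above) and the worst parent (one-sided, below)
#' with t-type tests using the bootstrap standard error of the mean
#' (`n_boot - 1` df). P values are Bonferroni-adjusted across the test
#' family (default family size: 3 tests per hybrid times the number of
#' hybrids classified). Categories: `below_worst`, `negative` (between
#' worst and mid), `additive`, `positive` (between mid and best),
#' `above_best`; hybrids with fewer than 2 replicates are
#' `unclassifiable`. "Best" is the larger parental value by default for
#' every trait (configurable per trait via `direction`).
#'
#' @param records replicate-level phenotype table (accessions and
#'   hybrids).
#' @param traits trait columns to classify.
#' @param n_boot bootstrap resamples (default 1000).
#' @param alpha significance level applied to adjusted p values.
#' @param family_size Bonferroni family size; default
#'   `3 * n_hybrids` per trait.
#' @param direction named vector of +1/-1 per trait; -1 flips which
#'   parent is "best" (useful for phenology traits where smaller may be
#'   better).
#' @param seed optional seed for the bootstrap.
#' @return Data frame: `hybrid_id, trait, category, p_mid, p_best,
#'   p_worst` (adjusted p values).
#' @export
classify_heterosis <- function(records,
                               traits = c("mass_mg", "age_d",
                                          "growth_mg_per_d", "fruit_n"),
                               n_boot = 1000, alpha = 0.05,
                               family_size = NULL, direction = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  summaries <- summarize_genotypes(records, traits)
  rownames(summaries) <- summaries$genotype_id
  hyb_ids <- summaries$genotype_id[summaries$type == "hybrid"]
  if (is.null(family_size)) family_size <- 3 * length(hyb_ids)
  out <- list()
  for (tr in traits) {
    dir <- if (!is.null(direction) && tr %in% names(direction))
      direction[[tr]] else 1
    for (h in hyb_ids) {
      p1 <- summaries[h, "parent1"]; p2 <- summaries[h, "parent2"]
      y1 <- summaries[p1, tr]; y2 <- summaries[p2, tr]
      reps <- records[[tr]][records$genotype_id == h]
      if (!is.finite(y1) || !is.finite(y2)) {
        out[[length(out) + 1L]] <- data.frame(
          hybrid_id = h, trait = tr, category = "unclassifiable",
          p_mid = NA_real_, p_best = NA_real_, p_worst = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      vals <- dir * c(y1, y2)
      cl <- .classify_one(dir * reps, mid = mean(vals), best = max(vals),
                          worst = min(vals), n_boot = n_boot, alpha = alpha,
                          family_size = family_size)
      out[[length(out) + 1L]] <- data.frame(
        hybrid_id = h, trait = tr, category = cl$category,
        p_mid = cl$p_mid, p_best = cl$p_best, p_worst = cl$p_worst,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Cohort summary of heterosis classification
#'
#' Percentage of hybrids in each category per trait (summing to 100
#' over classified hybrids), plus the share with any significant
#' heterosis (non-additive).
#'
#' @param classification output of [classify_heterosis()].
#' @return Data frame: `trait, category, n, percent`.
#' @export
summarize_classification <- function(classification) {
  cl <- classification[classification$category != "unclassifiable", ]
  out <- lapply(split(cl, cl$trait), function(d) {
    tab <- table(factor(d$category,
                        levels = c("below_worst", "negative", "additive",
                                   "positive", "above_best")))
    data.frame(trait = d$trait[1], category = names(tab),
               n = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Broad-sense heritability
#'
#' Fits the random-intercept model `Y ~ (1 | genotype)` by REML
#' (`lme4::lmer`) on replicate-level data and returns
#' `H2 = var(G) / (var(G) + var(residual))` — the fraction of
#' phenotypic variance explained by genotypic differences. Computed on
#' the pooled accession + hybrid data by default; subset `records`
#' first for group-specific estimates. Falls back to a method-of-
#' moments ANOVA estimator if the mixed model fails.
#'
#' @param records replicate-level phenotype table.
#' @param trait trait column.
#' @return list of class `heritability_estimate`: `trait`,
#'   `var_genotype`, `var_residual`, `h2`, `method`.
#' @export
heritability <- function(records, trait) {
  d <- records[!is.na(records[[trait]]), c("genotype_id", trait)]
  names(d) <- c("genotype", "y")
  reps <- table(d$genotype)
  if (sum(reps >= 2) < 2)
    stop("heritability needs >= 2 genotypes with >= 2 replicates")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ (1 | genotype), data = d,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    vg <- vc$vcov[vc$grp == "genotype"]
    vr <- vc$vcov[vc$grp == "Residual"]
    method <- "REML"
  } else {
    # method-of-moments from one-way ANOVA mean squares
    a <- anova(aov(y ~ genotype, data = d))
    msg <- a["genotype", "Mean Sq"]; mse <- a["Residuals", "Mean Sq"]
    n0 <- (sum(reps) - sum(reps^2) / sum(reps)) / (length(reps) - 1)
    vg <- max((msg - mse) / n0, 0); vr <- mse
    method <- "method-of-moments"
  }
  structure(list(trait = trait, var_genotype = vg, var_residual = vr,
                 h2 = vg / (vg + vr), method = method),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("Broad-sense heritability of %s: H2 = %.3f (var G %.4g, var res %.4g, %s)\n",
              x$trait, x$h2, x$var_genotype, x$var_residual, x$method))
  invisible(x)
}
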