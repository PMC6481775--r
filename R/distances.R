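#' Filter a SNP matrix by minor allele frequency and call rate
#'
#' Removes markers whose minor allele frequency (computed over
#' non-missing calls) falls below `maf_min` or whose call rate falls
#' below `call_rate_min`. Thresholds are inclusive (a marker exactly at
#' the threshold is retained). An empty result triggers a warning, not
#' an error.
#'
#' @param snps 0/1/NA matrix (genotypes x markers).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param call_rate_min minimum fraction of non-missing calls
#'   (default 0.85).
#' @return The filtered matrix, with attribute `"filter_report"`
#'   (markers before/after, counts failing each threshold).
#' @export
filter_snps <- function(snps, maf_min = 0.05, call_rate_min = 0.85) {
  stopifnot(is.matrix(snps))
  call_rate <- colMeans(!is.na(snps))
  p <- colMeans(snps, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  fail_maf <- maf < maf_min
  fail_cr <- call_rate < call_rate_min
  keep <- !(fail_maf | fail_cr)
  out <- snps[, keep, drop = FALSE]
  if (ncol(out) == 0) warning("no markers pass the filters")
  attr(out, "filter_report") <- list(
    n_before = ncol(snps), n_after = ncol(out),
    n_fail_maf = sum(fail_maf), n_fail_call_rate = sum(fail_cr))
  out
}

#' Pairwise genetic distance as allele-count differences
#'
#' For homozygous inbred lines coded 0/1, each differing biallelic site
#' contributes 2 allele differences (both homologous chromosomes carry
#' the alternative allele); `per_site = TRUE` counts 1 per differing
#' site instead. Sites with a missing call in either genotype are
#' skipped (pairwise-complete, no rescaling). For downstream
#' regressions the raw count is log10-transformed; identical genotypes
#' (count 0) have an undefined log distance and are excluded from
#' log-scale analyses.
#'
#' @param snps 0/1/NA matrix (genotypes x markers).
#' @param id1,id2 genotype ids (rownames of `snps`).
#' @param per_site count 1 instead of 2 per differing site.
#' @return Allele-count distance (numeric scalar).
#' @export
genetic_distance <- function(snps, id1, id2, per_site = FALSE) {
  if (!all(c(id1, id2) %in% rownames(snps)))
    stop("genotype id(s) not present in the SNP matrix")
  a <- snps[id1, ]; b <- snps[id2, ]
  ok <- !is.na(a) & !is.na(b)
  (if (per_site) 1 else 2) * sum(a[ok] != b[ok])
}

#' All pairwise genetic distances
#'
#' @inheritParams genetic_distance
#' @return Symmetric matrix of allele-count distances with zero
#'   diagonal.
#' @export
genetic_distance_matrix <- function(snps, per_site = FALSE) {
  x <- snps
  miss <- is.na(x)
  x0 <- x; x0[miss] <- 0L
  obs <- 1 - miss
  # differing sites among pairwise-complete calls:
  # |a - b| summed where both observed
  same1 <- x0 %*% t(x0)                      # both 1
  both_obs <- obs %*% t(obs)
  ones_vs_obs <- x0 %*% t(obs)               # a==1 and b observed
  diff <- ones_vs_obs + t(ones_vs_obs) - 2 * same1
  d <- (if (per_site) 1 else 2) * diff
  dimnames(d) <- list(rownames(snps), rownames(snps))
  diag(d) <- 0
  d
}

#' Top-effect SNP subset
#'
#' Ranks markers by absolute effect size (strongest positive and
#' negative effects together) and returns the top fraction; ties are
#' broken by marker id for determinism. Used to restrict genetic
#' distance to trait-associated markers.
#'
#' @param weights named numeric vector of per-marker effect sizes.
#' @param fraction fraction of markers to keep, in (0, 1]
#'   (default 0.01).
#' @return Character vector of selected marker ids.
#' @export
top_snp_subset <- function(weights, fraction = 0.01) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (is.null(names(weights))) stop("weights must be named by marker id")
  k <- max(1L, floor(length(weights) * fraction))
  ord <- order(-abs(weights), names(weights))
  names(weights)[ord][seq_len(k)]
}

#' Great-circle geographic distance
#'
#' Haversine distance on a sphere of mean Earth radius (6,371 km) from
#' decimal-degree longitude/latitude.
#'
#' @param coords data frame with `genotype_id, longitude, latitude`.
#' @param id1,id2 genotype ids.
#' @return Distance in km.
#' @export
geographic_distance <- function(coords, id1, id2) {
  rownames(coords) <- coords$genotype_id
  p1 <- as.numeric(coords[id1, c("longitude", "latitude")])
  p2 <- as.numeric(coords[id2, c("longitude", "latitude")])
  .check_lonlat(rbind(p1, p2))
  geosphere::distHaversine(p1, p2, r = 6371000) / 1000
}

.check_lonlat <- function(m) {
  if (any(!is.finite(m)) || any(abs(m[, 1]) > 180) || any(abs(m[, 2]) > 90))
    stop("coordinates out of range (longitude in [-180,180], latitude in [-90,90])")
}

#' All pairwise geographic distances
#' @param coords data frame with `genotype_id, longitude, latitude`.
#' @return Symmetric km matrix with zero diagonal.
#' @export
geographic_distance_matrix <- function(coords) {
  m <- as.matrix(coords[, c("longitude", "latitude")])
  .check_lonlat(m)
  d <- geosphere::distm(m, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(d) <- list(coords$genotype_id, coords$genotype_id)
  diag(d) <- 0
  d
}

#' Phenotypic distance between genotypes
#'
#' `mode = "euclidean"`: Euclidean distance over the trait vector,
#' standardized to unit variance across genotypes first (raw mg / d /
#' count scales are incommensurable; `standardize = FALSE` gives the
#' raw-scale variant). `mode = "mass"`: absolute difference in
#' vegetative dry mass (mg).
#'
#' @param summaries genotype summary data frame.
#' @param mode `"euclidean"` or `"mass"`.
#' @param traits trait columns used in euclidean mode.
#' @param standardize scale traits to unit variance first
#'   (euclidean mode).
#' @return Symmetric distance matrix over the genotypes with complete
#'   trait data (others are dropped with a message).
#' @export
phenotypic_distance_matrix <- function(summaries, mode = c("euclidean", "mass"),
                                       traits = c("mass_mg", "age_d",
                                                  "growth_mg_per_d", "fruit_n"),
                                       standardize = TRUE) {
  mode <- match.arg(mode)
  if (mode == "mass") traits <- "mass_mg"
  x <- as.matrix(summaries[, traits, drop = FALSE])
  rownames(x) <- summaries$genotype_id
  ok <- complete.cases(x)
  if (any(!ok))
    message(sum(!ok), " genotype(s) skipped for missing traits")
  x <- x[ok, , drop = FALSE]
  if (mode == "euclidean" && standardize) x <- scale(x)
  d <- as.matrix(dist(x, method = "euclidean"))
  diag(d) <- 0
  d
}

#' Phenotypic distance between one pair
#' @inheritParams phenotypic_distance_matrix
#' @param id1,id2 genotype ids.
#' @return Distance (scalar); errors if a required trait is missing for
#'   either genotype.
#' @export
phenotypic_distance <- function(summaries, id1, id2,
                                mode = c("euclidean", "mass"),
                                traits = c("mass_mg", "age_d",
                                           "growth_mg_per_d", "fruit_n"),
                                standardize = TRUE) {
  mode <- match.arg(mode)
  d <- phenotypic_distance_matrix(summaries, mode, traits, standardize)
  if (!all(c(id1, id2) %in% rownames(d)))
    stop("genotype pair has missing traits")
  d[id1, id2]
}

#' Regress heterosis on a parental distance
#'
#' Ordinary least squares of per-hybrid heterosis (MPH or BPH) on the
#' parental distance and its square, `h ~ d + d^2`, to test for
#' nonlinearity (e.g. an optimal intermediate distance); the
#' linear-only fit is reported alongside.
#'
#' @param distances numeric vector of parental distances, matched to
#'   `heterosis`.
#' @param heterosis numeric vector of per-hybrid heterosis values.
#' @return list of class `quadratic_regression`: `coefficients`
#'   (intercept, linear, quadratic), `p_values`, `r2`, and `linear`
#'   (same summaries for the linear-only model), `n`.
#' @export
regress_heterosis_on_distance <- function(distances, heterosis) {
  ok <- is.finite(distances) & is.finite(heterosis)
  d <- distances[ok]; h <- heterosis[ok]
  if (length(d) < 10) stop("need at least 10 matched pairs")
  if (sd(d) == 0) stop("degenerate predictor: zero variance in distances")
  quad <- lm(h ~ d + I(d^2))
  sq <- summary(quad)
  lin <- lm(h ~ d)
  sl <- summary(lin)
  structure(list(
    coefficients = setNames(coef(quad), c("intercept", "linear", "quadratic")),
    p_values = setNames(sq$coefficients[, "Pr(>|t|)"],
                        c("intercept", "linear", "quadratic")),
    r2 = sq$r.squared,
    linear = list(coefficients = setNames(coef(lin), c("intercept", "linear")),
                  p_values = setNames(sl$coefficients[, "Pr(>|t|)"],
                                      c("intercept", "linear")),
                  r2 = sl$r.squared),
    n = length(d)), class = "quadratic_regression")
}

#' @export
print.quadratic_regression <- function(x, ...) {
  cat(sprintf("Quadratic heterosis ~ distance regression (n = %d)\n", x$n))
  cat(sprintf("  quadratic: r2 = %.3f; coef (int, lin, quad) = %s\n",
              x$r2, paste(signif(x$coefficients, 3), collapse = ", ")))
  cat(sprintf("  p(quadratic term) = %.3g; linear-only r2 = %.3f\n",
              x$p_values[["quadratic"]], x$linear$r2))
  invisible(x)
}

#' Long-format export of a distance matrix
#' @param d symmetric distance matrix with dimnames.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  idx <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(id1 = rownames(d)[idx[, 1]], id2 = colnames(d)[idx[, 2]],
                    value = d[idx], stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
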