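#' Read a replicate-level phenotype table
#'
#' Reads the standard phenotype table (CSV or TSV, autodetected from the
#' file extension) with columns `genotype_id, type, parent1, parent2,
#' experiment, replicate, mass_mg, age_d, growth_mg_per_d, fruit_n`.
#' Traits may be missing per row (the four traits typically have
#' different per-trait sample sizes); such rows are retained. Rows with
#' a nonpositive recorded mass, age or growth rate are excluded, and
#' every exclusion is enumerated in the attached validation report —
#' nothing is dropped silently.
#'
#' @param source path to a CSV or TSV file.
#' @return A `data.frame` of replicate records with attribute
#'   `"validation"`: a list with `n_read`, `n_kept`, and a data frame
#'   `excluded` (row number and reason).
#' @export
read_phenotypes <- function(source) {
  sep <- if (grepl("\\.tsv$", source, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(source, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_phenotypes(df)
}

#' Validate an in-memory phenotype table
#'
#' @param df data frame with the standard phenotype columns.
#' @return As [read_phenotypes()].
#' @export
validate_phenotypes <- function(df) {
  required <- c("genotype_id", "type", "parent1", "parent2", "experiment",
                "replicate", "mass_mg", "age_d", "growth_mg_per_d", "fruit_n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (tr in c("mass_mg", "age_d", "growth_mg_per_d", "fruit_n"))
    df[[tr]] <- as.numeric(df[[tr]])
  bad_type <- !df$type %in% c("accession", "hybrid")
  nonpos <- rep(FALSE, nrow(df))
  for (tr in c("mass_mg", "age_d", "growth_mg_per_d"))
    nonpos <- nonpos | (!is.na(df[[tr]]) & df[[tr]] <= 0)
  neg_fruit <- !is.na(df$fruit_n) & df$fruit_n < 0
  bad_parents <- (df$type == "hybrid" &
                    (is.na(df$parent1) | is.na(df$parent2) |
                       df$parent1 == df$parent2))
  drop <- bad_type | nonpos | neg_fruit | bad_parents
  reason <- character(sum(drop))
  if (any(drop)) {
    reason <- ifelse(bad_type[drop], "unknown type",
              ifelse(bad_parents[drop], "invalid hybrid parent ids",
              ifelse(neg_fruit[drop], "negative fruit count",
                     "nonpositive trait value")))
  }
  report <- list(n_read = nrow(df), n_kept = sum(!drop),
                 excluded = data.frame(row = which(drop), reason = reason,
                                       stringsAsFactors = FALSE))
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- report
  out
}

#' Write a replicate-level phenotype table
#'
#' @param records phenotype data frame.
#' @param path output path (`.tsv` for tab-separated, otherwise CSV).
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a validation report as JSON
#' @param records validated phenotype table.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(records, path) {
  rep <- attr(records, "validation")
  if (is.null(rep)) rep <- list(n_read = nrow(records), n_kept = nrow(records),
                                excluded = data.frame())
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Estimate a cross-experiment correction from shared genotypes
#'
#' A subset of genotypes phenotyped in both experiments calibrates a
#' linear correction of the target experiment onto the reference
#' experiment. For each trait, a two-way ANOVA with genotype and
#' experiment as interacting factors tests for an experiment effect on
#' the shared genotypes; for traits with `p < alpha`, a least-squares
#' line of reference-experiment genotype means on target-experiment
#' genotype means is proposed as the correction `(intercept, slope)`.
#' Calibration is on genotype means.
#'
#' @param records replicate-level phenotype table containing the shared
#'   genotypes in both experiments.
#' @param reference,target experiment ids (`target` is the one to be
#'   corrected).
#' @param traits trait columns to examine.
#' @param alpha significance level for proposing a correction.
#' @return A data frame per trait: `trait, p_experiment, n_shared,
#'   intercept, slope` (coefficients `NA` where no correction is
#'   proposed).
#' @export
estimate_experiment_offset <- function(records, reference = "Exp1",
                                       target = "Exp2",
                                       traits = c("mass_mg", "age_d",
                                                  "growth_mg_per_d", "fruit_n"),
                                       alpha = 0.05) {
  out <- lapply(traits, function(tr) {
    sub <- records[records$experiment %in% c(reference, target) &
                     !is.na(records[[tr]]), ]
    shared <- intersect(sub$genotype_id[sub$experiment == reference],
                        sub$genotype_id[sub$experiment == target])
    if (length(shared) < 3)
      stop("need >= 3 genotypes shared between experiments (trait ", tr, ")")
    sub <- sub[sub$genotype_id %in% shared, ]
    geno <- factor(sub$genotype_id); expf <- factor(sub$experiment)
    tab <- summary(aov(sub[[tr]] ~ geno * expf))[[1]]
    if (!"Pr(>F)" %in% colnames(tab)) {
      # saturated (one replicate per cell): test from the additive model
      tab <- summary(aov(sub[[tr]] ~ geno + expf))[[1]]
    }
    row_exp <- grep("expf", trimws(rownames(tab)))[1]
    p_exp <- suppressWarnings(tab[row_exp, "Pr(>F)"])
    intercept <- slope <- NA_real_
    if (length(p_exp) == 1 && is.finite(p_exp) && p_exp < alpha) {
      mt <- tapply(sub[[tr]][sub$experiment == target],
                   sub$genotype_id[sub$experiment == target], mean)
      mr <- tapply(sub[[tr]][sub$experiment == reference],
                   sub$genotype_id[sub$experiment == reference], mean)
      mt <- mt[shared]; mr <- mr[shared]
      lf <- lm(mr ~ mt)
      intercept <- unname(coef(lf)[1]); slope <- unname(coef(lf)[2])
    }
    data.frame(trait = tr, p_experiment = p_exp, n_shared = length(shared),
               intercept = intercept, slope = slope,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Apply a linear cross-experiment correction to one trait
#'
#' Replaces `trait` in the target experiment by
#' `intercept + slope * observed` (e.g. a correction of
#' `(-37, 1.8)` maps an observed age of 50 d to 53 d). Corrected values
#' `<= 0` are flagged invalid (set `NA` and reported).
#'
#' @param records replicate-level phenotype table.
#' @param trait trait column to correct (default `"age_d"`).
#' @param coefficients numeric `c(intercept, slope)`.
#' @param experiment experiment id to which the correction applies.
#' @return The corrected table, with attribute `"correction"` listing
#'   the coefficients and any rows flagged invalid.
#' @export
correct_experiment_offset <- function(records, trait = "age_d",
                                      coefficients, experiment = "Exp2") {
  if (length(coefficients) != 2 || any(!is.finite(coefficients)))
    stop("coefficients must be finite c(intercept, slope)")
  sel <- records$experiment == experiment & !is.na(records[[trait]])
  corrected <- coefficients[1] + coefficients[2] * records[[trait]][sel]
  invalid <- which(sel)[corrected <= 0]
  corrected[corrected <= 0] <- NA_real_
  records[[trait]][sel] <- corrected
  attr(records, "correction") <- list(trait = trait, experiment = experiment,
                                      intercept = coefficients[1],
                                      slope = coefficients[2],
                                      invalid_rows = invalid)
  records
}

#' Aggregate replicate records to genotype summaries
#'
#' Per genotype and trait: mean, sd and replicate count over non-missing
#' replicates. The sd is `NA` for a single replicate. Aggregation is
#' permutation-invariant and idempotent (re-aggregating genotype means
#' returns them unchanged, with n = 1).
#'
#' @param records replicate-level phenotype table.
#' @param traits trait columns to summarize.
#' @return A data frame, one row per genotype: `genotype_id, type,
#'   parent1, parent2`, then `<trait>`, `<trait>_sd`, `<trait>_n` per
#'   trait (the bare trait column is the mean).
#' @export
summarize_genotypes <- function(records,
                                traits = c("mass_mg", "age_d",
                                           "growth_mg_per_d", "fruit_n")) {
  ids <- unique(records$genotype_id)
  meta <- records[!duplicated(records$genotype_id),
                  c("genotype_id", "type", "parent1", "parent2")]
  rownames(meta) <- meta$genotype_id
  out <- meta[ids, , drop = FALSE]
  for (tr in traits) {
    if (!tr %in% names(records)) next
    v <- records[[tr]]
    ok <- !is.na(v)
    mean_v <- tapply(v[ok], factor(records$genotype_id[ok], levels = ids), mean)
    sd_v <- tapply(v[ok], factor(records$genotype_id[ok], levels = ids), sd)
    n_v <- tapply(v[ok], factor(records$genotype_id[ok], levels = ids), length)
    out[[tr]] <- as.numeric(mean_v)
    out[[paste0(tr, "_sd")]] <- as.numeric(sd_v)
    out[[paste0(tr, "_n")]] <- as.integer(ifelse(is.na(n_v), 0L, n_v))
  }
  rownames(out) <- NULL
  out
}
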