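#' @name meta_engine
#' @title Inverse-variance pooling and heterogeneity
#'
#' @description
#' Fixed-effect and DerSimonian-Laird random-effects pooling of per-study
#' log odds ratios, with Cochran's Q, the I-squared statistic and the
#' moment estimator of the between-study variance tau-squared.  The
#' random-effects estimate is the primary reported result throughout the
#' package; the fixed-effect estimate serves as a diagnostic and as the
#' tau-squared = 0 limit.
NULL

# normalize any of: data.frame(log_or, se), list of study_effect,
# single study_effect -> data.frame(study_id, log_or, se)
.as_effects <- function(effects) {
  if (inherits(effects, "study_effect")) effects <- list(effects)
  if (is.list(effects) && !is.data.frame(effects) &&
      all(vapply(effects, inherits, logical(1), "study_effect"))) {
    effects <- data.frame(
      study_id = vapply(effects, function(e) as.character(e$study_id),
                        character(1)),
      log_or = vapply(effects, function(e) e$log_or, numeric(1)),
      se = vapply(effects, function(e) e$se, numeric(1)),
      stringsAsFactors = FALSE)
  }
  effects <- as.data.frame(effects)
  stopifnot(all(c("log_or", "se") %in% names(effects)))
  if (!"study_id" %in% names(effects))
    effects$study_id <- as.character(seq_len(nrow(effects)))
  stopifnot(all(effects$se > 0), all(is.finite(effects$log_or)))
  effects
}

.need_k <- function(effects, k, what) {
  if (nrow(effects) < k)
    .stop2("insufficient_data",
           sprintf("%s needs at least %d effects (got %d)",
                   what, k, nrow(effects)))
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights `w_i = 1/se_i^2`; pooled log OR is the weighted mean and its
#' standard error `1/sqrt(sum(w))`.
#'
#' @param effects per-study effects: a data frame with columns `log_or`
#'   and `se`, or a list of `study_effect` objects.
#' @return list with `log_or`, `se`, `k`.
#' @export
pool_fixed <- function(effects) {
  effects <- .as_effects(effects)
  .need_k(effects, 2L, "fixed-effect pooling")
  w <- 1 / effects$se^2
  list(log_or = sum(w * effects$log_or) / sum(w),
       se = 1 / sqrt(sum(w)), k = nrow(effects))
}

#' Cochran's Q homogeneity statistic
#'
#' `Q = sum(w_i * (theta_i - theta_fixed)^2)` with fixed-effect weights;
#' under homogeneity Q is chi-square with `k - 1` degrees of freedom,
#' giving the heterogeneity p-value `p_het`.
#'
#' @inheritParams pool_fixed
#' @return list with `q`, `df`, `p_het`.
#' @export
cochran_q <- function(effects) {
  effects <- .as_effects(effects)
  .need_k(effects, 2L, "Cochran's Q")
  w <- 1 / effects$se^2
  mu <- sum(w * effects$log_or) / sum(w)
  q <- sum(w * (effects$log_or - mu)^2)
  df <- nrow(effects) - 1L
  list(q = q, df = df, p_het = pchisq(q, df, lower.tail = FALSE))
}

#' I-squared heterogeneity percentage
#'
#' `I2 = max(0, (Q - df) / Q) * 100`; 0 when `Q = 0`.
#'
#' @param q Cochran's Q.
#' @param df its degrees of freedom (`k - 1`).
#' @return percentage in `[0, 100]`.
#' @export
i_squared <- function(q, df) {
  stopifnot(df >= 1, q >= 0)
  if (q <= 0) return(0)
  max(0, (q - df) / q) * 100
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator `tau2 = max(0, (Q - df) / (sum(w) -
#' sum(w^2)/sum(w)))` with fixed-effect weights `w`.
#'
#' @inheritParams pool_fixed
#' @return non-negative `tau2`.
#' @export
dl_tau2 <- function(effects) {
  effects <- .as_effects(effects)
  .need_k(effects, 2L, "DerSimonian-Laird tau-squared")
  w <- 1 / effects$se^2
  qq <- cochran_q(effects)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (qq$q - qq$df) / denom)
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Re-weights each study by `1/(se_i^2 + tau2)` and pools as in
#' [pool_fixed()].  The 95% confidence interval uses the normal quantile
#' 1.96 and the two-sided p-value comes from the standard normal deviate
#' `z = log_or / se`.  With `tau2 = 0` this reduces exactly to the
#' fixed-effect result.
#'
#' @inheritParams pool_fixed
#' @param tau2 between-study variance; estimated by [dl_tau2()] when
#'   `NULL`.
#' @return list with `log_or`, `se`, `or`, `ci_low`, `ci_high`, `z`, `p`,
#'   `tau2`, `k`.
#' @export
pool_random <- function(effects, tau2 = NULL) {
  effects <- .as_effects(effects)
  .need_k(effects, 2L, "random-effects pooling")
  if (is.null(tau2)) tau2 <- dl_tau2(effects)
  w <- 1 / (effects$se^2 + tau2)
  mu <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- mu / se
  list(log_or = mu, se = se, or = exp(mu),
       ci_low = exp(mu - 1.96 * se), ci_high = exp(mu + 1.96 * se),
       z = z, p = 2 * pnorm(-abs(z)), tau2 = tau2, k = nrow(effects))
}

#' Classify heterogeneity from I-squared
#'
#' Mild below 25%, moderate from 25% to 50% inclusive, large above 50%.
#'
#' @param i2 I-squared percentage.
#' @return `"mild"`, `"moderate"` or `"large"`.
#' @export
classify_heterogeneity <- function(i2) {
  stopifnot(i2 >= 0, i2 <= 100)
  if (i2 < 25) "mild" else if (i2 <= 50) "moderate" else "large"
}

#' Two-sided Wald p-value implied by a printed OR and 95% CI
#'
#' Back-calculates the log-scale standard error from the interval width,
#' `se = (log(hi) - log(lo)) / (2 * 1.96)`, and returns
#' `2 * pnorm(-abs(log(or)/se))`.  Used for self-consistency checks of
#' published OR / CI / P triplets.
#'
#' @param or,lo,hi pooled odds ratio and its 95% confidence bounds.
#' @return two-sided p-value.
#' @export
wald_p_from_ci <- function(or, lo, hi) {
  stopifnot(or > 0, lo > 0, hi > lo)
  se <- (log(hi) - log(lo)) / (2 * 1.96)
  2 * pnorm(-abs(log(or) / se))
}

# count independent sources: distinct publications; studies without a
# pubmed id count individually
.n_sources <- function(records) {
  pm <- as.character(records$pubmed_id)
  has_pm <- !is.na(pm) & nzchar(pm)
  length(unique(pm[has_pm])) + sum(!has_pm)
}

# filter a study table down to one variant x model x subgroup
.filter_records <- function(table, rsid, subgroup = NULL) {
  records <- as.data.frame(table)
  records <- records[records$rsid == rsid, , drop = FALSE]
  label <- "all"
  if (!is.null(subgroup) && length(subgroup) > 0L) {
    for (dim in names(subgroup)) {
      records <- records[records[[dim]] == subgroup[[dim]], , drop = FALSE]
    }
    label <- paste(unlist(subgroup), collapse = "/")
  }
  list(records = records, label = label)
}

# per-study effects for a record set under one model; degenerate tables
# are dropped with a reason
.study_effects <- function(records, model) {
  kept <- list(); dropped <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    eff <- tryCatch(
      study_odds_ratio(build_contrast(rec, model), study_id = rec$study_id),
      genesynopsis_error = function(e) e)
    if (inherits(eff, "study_effect")) kept[[length(kept) + 1L]] <- eff
    else dropped[[length(dropped) + 1L]] <-
        data.frame(study_id = rec$study_id,
                   reason = conditionMessage(eff),
                   stringsAsFactors = FALSE)
  }
  list(effects = kept,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else data.frame(study_id = character(),
                                 reason = character()))
}

# pool an effects set into the meta_result core fields
.pool_summary <- function(effects_df) {
  fixed <- pool_fixed(effects_df)
  qq <- cochran_q(effects_df)
  tau2 <- dl_tau2(effects_df)
  rand <- pool_random(effects_df, tau2 = tau2)
  i2 <- i_squared(qq$q, qq$df)
  list(fixed = fixed, q = qq$q, q_df = qq$df, p_het = qq$p_het,
       i2 = i2, tau2 = tau2, random = rand,
       het_class = classify_heterogeneity(i2))
}

#' Meta-analysis of one variant under one genetic model
#'
#' Filters the study table to one variant (optionally one subgroup),
#' derives per-study contrasts and odds ratios, checks the eligibility
#' rule of at least three independent sources (distinct publications; two
#' cohorts within one publication count once toward eligibility but both
#' contribute effects), and pools by the DerSimonian-Laird random-effects
#' method, with the fixed-effect result retained as a diagnostic.
#'
#' @param table a `study_table`.
#' @param rsid the variant to analyse.
#' @param model genetic model (see [build_contrast()]).
#' @param subgroup optional named list/vector restricting the analysis,
#'   e.g. `c(ethnicity = "Asian")` or `c(virus_type = "HBV")`.
#' @param min_sources eligibility threshold on independent sources
#'   (default 3).
#' @return a `meta_result`: pooled OR with 95% CI and p (random effects),
#'   Q, `p_het`, I-squared, tau-squared, heterogeneity class, study and
#'   subject counts, effect-allele frequency and allele-count totals
#'   (genotype scheme), the per-study effects and the fixed-effect
#'   diagnostic.
#' @export
meta_analyze <- function(table, rsid, model = "additive", subgroup = NULL,
                         min_sources = 3L) {
  model <- match.arg(model, .MODELS)
  flt <- .filter_records(table, rsid, subgroup)
  records <- flt$records
  if (nrow(records) == 0L)
    .stop2("eligibility_error",
           sprintf("no records for %s [%s]", rsid, flt$label),
           n_sources = 0L)
  schemes <- unique(records$variant_scheme)
  if (length(schemes) > 1L)
    .stop2("applicability_error",
           "genotype- and carrier-scheme records cannot be pooled together")
  n_src <- .n_sources(records)
  if (n_src < min_sources)
    .stop2("eligibility_error",
           sprintf("%s [%s]: %d independent source(s), need %d",
                   rsid, flt$label, n_src, min_sources),
           n_sources = n_src)
  se_list <- .study_effects(records, model)
  effects_df <- .as_effects(se_list$effects)
  res <- .pool_summary(effects_df)

  scheme <- schemes[1]
  if (scheme == "genotype") {
    eaf <- effect_allele_frequency(records, arm = "controls")
    n_cases <- sum(records$case_n_AA + records$case_n_Aa + records$case_n_aa)
    n_controls <- sum(records$control_n_AA + records$control_n_Aa +
                        records$control_n_aa)
    allele_count <- sum(2 * (records$case_n_AA + records$control_n_AA) +
                          records$case_n_Aa + records$control_n_Aa)
  } else {
    eaf <- NA_real_
    n_cases <- sum(records$case_n_present + records$case_n_null)
    n_controls <- sum(records$control_n_present + records$control_n_null)
    allele_count <- sum(records$case_n_present + records$control_n_present)
  }
  structure(list(
    variant = rsid,
    gene = records$gene[1],
    comparison = paste(records$effect_allele[1], "vs",
                       records$other_allele[1]),
    model = model,
    subgroup = flt$label,
    k = nrow(effects_df),
    n_sources = n_src,
    n_cases = n_cases, n_controls = n_controls,
    eaf = eaf, allele_count = allele_count,
    or_pooled = res$random$or,
    ci_low = res$random$ci_low, ci_high = res$random$ci_high,
    p = res$random$p,
    q = res$q, q_df = res$q_df, p_het = res$p_het,
    i2 = res$i2, tau2 = res$tau2,
    het_class = res$het_class,
    method = "random",
    or_fixed = exp(res$fixed$log_or),
    log_or = res$random$log_or, se = res$random$se,
    effects = effects_df,
    dropped = se_list$dropped,
    scheme = scheme
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s %s (%s model, %s): %d studies, %d sources\n",
              x$gene, x$variant, x$model, x$subgroup, x$k, x$n_sources))
  cat(sprintf("  random-effects OR %.2f (95%% CI %.2f-%.2f), p = %s\n",
              x$or_pooled, x$ci_low, x$ci_high, .format_p(x$p)))
  cat(sprintf("  Q = %.2f (df %d, p = %.3f), I2 = %.1f%% (%s), tau2 = %.4f\n",
              x$q, x$q_df, x$p_het, x$i2, x$het_class, x$tau2))
  invisible(x)
}
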