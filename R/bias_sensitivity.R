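#' @name bias_sensitivity
#' @title Publication-bias tests and sensitivity analyses
#'
#' @description
#' Small-study / publication-bias diagnostics (Egger's regression, Begg's
#' rank correlation, funnel-plot data) and the two standard sensitivity
#' analyses of a field synopsis: leave-one-out re-pooling and exclusion
#' of studies whose controls deviate from Hardy-Weinberg equilibrium.
#' Both bias tests have low power at small study counts; results with
#' fewer than 10 studies are flagged `low_power`.
NULL

#' Egger's linear regression test for funnel asymmetry
#'
#' Ordinary least-squares regression of the standardized effect
#' `theta_i / se_i` on the precision `1 / se_i` (the classic
#' formulation).  The intercept estimates funnel asymmetry; its two-sided
#' p-value uses a t distribution with `k - 2` degrees of freedom.
#'
#' @inheritParams pool_fixed
#' @return list with `intercept`, `se`, `t`, `p`, `k`, `low_power`.
#' @export
egger_test <- function(effects) {
  effects <- .as_effects(effects)
  .need_k(effects, 3L, "Egger's test")
  prec <- 1 / effects$se
  snd <- effects$log_or / effects$se
  if (var(prec) < .Machine$double.eps)
    .stop2("degenerate_regression",
           "all standard errors identical: precision has no spread")
  fit <- lm(snd ~ prec)
  sm <- summary(fit)$coefficients
  k <- nrow(effects)
  tval <- sm["(Intercept)", "t value"]
  list(intercept = sm["(Intercept)", "Estimate"],
       se = sm["(Intercept)", "Std. Error"],
       t = tval,
       p = 2 * pt(-abs(tval), df = k - 2L),
       k = k, low_power = k < 10L)
}

# Kendall pair counting with tau-b tie normalisation and the
# tie-corrected normal approximation for the test
.kendall <- function(x, y) {
  n <- length(x)
  cd <- 0; nx <- 0; ny <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      cd <- cd + sx * sy
      nx <- nx + (sx != 0); ny <- ny + (sy != 0)
    }
  }
  n0 <- n * (n - 1) / 2
  tau <- if (nx == 0 || ny == 0) 0 else cd / sqrt(nx * ny)
  # tie-corrected variance of S = C - D (Kendall 1970)
  tx <- table(x); ty <- table(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (var_s <= 0) 0 else cd / sqrt(var_s)
  list(tau = tau, s = cd, z = z, p = 2 * pnorm(-abs(z)))
}

#' Begg and Mazumdar's rank correlation test
#'
#' Kendall rank correlation between the standardized deviates
#' `(theta_i - theta_fixed) / sqrt(v_i - v_fixed)` and the sampling
#' variances `v_i`, where `theta_fixed` and `v_fixed` are the
#' fixed-effect pooled estimate and its variance.  The radicand is
#' floored at 1e-12.  The two-sided p-value uses the tie-corrected
#' normal approximation.
#'
#' @inheritParams pool_fixed
#' @return list with `tau`, `z`, `p`, `k`, `low_power`.
#' @export
begg_test <- function(effects) {
  effects <- .as_effects(effects)
  .need_k(effects, 3L, "Begg's test")
  fixed <- pool_fixed(effects)
  v <- effects$se^2
  vstar <- pmax(v - fixed$se^2, 1e-12)
  dev <- (effects$log_or - fixed$log_or) / sqrt(vstar)
  kt <- .kendall(dev, v)
  list(tau = kt$tau, z = kt$z, p = kt$p, k = nrow(effects),
       low_power = nrow(effects) < 10L)
}

#' Funnel-plot data
#'
#' Plot-ready per-study points (log OR vs standard error) with the
#' random-effects pooled log OR as the reference line.  No rendering is
#' done here.
#'
#' @inheritParams pool_fixed
#' @return list with `points` (data frame `study_id`, `log_or`, `se`) and
#'   `reference` (pooled random-effects log OR, `NA` for k < 2).
#' @export
funnel_data <- function(effects) {
  effects <- .as_effects(effects)
  ref <- if (nrow(effects) >= 2L) pool_random(effects)$log_or else NA_real_
  list(points = effects[, c("study_id", "log_or", "se")], reference = ref)
}

# re-pool an effect subset without the >=3-source eligibility gate
.repool_row <- function(effects_df, omitted, alpha = 0.05) {
  res <- .pool_summary(effects_df)
  data.frame(omitted = omitted,
             k = nrow(effects_df),
             or = res$random$or,
             ci_low = res$random$ci_low,
             ci_high = res$random$ci_high,
             p = res$random$p,
             i2 = res$i2,
             significant = res$random$p < alpha,
             sub_threshold = nrow(effects_df) < 3L,
             stringsAsFactors = FALSE)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the meta-analysis omitting each study in turn.  The result is
#' `robust` when no single omission flips significance at `alpha`.
#' Omission results that fall below three studies are computed but
#' flagged `sub_threshold`.
#'
#' @inheritParams meta_analyze
#' @param alpha significance level for the robustness flag (default 0.05).
#' @return a `sensitivity_result`: list with `baseline` (the full
#'   `meta_result`), `leave_one_out` (data frame of k re-pooled results)
#'   and `robust`.
#' @export
leave_one_out <- function(table, rsid, model = "additive", subgroup = NULL,
                          alpha = 0.05, min_sources = 3L) {
  baseline <- meta_analyze(table, rsid, model, subgroup,
                           min_sources = min_sources)
  eff <- baseline$effects
  rows <- lapply(seq_len(nrow(eff)), function(i)
    .repool_row(eff[-i, , drop = FALSE], omitted = eff$study_id[i],
                alpha = alpha))
  loo <- do.call(rbind, rows)
  base_sig <- baseline$p < alpha
  structure(list(baseline = baseline, leave_one_out = loo,
                 robust = all(loo$significant == base_sig)),
            class = "sensitivity_result")
}

#' HWE-exclusion sensitivity analysis
#'
#' Re-pools the meta-analysis after excluding studies whose control
#' genotype distribution deviates from Hardy-Weinberg equilibrium at
#' `alpha` (see [hwe_test()]).  Deviation in controls may denote
#' genotyping error or selection bias, so the primary analysis keeps all
#' studies and this re-analysis probes their influence.
#'
#' @inheritParams leave_one_out
#' @param alpha significance level of the HWE test (default 0.05).
#' @return list with `baseline`, `hwe_excluded` (re-pooled result, or
#'   `NULL` when nothing was excluded), `excluded_ids` and `reason`
#'   (non-`NA` when the surviving subset was too small to pool).
#' @export
hwe_sensitivity <- function(table, rsid, model = "additive", subgroup = NULL,
                            alpha = 0.05, min_sources = 3L) {
  baseline <- meta_analyze(table, rsid, model, subgroup,
                           min_sources = min_sources)
  if (baseline$scheme != "genotype")
    .stop2("applicability_error",
           "HWE sensitivity applies to genotype-scheme records only")
  records <- .filter_records(table, rsid, subgroup)$records
  viol <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    hwe_test(c(r$control_n_AA, r$control_n_Aa, r$control_n_aa),
             alpha = alpha)$violated
  }, logical(1))
  excluded_ids <- records$study_id[viol]
  out <- list(baseline = baseline, hwe_excluded = NULL,
              excluded_ids = excluded_ids, reason = NA_character_)
  if (length(excluded_ids) == 0L) return(out)
  keep <- baseline$effects[!baseline$effects$study_id %in% excluded_ids, ,
                           drop = FALSE]
  if (nrow(keep) < 2L) {
    out$reason <- sprintf(
      "only %d study(ies) pass HWE: subset not poolable", nrow(keep))
    return(out)
  }
  out$hwe_excluded <- .repool_row(keep, omitted = NA_character_)
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("leave-one-out over %d studies: baseline OR %.2f (p = %s), %s\n",
              x$baseline$k, x$baseline$or_pooled, .format_p(x$baseline$p),
              if (x$robust) "robust" else "NOT robust"))
  invisible(x)
}
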