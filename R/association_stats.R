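#' Per-study odds ratio from a 2x2 contrast
#'
#' Cross-product odds ratio on the log scale with the Woolf standard
#' error `sqrt(1/a + 1/b + 1/c + 1/d)`.  If any raw cell is zero, 0.5 is
#' added to all four cells before computing (Haldane-Anscombe continuity
#' correction) and the result is flagged `corrected`.
#'
#' @param table a `contrast_table` from [build_contrast()], or a numeric
#'   vector `c(case_exposed, case_unexposed, control_exposed,
#'   control_unexposed)`.
#' @param study_id optional identifier carried through to pooling.
#' @return a `study_effect`: list with `log_or`, `se`, `corrected`,
#'   `study_id`.
#' @examples
#' study_odds_ratio(c(10, 20, 30, 40))  # OR = 2/3
#' @export
study_odds_ratio <- function(table, study_id = NA_character_) {
  cells <- if (inherits(table, "contrast_table"))
    c(table$case_exposed, table$case_unexposed,
      table$control_exposed, table$control_unexposed)
  else as.numeric(table)
  stopifnot(length(cells) == 4L, all(cells >= 0))
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    .stop2("degenerate_table",
           "a full row or column of the 2x2 table is zero")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  structure(list(
    log_or = log(cells[1] * cells[4] / (cells[2] * cells[3])),
    se = sqrt(sum(1 / cells)),
    corrected = corrected,
    study_id = study_id
  ), class = "study_effect")
}

#' Hardy-Weinberg equilibrium test on control genotypes
#'
#' Asymptotic 1-df Pearson chi-square comparing observed control genotype
#' counts `(n_AA, n_Aa, n_aa)` with the Hardy-Weinberg expectation
#' `n * (p^2, 2pq, q^2)`, `p` estimated as the control effect-allele
#' frequency.  No continuity correction is applied.  Monomorphic controls
#' (`p` of 0 or 1) satisfy HWE trivially and are returned with
#' `degenerate = TRUE`.
#'
#' @param control_counts numeric vector `(n_AA, n_Aa, n_aa)`.
#' @param alpha significance level used to set the `violated` flag
#'   (default 0.05).
#' @return an `hwe_result`: list with `chi2`, `p`, `violated`,
#'   `degenerate`.
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE proportions: chi2 = 0, p = 1
#' @export
hwe_test <- function(control_counts, alpha = 0.05) {
  obs <- as.numeric(control_counts)
  stopifnot(length(obs) == 3L, all(obs >= 0))
  n <- sum(obs)
  if (n < 1) .stop2("insufficient_data", "no control subjects")
  p <- (2 * obs[1] + obs[2]) / (2 * n)
  if (p <= 0 || p >= 1) {
    return(structure(list(chi2 = 0, p = 1, violated = FALSE,
                          degenerate = TRUE), class = "hwe_result"))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((obs - expected)^2 / expected)
  pval <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(chi2 = chi2, p = pval, violated = pval < alpha,
                 degenerate = FALSE), class = "hwe_result")
}

#' @export
print.study_effect <- function(x, ...) {
  cat(sprintf("study effect%s: OR = %.4f (log OR %.4f, SE %.4f)%s\n",
              if (is.na(x$study_id)) "" else paste0(" [", x$study_id, "]"),
              exp(x$log_or), x$log_or, x$se,
              if (x$corrected) ", continuity-corrected" else ""))
  invisible(x)
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.3f (1 df), p = %.4g%s%s\n", x$chi2, x$p,
              if (x$violated) " [deviates from HWE]" else "",
              if (x$degenerate) " [monomorphic controls]" else ""))
  invisible(x)
}
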