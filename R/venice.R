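#' @name venice
#' @title Venice-criteria grading of cumulative evidence
#'
#' @description
#' The Venice criteria grade each nominally significant meta-analysis on
#' three axes, each scored A/B/C: *amount of evidence* (total copies of
#' the tested allele among cases and controls combined), *replication*
#' (between-study heterogeneity via I-squared) and *protection from
#' bias*.  The composite label is **strong** when all three letters are
#' A, **weak** when any letter is C, and **moderate** otherwise.
#'
#' Parts of the bias axis require judgment that cannot be automated
#' (genotyping error, population stratification, phenotype
#' misclassification); [grade_bias()] automates the effect-magnitude and
#' Egger-test rules and accepts manual flags for the rest.
NULL

#' Grade the amount of evidence
#'
#' A above 1,000 tested-allele copies, B from 100 to 1,000 inclusive, C
#' below 100.  For rare variants (frequency below 1%) an A grade may be
#' unobtainable however large the studies; a caution is attached via the
#' `"rare_variant"` attribute.
#'
#' @param allele_count total copies of the tested (effect) allele among
#'   cases and controls combined.
#' @param frequency optional effect-allele frequency used for the
#'   rare-variant caution.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
grade_amount <- function(allele_count, frequency = NA_real_) {
  stopifnot(allele_count >= 0)
  letter <- if (allele_count > 1000) "A"
            else if (allele_count >= 100) "B"
            else "C"
  if (!is.na(frequency) && frequency < 0.01) {
    warning("rare variant (frequency < 1%): amount grade may be capped",
            call. = FALSE)
    attr(letter, "rare_variant") <- TRUE
  }
  letter
}

#' Grade the extent of replication
#'
#' A for I-squared below 25%, B from 25% to 50% inclusive, C above 50%
#' (same cut points as [classify_heterogeneity()]).
#'
#' @param i2 I-squared percentage in `[0, 100]` of the reported model.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
grade_replication <- function(i2) {
  stopifnot(i2 >= 0, i2 <= 100)
  if (i2 < 25) "A" else if (i2 <= 50) "B" else "C"
}

#' Grade protection from bias
#'
#' Automates two rules: (i) an association with summary OR magnitude
#' `max(OR, 1/OR)` below 1.15 is graded C unless it has been replicated
#' prospectively by multiple studies with no evidence of publication bias
#' (`prospective_replication`, a manual flag, default off); (ii) evident
#' publication bias (Egger p below 0.05, or a hard manual flag) gives C,
#' possible bias (Egger p in [0.05, 0.10), or a soft manual flag) gives
#' B, otherwise A.  An unavailable Egger test (k too small) with no flags
#' does not demote the grade.
#'
#' @param or_pooled pooled odds ratio.
#' @param egger_p Egger-test p-value, or `NA` when not computable.
#' @param hard_bias manual flag: bias evident / likely explains the
#'   association.
#' @param soft_bias manual flag: bias could be present.
#' @param prospective_replication manual flag exempting the OR < 1.15
#'   rule.
#' @return `"A"`, `"B"` or `"C"`.
#' @export
grade_bias <- function(or_pooled, egger_p = NA_real_, hard_bias = FALSE,
                       soft_bias = FALSE, prospective_replication = FALSE) {
  stopifnot(or_pooled > 0)
  magnitude <- max(or_pooled, 1 / or_pooled)
  if (hard_bias) return("C")
  if (!is.na(egger_p) && egger_p < 0.05) return("C")
  if (magnitude < 1.15 && !prospective_replication) return("C")
  if (soft_bias) return("B")
  if (!is.na(egger_p) && egger_p < 0.10) return("B")
  "A"
}

#' Combine three letter grades into the cumulative-evidence label
#'
#' Strong iff all three grades are A; weak iff one or more grades are C;
#' moderate for every other combination.  The composite is monotone:
#' degrading any letter never improves the label.
#'
#' @param amount,replication,bias letters in `{A, B, C}`.
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
venice_composite <- function(amount, replication, bias) {
  letters3 <- c(amount, replication, bias)
  stopifnot(all(letters3 %in% c("A", "B", "C")))
  if (all(letters3 == "A")) return("strong")
  if (any(letters3 == "C")) return("weak")
  "moderate"
}

#' Grade a pooled result on the Venice criteria
#'
#' Assembles the three letters and the composite label for one
#' meta-analysis, recording which rule fired for each axis.
#'
#' @param meta a `meta_result` from [meta_analyze()].
#' @param bias a bias-test result from [egger_test()], or `NULL` when not
#'   computable.
#' @param allele_count override for the tested-allele total (defaults to
#'   the count carried by `meta`).
#' @param hard_bias,soft_bias,prospective_replication manual bias flags,
#'   see [grade_bias()].
#' @return a `venice_grade`: list with `amount`, `replication`, `bias`,
#'   `composite`, `grade_string` (e.g. `"ABA"`) and a `rationale` string.
#' @export
venice_grade <- function(meta, bias = NULL, allele_count = NULL,
                         hard_bias = FALSE, soft_bias = FALSE,
                         prospective_replication = FALSE) {
  if (is.null(allele_count)) allele_count <- meta$allele_count
  egger_p <- if (is.null(bias)) NA_real_ else bias$p
  a <- grade_amount(allele_count,
                    frequency = if (is.null(meta$eaf)) NA_real_ else meta$eaf)
  r <- grade_replication(meta$i2)
  b <- grade_bias(meta$or_pooled, egger_p = egger_p, hard_bias = hard_bias,
                  soft_bias = soft_bias,
                  prospective_replication = prospective_replication)
  rationale <- paste(
    sprintf("amount=%s (%d tested-allele copies)", a, round(allele_count)),
    sprintf("replication=%s (I2 = %.1f%%)", r, meta$i2),
    sprintf("bias=%s (OR magnitude %.2f, Egger p %s)", b,
            max(meta$or_pooled, 1 / meta$or_pooled),
            if (is.na(egger_p)) "not computable" else sprintf("%.3f", egger_p)),
    sep = "; ")
  structure(list(amount = as.character(a), replication = r, bias = b,
                 composite = venice_composite(a, r, b),
                 grade_string = paste0(a, r, b),
                 rationale = rationale),
            class = "venice_grade")
}

#' @export
print.venice_grade <- function(x, ...) {
  cat(sprintf("Venice grade %s -> %s\n  %s\n", x$grade_string,
              x$composite, x$rationale))
  invisible(x)
}
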