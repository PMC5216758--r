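#' Collapse genotype counts into a 2x2 contrast table
#'
#' Derives the case/control x exposed/unexposed table for one study under
#' a genetic model.  With A the effect allele and a the other allele:
#' \describe{
#'   \item{additive}{allele contrast, A vs a: exposed = `2*n_AA + n_Aa`
#'     allele copies per arm, unexposed = `2*n_aa + n_Aa` (table counts
#'     alleles, totals are twice the subject totals).}
#'   \item{dominant}{carriers vs non-carriers: `(AA + Aa)` vs `aa`.}
#'   \item{recessive}{homozygotes vs the rest: `AA` vs `(Aa + aa)`.}
#'   \item{carrier}{present vs null, for deletion-type variants recorded
#'     on the carrier scheme.}
#' }
#' The additive, dominant and recessive models apply only to
#' genotype-scheme records; the carrier model only to carrier-scheme
#' records.  Orientation is fixed by the declared effect allele and never
#' re-derived from minor-allele frequency, which can flip between
#' populations.
#'
#' @param record one study record (single-row data frame or list with the
#'   study-table count fields).
#' @param model one of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"carrier"`.
#' @return a `contrast_table`: list with `case_exposed`, `case_unexposed`,
#'   `control_exposed`, `control_unexposed`, `unit` (`"alleles"` or
#'   `"subjects"`) and `model`.
#' @examples
#' rec <- list(variant_scheme = "genotype",
#'             case_n_AA = 10, case_n_Aa = 20, case_n_aa = 30,
#'             control_n_AA = 25, control_n_Aa = 50, control_n_aa = 25)
#' build_contrast(rec, "additive")$case_exposed   # 40 allele copies
#' build_contrast(rec, "dominant")$case_exposed   # 30 carriers
#' @export
build_contrast <- function(record, model) {
  model <- match.arg(model, .MODELS)
  scheme <- record$variant_scheme
  if (model == "carrier" && scheme != "carrier")
    .stop2("applicability_error",
           "carrier model applies only to carrier-scheme records")
  if (model != "carrier" && scheme != "genotype")
    .stop2("applicability_error",
           sprintf("%s model applies only to genotype-scheme records", model))
  if (scheme == "carrier") {
    tab <- list(case_exposed = record$case_n_present,
                case_unexposed = record$case_n_null,
                control_exposed = record$control_n_present,
                control_unexposed = record$control_n_null,
                unit = "subjects")
  } else {
    cs <- c(record$case_n_AA, record$case_n_Aa, record$case_n_aa)
    ct <- c(record$control_n_AA, record$control_n_Aa, record$control_n_aa)
    tab <- switch(model,
      additive = list(case_exposed = 2 * cs[1] + cs[2],
                      case_unexposed = 2 * cs[3] + cs[2],
                      control_exposed = 2 * ct[1] + ct[2],
                      control_unexposed = 2 * ct[3] + ct[2],
                      unit = "alleles"),
      dominant = list(case_exposed = cs[1] + cs[2],
                      case_unexposed = cs[3],
                      control_exposed = ct[1] + ct[2],
                      control_unexposed = ct[3],
                      unit = "subjects"),
      recessive = list(case_exposed = cs[1],
                       case_unexposed = cs[2] + cs[3],
                       control_exposed = ct[1],
                       control_unexposed = ct[2] + ct[3],
                       unit = "subjects"))
  }
  tab$model <- model
  structure(tab, class = "contrast_table")
}

#' Effect-allele frequency across studies
#'
#' Pooled count-based frequency of the effect allele,
#' `sum(2*n_AA + n_Aa) / sum(2*N)`, over the chosen arm of
#' genotype-scheme records of a single variant.
#'
#' @param records study records (data frame), all `variant_scheme ==
#'   "genotype"` and sharing one `rsid`.
#' @param arm `"pooled"` (cases + controls), `"cases"` or `"controls"`.
#' @return frequency in `[0, 1]`.
#' @export
effect_allele_frequency <- function(records,
                                    arm = c("pooled", "cases", "controls")) {
  arm <- match.arg(arm)
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    .stop2("insufficient_data", "no records supplied")
  if (any(records$variant_scheme != "genotype"))
    .stop2("applicability_error",
           "allele frequency defined for genotype-scheme records only")
  if (length(unique(records$rsid)) > 1L)
    .stop2("applicability_error", "records span more than one variant")
  eff <- 0; tot <- 0
  if (arm %in% c("pooled", "cases")) {
    eff <- eff + sum(2 * records$case_n_AA + records$case_n_Aa)
    tot <- tot + sum(2 * (records$case_n_AA + records$case_n_Aa +
                            records$case_n_aa))
  }
  if (arm %in% c("pooled", "controls")) {
    eff <- eff + sum(2 * records$control_n_AA + records$control_n_Aa)
    tot <- tot + sum(2 * (records$control_n_AA + records$control_n_Aa +
                            records$control_n_aa))
  }
  eff / tot
}

#' @export
print.contrast_table <- function(x, ...) {
  m <- matrix(c(x$case_exposed, x$case_unexposed,
                x$control_exposed, x$control_unexposed),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("exposed", "unexposed")))
  cat(sprintf("2x2 contrast (%s model, unit = %s)\n", x$model, x$unit))
  print(m)
  invisible(x)
}
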