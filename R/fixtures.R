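#' Bundled 31-row hepatocellular-carcinoma synopsis table
#'
#' Machine-readable transcription of a published field synopsis of
#' candidate-gene association studies in hepatocellular carcinoma: the 31
#' variant x model rows reported as nominally significant, with the
#' pooled OR and 95% CI, the printed two-sided P, the heterogeneity
#' p-value (`ph`) and I-squared, the three-letter Venice grade string and
#' the strong/moderate/weak cumulative-evidence label.  Rows analysed
#' under a dominant or recessive model additionally carry the allelic
#' (`allelic_*`) columns of the same variant.  Printed values are stored
#' verbatim (`p` and `ph` as character, preserving displayed precision;
#' Greek gene symbols transliterated to ASCII).  Used by the
#' self-consistency checks of the grading and Wald machinery.
#'
#' @return data frame of 31 rows.
#' @export
synopsis_fixture <- function() {
  path <- system.file("extdata", "hcc_synopsis_rows.csv",
                      package = "genesynopsis", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(p = "character", ph = "character",
                                allelic_p = "character",
                                allelic_ph = "character"))
  stopifnot(nrow(df) == 31L)
  df
}
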