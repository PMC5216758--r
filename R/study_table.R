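#' @name study_table
#' @title Study tables: one row per study x variant
#'
#' @description
#' The atomic input is a *study record*: genotype (or carrier) counts for
#' cases and controls of one study for one variant, plus metadata.  A
#' *study table* is a data frame of such records.  Genotype columns are
#' keyed to the declared effect allele: `case_n_AA` counts case subjects
#' carrying two copies of `effect_allele`, `case_n_Aa` heterozygotes and
#' `case_n_aa` subjects with none.  Present/null variants (e.g. GSTM1,
#' GSTT1 deletions) use `variant_scheme = "carrier"` with
#' `*_n_present` / `*_n_null` columns instead.
#'
#' @details
#' Required columns: `study_id`, `pubmed_id`, `first_author`, `year`,
#' `gene`, `rsid`, `effect_allele`, `other_allele`, `ethnicity`
#' (Caucasian/Asian/African/mixed), `control_source`
#' (hospital/population/family/unknown), `virus_type`
#' (HBV/HCV/mixed/none/unknown), `variant_scheme` (genotype/carrier) and
#' the count columns for the relevant scheme.  Counts must be
#' non-negative integers and each arm must total at least one subject.
#' Missing `control_source` / `virus_type` values default to `"unknown"`;
#' counts are never imputed.
NULL

.GENO_COUNT_COLS <- c("case_n_AA", "case_n_Aa", "case_n_aa",
                      "control_n_AA", "control_n_Aa", "control_n_aa")
.CARRIER_COUNT_COLS <- c("case_n_present", "case_n_null",
                         "control_n_present", "control_n_null")
.META_COLS <- c("study_id", "pubmed_id", "first_author", "year", "gene",
                "rsid", "effect_allele", "other_allele", "ethnicity",
                "control_source", "virus_type", "variant_scheme")
.ALL_COLS <- c(.META_COLS, .GENO_COUNT_COLS, .CARRIER_COUNT_COLS)

.is_count <- function(x) {
  !is.na(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

#' Validate study records
#'
#' Checks each row of a candidate study table against the record
#' invariants and returns a per-row diagnosis.
#'
#' @param df data frame with at least the required study-table columns.
#' @return data frame with columns `row` (index into `df`) and `problem`
#'   (description); zero rows when everything passes.
#' @export
validate_study_rows <- function(df) {
  problems <- list()
  note <- function(i, msg) problems[[length(problems) + 1L]] <<-
    data.frame(row = i, problem = msg, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$study_id) || !nzchar(r$study_id)) note(i, "empty study_id")
    if (!r$ethnicity %in% .ETHNICITIES)
      note(i, sprintf("ethnicity '%s' not one of %s", r$ethnicity,
                      paste(.ETHNICITIES, collapse = "/")))
    if (!r$control_source %in% .CONTROL_SOURCES)
      note(i, sprintf("control_source '%s' invalid", r$control_source))
    if (!r$virus_type %in% .VIRUS_TYPES)
      note(i, sprintf("virus_type '%s' invalid", r$virus_type))
    if (!r$variant_scheme %in% .SCHEMES) {
      note(i, sprintf("variant_scheme '%s' invalid", r$variant_scheme))
      next
    }
    cols <- if (r$variant_scheme == "genotype") .GENO_COUNT_COLS
            else .CARRIER_COUNT_COLS
    cnt <- as.numeric(r[cols])
    if (!all(.is_count(cnt))) {
      note(i, sprintf("non-integer or negative count in %s",
                      paste(cols[!.is_count(cnt)], collapse = ", ")))
      next
    }
    case_tot <- sum(cnt[grep("^case_", cols)])
    ctrl_tot <- sum(cnt[grep("^control_", cols)])
    if (case_tot < 1) note(i, "case arm has zero subjects")
    if (ctrl_tot < 1) note(i, "control arm has zero subjects")
  }
  if (length(problems) == 0L)
    return(data.frame(row = integer(), problem = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, problems)
}

#' Assemble a validated study table
#'
#' @param records data frame of study records (see [study_table]).
#' @param provenance free-text description of where the records came from.
#' @return the records as a `study_table` data frame (row order preserved).
#' @export
as_study_table <- function(records, provenance = "") {
  missing_cols <- setdiff(c(.META_COLS), names(records))
  if (length(missing_cols) > 0L)
    .stop2("format_error",
           paste0("missing required column(s): ",
                  paste(missing_cols, collapse = ", ")))
  for (col in c(.GENO_COUNT_COLS, .CARRIER_COUNT_COLS))
    if (!col %in% names(records)) records[[col]] <- NA_real_
  # default unknown metadata rather than rejecting the row
  for (col in c("control_source", "virus_type")) {
    x <- as.character(records[[col]])
    x[is.na(x) | !nzchar(x)] <- "unknown"
    records[[col]] <- x
  }
  records$pubmed_id[is.na(records$pubmed_id)] <- ""
  for (col in c(.GENO_COUNT_COLS, .CARRIER_COUNT_COLS))
    records[[col]] <- as.numeric(records[[col]])
  bad <- validate_study_rows(records)
  if (nrow(bad) > 0L)
    .stop2("validation_error",
           paste0("invalid study record(s): ",
                  paste(sprintf("row %d (%s)", bad$row, bad$problem),
                        collapse = "; ")))
  if (anyDuplicated(records$study_id))
    .stop2("validation_error", "duplicate study_id values")
  records <- records[, .ALL_COLS]
  rownames(records) <- NULL
  class(records) <- c("study_table", "data.frame")
  attr(records, "provenance") <- provenance
  records
}

#' Read a study table from CSV
#'
#' @param path path to a CSV file in the canonical dialect (UTF-8, header
#'   row, comma-separated, counts as plain integers).
#' @param strict if `TRUE` (default) any invalid row aborts with a
#'   validation error naming the row; if `FALSE`, invalid rows are dropped
#'   and tallied in the `"dropped"` attribute of the result.
#' @return a `study_table`; with `strict = FALSE` the attribute
#'   `"dropped"` holds the per-row problems of discarded records.
#' @export
read_study_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) .stop2("io_error", paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("study_id", "pubmed_id"), names(df)))
    df[[col]] <- as.character(df[[col]])
  missing_cols <- setdiff(.META_COLS, names(df))
  if (length(missing_cols) > 0L)
    .stop2("format_error",
           paste0("missing required column(s): ",
                  paste(missing_cols, collapse = ", ")))
  dropped <- NULL
  if (!strict) {
    for (col in c(.GENO_COUNT_COLS, .CARRIER_COUNT_COLS))
      if (!col %in% names(df)) df[[col]] <- NA_real_
    for (col in c("control_source", "virus_type")) {
      x <- as.character(df[[col]])
      x[is.na(x) | !nzchar(x)] <- "unknown"
      df[[col]] <- x
    }
    bad <- validate_study_rows(df)
    if (nrow(bad) > 0L) {
      keep <- setdiff(seq_len(nrow(df)), unique(bad$row))
      message(sprintf("read_study_table: dropped %d invalid row(s)",
                      length(unique(bad$row))))
      dropped <- bad
      df <- df[keep, , drop = FALSE]
    }
  }
  out <- as_study_table(df, provenance = path)
  attr(out, "dropped") <- dropped
  out
}

#' Write a study table to CSV
#'
#' Inverse of [read_study_table()]: the written file reads back to a
#' field-identical table, preserving row order.
#'
#' @param table a `study_table`.
#' @param path output path.
#' @export
write_study_table <- function(table, path) {
  stopifnot(inherits(table, "study_table") || is.data.frame(table))
  ok <- tryCatch({
    write.csv(as.data.frame(table)[, .ALL_COLS, drop = FALSE], path,
              row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stop2("io_error", conditionMessage(ok))
  invisible(path)
}

.format_p <- function(p) {
  # three decimals, printed "0" below the displayable floor
  ifelse(p < 5e-4, "0", sprintf("%.3f", p))
}

.format_or_ci <- function(or, lo, hi) sprintf("%.2f(%.2f-%.2f)", or, lo, hi)

.synopsis_row <- function(meta, grade) {
  data.frame(
    gene = if (is.null(meta$gene)) NA_character_ else meta$gene,
    rsid = meta$variant,
    comparison = if (is.null(meta$comparison)) NA_character_ else meta$comparison,
    frequency = if (is.null(meta$eaf)) NA_real_ else round(100 * meta$eaf, 2),
    model = meta$model,
    subgroup = meta$subgroup,
    studies = meta$k,
    cases = meta$n_cases,
    controls = meta$n_controls,
    or_ci = .format_or_ci(meta$or_pooled, meta$ci_low, meta$ci_high),
    p = .format_p(meta$p),
    ph_i2 = sprintf("%s/%.1f%%", .format_p(meta$p_het), meta$i2),
    grade = if (is.null(grade)) NA_character_ else grade$grade_string,
    evidence = if (is.null(grade)) NA_character_ else grade$composite,
    stringsAsFactors = FALSE
  )
}

#' Write a synopsis table
#'
#' Renders pooled results plus their evidence grades in the layout of a
#' printed field-synopsis table: one row per variant x model x subgroup
#' with `OR(95\%CI)`, `P`, `Ph/I2`, the three-letter grade string and the
#' strong/moderate/weak label.
#'
#' @param results list of `list(meta = <meta_result>, grade =
#'   <venice_grade> or NULL)` pairs, or a `synopsis_report` from
#'   [run_synopsis()].
#' @param path output path.
#' @param format `"csv"` or `"markdown"`.
#' @return the formatted data frame, invisibly.
#' @export
write_synopsis <- function(results, path, format = c("csv", "markdown")) {
  if (!format[1] %in% c("csv", "markdown"))
    .stop2("usage_error", paste0("unknown format: ", format[1]))
  format <- format[1]
  if (inherits(results, "synopsis_report")) results <- results$results
  rows <- lapply(results, function(r) .synopsis_row(r$meta, r$grade))
  empty <- data.frame(gene = character(), rsid = character(),
                      comparison = character(), frequency = numeric(),
                      model = character(), subgroup = character(),
                      studies = integer(), cases = integer(),
                      controls = integer(), or_ci = character(),
                      p = character(), ph_i2 = character(),
                      grade = character(), evidence = character(),
                      stringsAsFactors = FALSE)
  tab <- if (length(rows) == 0L) empty else do.call(rbind, rows)
  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE, na = "")
  } else {
    hdr <- paste0("| ", paste(names(tab), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
    body <- apply(tab, 1L, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, body), path)
  }
  invisible(tab)
}
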