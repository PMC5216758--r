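#' Pipeline configuration
#'
#' Bundles the rules of a synopsis run: which genetic models to fit,
#' which subgroup dimensions to stratify by, the eligibility threshold of
#' independent sources, the presentation rule for null results, and the
#' alpha levels.  Defaults follow standard field-synopsis practice:
#' meta-analyses require at least three independent sources; to limit
#' false negatives from allele-orientation ambiguity, variants with no
#' evidence of association are presented only when at least six
#' independent datasets contribute; nominal p-values with no
#' multiple-testing correction.
#'
#' @param models genetic models to fit to genotype-scheme variants
#'   (carrier-scheme variants always use the carrier contrast).
#' @param subgroup_dims subset of `c("ethnicity", "virus_type")`.
#' @param min_sources eligibility threshold (default 3).
#' @param null_presentation_min minimum datasets for presenting a
#'   non-significant variant (default 6).
#' @param hwe_alpha,meta_alpha,egger_alpha significance levels.
#' @param seed integer seed for any resampling step.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(models = c("additive", "dominant", "recessive"),
                            subgroup_dims = "ethnicity",
                            min_sources = 3L, null_presentation_min = 6L,
                            hwe_alpha = 0.05, meta_alpha = 0.05,
                            egger_alpha = 0.05, seed = 1L) {
  models <- match.arg(models, .MODELS, several.ok = TRUE)
  stopifnot(all(subgroup_dims %in% c("ethnicity", "virus_type")),
            min_sources >= 2,
            hwe_alpha > 0, hwe_alpha < 1, meta_alpha > 0, meta_alpha < 1,
            egger_alpha > 0, egger_alpha < 1)
  structure(list(models = models, subgroup_dims = subgroup_dims,
                 min_sources = as.integer(min_sources),
                 null_presentation_min = as.integer(null_presentation_min),
                 hwe_alpha = hwe_alpha, meta_alpha = meta_alpha,
                 egger_alpha = egger_alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

.analyze_one <- function(table, rsid, model, subgroup, config) {
  meta <- meta_analyze(table, rsid, model, subgroup,
                       min_sources = config$min_sources)
  bias <- tryCatch(egger_test(meta$effects),
                   genesynopsis_error = function(e) NULL)
  begg <- tryCatch(begg_test(meta$effects),
                   genesynopsis_error = function(e) NULL)
  sens <- tryCatch(leave_one_out(table, rsid, model, subgroup,
                                 alpha = config$meta_alpha,
                                 min_sources = config$min_sources),
                   genesynopsis_error = function(e) NULL)
  hwe <- if (meta$scheme == "genotype")
    tryCatch(hwe_sensitivity(table, rsid, model, subgroup,
                             alpha = config$hwe_alpha,
                             min_sources = config$min_sources),
             genesynopsis_error = function(e) NULL)
  else NULL
  grade <- if (meta$p < config$meta_alpha)
    venice_grade(meta, bias = bias) else NULL
  list(meta = meta, egger = bias, begg = begg, sensitivity = sens,
       hwe_sensitivity = hwe, grade = grade)
}

#' Run the full synopsis pipeline
#'
#' For every variant x model x subgroup with enough independent sources:
#' pools the studies (random effects), runs the Egger and Begg bias
#' tests, the leave-one-out and HWE-exclusion sensitivity analyses, and
#' grades nominally significant results on the Venice criteria.  The
#' presentation filter keeps every significant association and shows
#' non-significant ones only when at least `null_presentation_min`
#' independent datasets contribute.  Genotype- and carrier-scheme records
#' of the same variant are never pooled together.  The run is
#' deterministic: identical inputs give identical reports.
#'
#' @param table a `study_table`.
#' @param config a [pipeline_config()].
#' @return a `synopsis_report`: list with `results` (one entry per
#'   analysis, each carrying `meta`, `egger`, `begg`, `sensitivity`,
#'   `hwe_sensitivity`, `grade`), `table` (summary data frame with the
#'   `significant` and `presented` flags) and `skipped` (data frame of
#'   ineligible or failed analyses with reasons).
#' @export
run_synopsis <- function(table, config = pipeline_config()) {
  records <- as.data.frame(table)
  results <- list(); skipped <- list()
  skip <- function(rsid, model, subgroup, reason) skipped[[length(skipped) + 1L]] <<-
    data.frame(rsid = rsid, model = model, subgroup = subgroup,
               reason = reason, stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    warning("empty study table: empty report", call. = FALSE)
  for (rsid in unique(records$rsid)) {
    recs <- records[records$rsid == rsid, , drop = FALSE]
    schemes <- unique(recs$variant_scheme)
    if (length(schemes) > 1L) {
      skip(rsid, "-", "all", "mixed genotype/carrier schemes; refusing to pool")
      next
    }
    models <- if (schemes == "carrier") "carrier"
              else intersect(config$models,
                             c("additive", "dominant", "recessive"))
    subgroups <- list(NULL)
    for (dim in config$subgroup_dims) {
      for (lev in unique(recs[[dim]])) {
        sub_recs <- recs[recs[[dim]] == lev, , drop = FALSE]
        if (.n_sources(sub_recs) >= config$min_sources &&
            nrow(sub_recs) < nrow(recs))
          subgroups[[length(subgroups) + 1L]] <- setNames(list(lev), dim)
      }
    }
    for (model in models) {
      for (subgroup in subgroups) {
        label <- if (is.null(subgroup)) "all"
                 else paste(unlist(subgroup), collapse = "/")
        entry <- tryCatch(
          .analyze_one(records, rsid, model, subgroup, config),
          genesynopsis_error = function(e) e)
        if (inherits(entry, "condition")) {
          skip(rsid, model, label, conditionMessage(entry))
        } else {
          results[[length(results) + 1L]] <- entry
        }
      }
    }
  }
  summary_rows <- lapply(results, function(r) {
    row <- .synopsis_row(r$meta, r$grade)
    row$significant <- r$meta$p < config$meta_alpha
    row$n_sources <- r$meta$n_sources
    row$presented <- row$significant ||
      r$meta$n_sources >= config$null_presentation_min
    row
  })
  tab <- if (length(summary_rows)) do.call(rbind, summary_rows)
         else NULL
  structure(list(
    results = results,
    table = tab,
    skipped = if (length(skipped)) do.call(rbind, skipped)
              else data.frame(rsid = character(), model = character(),
                              subgroup = character(), reason = character()),
    config = config
  ), class = "synopsis_report")
}

#' @export
print.synopsis_report <- function(x, ...) {
  n <- length(x$results)
  cat(sprintf("synopsis report: %d analyses (%d presented, %d skipped)\n",
              n, if (is.null(x$table)) 0L else sum(x$table$presented),
              nrow(x$skipped)))
  if (!is.null(x$table))
    print(x$table[x$table$presented,
                  c("gene", "rsid", "model", "subgroup", "studies",
                    "or_ci", "p", "ph_i2", "grade", "evidence")],
          row.names = FALSE)
  invisible(x)
}
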