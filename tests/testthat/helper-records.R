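# fixtures built in code: handcrafted study records and small tables

make_record <- function(study_id = "s1", pubmed_id = study_id,
                        rsid = "rs0000001", gene = "GENE1",
                        ethnicity = "Asian", virus_type = "unknown",
                        control_source = "population",
                        scheme = "genotype",
                        case = c(10, 20, 30), control = c(25, 50, 25)) {
  rec <- data.frame(
    study_id = study_id, pubmed_id = pubmed_id, first_author = "Doe",
    year = 2010L, gene = gene, rsid = rsid,
    effect_allele = "A", other_allele = "a",
    ethnicity = ethnicity, control_source = control_source,
    virus_type = virus_type, variant_scheme = scheme,
    case_n_AA = NA_real_, case_n_Aa = NA_real_, case_n_aa = NA_real_,
    control_n_AA = NA_real_, control_n_Aa = NA_real_,
    control_n_aa = NA_real_,
    case_n_present = NA_real_, case_n_null = NA_real_,
    control_n_present = NA_real_, control_n_null = NA_real_,
    stringsAsFactors = FALSE
  )
  if (scheme == "genotype") {
    rec[c("case_n_AA", "case_n_Aa", "case_n_aa")] <- as.list(case)
    rec[c("control_n_AA", "control_n_Aa", "control_n_aa")] <- as.list(control)
  } else {
    rec[c("case_n_present", "case_n_null")] <- as.list(case)
    rec[c("control_n_present", "control_n_null")] <- as.list(control)
  }
  rec
}

make_table <- function(...) as_study_table(do.call(rbind, list(...)))

# study table stripped to plain comparable columns
plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  attr(x, "dropped") <- NULL
  attr(x, "n_censored") <- NULL
  rownames(x) <- NULL
  x
}

# effects data frame shorthand
eff_df <- function(log_or, se) {
  data.frame(study_id = as.character(seq_along(log_or)),
             log_or = log_or, se = se, stringsAsFactors = FALSE)
}

# a k-study table with a common fixed effect, deterministic counts
replicated_table <- function(k = 5, rsid = "rs0000001",
                             case = c(300, 500, 200),
                             control = c(250, 500, 250),
                             ethnicity = rep("Asian", k)) {
  rows <- lapply(seq_len(k), function(i)
    make_record(study_id = sprintf("%s_s%d", rsid, i),
                pubmed_id = sprintf("%s_p%d", rsid, i),
                rsid = rsid, ethnicity = ethnicity[i],
                case = case, control = control))
  do.call(make_table, rows)
}
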