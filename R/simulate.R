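#' Simulation configuration for multi-study case-control genotype data
#'
#' Defines the generating process the analysis pipeline assumes: controls
#' drawn from Hardy-Weinberg proportions at control effect-allele
#' frequency `p0`; cases from the same proportions tilted by a
#' multiplicative per-allele odds model, so the population allelic odds
#' ratio of study *i* is exactly `exp(theta_i)`; study-level true log ORs
#' `theta_i ~ Normal(theta, tau2)`; and an optional publication-bias
#' mechanism that suppresses each study whose allelic-contrast p-value is
#' at least `censor_alpha` with probability `censor_prob`.
#'
#' @param k number of studies.
#' @param n_cases,n_controls per-study arm sizes: a single integer, or a
#'   length-2 range sampled uniformly per study.
#' @param p0 control effect-allele frequency: a single value in (0, 1),
#'   or a length-2 vector of Beta shape parameters from which each
#'   study's frequency is drawn.
#' @param theta true mean per-allele log odds ratio.
#' @param tau2 between-study variance of the study-level log OR.
#' @param ethnicities named probability vector over the ethnicity labels.
#' @param censor_prob probability of suppressing a non-significant study.
#' @param censor_alpha significance threshold of the censoring mechanism.
#' @param gene,rsid labels stamped on the generated records.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(k = 10L, n_cases = 500L, n_controls = 500L,
                       p0 = 0.3, theta = 0, tau2 = 0,
                       ethnicities = c(Asian = 0.5, Caucasian = 0.3,
                                       African = 0.1, mixed = 0.1),
                       censor_prob = 0, censor_alpha = 0.05,
                       gene = "GENE1", rsid = "rs0000001", seed = 1L) {
  stopifnot(k >= 1, all(n_cases >= 1), all(n_controls >= 1),
            length(n_cases) <= 2, length(n_controls) <= 2,
            tau2 >= 0, censor_prob >= 0, censor_prob <= 1,
            censor_alpha > 0, censor_alpha < 1,
            length(p0) <= 2)
  if (length(p0) == 1L) stopifnot(p0 > 0, p0 < 1) else stopifnot(all(p0 > 0))
  stopifnot(all(names(ethnicities) %in% .ETHNICITIES),
            abs(sum(ethnicities) - 1) < 1e-8)
  structure(list(k = as.integer(k), n_cases = n_cases,
                 n_controls = n_controls, p0 = p0, theta = theta,
                 tau2 = tau2, ethnicities = ethnicities,
                 censor_prob = censor_prob, censor_alpha = censor_alpha,
                 gene = gene, rsid = rsid, seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-study substream seed: changing k never reshuffles
# the draws of earlier studies
.split_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 104729) %%
               2147483587)
}

.draw_size <- function(spec) {
  if (length(spec) == 1L) as.integer(spec)
  else sample(seq.int(spec[1], spec[2]), 1L)
}

# genotype probabilities: HWE tilted by the per-allele odds model
# (g = effect-allele copies; AA, Aa, aa)
.case_genotype_probs <- function(p0, study_theta) {
  q0 <- 1 - p0
  hwe <- c(p0^2, 2 * p0 * q0, q0^2)
  w <- hwe * exp(study_theta * c(2, 1, 0))
  w / sum(w)
}

#' Simulate one case-control study
#'
#' Draws control genotype counts from Hardy-Weinberg proportions and case
#' counts from the HWE proportions re-weighted by
#' `exp(study_theta * g)` (g = effect-allele copies), renormalized -- the
#' multiplicative per-allele odds model, under which the population
#' allelic odds ratio equals `exp(study_theta)` exactly.
#'
#' @param config a [sim_config()].
#' @param study_theta this study's true log odds ratio.
#' @param study_id,pubmed_id identifiers for the generated record.
#' @param seed optional substream seed; when `NULL` the current RNG state
#'   is used.
#' @return a one-row study-record data frame.
#' @export
simulate_study <- function(config, study_theta, study_id = "sim_001",
                           pubmed_id = "", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ca <- .draw_size(config$n_cases)
  n_co <- .draw_size(config$n_controls)
  p0 <- if (length(config$p0) == 1L) config$p0
        else rbeta(1L, config$p0[1], config$p0[2])
  eth <- sample(names(config$ethnicities), 1L, prob = config$ethnicities)
  q0 <- 1 - p0
  ctrl <- as.integer(rmultinom(1L, n_co, c(p0^2, 2 * p0 * q0, q0^2)))
  case <- as.integer(rmultinom(1L, n_ca,
                               .case_genotype_probs(p0, study_theta)))
  data.frame(
    study_id = study_id, pubmed_id = pubmed_id,
    first_author = paste0("Sim-", study_id), year = 2010L,
    gene = config$gene, rsid = config$rsid,
    effect_allele = "A", other_allele = "a",
    ethnicity = eth, control_source = "population",
    virus_type = "unknown", variant_scheme = "genotype",
    case_n_AA = case[1], case_n_Aa = case[2], case_n_aa = case[3],
    control_n_AA = ctrl[1], control_n_Aa = ctrl[2], control_n_aa = ctrl[3],
    case_n_present = NA_real_, case_n_null = NA_real_,
    control_n_present = NA_real_, control_n_null = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-study dataset
#'
#' Generates `k` studies with study-level true log ORs drawn
#' `Normal(theta, tau2)`, then applies the configured publication-bias
#' censoring: each study whose additive-contrast p-value is at least
#' `censor_alpha` is suppressed with probability `censor_prob`.  Output
#' is deterministic given the seed; each study has its own derived
#' substream, so changing `k` leaves earlier studies unchanged.
#'
#' @param config a [sim_config()].
#' @return a `study_table` of the surviving studies; attribute
#'   `"n_censored"` records how many were suppressed.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list(); n_censored <- 0L
  for (i in seq_len(config$k)) {
    set.seed(.split_seed(config$seed, i))
    study_theta <- rnorm(1L, config$theta, sqrt(config$tau2))
    rec <- simulate_study(config, study_theta,
                          study_id = sprintf("sim_%03d", i),
                          pubmed_id = sprintf("PM%07d", i))
    if (config$censor_prob > 0) {
      eff <- tryCatch(study_odds_ratio(build_contrast(rec, "additive")),
                      genesynopsis_error = function(e) NULL)
      p <- if (is.null(eff)) 1
           else 2 * pnorm(-abs(eff$log_or / eff$se))
      if (p >= config$censor_alpha && runif(1L) < config$censor_prob) {
        n_censored <- n_censored + 1L
        next
      }
    }
    rows[[length(rows) + 1L]] <- rec
  }
  if (length(rows) == 0L) {
    warning("all simulated studies were censored", call. = FALSE)
    out <- as_study_table(
      simulate_study(config, config$theta)[0, ],
      provenance = "simulate_dataset (all censored)")
  } else {
    out <- as_study_table(do.call(rbind, rows),
                          provenance = sprintf("simulate_dataset(seed=%d)",
                                               config$seed))
  }
  attr(out, "n_censored") <- n_censored
  out
}
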