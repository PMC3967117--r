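#' @import methods
NULL

## Column schema for the association catalog TSV. One row is one
## study x SNP x disease observation with its case/control genotype
## frequency triples (genotype = count of effect alleles, 0/1/2).
CATALOG_COLUMNS <- c(
  "disease", "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "study_id", "ancestry", "n_cases", "n_controls", "sample_size", "p_value",
  "block_id",
  "freq0_cases", "freq1_cases", "freq2_cases",
  "freq0_controls", "freq1_controls", "freq2_controls"
)

#' The five-level risk scale
#'
#' Ordered category labels shared by clinical binning and genetic
#' percentile ranking, from lowest to highest risk.
#'
#' @format Character vector of length 5.
#' @export
RISK_LEVELS <- c("very_low", "low", "intermediate", "high", "very_high")

#' The eight wellness domains
#'
#' Disease categories over which clinical and genetic risk are summarised
#' in the gridiron display.
#'
#' @format Character vector of length 8.
#' @export
HEALTH_DOMAINS <- c(
  "immunological", "metabolic", "cardiovascular", "musculoskeletal",
  "respiratory", "cognitive", "psychiatric", "oncological"
)

#' AssociationCatalog: curated case-control association records
#'
#' Holds one row per study x SNP x disease observation: genotype frequency
#' triples in cases and controls, sample sizes, the association P-value,
#' ancestry, and a haplotype-block identifier. This is the input the
#' likelihood-ratio engine consumes after significance filtering and
#' block pruning.
#'
#' @slot records data.frame with the documented catalog columns.
#'
#' @seealso [readAssociationCatalog()], [filterSignificant()], [ldPrune()],
#'   [computeSnpLR()]
#' @export
setClass("AssociationCatalog", representation(records = "data.frame"))

setValidity("AssociationCatalog", function(object) {
  rec <- object@records
  missing_cols <- setdiff(CATALOG_COLUMNS, names(rec))
  if (length(missing_cols))
    return(paste("missing catalog columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  msgs <- character()
  fc <- rec$freq0_cases + rec$freq1_cases + rec$freq2_cases
  fn <- rec$freq0_controls + rec$freq1_controls + rec$freq2_controls
  if (any(abs(fc - 1) > 1e-6) || any(abs(fn - 1) > 1e-6))
    msgs <- c(msgs, "genotype frequency triples must each sum to 1 (tolerance 1e-6)")
  if (any(rec$sample_size != rec$n_cases + rec$n_controls))
    msgs <- c(msgs, "sample_size must equal n_cases + n_controls")
  if (any(rec$p_value <= 0 | rec$p_value > 1))
    msgs <- c(msgs, "p_value must lie in (0, 1]")
  freq_cols <- grep("^freq", names(rec), value = TRUE)
  if (any(as.matrix(rec[freq_cols]) < 0))
    msgs <- c(msgs, "genotype frequencies must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn AssociationCatalog-class Number of catalog rows.
#' @param x,object An `AssociationCatalog`.
#' @export
setMethod("length", "AssociationCatalog", function(x) nrow(x@records))

setMethod("show", "AssociationCatalog", function(object) {
  rec <- object@records
  cat("AssociationCatalog with", nrow(rec), "study-level records\n")
  if (nrow(rec)) {
    cat("  diseases:", length(unique(rec$disease)),
        " SNPs:", length(unique(rec$snp_id)),
        " studies:", length(unique(rec$study_id)), "\n")
    cat("  ancestries:", paste(unique(rec$ancestry), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Access the records of a catalog-like object
#'
#' @param x An `AssociationCatalog`, `SnpLRSet` or `Riskogram`.
#' @return A data.frame, one row per record.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "AssociationCatalog", function(x) x@records)

#' SnpLRSet: per-SNP genotype likelihood ratios
#'
#' One row per SNP x disease after multi-study weighting: LR for each
#' genotype dosage (0, 1, 2 effect alleles), the number of contributing
#' studies and the total sample-size weight.
#'
#' @slot table data.frame with columns snp_id, disease, chrom, pos,
#'   effect_allele, other_allele, lr0, lr1, lr2, n_studies, total_weight.
#' @seealso [computeSnpLR()], [combinePostTest()]
#' @export
setClass("SnpLRSet", representation(table = "data.frame"))

setValidity("SnpLRSet", function(object) {
  tab <- object@table
  need <- c("snp_id", "disease", "lr0", "lr1", "lr2", "n_studies", "total_weight")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(tab) && any(as.matrix(tab[c("lr0", "lr1", "lr2")]) <= 0))
    return("all likelihood ratios must be strictly positive")
  if (nrow(tab) && anyDuplicated(tab[c("snp_id", "disease")]))
    return("one row per SNP x disease required")
  TRUE
})

setMethod("show", "SnpLRSet", function(object) {
  cat("SnpLRSet:", nrow(object@table), "SNP x disease likelihood-ratio rows\n")
  if (nrow(object@table))
    cat("  diseases:", paste(unique(object@table$disease), collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname records
#' @export
setMethod("records", "SnpLRSet", function(x) x@table)

#' Riskogram: rank-ordered per-disease post-test assessments
#'
#' One row per disease for a single subject: baseline (pre-test)
#' probability, combined genotypic likelihood ratio, post-test odds and
#' probability, SNP count, and rank by post-test probability.
#'
#' @slot subject_id character scalar.
#' @slot sex character scalar, "F" or "M".
#' @slot table data.frame of assessments, sorted by decreasing
#'   post-test probability (ties broken by disease name).
#' @seealso [buildRiskogram()], [conditionRiskogram()]
#' @export
setClass("Riskogram",
         representation(subject_id = "character", sex = "character",
                        table = "data.frame"))

setValidity("Riskogram", function(object) {
  tab <- object@table
  need <- c("disease", "pre_test_probability", "combined_lr",
            "post_test_odds", "post_test_probability", "n_snps")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(tab)) {
    odds_p <- tab$post_test_odds / (1 + tab$post_test_odds)
    if (any(abs(odds_p - tab$post_test_probability) > 1e-12))
      return("post_test_probability must equal post_test_odds/(1+post_test_odds)")
    if (is.unsorted(rev(tab$post_test_probability)))
      return("rows must be sorted by decreasing post_test_probability")
  }
  TRUE
})

setMethod("show", "Riskogram", function(object) {
  cat("Riskogram for subject", object@subject_id,
      paste0("(", object@sex, "):"), nrow(object@table), "diseases\n")
  if (nrow(object@table)) {
    tab <- object@table
    top <- utils::head(tab[order(-tab$post_test_probability), ], 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s: pre %.3f -> post %.3f (LR %.2f, %d SNPs)\n",
                  top$disease[i], top$pre_test_probability[i],
                  top$post_test_probability[i], top$combined_lr[i],
                  top$n_snps[i]))
  }
  invisible(NULL)
})

#' @rdname records
#' @export
setMethod("records", "Riskogram", function(x) x@table)

#' ClinicalCohort: z-scored longitudinal clinical profiles
#'
#' Cohort-level container built from long-format visit measurements: the
#' per-subject visit-averaged trait values, cohort-referenced z-scores,
#' five-level risk categories, and per-domain aggregates.
#'
#' @slot subjects data.frame(subject_id, sex).
#' @slot traits data.frame per subject x trait: mean_value (average of the
#'   first visits), z, adjusted_z (sign-flipped for protective traits),
#'   category.
#' @slot domains data.frame per subject x domain: z (mean of contributing
#'   adjusted z-scores), category.
#' @slot cohortStats data.frame per trait: cohort mean, sd, n.
#' @slot traitConfig the trait configuration used (see [traitConfig()]).
#' @seealso [buildClinicalProfiles()]
#' @export
setClass("ClinicalCohort",
         representation(subjects = "data.frame", traits = "data.frame",
                        domains = "data.frame", cohortStats = "data.frame",
                        traitConfig = "data.frame"))

setValidity("ClinicalCohort", function(object) {
  if (nrow(object@traits) && any(!is.finite(object@traits$z)))
    return("all z-scores must be finite")
  if (nrow(object@traits) &&
      !all(object@traits$category %in% RISK_LEVELS))
    return("trait categories must be on the five-level risk scale")
  TRUE
})

setMethod("show", "ClinicalCohort", function(object) {
  cat("ClinicalCohort:", nrow(object@subjects), "subjects,",
      nrow(object@cohortStats), "traits,",
      length(unique(object@domains$domain)), "domains\n")
  invisible(NULL)
})
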