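#' Condition a baseline prior on a clinical likelihood ratio
#'
#' Adjusts the pre-test probability by a clinical LR (e.g. the subject's
#' Framingham score relative to the cohort mean) with
#' \deqn{p' = \frac{p\,LR}{1 + p\,(LR - 1)}}
#' which is Bayes' rule written on the probability scale: it equals
#' converting to odds, multiplying by LR, and converting back. Maps
#' (0,1) into (0,1) for any positive LR, is the identity at LR = 1, and
#' is strictly increasing in LR.
#'
#' @param prior pre-test probability in (0,1) (vectorized).
#' @param clinicalLR positive likelihood ratio (vectorized).
#' @return Adjusted prior(s) in (0,1).
#' @examples
#' conditionFrs(0.1, 2)  # 0.1818...
#' @export
conditionFrs <- function(prior, clinicalLR) {
  stopIfNot(all(prior > 0 & prior < 1), "prior must lie in (0,1)")
  stopIfNot(all(clinicalLR > 0), "clinical LR must be strictly positive")
  prior * clinicalLR / (1 + prior * (clinicalLR - 1))
}

#' Condition a baseline prior by heritability-scaled clinical LR
#'
#' For traits where the clinical measurement is essentially the disease
#' endophenotype (body mass index for obesity, triglycerides for
#' hypertriglyceridemia), the clinical contribution is scaled by the
#' trait's heritability: the pre-test probability is multiplied by
#' \eqn{2 h^2 LR}. With h-squared = 0.5 the multiplier is exactly the
#' clinical LR; with 0.3 it is 60 percent of the LR. The product is a
#' direct probability multiplication (not an odds update); when it
#' exceeds 1 it is clipped to 1 - 1e-9 with a warning.
#'
#' @param prior pre-test probability in (0,1) (vectorized).
#' @param h2 heritability in (0,1].
#' @param clinicalLR positive likelihood ratio (vectorized).
#' @return Adjusted prior(s), clipped below 1.
#' @examples
#' conditionHeritability(0.2, 0.5, 1)    # unchanged: multiplier is the LR = 1
#' conditionHeritability(0.2, 0.3, 2)    # 0.2 * 0.6 * 2
#' @export
conditionHeritability <- function(prior, h2, clinicalLR) {
  stopIfNot(all(prior > 0 & prior < 1), "prior must lie in (0,1)")
  stopIfNot(all(is.finite(h2) & h2 > 0 & h2 <= 1),
            "heritability must lie in (0,1]")
  stopIfNot(all(clinicalLR > 0), "clinical LR must be strictly positive")
  adj <- prior * 2 * h2 * clinicalLR
  if (any(adj >= 1)) {
    warning(sprintf("heritability-scaled prior exceeded 1 for %d value(s); clipped",
                    sum(adj >= 1)), call. = FALSE)
    adj <- pmin(adj, 1 - 1e-9)
  }
  adj
}

#' Five-level genetic risk category by cohort percentile
#'
#' Places a subject's genetic risk score (combined LR or post-test
#' probability) within the cohort distribution of the same score and
#' bins the empirical percentile at 2.5 / 16 / 84 / 97.5 — cutoffs
#' chosen to mirror the one- and two-SD clinical bins.
#'
#' @param x subject score(s).
#' @param cohort numeric vector of cohort scores (n >= 20).
#' @return Ordered factor on [RISK_LEVELS].
#' @export
geneticCategory <- function(x, cohort) {
  stopIfNot(length(cohort) >= 20,
            "cohort distribution of at least 20 scores required")
  if (stats::sd(cohort) == 0) {
    warning("degenerate cohort score distribution; category set to intermediate",
            call. = FALSE)
    return(riskFactor(rep("intermediate", length(x))))
  }
  pct <- vapply(x, function(xi)
    100 * (sum(cohort < xi) + 0.5 * sum(cohort == xi)) / length(cohort), 0)
  lev <- ifelse(pct < 2.5, "very_low",
                ifelse(pct < 16, "low",
                       ifelse(pct <= 84, "intermediate",
                              ifelse(pct <= 97.5, "high", "very_high"))))
  riskFactor(lev)
}

#' Classify genetic/clinical concordance
#'
#' Compares the direction of the genotypic evidence (combined LR against
#' 1) with the direction of the clinical evidence (five-level category
#' against intermediate). Concordant when both deviate from neutral in
#' the same direction, discordant when they deviate in opposite
#' directions, indeterminate when either side is neutral (LR within the
#' neutral zone, or category intermediate).
#'
#' @param combinedLr genotypic combined likelihood ratio(s).
#' @param category clinical five-level categor(ies) on [RISK_LEVELS].
#' @param lrNeutral LR interval treated as neutral (default
#'   c(0.95, 1.05)).
#' @return character vector in \{"concordant", "discordant",
#'   "indeterminate"\}.
#' @examples
#' classifyConcordance(2.2, "very_high")  # concordant
#' classifyConcordance(0.5, "very_high")  # discordant
#' @export
classifyConcordance <- function(combinedLr, category,
                                lrNeutral = c(0.95, 1.05)) {
  stopIfNot(all(combinedLr > 0), "combined LR must be positive")
  category <- as.character(category)
  stopIfNot(all(category %in% RISK_LEVELS),
            "category must be on the five-level risk scale")
  gdir <- ifelse(combinedLr < lrNeutral[1], -1L,
                 ifelse(combinedLr > lrNeutral[2], 1L, 0L))
  cidx <- match(category, RISK_LEVELS) - 3L  # intermediate -> 0
  cdir <- sign(cidx)
  ifelse(gdir == 0L | cdir == 0L, "indeterminate",
         ifelse(gdir == cdir, "concordant", "discordant"))
}

## Direction comparison on two five-level categories (used by the
## gridiron, where the genetic side is itself a percentile category).
categoryConcordance <- function(clinical, genetic) {
  cdir <- sign(match(as.character(clinical), RISK_LEVELS) - 3L)
  gdir <- sign(match(as.character(genetic), RISK_LEVELS) - 3L)
  ifelse(cdir == 0L | gdir == 0L, "indeterminate",
         ifelse(cdir == gdir, "concordant", "discordant"))
}

#' Assemble a gridiron: clinical vs genetic category per domain
#'
#' One cell per wellness domain present on either side, holding the
#' clinical five-level category, the genetic five-level (percentile)
#' category, and a concordance flag: concordant when both deviate from
#' intermediate in the same direction, discordant when opposite,
#' indeterminate when either is intermediate, and missing when only one
#' side is available.
#'
#' @param clinicalDomains data.frame(domain, category) for one subject,
#'   e.g. the subject's rows of `ClinicalCohort@domains`.
#' @param geneticDomains data.frame(domain, category) of the subject's
#'   per-domain genetic categories (see [geneticCategory()]).
#' @return data.frame(domain, clinical_category, genetic_category,
#'   concordance), ordered as [HEALTH_DOMAINS].
#' @export
buildGridiron <- function(clinicalDomains, geneticDomains) {
  doms <- union(clinicalDomains$domain, geneticDomains$domain)
  stopIfNot(length(doms) >= 1, "no domains on either side")
  out <- data.frame(domain = doms, stringsAsFactors = FALSE)
  out$clinical_category <-
    as.character(clinicalDomains$category[match(doms, clinicalDomains$domain)])
  out$genetic_category <-
    as.character(geneticDomains$category[match(doms, geneticDomains$domain)])
  haveBoth <- !is.na(out$clinical_category) & !is.na(out$genetic_category)
  out$concordance <- "missing"
  out$concordance[haveBoth] <-
    categoryConcordance(out$clinical_category[haveBoth],
                        out$genetic_category[haveBoth])
  out <- out[order(match(out$domain, HEALTH_DOMAINS), out$domain), ]
  rownames(out) <- NULL
  out
}

#' Condition a risk-o-gram on clinical likelihood ratios
#'
#' Replaces each disease's baseline prior with a clinically adjusted
#' prior — via Bayes' rule on the probability scale (`method =
#' "frs_ratio"`, see [conditionFrs()]) or via the heritability-scaled
#' multiplier (`method = "heritability_scaled"`, see
#' [conditionHeritability()]) — and reruns the genotypic update from the
#' adjusted baseline. The genotypic combined LR of each disease is left
#' untouched; only the baseline, the post-test probability, and hence
#' the rank order change. Diseases without a clinical LR keep their
#' original row.
#'
#' @param riskogram A [Riskogram-class].
#' @param clinicalLRs data.frame(disease, clinical_lr) and, for the
#'   heritability method, a heritability column `h2`.
#' @param method "frs_ratio" or "heritability_scaled".
#' @return A new [Riskogram-class] whose table additionally carries
#'   original_prior, clinical_lr, conditioning_method, rank_before.
#' @export
conditionRiskogram <- function(riskogram, clinicalLRs,
                               method = c("frs_ratio", "heritability_scaled")) {
  method <- match.arg(method)
  tab <- records(riskogram)
  i <- match(tab$disease, clinicalLRs$disease)
  lr <- clinicalLRs$clinical_lr[i]
  tab$original_prior <- tab$pre_test_probability
  tab$clinical_lr <- lr
  tab$conditioning_method <- ifelse(is.na(lr), NA_character_, method)
  tab$rank_before <- tab$rank
  have <- !is.na(lr)
  if (any(have)) {
    if (method == "frs_ratio") {
      adj <- conditionFrs(tab$pre_test_probability[have], lr[have])
    } else {
      stopIfNot(!is.null(clinicalLRs$h2),
                "heritability_scaled conditioning needs an h2 column")
      h2 <- clinicalLRs$h2[i][have]
      stopIfNot(all(!is.na(h2)),
                "missing heritability for a conditioned disease")
      adj <- conditionHeritability(tab$pre_test_probability[have], h2,
                                   lr[have])
    }
    tab$pre_test_probability[have] <- adj
    preOdds <- adj / (1 - adj)
    tab$post_test_odds[have] <- preOdds * tab$combined_lr[have]
    tab$post_test_probability[have] <-
      tab$post_test_odds[have] / (1 + tab$post_test_odds[have])
    tab$fold_change[have] <- tab$post_test_probability[have] / adj
  }
  ord <- order(-tab$post_test_probability, tab$disease)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("Riskogram", subject_id = riskogram@subject_id, sex = riskogram@sex,
      table = tab)
}
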