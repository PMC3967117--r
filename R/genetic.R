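## Haldane-style continuity correction for a single study's frequency
## triples: wherever a genotype has zero frequency in cases or controls,
## add 0.5 to that genotype's implied count in BOTH groups, then
## renormalize each triple. Keeps the log likelihood ratio finite.
haldaneCorrect <- function(fc, fn, nCases, nControls) {
  zero <- fc == 0 | fn == 0
  if (!any(zero)) return(list(cases = fc, controls = fn, corrected = FALSE))
  cc <- fc * nCases
  cn <- fn * nControls
  cc[zero] <- cc[zero] + 0.5
  cn[zero] <- cn[zero] + 0.5
  list(cases = cc / sum(cc), controls = cn / sum(cn), corrected = TRUE)
}

#' Sample-size-weighted per-SNP genotype likelihood ratios
#'
#' For each SNP x disease in the catalog, computes the likelihood ratio
#' of each genotype dosage g in \{0, 1, 2\} by weighting the per-study
#' log-ratios of case to control genotype frequencies by study sample
#' size:
#' \deqn{\log LR(g) = \frac{\sum_i \log\frac{F(g, cases, i)}{F(g, controls, i)}\, S(i)}{\sum_i S(i)}}
#' The mean is taken in log space, not as a weighted mean of ratios. For
#' a single study this reduces to the plain frequency ratio. Studies with
#' a zero genotype frequency in either group receive a continuity
#' correction (see Details) with a warning.
#'
#' @details Zero-frequency genotypes get a Haldane-style correction: 0.5
#' is added to the implied genotype count in both cases and controls and
#' the triples are renormalized, keeping the log-ratio finite without
#' discarding the study.
#'
#' @param catalog An [AssociationCatalog-class] (typically after
#'   [filterSignificant()] and [ldPrune()]).
#' @return A [SnpLRSet-class], one row per SNP x disease.
#' @examples
#' cfg <- simulationConfig(seed = 2)
#' lrs <- computeSnpLR(simulateAssociationCatalog(cfg))
#' head(records(lrs))
#' @export
computeSnpLR <- function(catalog) {
  rec <- records(catalog)
  stopIfNot(nrow(rec) > 0, "empty catalog: no records to compute LRs from")
  key <- paste(rec$disease, rec$snp_id, sep = "\r")
  groups <- split(seq_len(nrow(rec)), key)
  nCorrected <- 0L
  rows <- lapply(groups, function(idx) {
    g <- rec[idx, , drop = FALSE]
    w <- g$sample_size
    stopIfNot(sum(w) > 0, "all-zero study weights for a SNP")
    logRatios <- matrix(0, nrow(g), 3)
    for (i in seq_len(nrow(g))) {
      fc <- as.numeric(g[i, c("freq0_cases", "freq1_cases", "freq2_cases")])
      fn <- as.numeric(g[i, c("freq0_controls", "freq1_controls",
                              "freq2_controls")])
      corr <- haldaneCorrect(fc, fn, g$n_cases[i], g$n_controls[i])
      if (corr$corrected) nCorrected <<- nCorrected + 1L
      logRatios[i, ] <- log(corr$cases / corr$controls)
    }
    if (nrow(g) == 1L) {
      ## single study: the weighted log mean reduces to the plain
      ## frequency ratio; compute it directly so the identity is exact
      corr <- haldaneCorrect(
        as.numeric(g[1, c("freq0_cases", "freq1_cases", "freq2_cases")]),
        as.numeric(g[1, c("freq0_controls", "freq1_controls",
                          "freq2_controls")]),
        g$n_cases[1], g$n_controls[1])
      lr <- corr$cases / corr$controls
    } else {
      lr <- exp(colSums(logRatios * w) / sum(w))
    }
    data.frame(snp_id = g$snp_id[1], disease = g$disease[1],
               chrom = g$chrom[1], pos = g$pos[1],
               effect_allele = g$effect_allele[1],
               other_allele = g$other_allele[1],
               lr0 = lr[1], lr1 = lr[2], lr2 = lr[3],
               n_studies = nrow(g), total_weight = sum(w),
               stringsAsFactors = FALSE)
  })
  if (nCorrected > 0L)
    warning(sprintf("continuity correction applied to %d study record(s) with a zero genotype frequency",
                    nCorrected), call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("SnpLRSet", table = tab)
}

#' Read sex-specific baseline disease priors
#'
#' @param path TSV with columns disease, sex, pre_test_probability
#'   (baseline lifetime risk, in the open interval (0,1)).
#' @return data.frame of priors.
#' @export
readPriors <- function(path) {
  pr <- readTsv(path)
  stopIfNot(all(c("disease", "sex", "pre_test_probability") %in% names(pr)),
            "priors file needs columns disease, sex, pre_test_probability")
  stopIfNot(all(pr$pre_test_probability > 0 & pr$pre_test_probability < 1),
            "pre-test probabilities must lie in (0,1)")
  pr
}

#' Combine a baseline prior with per-SNP likelihood ratios
#'
#' Bayesian post-test update on the odds scale: the pre-test probability
#' is converted to odds p/(1-p), multiplied by the product of the
#' subject's per-SNP genotype likelihood ratios, and converted back with
#' odds/(1+odds). SNPs with a missing genotype (NA likelihood ratio)
#' contribute the neutral LR = 1 and are counted separately.
#'
#' @param prior pre-test probability in (0,1).
#' @param lrs numeric vector of the subject's per-SNP likelihood ratios
#'   (the LR of the genotype the subject carries at each SNP); NA marks a
#'   missing genotype.
#' @param disease,sex optional labels carried into the result.
#' @return One-row data.frame: disease, sex, pre_test_probability,
#'   combined_lr, post_test_odds, post_test_probability, n_snps (SNPs
#'   with a called genotype), n_skipped, fold_change (post/pre).
#' @examples
#' combinePostTest(0.1, c(2, 0.5))      # product 1: post equals prior
#' combinePostTest(0.1, 2)$post_test_probability  # 0.2/1.1
#' @export
combinePostTest <- function(prior, lrs, disease = NA_character_,
                            sex = NA_character_) {
  stopIfNot(is.numeric(prior) && length(prior) == 1L && prior > 0 && prior < 1,
            "prior must be a single probability in (0,1)")
  stopIfNot(all(is.na(lrs) | lrs > 0),
            "likelihood ratios must be strictly positive")
  called <- !is.na(lrs)
  combined <- prod(lrs[called])
  preOdds <- prior / (1 - prior)
  postOdds <- preOdds * combined
  postP <- postOdds / (1 + postOdds)
  data.frame(disease = disease, sex = sex, pre_test_probability = prior,
             combined_lr = combined, post_test_odds = postOdds,
             post_test_probability = postP,
             n_snps = sum(called), n_skipped = sum(!called),
             fold_change = postP / prior, stringsAsFactors = FALSE)
}

#' Read genotypes from a VCF file
#'
#' Thin wrapper over [vcfR::read.vcfR()] extracting the GT field as
#' ALT-allele dosages.
#'
#' @param path a VCF file (v4.x, GT format field present).
#' @return list with `snps` (data.frame chrom, pos, id, ref, alt) and
#'   `dosage` (integer matrix samples x variants of ALT-allele counts,
#'   NA for missing calls).
#' @export
readGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dosage[alleles == "0/0"] <- 0L
  dosage[alleles %in% c("0/1", "1/0")] <- 1L
  dosage[alleles == "1/1"] <- 2L
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = fix$ID, ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  list(snps = snps, dosage = t(dosage))
}

#' Look up effect-allele dosages for catalog SNPs in genotype data
#'
#' Matches catalog SNPs to VCF variants by (chrom, pos) and orients the
#' effect allele against REF/ALT: when the effect allele is ALT the
#' dosage is the ALT count, when it is REF the dosage is 2 minus the ALT
#' count (allele swap). Strand-ambiguous SNPs (A/T, C/G) and SNPs whose
#' alleles match in neither orientation are returned as missing, with a
#' message of the counts.
#'
#' @param genotypes as returned by [readGenotypes()].
#' @param snps data.frame with snp_id, chrom, pos, effect_allele,
#'   other_allele (e.g. `records(computeSnpLR(catalog))`).
#' @return integer matrix samples x catalog SNPs of effect-allele dosages
#'   (0/1/2, NA = missing or unmatched).
#' @export
genotypeLookup <- function(genotypes, snps) {
  vk <- paste(genotypes$snps$chrom, genotypes$snps$pos, sep = ":")
  out <- matrix(NA_integer_, nrow(genotypes$dosage), nrow(snps),
                dimnames = list(rownames(genotypes$dosage), snps$snp_id))
  ambiguous <- isStrandAmbiguous(snps$effect_allele, snps$other_allele)
  unmatched <- 0L
  for (j in seq_len(nrow(snps))) {
    if (ambiguous[j]) next
    i <- match(paste(snps$chrom[j], snps$pos[j], sep = ":"), vk)
    if (is.na(i)) { unmatched <- unmatched + 1L; next }
    ref <- genotypes$snps$ref[i]; alt <- genotypes$snps$alt[i]
    if (snps$effect_allele[j] == alt && snps$other_allele[j] == ref) {
      out[, j] <- genotypes$dosage[, i]
    } else if (snps$effect_allele[j] == ref && snps$other_allele[j] == alt) {
      out[, j] <- 2L - genotypes$dosage[, i]
    } else {
      unmatched <- unmatched + 1L
    }
  }
  if (unmatched > 0L || any(ambiguous))
    message(sprintf("genotype lookup: %d unmatched, %d strand-ambiguous SNP(s) set to missing",
                    unmatched, sum(ambiguous)))
  out
}

#' Per-disease post-test assessments for one subject
#'
#' For every disease with a likelihood-ratio row set and a prior for the
#' subject's sex, picks the subject's genotype LR at each SNP and runs
#' [combinePostTest()]. Diseases with no prior for this sex (e.g.
#' prostate cancer for a female subject) are omitted.
#'
#' @param lrSet A [SnpLRSet-class].
#' @param priors data.frame from [readPriors()].
#' @param dosages named integer vector of effect-allele dosages for this
#'   subject (names = snp_id; NA = missing).
#' @param sex "F" or "M".
#' @return data.frame of assessments, one row per assessable disease.
#' @export
assessSubject <- function(lrSet, priors, dosages, sex) {
  tab <- records(lrSet)
  pri <- priors[priors$sex == sex, , drop = FALSE]
  out <- lapply(intersect(unique(tab$disease), pri$disease), function(d) {
    rows <- tab[tab$disease == d, , drop = FALSE]
    g <- dosages[rows$snp_id]
    lrMat <- as.matrix(rows[c("lr0", "lr1", "lr2")])
    lr <- ifelse(is.na(g), NA_real_, lrMat[cbind(seq_len(nrow(rows)),
                                                 as.integer(g) + 1L)])
    combinePostTest(pri$pre_test_probability[match(d, pri$disease)], lr,
                    disease = d, sex = sex)
  })
  do.call(rbind, out)
}

#' Assemble a rank-ordered risk-o-gram
#'
#' Orders a subject's per-disease post-test assessments by decreasing
#' post-test probability (ties broken by disease name), annotating each
#' row with its rank, the direction of the genotypic effect (increased
#' for combined LR > 1, decreased for < 1), and the fold change relative
#' to baseline.
#'
#' @param assessments data.frame as from [assessSubject()] (or rbind of
#'   [combinePostTest()] rows).
#' @param subject_id,sex subject labels (sex defaults to the assessments'
#'   sex column).
#' @return A [Riskogram-class].
#' @export
buildRiskogram <- function(assessments, subject_id = "subject",
                           sex = assessments$sex[1]) {
  stopIfNot(is.data.frame(assessments) && nrow(assessments) >= 1,
            "at least one assessment required")
  ord <- order(-assessments$post_test_probability, assessments$disease)
  tab <- assessments[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$direction <- ifelse(tab$combined_lr > 1, "increased",
                          ifelse(tab$combined_lr < 1, "decreased", "neutral"))
  rownames(tab) <- NULL
  new("Riskogram", subject_id = subject_id,
      sex = if (is.na(sex)) "unknown" else sex, table = tab)
}
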