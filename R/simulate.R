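#' SimulationConfig: parameters of the synthetic study generator
#'
#' Fully determines (together with `seed`) a synthetic association catalog,
#' a genotyped cohort with disease status, baseline priors, and a
#' longitudinal clinical table. Construct with [simulationConfig()].
#'
#' @slot nSubjects number of cohort subjects.
#' @slot diseases disease names.
#' @slot nSnpsPerDisease independent risk SNPs simulated per disease.
#' @slot prevalence data.frame(disease, sex, pre_test_probability); the
#'   generative model uses the per-disease mean across sexes.
#' @slot alleleFreqs risk-allele frequencies, recycled over SNPs.
#' @slot perAlleleOR per-allele odds ratios, recycled over SNPs.
#' @slot nStudiesPerSnp case-control studies simulated per SNP.
#' @slot studySizes total sample sizes cycled over studies.
#' @slot nVisits clinic visits per subject.
#' @slot traits trait configuration (see [traitConfig()]) plus a
#'   `liability_corr` column: target correlation between the subject-level
#'   trait mean and the linked disease's risk liability.
#' @slot visitNoiseSd SD of within-subject visit noise, in units of the
#'   between-subject trait SD (traits are generated on the z scale).
#' @slot seed integer seed; fixes all outputs byte-for-byte.
#' @export
setClass("SimulationConfig",
         representation(nSubjects = "numeric", diseases = "character",
                        nSnpsPerDisease = "numeric", prevalence = "data.frame",
                        alleleFreqs = "numeric", perAlleleOR = "numeric",
                        nStudiesPerSnp = "numeric", studySizes = "numeric",
                        nVisits = "numeric", traits = "data.frame",
                        visitNoiseSd = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@nSubjects < 1) msgs <- c(msgs, "nSubjects must be >= 1")
  if (!length(object@diseases)) msgs <- c(msgs, "at least one disease required")
  pr <- object@prevalence$pre_test_probability
  if (any(pr <= 0 | pr >= 1))
    msgs <- c(msgs, "prevalences must lie in the open interval (0,1)")
  if (!all(object@diseases %in% object@prevalence$disease))
    msgs <- c(msgs, "every disease needs a prevalence row")
  if (any(object@alleleFreqs <= 0 | object@alleleFreqs >= 1))
    msgs <- c(msgs, "allele frequencies must lie in (0,1)")
  if (any(object@perAlleleOR <= 0))
    msgs <- c(msgs, "per-allele odds ratios must be strictly positive")
  if (nrow(object@traits)) {
    if (any(abs(object@traits$liability_corr) > 1))
      msgs <- c(msgs, "trait_liability_corr must lie in [-1,1]")
    if (!all(object@traits$direction %in%
             c("risk-increasing-high", "risk-increasing-low")))
      msgs <- c(msgs, "unknown trait direction")
  }
  if (object@visitNoiseSd < 0) msgs <- c(msgs, "visitNoiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

defaultPrevalence <- function(diseases) {
  defaults <- c(coronary_artery_disease_F = 0.25, coronary_artery_disease_M = 0.40,
                type_2_diabetes_F = 0.30, type_2_diabetes_M = 0.30,
                hypertension_F = 0.60, hypertension_M = 0.60,
                obesity_F = 0.35, obesity_M = 0.35,
                hypertriglyceridemia_F = 0.20, hypertriglyceridemia_M = 0.30)
  out <- expand.grid(disease = diseases, sex = c("F", "M"),
                     stringsAsFactors = FALSE)
  key <- paste(out$disease, out$sex, sep = "_")
  out$pre_test_probability <- ifelse(key %in% names(defaults),
                                     defaults[key], 0.20)
  out[order(out$disease, out$sex), ]
}

defaultTraits <- function(diseases) {
  tr <- data.frame(
    trait = c("bmi", "triglycerides", "fasting_glucose", "systolic_bp",
              "hdl_c", "crp", "bone_density", "fev1", "memory_score",
              "mood_score", "tumour_marker"),
    direction = c("risk-increasing-high", "risk-increasing-high",
                  "risk-increasing-high", "risk-increasing-high",
                  "risk-increasing-low", "risk-increasing-high",
                  "risk-increasing-low", "risk-increasing-low",
                  "risk-increasing-low", "risk-increasing-low",
                  "risk-increasing-high"),
    domain = c("metabolic", "metabolic", "metabolic", "cardiovascular",
               "cardiovascular", "immunological", "musculoskeletal",
               "respiratory", "cognitive", "psychiatric", "oncological"),
    linked_disease = c("obesity", "hypertriglyceridemia", "type_2_diabetes",
                       "hypertension", "coronary_artery_disease",
                       NA, NA, NA, NA, NA, NA),
    heritability = c(0.50, 0.30, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    liability_corr = c(0.5, 0.5, 0.4, 0.4, -0.3, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  tr$linked_disease[!tr$linked_disease %in% diseases] <- NA
  tr$liability_corr[is.na(tr$linked_disease)] <- 0
  tr
}

#' Build a simulation configuration
#'
#' Defaults describe a small wellness-cohort study: five prevalent,
#' inter-related conditions with sex-specific lifetime risks, a handful of
#' genome-wide significant SNPs per disease with modest per-allele odds
#' ratios, a few case-control studies per SNP, and a clinical panel
#' covering the eight wellness domains with four visits per subject.
#'
#' @param nSubjects cohort size (default 8).
#' @param diseases character vector of disease names.
#' @param nSnpsPerDisease SNPs per disease (default 9).
#' @param prevalence data.frame(disease, sex, pre_test_probability);
#'   defaults to plausible sex-specific lifetime risks.
#' @param alleleFreqs risk-allele frequencies, recycled (default an even
#'   spread over 0.1-0.5).
#' @param perAlleleOR per-allele odds ratios, recycled (default 1.2).
#' @param nStudiesPerSnp studies per SNP (default 3).
#' @param studySizes total study sizes, cycled (default 2000/5000/10000).
#' @param nVisits visits per subject (default 4).
#' @param traits trait configuration data.frame; see [traitConfig()].
#' @param visitNoiseSd within-subject visit noise SD (default 0.3).
#' @param seed integer seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nSubjects = 50, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nSubjects = 8,
                             diseases = c("coronary_artery_disease",
                                          "type_2_diabetes", "hypertension",
                                          "obesity", "hypertriglyceridemia"),
                             nSnpsPerDisease = 9,
                             prevalence = defaultPrevalence(diseases),
                             alleleFreqs = seq(0.1, 0.5,
                                               length.out = nSnpsPerDisease),
                             perAlleleOR = 1.2,
                             nStudiesPerSnp = 3,
                             studySizes = c(2000, 5000, 10000),
                             nVisits = 4,
                             traits = defaultTraits(diseases),
                             visitNoiseSd = 0.3,
                             seed = 1) {
  new("SimulationConfig",
      nSubjects = nSubjects, diseases = diseases,
      nSnpsPerDisease = nSnpsPerDisease, prevalence = prevalence,
      alleleFreqs = rep_len(alleleFreqs, nSnpsPerDisease),
      perAlleleOR = rep_len(perAlleleOR, nSnpsPerDisease),
      nStudiesPerSnp = nStudiesPerSnp, studySizes = studySizes,
      nVisits = nVisits, traits = traits, visitNoiseSd = visitNoiseSd,
      seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSubjects, "subjects,",
      length(object@diseases), "diseases x", object@nSnpsPerDisease,
      "SNPs,", object@nVisits, "visits, seed", object@seed, "\n")
  invisible(NULL)
})

#' Expected case/control genotype frequencies under a per-allele odds ratio
#'
#' The analytic core of the generator: with risk-allele frequency `p`, the
#' population genotype distribution is Hardy-Weinberg; disease status
#' follows a logistic model on allele dosage with per-allele odds ratio
#' `orPerAllele`, its intercept calibrated by root-finding so the marginal
#' prevalence equals `prevalence`. Case and control genotype frequencies
#' then follow by Bayes inversion.
#'
#' @param p risk-allele frequency in (0,1).
#' @param orPerAllele per-allele odds ratio, > 0.
#' @param prevalence marginal disease probability in (0,1).
#' @return list with elements `cases` and `controls` (genotype frequency
#'   triples for dosage 0/1/2, each summing to 1), `population` (the HWE
#'   triple) and `intercept` (the calibrated logistic intercept).
#' @examples
#' expectedGenotypeFreqs(0.3, 1.5, 0.1)
#' @export
expectedGenotypeFreqs <- function(p, orPerAllele, prevalence) {
  stopIfNot(is.finite(p) && p > 0 && p < 1,
            "allele frequency must lie in (0,1)")
  stopIfNot(is.finite(orPerAllele) && orPerAllele > 0,
            "per-allele odds ratio must be strictly positive")
  stopIfNot(is.finite(prevalence) && prevalence > 0 && prevalence < 1,
            "prevalence must lie in (0,1)")
  pg <- hweProbs(p)
  beta <- log(orPerAllele)
  b0 <- stats::uniroot(function(b) sum(stats::plogis(b + beta * 0:2) * pg) -
                         prevalence,
                       interval = c(-60, 60), tol = 1e-14)$root
  pcase <- stats::plogis(b0 + beta * 0:2)
  list(cases = pcase * pg / prevalence,
       controls = (1 - pcase) * pg / (1 - prevalence),
       population = pg, intercept = b0)
}

## Non-strand-ambiguous allele pairs cycled over simulated SNPs
## (other_allele, effect_allele).
ALLELE_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))

## SNP annotation table for one config: disease, snp_id, chrom, pos,
## alleles, allele frequency, OR, block id.
snpTable <- function(config) {
  out <- do.call(rbind, lapply(seq_along(config@diseases), function(d) {
    j <- seq_len(config@nSnpsPerDisease)
    pair <- ALLELE_PAIRS[((d + j) %% length(ALLELE_PAIRS)) + 1L]
    data.frame(disease = config@diseases[d],
               snp_id = sprintf("rs%d", d * 100000L + j),
               chrom = "chrS",
               pos = d * 1000000L + j * 1000L,
               other_allele = vapply(pair, `[`, "", 1L),
               effect_allele = vapply(pair, `[`, "", 2L),
               allele_freq = config@alleleFreqs[j],
               per_allele_or = config@perAlleleOR[j],
               stringsAsFactors = FALSE)
  }))
  out$block_id <- paste0("blk_", out$snp_id)
  out
}

diseasePrevalence <- function(config) {
  tapply(config@prevalence$pre_test_probability, config@prevalence$disease,
         mean)[config@diseases]
}

chisq2x3 <- function(caseCounts, ctrlCounts) {
  tab <- rbind(caseCounts, ctrlCounts)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) return(1)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  if (!is.finite(p)) 1 else min(max(p, .Machine$double.xmin), 1)
}

#' Simulate a multi-study case-control association catalog
#'
#' For every SNP of every configured disease, draws `nStudiesPerSnp`
#' case-control studies (half cases, half controls) with genotype counts
#' multinomial around the expected case/control frequencies of
#' [expectedGenotypeFreqs()], and attaches a chi-square association
#' P-value computed from the simulated 2x3 table.
#'
#' @param config A [SimulationConfig-class].
#' @return An [AssociationCatalog-class].
#' @examples
#' cat6 <- simulateAssociationCatalog(simulationConfig(seed = 7))
#' cat6
#' @export
simulateAssociationCatalog <- function(config) {
  validObject(config)
  set.seed(config@seed)
  snps <- snpTable(config)
  prev <- diseasePrevalence(config)
  sizes <- rep_len(config@studySizes, config@nStudiesPerSnp)
  rows <- vector("list", nrow(snps) * config@nStudiesPerSnp)
  k <- 0L
  for (r in seq_len(nrow(snps))) {
    ef <- expectedGenotypeFreqs(snps$allele_freq[r], snps$per_allele_or[r],
                                prev[[snps$disease[r]]])
    for (s in seq_len(config@nStudiesPerSnp)) {
      nca <- floor(sizes[s] / 2)
      nco <- sizes[s] - nca
      caseCounts <- as.vector(stats::rmultinom(1, nca, ef$cases))
      ctrlCounts <- as.vector(stats::rmultinom(1, nco, ef$controls))
      k <- k + 1L
      rows[[k]] <- data.frame(
        disease = snps$disease[r], snp_id = snps$snp_id[r],
        chrom = snps$chrom[r], pos = snps$pos[r],
        effect_allele = snps$effect_allele[r],
        other_allele = snps$other_allele[r],
        study_id = sprintf("%s_study%d", snps$snp_id[r], s),
        ancestry = "European",
        n_cases = nca, n_controls = nco, sample_size = nca + nco,
        p_value = chisq2x3(caseCounts, ctrlCounts),
        block_id = snps$block_id[r],
        freq0_cases = caseCounts[1] / nca,
        freq1_cases = caseCounts[2] / nca,
        freq2_cases = caseCounts[3] / nca,
        freq0_controls = ctrlCounts[1] / nco,
        freq1_controls = ctrlCounts[2] / nco,
        freq2_controls = ctrlCounts[3] / nco,
        stringsAsFactors = FALSE)
    }
  }
  new("AssociationCatalog", records = do.call(rbind, rows))
}

#' Simulate a genotyped, clinically phenotyped cohort
#'
#' Draws, per subject and disease: case status from the configured
#' prevalence, then genotypes at each risk SNP conditionally on status
#' from the same calibrated single-locus model as the association catalog
#' (so per-allele odds ratios are exact and genotypes are Hardy-Weinberg
#' in the population). The true liability is the log-odds of disease given
#' the genotype vector. Each clinical trait is a linear function of the
#' standardized liability of its linked disease plus Gaussian noise,
#' achieving the configured subject-level correlation; visits add
#' independent Gaussian noise around the subject mean (no time trend).
#'
#' @param config A [SimulationConfig-class].
#' @param dir optional directory; when given, writes `genotypes.vcf`
#'   (VCFv4.2, GT only, contig chrS), `clinical.tsv` (long format),
#'   `priors.tsv` and `truth.json` there.
#' @return list with elements:
#'   \describe{
#'     \item{subjects}{data.frame(subject_id, sex)}
#'     \item{genotypes}{integer matrix subjects x SNPs of effect-allele
#'       dosages (0/1/2)}
#'     \item{snpInfo}{per-SNP annotation (alleles, position, disease)}
#'     \item{clinical}{long data.frame(subject_id, sex, visit, trait, value)}
#'     \item{truth}{list with `liability` and `case` matrices
#'       (subjects x diseases) — simulation ground truth}
#'     \item{paths}{written file paths, when `dir` was given}
#'   }
#' @examples
#' sim <- simulateCohort(simulationConfig(nSubjects = 20, seed = 3))
#' str(sim$truth$case)
#' @export
simulateCohort <- function(config, dir = NULL) {
  validObject(config)
  set.seed((config@seed + 1) %% .Machine$integer.max)
  n <- config@nSubjects
  snps <- snpTable(config)
  prev <- diseasePrevalence(config)
  subjects <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  geno <- matrix(0L, n, nrow(snps),
                 dimnames = list(subjects$subject_id, snps$snp_id))
  liability <- matrix(0, n, length(config@diseases),
                      dimnames = list(subjects$subject_id, config@diseases))
  case <- matrix(FALSE, n, length(config@diseases),
                 dimnames = list(subjects$subject_id, config@diseases))
  for (d in config@diseases) {
    k <- prev[[d]]
    idx <- which(snps$disease == d)
    status <- stats::rbinom(n, 1, k) == 1
    loglr <- numeric(n)
    for (r in idx) {
      ef <- expectedGenotypeFreqs(snps$allele_freq[r], snps$per_allele_or[r], k)
      g <- integer(n)
      if (any(status))
        g[status] <- sample(0:2, sum(status), replace = TRUE, prob = ef$cases)
      if (any(!status))
        g[!status] <- sample(0:2, sum(!status), replace = TRUE,
                             prob = ef$controls)
      geno[, r] <- g
      loglr <- loglr + log(ef$cases[g + 1L] / ef$controls[g + 1L])
    }
    case[, d] <- status
    liability[, d] <- stats::qlogis(k) + loglr
  }

  clinical <- simulateClinical(config, subjects, liability)

  out <- list(subjects = subjects, genotypes = geno, snpInfo = snps,
              clinical = clinical,
              truth = list(liability = liability, case = case))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                  clinical = file.path(dir, "clinical.tsv"),
                  priors = file.path(dir, "priors.tsv"),
                  truth = file.path(dir, "truth.json"))
    writeCohortVcf(geno, snps, paths$vcf)
    writeTsv(clinical, paths$clinical)
    writeTsv(config@prevalence, paths$priors)
    jsonlite::write_json(
      list(subjects = subjects, liability = as.data.frame(liability),
           case = as.data.frame(case)),
      paths$truth, digits = NA, dataframe = "columns")
    out$paths <- paths
  }
  out
}

## Clinical long table: subject-level trait means correlated with the
## linked disease's standardized liability, plus per-visit noise.
simulateClinical <- function(config, subjects, liability) {
  n <- nrow(subjects)
  tr <- config@traits
  if (!nrow(tr)) return(data.frame(subject_id = character(), sex = character(),
                                   visit = integer(), trait = character(),
                                   value = numeric()))
  blocks <- vector("list", nrow(tr))
  for (t in seq_len(nrow(tr))) {
    rho <- tr$liability_corr[t]
    if (!is.na(tr$linked_disease[t]) && rho != 0 && n > 1) {
      z <- as.vector(scale(liability[, tr$linked_disease[t]]))
      if (any(!is.finite(z))) z <- numeric(n)  # degenerate liability
      m <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    } else {
      m <- stats::rnorm(n)
    }
    visits <- rep(seq_len(config@nVisits), each = n)
    blocks[[t]] <- data.frame(
      subject_id = rep(subjects$subject_id, config@nVisits),
      sex = rep(subjects$sex, config@nVisits),
      visit = visits,
      trait = tr$trait[t],
      value = rep(m, config@nVisits) +
        stats::rnorm(n * config@nVisits, sd = config@visitNoiseSd),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$subject_id, out$trait, out$visit), ]
  rownames(out) <- NULL
  out
}

## Minimal VCFv4.2 writer: GT-only, one multi-sample body, contig chrS.
writeCohortVcf <- function(geno, snps, path) {
  gtCode <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chrS>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(snps)), function(r) {
    paste(c(snps$chrom[r], snps$pos[r], snps$snp_id[r],
            snps$other_allele[r], snps$effect_allele[r], ".", "PASS", ".",
            "GT", gtCode[geno[, r] + 1L]), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write every synthetic study input to a directory
#'
#' Convenience wrapper producing the full set of pipeline inputs:
#' association catalog, genotypes VCF, clinical long table, priors,
#' trait configuration JSON, and the simulation truth.
#'
#' @param config A [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
simulateStudy <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat_path <- file.path(dir, "catalog.tsv")
  writeAssociationCatalog(simulateAssociationCatalog(config), cat_path)
  sim <- simulateCohort(config, dir = dir)
  traits_path <- file.path(dir, "traits.json")
  jsonlite::write_json(config@traits, traits_path, digits = NA, na = "null")
  invisible(c(list(catalog = cat_path, traits = traits_path), sim$paths))
}
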