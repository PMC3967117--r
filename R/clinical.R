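#' Build or validate a trait configuration
#'
#' The trait configuration maps each measured clinical trait to one of
#' the eight wellness domains, declares its risk direction (whether high
#' or low values confer risk), optionally links it to a disease, and
#' carries the heritability used by heritability-scaled conditioning.
#'
#' @param trait trait names.
#' @param direction "risk-increasing-high" (high values are risky) or
#'   "risk-increasing-low" (high values are protective, e.g. HDL
#'   cholesterol); the latter are sign-flipped before binning.
#' @param domain one of [HEALTH_DOMAINS] per trait.
#' @param linked_disease optional disease name per trait (NA allowed).
#' @param heritability optional h-squared in (0, 1\] per trait; required
#'   for any trait used in heritability-scaled conditioning.
#' @return Validated data.frame with those columns.
#' @export
traitConfig <- function(trait, direction, domain,
                        linked_disease = NA_character_,
                        heritability = NA_real_) {
  out <- data.frame(trait = trait, direction = direction, domain = domain,
                    linked_disease = linked_disease,
                    heritability = heritability, stringsAsFactors = FALSE)
  stopIfNot(all(out$direction %in% c("risk-increasing-high",
                                     "risk-increasing-low")),
            "direction must be risk-increasing-high or risk-increasing-low")
  stopIfNot(all(out$domain %in% HEALTH_DOMAINS),
            paste("domain must be one of:", paste(HEALTH_DOMAINS, collapse = ", ")))
  h <- out$heritability
  stopIfNot(all(is.na(h) | (h > 0 & h <= 1)),
            "heritability must lie in (0,1] where given")
  out
}

#' Read a trait configuration from JSON
#'
#' @param path JSON file with fields trait, direction, domain,
#'   linked_disease, heritability (array of objects or parallel arrays).
#' @return Validated trait configuration data.frame.
#' @export
readTraitConfig <- function(path) {
  x <- jsonlite::fromJSON(path)
  traitConfig(x$trait, x$direction, x$domain,
              x$linked_disease %||% NA_character_,
              x$heritability %||% NA_real_)
}

#' Cohort-referenced z-score
#'
#' Standardizes a value against a cohort: subtract the cohort mean and
#' divide by the cohort standard deviation (n-1 denominator).
#'
#' @param x value(s) to standardize.
#' @param cohort numeric vector of cohort values (n >= 2), typically the
#'   per-subject visit-averaged trait values.
#' @return z-score(s).
#' @examples
#' zScore(2, c(0, 2))  # +1/sqrt(2)
#' @export
zScore <- function(x, cohort) {
  stopIfNot(length(cohort) >= 2, "cohort must contain at least 2 values")
  s <- stats::sd(cohort)
  if (!is.finite(s) || s == 0)
    stop("cohort standard deviation is zero; z-scores undefined", call. = FALSE)
  (x - mean(cohort)) / s
}

#' Bin a z-score into the five-level risk scale
#'
#' After direction adjustment (the additive inverse is taken when high
#' values are protective), z-scores are cut at one and two standard
#' deviation units from the cohort mean:
#' z < -2 very_low, \[-2, -1) low, \[-1, 1\] intermediate, (1, 2\] high,
#' > 2 very_high.
#'
#' @param z finite z-score(s).
#' @param direction "risk-increasing-high" (default) or
#'   "risk-increasing-low" (protective: z is negated before binning).
#' @return Ordered factor on [RISK_LEVELS].
#' @examples
#' binCategory(2.5)                                # very_high
#' binCategory(2.5, "risk-increasing-low")          # very_low
#' @export
binCategory <- function(z, direction = "risk-increasing-high") {
  stopIfNot(all(is.finite(z)), "z-scores must be finite")
  stopIfNot(all(direction %in% c("risk-increasing-high",
                                 "risk-increasing-low")),
            "unknown trait direction")
  adj <- ifelse(rep_len(direction, length(z)) == "risk-increasing-low", -z, z)
  lev <- ifelse(adj < -2, "very_low",
                ifelse(adj < -1, "low",
                       ifelse(adj <= 1, "intermediate",
                              ifelse(adj <= 2, "high", "very_high"))))
  riskFactor(lev)
}

#' Aggregate direction-adjusted z-scores over a domain
#'
#' The domain score is the unweighted mean of the direction-adjusted
#' z-scores of the domain's traits, binned with [binCategory()].
#'
#' @param adjustedZ numeric vector of direction-adjusted trait z-scores
#'   belonging to one domain (length >= 1).
#' @return list(z = mean, category = five-level bin).
#' @export
domainScore <- function(adjustedZ) {
  stopIfNot(length(adjustedZ) >= 1 && all(is.finite(adjustedZ)),
            "at least one finite adjusted z-score required")
  m <- mean(adjustedZ)
  list(z = m, category = binCategory(m))
}

#' Build cohort clinical profiles from longitudinal measurements
#'
#' Per subject and trait, averages the first `maxVisits` visits (fewer if
#' fewer are available, ordered by visit number); the cohort reference is
#' the mean and SD (n-1 denominator) of these per-subject averages.
#' Z-scores are direction-adjusted per the trait configuration, binned
#' into the five-level scale, and aggregated per domain as the
#' unweighted mean of the contributing adjusted z-scores. Domains with no
#' configured trait are absent from the output.
#'
#' @param clinical long data.frame(subject_id, sex, visit, trait, value).
#' @param traits trait configuration (see [traitConfig()]).
#' @param maxVisits number of leading visits to average (default 3).
#' @return A [ClinicalCohort-class].
#' @examples
#' cfg <- simulationConfig(nSubjects = 30, seed = 5)
#' sim <- simulateCohort(cfg)
#' prof <- buildClinicalProfiles(sim$clinical, cfg@traits)
#' prof
#' @export
buildClinicalProfiles <- function(clinical, traits, maxVisits = 3) {
  need <- c("subject_id", "sex", "visit", "trait", "value")
  stopIfNot(all(need %in% names(clinical)),
            paste("clinical table needs columns:", paste(need, collapse = ", ")))
  traits <- traitConfig(traits$trait, traits$direction, traits$domain,
                        traits$linked_disease %||% NA_character_,
                        traits$heritability %||% NA_real_)
  clin <- clinical[clinical$trait %in% traits$trait, , drop = FALSE]
  stopIfNot(nrow(clin) > 0, "no measurements match the configured traits")
  clin <- clin[order(clin$subject_id, clin$trait, clin$visit), ]
  ## mean of the first min(maxVisits, available) visits
  keyST <- paste(clin$subject_id, clin$trait, sep = "\r")
  firstK <- unlist(lapply(split(seq_len(nrow(clin)), keyST), function(i)
    i[seq_len(min(maxVisits, length(i)))]), use.names = FALSE)
  sub <- clin[sort(firstK), ]
  agg <- stats::aggregate(value ~ subject_id + trait, data = sub, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"

  subjects <- unique(clinical[c("subject_id", "sex")])
  rownames(subjects) <- NULL

  stats_list <- lapply(split(agg, agg$trait), function(a) {
    if (nrow(a) < 2)
      stop(sprintf("trait '%s': cohort of %d subject(s) too small for z-scores",
                   a$trait[1], nrow(a)), call. = FALSE)
    s <- stats::sd(a$mean_value)
    if (!is.finite(s) || s == 0)
      stop(sprintf("trait '%s': zero cohort standard deviation", a$trait[1]),
           call. = FALSE)
    data.frame(trait = a$trait[1], mean = mean(a$mean_value), sd = s,
               n = nrow(a), stringsAsFactors = FALSE)
  })
  cohortStats <- do.call(rbind, stats_list)
  rownames(cohortStats) <- NULL

  i <- match(agg$trait, cohortStats$trait)
  agg$z <- (agg$mean_value - cohortStats$mean[i]) / cohortStats$sd[i]
  dirn <- traits$direction[match(agg$trait, traits$trait)]
  agg$adjusted_z <- ifelse(dirn == "risk-increasing-low", -agg$z, agg$z)
  agg$category <- as.character(binCategory(agg$adjusted_z))
  agg$domain <- traits$domain[match(agg$trait, traits$trait)]

  dom <- stats::aggregate(adjusted_z ~ subject_id + domain, data = agg,
                          FUN = mean)
  names(dom)[names(dom) == "adjusted_z"] <- "z"
  dom$category <- as.character(binCategory(dom$z))
  dom <- dom[order(dom$subject_id, match(dom$domain, HEALTH_DOMAINS)), ]
  rownames(dom) <- NULL

  traitsOut <- agg[order(agg$subject_id, agg$trait),
                   c("subject_id", "trait", "domain", "mean_value", "z",
                     "adjusted_z", "category")]
  rownames(traitsOut) <- NULL
  new("ClinicalCohort", subjects = subjects, traits = traitsOut,
      domains = dom, cohortStats = cohortStats, traitConfig = traits)
}

#' Clinical likelihood ratio from a Framingham-type score
#'
#' The subject's score (averaged over their first visits) divided by the
#' cohort mean score. By construction the cohort-average LR is 1.
#'
#' @param subjectMean subject's mean score.
#' @param cohortMean cohort mean score (> 0).
#' @return Likelihood ratio (positive real).
#' @export
frsLR <- function(subjectMean, cohortMean) {
  stopIfNot(is.finite(cohortMean) && cohortMean > 0,
            "cohort mean score must be positive")
  subjectMean / cohortMean
}

#' Framingham risk scores are inputs, not outputs
#'
#' This package consumes externally computed Framingham risk scores as
#' columns of its input; it deliberately does not implement the
#' Framingham equations. Calling this stub is always an error.
#'
#' @param ... ignored.
#' @export
computeFRS <- function(...) {
  stop("Framingham risk scores must be supplied as input (column 'frs'); ",
       "this package does not implement the Framingham equations",
       call. = FALSE)
}

#' Clinical likelihood ratio for a given z-score
#'
#' Default model: the equal-variance Gaussian-shift likelihood ratio. If
#' affected subjects' trait z-scores are N(delta, 1) and unaffected
#' N(0, 1), the density ratio at z is exp(delta * z - delta^2 / 2).
#' Alternatively, an empirical model assigns an LR per z-bin from a
#' labelled cohort.
#'
#' @param z z-score(s).
#' @param delta Gaussian mean shift between affected and unaffected;
#'   must be supplied (there is no defensible default) unless `bins` is.
#' @param bins optional empirical model: data.frame(lo, hi, lr) of
#'   half-open z intervals \[lo, hi) and their LRs.
#' @return Positive likelihood ratio(s).
#' @examples
#' clinicalLRFromZ(1, delta = 1)  # exp(0.5)
#' @export
clinicalLRFromZ <- function(z, delta = NULL, bins = NULL) {
  if (is.null(delta) && is.null(bins))
    stop("clinical LR model not configured: supply 'delta' (Gaussian shift) ",
         "or 'bins' (empirical z-bin LRs)", call. = FALSE)
  if (!is.null(bins)) {
    stopIfNot(all(c("lo", "hi", "lr") %in% names(bins)),
              "bins needs columns lo, hi, lr")
    stopIfNot(all(bins$lr > 0), "bin LRs must be positive")
    idx <- vapply(z, function(zi)
      which(zi >= bins$lo & zi < bins$hi)[1], 1L)
    stopIfNot(all(!is.na(idx)), "z-score outside the configured bins")
    return(bins$lr[idx])
  }
  exp(delta * z - delta^2 / 2)
}
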