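#' Assemble a per-subject report
#'
#' Bundles everything the pipeline knows about one subject — the
#' risk-o-gram, its clinically conditioned counterpart, the per-domain
#' gridiron cells and a concordance summary — together with a provenance
#' block (MD5 of the catalog records and of the configuration, the seed,
#' and the package version) so every number is traceable to its inputs.
#' By default clinical values appear only as z-scores, never as raw
#' measurements.
#'
#' @param riskogram A [Riskogram-class].
#' @param conditioned optional conditioned [Riskogram-class].
#' @param gridiron optional data.frame from [buildGridiron()].
#' @param clinicalTraits optional data.frame of the subject's trait rows
#'   (z-scores and categories).
#' @param provenance named list (e.g. catalog_md5, config_md5, seed).
#' @return A `SubjectReport`: a named list with class "SubjectReport".
#' @export
buildSubjectReport <- function(riskogram, conditioned = NULL, gridiron = NULL,
                               clinicalTraits = NULL, provenance = list()) {
  grid <- if (is.null(gridiron))
    data.frame(domain = character(), clinical_category = character(),
               genetic_category = character(), concordance = character(),
               stringsAsFactors = FALSE) else gridiron
  counts <- c(concordant = sum(grid$concordance == "concordant"),
              discordant = sum(grid$concordance == "discordant"),
              indeterminate = sum(grid$concordance == "indeterminate"))
  ratio <- if (counts[["discordant"]] > 0)
    counts[["concordant"]] / counts[["discordant"]] else NA_real_
  structure(list(
    subject_id = riskogram@subject_id,
    sex = riskogram@sex,
    riskogram = records(riskogram),
    conditioned_riskogram = if (is.null(conditioned)) NULL
                            else records(conditioned),
    gridiron = grid,
    clinical = clinicalTraits,
    concordance_summary = list(counts = as.list(counts),
                               concordant_to_discordant = ratio),
    provenance = provenance
  ), class = "SubjectReport")
}

#' @method print SubjectReport
#' @export
print.SubjectReport <- function(x, ...) {
  cat("SubjectReport", x$subject_id, paste0("(", x$sex, ")"), "\n")
  cat("  riskogram:", nrow(x$riskogram), "diseases;",
      "gridiron:", nrow(x$gridiron), "domains\n")
  cs <- x$concordance_summary$counts
  cat(sprintf("  concordance: %d concordant / %d discordant / %d indeterminate\n",
              cs$concordant, cs$discordant, cs$indeterminate))
  invisible(x)
}

#' Write a subject report to disk
#'
#' `json` writes a single schema-stable JSON file that [readSubjectReport()]
#' round-trips; `tsv` writes the risk-o-gram (and gridiron, if present)
#' as tab-separated tables; `png` renders the risk-o-gram, gridiron and
#' radar plots with base graphics (safe on headless systems). Sections
#' that are empty are serialized as empty lists and produce no plot.
#'
#' @param report A `SubjectReport` from [buildSubjectReport()].
#' @param dir output directory (created if needed).
#' @param formats subset of c("json", "tsv", "png").
#' @return Invisibly, the written file paths.
#' @export
renderReport <- function(report, dir, formats = "json") {
  bad <- setdiff(formats, c("json", "tsv", "png"))
  if (length(bad))
    stop("unknown report format(s): ", paste(bad, collapse = ", "),
         " (supported: json, tsv, png)", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, report$subject_id)
  paths <- character()
  if ("json" %in% formats) {
    p <- paste0(stem, "_report.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    p <- paste0(stem, "_riskogram.tsv")
    writeTsv(report$riskogram, p)
    paths <- c(paths, p)
    if (nrow(report$gridiron)) {
      p2 <- paste0(stem, "_gridiron.tsv")
      writeTsv(report$gridiron, p2)
      paths <- c(paths, p2)
    }
  }
  if ("png" %in% formats) {
    if (nrow(report$riskogram)) {
      p <- paste0(stem, "_riskogram.png")
      grDevices::png(p, width = 800, height = 500)
      plotRiskogram(report$riskogram, main = paste("Risk-o-gram:",
                                                   report$subject_id))
      grDevices::dev.off()
      paths <- c(paths, p)
    }
    if (nrow(report$gridiron)) {
      p <- paste0(stem, "_gridiron.png")
      grDevices::png(p, width = 700, height = 450)
      plotGridiron(report$gridiron, main = paste("Gridiron:",
                                                 report$subject_id))
      grDevices::dev.off()
      paths <- c(paths, p)
      p <- paste0(stem, "_radar.png")
      grDevices::png(p, width = 550, height = 550)
      plotRadar(report$gridiron, main = paste("Domain summary:",
                                              report$subject_id))
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read a subject report back from JSON
#'
#' @param path a JSON file written by [renderReport()].
#' @return A `SubjectReport` list.
#' @export
readSubjectReport <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (f in c("riskogram", "conditioned_riskogram", "gridiron", "clinical"))
    if (!is.null(x[[f]]) && is.data.frame(x[[f]])) rownames(x[[f]]) <- NULL
  structure(x, class = "SubjectReport")
}

#' Plot a risk-o-gram
#'
#' Rank-ordered horizontal display: baseline pre-test probability
#' (triangle) joined to the genotypically adjusted post-test probability
#' (point), coloured by the direction of the genotypic effect, with the
#' SNP count in the right margin.
#'
#' @param tab riskogram data.frame (`records()` of a [Riskogram-class]).
#' @param main plot title.
#' @return Invisibly, NULL.
#' @export
plotRiskogram <- function(tab, main = "Risk-o-gram") {
  tab <- tab[order(tab$post_test_probability), , drop = FALSE]
  n <- nrow(tab)
  op <- graphics::par(mar = c(4, 12, 3, 4))
  on.exit(graphics::par(op))
  xmax <- max(tab$post_test_probability, tab$pre_test_probability) * 1.1
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "Disease probability", ylab = "",
                 main = main)
  graphics::axis(2, at = seq_len(n), labels = tab$disease, las = 1,
                 cex.axis = 0.8)
  col <- ifelse(tab$combined_lr > 1, "darkorange2",
                ifelse(tab$combined_lr < 1, "purple3", "grey40"))
  graphics::segments(tab$pre_test_probability, seq_len(n),
                     tab$post_test_probability, seq_len(n), col = col, lwd = 2)
  graphics::points(tab$pre_test_probability, seq_len(n), pch = 17,
                   col = "black")
  graphics::points(tab$post_test_probability, seq_len(n), pch = 16, col = col)
  graphics::mtext(paste0("n=", tab$n_snps), side = 4, at = seq_len(n),
                  las = 1, cex = 0.7, line = 0.5)
  invisible(NULL)
}

#' Plot a gridiron
#'
#' Domains on the x-axis, the five risk levels on the y-axis; clinical
#' categories drawn as filled squares, genetic categories as open
#' circles, discordant domains flagged in red.
#'
#' @param cells data.frame from [buildGridiron()].
#' @param main plot title.
#' @return Invisibly, NULL.
#' @export
plotGridiron <- function(cells, main = "Gridiron") {
  n <- nrow(cells)
  op <- graphics::par(mar = c(8, 8, 3, 2))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(0.5, 5.5),
                 xaxt = "n", yaxt = "n", xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(n), labels = cells$domain, las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = 1:5, labels = RISK_LEVELS, las = 1, cex.axis = 0.8)
  graphics::abline(h = 1:5, col = "grey85")
  flag <- cells$concordance == "discordant"
  cy <- match(cells$clinical_category, RISK_LEVELS)
  gy <- match(cells$genetic_category, RISK_LEVELS)
  graphics::points(seq_len(n) - 0.12, cy, pch = 15, cex = 1.6,
                   col = ifelse(flag, "red3", "steelblue4"))
  graphics::points(seq_len(n) + 0.12, gy, pch = 21, cex = 1.6, lwd = 2,
                   col = ifelse(flag, "red3", "darkgreen"))
  graphics::legend("topright", pch = c(15, 21),
                   col = c("steelblue4", "darkgreen"),
                   legend = c("clinical", "genetic"), bty = "n")
  invisible(NULL)
}

#' Radar-style domain summary
#'
#' Polar display of the per-domain risk levels (clinical solid, genetic
#' dashed), one spoke per domain.
#'
#' @param cells data.frame from [buildGridiron()].
#' @param main plot title.
#' @return Invisibly, NULL.
#' @export
plotRadar <- function(cells, main = "Domain summary") {
  n <- nrow(cells)
  if (n < 3) {
    graphics::plot.new()
    graphics::title(main = main)
    graphics::text(0.5, 0.5, "too few domains for a radar display")
    return(invisible(NULL))
  }
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  op <- graphics::par(mar = c(2, 2, 3, 2))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (r in (1:5) / 5)
    graphics::polygon(r * cos(theta), r * sin(theta), border = "grey85")
  graphics::segments(0, 0, cos(theta), sin(theta), col = "grey85")
  graphics::text(1.25 * cos(theta), 1.25 * sin(theta), cells$domain,
                 cex = 0.7)
  drawSide <- function(levels, col, lty) {
    r <- match(levels, RISK_LEVELS) / 5
    ok <- !is.na(r)
    if (sum(ok) >= 3)
      graphics::polygon(ifelse(ok, r, 0) * cos(theta),
                        ifelse(ok, r, 0) * sin(theta),
                        border = col, lwd = 2, lty = lty)
  }
  drawSide(cells$clinical_category, "steelblue4", 1)
  drawSide(cells$genetic_category, "darkgreen", 2)
  invisible(NULL)
}

#' Run the whole synthetic study end to end
#'
#' Simulates the study inputs from `config`, writes them to disk, and
#' runs every downstream stage through the same file interfaces a real
#' analysis would use: catalog read-back and validation, significance
#' filtering and block pruning, likelihood-ratio estimation, VCF
#' genotype lookup, clinical profiling, per-subject risk-o-grams,
#' clinical conditioning (heritability-scaled where the linked trait has
#' a heritability, Bayes probability update otherwise), gridiron
#' assembly, and report rendering. Diseases left with no SNP after
#' curation are assessed with the neutral combined LR = 1. All
#' randomness flows from `config@seed`; rerunning with the same
#' configuration reproduces byte-identical JSON reports.
#'
#' @param config A [SimulationConfig-class], or a path to a JSON file of
#'   [simulationConfig()] arguments.
#' @param outDir output directory (default: a fresh temporary directory).
#' @param clinicalDelta Gaussian shift of [clinicalLRFromZ()] used to
#'   turn trait z-scores into clinical LRs (default 0.5).
#' @param ancestry,pmax,r2 curation settings passed to
#'   [filterSignificant()] and [ldPrune()].
#' @param formats report formats for [renderReport()].
#' @return list: `reports` (per-subject `SubjectReport`s), `riskograms`,
#'   `conditioned`, `profiles` (a [ClinicalCohort-class]), `lrSet`,
#'   `concordance` (cohort-level counts), `dir`.
#' @examples
#' \donttest{
#' res <- runPipeline(simulationConfig(nSubjects = 24, seed = 11))
#' res$concordance
#' }
#' @export
runPipeline <- function(config, outDir = tempfile("riskogram_run_"),
                        clinicalDelta = 0.5, ancestry = "European",
                        pmax = 1e-6, r2 = 0.8, formats = "json") {
  if (is.character(config)) {
    args <- jsonlite::fromJSON(config)
    args$prevalence <- if (!is.null(args$prevalence))
      as.data.frame(args$prevalence) else NULL
    args$traits <- if (!is.null(args$traits)) as.data.frame(args$traits)
      else NULL
    config <- do.call(simulationConfig, args[!vapply(args, is.null, TRUE)])
  }
  validObject(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  message("stage simulate: writing synthetic study inputs")
  paths <- simulateStudy(config, outDir)
  catalog <- readAssociationCatalog(paths$catalog)
  message(sprintf("stage curate: %d records read", length(catalog)))
  curated <- ldPrune(filterSignificant(catalog, ancestry, pmax), r2Threshold = r2)
  message(sprintf("stage curate: %d records kept after P<%g filter and r2>=%g pruning",
                  length(curated), pmax, r2))

  lrTab <- if (length(curated) > 0) records(computeSnpLR(curated)) else
    records(new("SnpLRSet", table = data.frame(
      snp_id = character(), disease = character(), chrom = character(),
      pos = integer(), effect_allele = character(), other_allele = character(),
      lr0 = numeric(), lr1 = numeric(), lr2 = numeric(),
      n_studies = integer(), total_weight = numeric())))
  lrSet <- new("SnpLRSet", table = lrTab)

  genotypes <- readGenotypes(paths$vcf)
  dosages <- if (nrow(lrTab)) genotypeLookup(genotypes, lrTab) else NULL
  message(sprintf("stage grisk: %d SNP LRs, %d genotype calls matched",
                  nrow(lrTab), if (is.null(dosages)) 0L else sum(!is.na(dosages))))

  clinical <- readTsv(paths$clinical)
  traits <- readTraitConfig(paths$traits)
  profiles <- buildClinicalProfiles(clinical, traits)
  priors <- readPriors(paths$priors)

  catalogHash <- hashFile(paths$catalog)
  configHash <- hashObject(config)
  version <- as.character(utils::packageVersion("riskogram"))

  subjects <- profiles@subjects
  diseaseDomain <- traits[!is.na(traits$linked_disease),
                          c("linked_disease", "domain", "trait", "heritability")]
  riskograms <- list(); conditioned <- list(); reports <- list()
  assessAll <- function(sid, sex) {
    d <- if (is.null(dosages)) stats::setNames(integer(), character())
         else dosages[sid, ]
    a <- if (nrow(lrTab)) assessSubject(lrSet, priors, d, sex) else NULL
    pri <- priors[priors$sex == sex, , drop = FALSE]
    missing <- setdiff(intersect(config@diseases, pri$disease),
                       if (is.null(a)) character() else a$disease)
    neutral <- lapply(missing, function(dd)
      combinePostTest(pri$pre_test_probability[match(dd, pri$disease)],
                      numeric(), disease = dd, sex = sex))
    do.call(rbind, c(list(a), neutral))
  }
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]; sex <- subjects$sex[i]
    riskograms[[sid]] <- buildRiskogram(assessAll(sid, sex), sid, sex)
  }

  ## clinical LRs per disease from the linked trait's z-score
  subjTraits <- profiles@traits
  clinLR <- function(sid) {
    dd <- diseaseDomain
    z <- subjTraits$adjusted_z[match(paste(sid, dd$trait),
                                     paste(subjTraits$subject_id, dd$trait))]
    data.frame(disease = dd$linked_disease,
               clinical_lr = clinicalLRFromZ(z, delta = clinicalDelta),
               h2 = dd$heritability, stringsAsFactors = FALSE)
  }

  ## per-domain genetic score: mean combined LR of the domain's diseases
  domScores <- do.call(rbind, lapply(subjects$subject_id, function(sid) {
    tab <- records(riskograms[[sid]])
    dd <- diseaseDomain[diseaseDomain$linked_disease %in% tab$disease, ]
    if (!nrow(dd)) return(NULL)
    agg <- tapply(tab$combined_lr[match(dd$linked_disease, tab$disease)],
                  dd$domain, mean)
    data.frame(subject_id = sid, domain = names(agg), score = as.vector(agg),
               stringsAsFactors = FALSE)
  }))

  smallCohort <- nrow(subjects) < 20
  if (smallCohort)
    message("stage gridiron: cohort below 20 subjects; genetic percentile categories omitted")

  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    lrs <- clinLR(sid)
    haveH2 <- !is.na(lrs$h2)
    cond <- riskograms[[sid]]
    if (any(haveH2))
      cond <- conditionRiskogram(cond, lrs[haveH2, ], "heritability_scaled")
    if (any(!haveH2))
      cond <- conditionRiskogram(cond, lrs[!haveH2, ], "frs_ratio")
    conditioned[[sid]] <- cond

    clinDom <- profiles@domains[profiles@domains$subject_id == sid,
                                c("domain", "category")]
    genDom <- if (smallCohort || is.null(domScores)) {
      data.frame(domain = character(), category = character())
    } else {
      ds <- domScores[domScores$subject_id == sid, , drop = FALSE]
      cats <- vapply(seq_len(nrow(ds)), function(k) {
        pool <- domScores$score[domScores$domain == ds$domain[k]]
        as.character(geneticCategory(ds$score[k], pool))
      }, "")
      data.frame(domain = ds$domain, category = cats, stringsAsFactors = FALSE)
    }
    grid <- buildGridiron(clinDom, genDom)
    reports[[sid]] <- buildSubjectReport(
      riskograms[[sid]], conditioned[[sid]], grid,
      clinicalTraits = subjTraits[subjTraits$subject_id == sid,
                                  c("trait", "domain", "z", "adjusted_z",
                                    "category")],
      provenance = list(catalog_md5 = catalogHash, config_md5 = configHash,
                        seed = config@seed, tool_version = version))
    renderReport(reports[[sid]], file.path(outDir, "reports"),
                 formats = formats)
  }

  allGrid <- do.call(rbind, lapply(reports, `[[`, "gridiron"))
  concordance <- c(concordant = sum(allGrid$concordance == "concordant"),
                   discordant = sum(allGrid$concordance == "discordant"),
                   indeterminate = sum(allGrid$concordance == "indeterminate"))
  message(sprintf("stage report: %d reports written to %s",
                  length(reports), file.path(outDir, "reports")))
  list(reports = reports, riskograms = riskograms, conditioned = conditioned,
       profiles = profiles, lrSet = lrSet, concordance = concordance,
       dir = outDir)
}
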