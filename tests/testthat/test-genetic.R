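test_that("a single study gives the plain frequency ratio, exactly", {
  fc <- c(0.50, 0.30, 0.20)
  fn <- c(0.25, 0.50, 0.25)
  cat1 <- makeCatalog(catalogRow(fc = fc, fn = fn))
  lr <- records(computeSnpLR(cat1))
  expect_identical(lr$lr0, fc[1] / fn[1])  # 2.0
  expect_equal(c(lr$lr0, lr$lr1, lr$lr2), fc / fn, tolerance = 1e-15)
  ## control-expectation identity: sum_g F(g, controls) * LR(g) = 1
  expect_equal(sum(fn * c(lr$lr0, lr$lr1, lr$lr2)), 1, tolerance = 1e-12)
})

test_that("identical case and control frequencies give LR = 1 for every genotype", {
  f <- hweTriple(0.4)
  lr <- records(computeSnpLR(makeCatalog(catalogRow(fc = f, fn = f))))
  expect_equal(c(lr$lr0, lr$lr1, lr$lr2), c(1, 1, 1), tolerance = 1e-15)
})

test_that("multi-study weighting averages log-ratios by sample size", {
  ## two studies with per-genotype ratio 2 and 4, sizes 100 and 300:
  ## LR = exp((100 log 2 + 300 log 4) / 400) = 3.36358566101486 (frozen
  ## from a direct evaluation of the weighted sum)
  fc1 <- c(0.50, 0.30, 0.20); fn1 <- c(0.25, 0.50, 0.25)  # ratio 2 at g=0
  fc2 <- c(0.80, 0.12, 0.08); fn2 <- c(0.20, 0.50, 0.30)  # ratio 4 at g=0
  cat1 <- makeCatalog(
    catalogRow(study_id = "s1", n_cases = 50L, n_controls = 50L, fc = fc1,
               fn = fn1),
    catalogRow(study_id = "s2", n_cases = 150L, n_controls = 150L, fc = fc2,
               fn = fn2))
  lr <- records(computeSnpLR(cat1))
  expect_equal(lr$lr0, 3.36358566101486, tolerance = 1e-12)
  ## cross-check every genotype against the direct weighted sum
  direct <- exp((log(fc1 / fn1) * 100 + log(fc2 / fn2) * 300) / 400)
  expect_equal(c(lr$lr0, lr$lr1, lr$lr2), direct, tolerance = 1e-12)
  expect_equal(lr$n_studies, 2L)
  expect_equal(lr$total_weight, 400)
})

test_that("zero genotype frequencies get a finite continuity-corrected LR", {
  cat1 <- makeCatalog(catalogRow(n_cases = 100L, n_controls = 100L,
                                 fc = c(0.50, 0.50, 0.00),
                                 fn = c(0.40, 0.50, 0.10)))
  expect_warning(lr <- records(computeSnpLR(cat1)), "continuity")
  expect_true(all(is.finite(c(lr$lr0, lr$lr1, lr$lr2))))
  expect_true(all(c(lr$lr0, lr$lr1, lr$lr2) > 0))
  ## the corrected g=2 ratio equals (0 + .5)/(10 + .5) times the
  ## renormalization of both triples, computed by hand
  cc <- c(50, 50, 0.5); cn <- c(40, 50, 10.5)
  expect_equal(lr$lr2, (cc[3] / sum(cc)) / (cn[3] / sum(cn)),
               tolerance = 1e-12)
})

test_that("post-test update follows Bayes' rule on the odds scale", {
  ## identity and cancellation
  expect_equal(combinePostTest(0.5, c(1, 1, 1))$post_test_probability, 0.5)
  expect_equal(combinePostTest(0.1, c(2, 0.5))$post_test_probability, 0.1,
               tolerance = 1e-15)
  ## hand Bayes oracle: p=0.1, LR=2 -> odds 1/9 * 2 = 2/9 -> p = 2/11
  out <- combinePostTest(0.1, 2)
  expect_equal(out$post_test_probability, 2 / 11, tolerance = 1e-15)
  expect_equal(out$post_test_odds, 2 / 9, tolerance = 1e-15)
  expect_equal(out$fold_change, (2 / 11) / 0.1, tolerance = 1e-12)
  ## missing genotypes contribute the neutral LR and are counted
  out <- combinePostTest(0.2, c(2, NA, 0.5, NA))
  expect_equal(out$n_snps, 2L)
  expect_equal(out$n_skipped, 2L)
  expect_equal(out$combined_lr, 1)
  expect_error(combinePostTest(1.2, 1), "in \\(0,1\\)")
  expect_error(combinePostTest(0.5, -1), "strictly positive")
})

test_that("post-test probability is strictly increasing in any single LR", {
  base <- c(1.3, 0.7, 2.1)
  for (j in 1:3) {
    lo <- base; hi <- base
    lo[j] <- base[j] * 0.9; hi[j] <- base[j] * 1.1
    expect_lt(combinePostTest(0.15, lo)$post_test_probability,
              combinePostTest(0.15, hi)$post_test_probability)
  }
})

test_that("VCF dosages match effect alleles in either orientation", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "g.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", sep = "\t"),
    paste("chrS", 100, "rs1", "A", "G", ".", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("chrS", 200, "rs2", "G", "A", ".", "PASS", ".", "GT", "1/1",
          sep = "\t"),
    paste("chrS", 300, "rs3", "A", "T", ".", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("chrS", 400, "rs4", "C", "A", ".", "PASS", ".", "GT", "0/0",
          sep = "\t")), vcf)
  g <- readGenotypes(vcf)
  snps <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4"), chrom = "chrS",
    pos = c(100L, 200L, 300L, 400L),
    effect_allele = c("A", "A", "A", "G"),
    other_allele = c("G", "G", "T", "A"), stringsAsFactors = FALSE)
  expect_message(dos <- genotypeLookup(g, snps), "strand-ambiguous")
  ## rs1: effect allele is REF, one ALT allele -> one effect allele... g = 2-1
  expect_equal(dos["P1", "rs1"], 1L)
  ## rs2: swap orientation, effect = ALT, GT 1/1 -> g = 2
  expect_equal(dos["P1", "rs2"], 2L)
  ## rs3 is A/T strand-ambiguous -> missing
  expect_true(is.na(dos["P1", "rs3"]))
  ## rs4: alleles match in neither orientation -> missing
  expect_true(is.na(dos["P1", "rs4"]))
})

test_that("dosages from a synthetic VCF equal a naive string re-parse", {
  cfg <- tinyConfig(17, nSubjects = 25, nSnps = 20)
  d <- withr::local_tempdir()
  sim <- simulateCohort(cfg, dir = d)
  g <- readGenotypes(sim$paths$vcf)
  snps <- sim$snpInfo
  snps$effect_allele <- snps$effect_allele  # catalog orientation = ALT
  dos <- genotypeLookup(g, snps)
  naive <- naiveVcfDosage(sim$paths$vcf)
  expect_equal(unname(dos[rownames(naive), colnames(naive)]),
               unname(naive))
  ## and both equal the simulated truth
  expect_equal(unname(dos[rownames(sim$genotypes), colnames(sim$genotypes)]),
               unname(sim$genotypes))
})

test_that("risk-o-grams are ordered by post-test probability with stable ties", {
  a <- rbind(combinePostTest(0.2, 2, disease = "b", sex = "F"),
             combinePostTest(0.2, 1, disease = "a", sex = "F"),
             combinePostTest(0.2, 1, disease = "c", sex = "F"))
  rg <- buildRiskogram(a, "S1", "F")
  tab <- records(rg)
  expect_equal(tab$disease, c("b", "a", "c"))  # tie a/c broken by name
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$direction, c("increased", "neutral", "neutral"))

  ## 20 random assessments match an independent sort of (post, name)
  set.seed(4)
  many <- do.call(rbind, lapply(1:20, function(i)
    combinePostTest(runif(1, 0.05, 0.5), runif(3, 0.5, 2),
                    disease = paste0("dis", i), sex = "M")))
  tab <- records(buildRiskogram(many, "S2", "M"))
  oracle <- many[order(-many$post_test_probability, many$disease), "disease"]
  expect_equal(tab$disease, oracle)

  ## with all LR = 1, ordering equals ordering by the prior
  null <- do.call(rbind, lapply(1:6, function(i)
    combinePostTest(i / 10, 1, disease = paste0("d", i), sex = "F")))
  tab <- records(buildRiskogram(null, "S3", "F"))
  expect_equal(tab$disease, paste0("d", 6:1))
})

test_that("sex-specific priors omit diseases not assessable for the subject", {
  lrTab <- records(computeSnpLR(makeCatalog(
    catalogRow(disease = "prostate_cancer"),
    catalogRow(disease = "breast_cancer", snp_id = "rs2", pos = 200L))))
  priors <- data.frame(
    disease = c("prostate_cancer", "breast_cancer"),
    sex = c("M", "F"), pre_test_probability = c(0.15, 0.12),
    stringsAsFactors = FALSE)
  dosages <- c(rs1 = 1L, rs2 = 1L)
  lrSet <- new("SnpLRSet", table = lrTab)
  aF <- assessSubject(lrSet, priors, dosages, "F")
  aM <- assessSubject(lrSet, priors, dosages, "M")
  expect_equal(aF$disease, "breast_cancer")
  expect_equal(aM$disease, "prostate_cancer")
})

test_that("per-subject mean post-test probability calibrates to prevalence", {
  ## cohort drawn from the same generative model as the catalog, scored
  ## with the exact (expected) catalog frequencies
  k <- 0.1
  cfg <- tinyConfig(8, nSubjects = 5000, nSnps = 10, or = 1.3,
                    prevalence = k, nVisits = 1,
                    alleleFreqs = seq(0.15, 0.5, length.out = 10))
  sim <- simulateCohort(cfg)
  lrByGeno <- vapply(seq_len(10), function(j) {
    ef <- expectedGenotypeFreqs(cfg@alleleFreqs[j], cfg@perAlleleOR[j], k)
    ef$cases / ef$controls
  }, numeric(3))
  post <- vapply(seq_len(nrow(sim$genotypes)), function(i) {
    lrs <- lrByGeno[cbind(sim$genotypes[i, ] + 1L, seq_len(10))]
    combinePostTest(k, lrs)$post_test_probability
  }, 0)
  se <- sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post) - k), 3 * se)
})
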