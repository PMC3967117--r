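test_that("probability-scale conditioning equals the odds-form computation", {
  expect_equal(conditionFrs(0.2, 1), 0.2)
  ## odds-form algebraic oracle: odds*LR/(1+odds*LR)
  oddsForm <- function(p, lr) { o <- p / (1 - p) * lr; o / (1 + o) }
  expect_equal(conditionFrs(0.1, 2), oddsForm(0.1, 2), tolerance = 1e-15)
  expect_equal(conditionFrs(0.1, 2), 2 / 11, tolerance = 1e-15)
  grid <- expand.grid(p = seq(0.01, 0.99, by = 0.07),
                      lr = c(0.01, 0.1, 0.5, 1, 2, 10, 100))
  expect_equal(conditionFrs(grid$p, grid$lr), oddsForm(grid$p, grid$lr),
               tolerance = 1e-12)
  ## maps (0,1) into (0,1): no clipping ever needed
  expect_true(all(conditionFrs(grid$p, grid$lr) > 0 &
                    conditionFrs(grid$p, grid$lr) < 1))
  ## strictly increasing in LR at fixed prior
  lrs <- sort(c(0.01, 0.1, 0.5, 1, 2, 10, 100))
  for (p in c(0.05, 0.5, 0.95))
    expect_true(all(diff(conditionFrs(p, lrs)) > 0))
  ## limits
  expect_lt(conditionFrs(0.3, 1e-12), 1e-11)
  expect_gt(conditionFrs(0.3, 1e12), 1 - 1e-11)
  expect_error(conditionFrs(0.3, 0), "positive")
})

test_that("heritability scaling multiplies the prior by 2 h2 LR", {
  ## h2 = 0.5: the multiplier is exactly the clinical LR
  expect_equal(conditionHeritability(0.2, 0.5, 1.7), 0.2 * 1.7)
  ## h2 = 0.3: the multiplier is 60% of the LR
  expect_equal(conditionHeritability(0.2, 0.3, 2), 0.2 * 0.6 * 2)
  ## LR = 1, h2 = 0.5: prior unchanged, exactly
  expect_identical(conditionHeritability(0.37, 0.5, 1), 0.37)
  ## 2 h2 LR = 1 returns the prior exactly
  expect_equal(conditionHeritability(0.41, 0.25, 2), 0.41)
  ## clipping with a warning when the product exceeds 1
  expect_warning(out <- conditionHeritability(0.8, 0.5, 3), "clipped")
  expect_equal(out, 1 - 1e-9)
  expect_error(conditionHeritability(0.2, 1.2, 1), "\\(0,1\\]")
  expect_error(conditionHeritability(0.2, 0, 1), "\\(0,1\\]")
})

test_that("genetic percentile categories mirror the SD bins", {
  set.seed(6)
  cohort <- rnorm(1000)
  expect_equal(as.character(geneticCategory(median(cohort), cohort)),
               "intermediate")
  expect_equal(as.character(geneticCategory(max(cohort) + 1, cohort)),
               "very_high")
  expect_equal(as.character(geneticCategory(min(cohort) - 1, cohort)),
               "very_low")
  ## quantile re-computation oracle: category counts over the cohort
  ## itself match direct quantile cuts at 2.5/16/84/97.5
  cats <- geneticCategory(cohort, cohort)
  pct <- 100 * (rank(cohort) - 0.5) / 1000
  oracle <- cut(pct, c(-Inf, 2.5, 16, 84, 97.5, Inf),
                labels = RISK_LEVELS, right = FALSE)
  ## boundary conventions differ only where pct == a cutoff exactly
  agree <- as.character(cats) == as.character(oracle)
  expect_gt(mean(agree), 0.99)
  expect_equal(unname(table(cats)["intermediate"]),
               sum(pct > 16 & pct <= 84))
  expect_error(geneticCategory(0, rnorm(10)), "at least 20")
  expect_warning(out <- geneticCategory(1, rep(1, 30)), "degenerate")
  expect_equal(as.character(out), "intermediate")
})

test_that("concordance compares directions with a neutral zone", {
  expect_equal(classifyConcordance(2.2, "very_high"), "concordant")
  expect_equal(classifyConcordance(0.5, "very_high"), "discordant")
  expect_equal(classifyConcordance(0.5, "low"), "concordant")
  expect_equal(classifyConcordance(1.02, "very_high"), "indeterminate")
  expect_equal(classifyConcordance(2.0, "intermediate"), "indeterminate")
  ## batch of 30 synthetic pairs equals a hand enumeration
  set.seed(13)
  lrs <- exp(runif(30, -1, 1))
  cats <- sample(RISK_LEVELS, 30, replace = TRUE)
  got <- classifyConcordance(lrs, cats)
  oracle <- vapply(1:30, function(i) {
    g <- if (lrs[i] < 0.95) -1 else if (lrs[i] > 1.05) 1 else 0
    cc <- match(cats[i], RISK_LEVELS) - 3
    if (g == 0 || cc == 0) "indeterminate"
    else if (sign(cc) == g) "concordant" else "discordant"
  }, "")
  expect_equal(got, oracle)
})

test_that("gridiron cells flag concordance per domain, truth-table style", {
  clin <- data.frame(domain = c("metabolic", "cardiovascular", "respiratory"),
                     category = c("very_high", "high", "intermediate"))
  gen <- data.frame(domain = c("metabolic", "cardiovascular", "oncological"),
                    category = c("very_high", "low", "high"))
  cells <- buildGridiron(clin, gen)
  expect_equal(cells$concordance[cells$domain == "metabolic"], "concordant")
  expect_equal(cells$concordance[cells$domain == "cardiovascular"],
               "discordant")
  expect_equal(cells$concordance[cells$domain == "respiratory"], "missing")
  expect_equal(cells$concordance[cells$domain == "oncological"], "missing")

  ## randomized categories across all eight domains match the truth table
  set.seed(19)
  for (rep in 1:5) {
    cats1 <- sample(RISK_LEVELS, 8, replace = TRUE)
    cats2 <- sample(RISK_LEVELS, 8, replace = TRUE)
    cells <- buildGridiron(data.frame(domain = HEALTH_DOMAINS, category = cats1),
                           data.frame(domain = HEALTH_DOMAINS, category = cats2))
    i <- match(cells$domain, HEALTH_DOMAINS)
    d1 <- sign(match(cats1[i], RISK_LEVELS) - 3)
    d2 <- sign(match(cats2[i], RISK_LEVELS) - 3)
    oracle <- ifelse(d1 == 0 | d2 == 0, "indeterminate",
                     ifelse(d1 == d2, "concordant", "discordant"))
    expect_equal(cells$concordance, oracle)
  }
})

test_that("conditioning re-ranks without touching the genotypic LR", {
  a <- rbind(combinePostTest(0.30, 1.2, disease = "hypertension", sex = "F"),
             combinePostTest(0.25, 1.8, disease = "hypertriglyceridemia",
                             sex = "F"),
             combinePostTest(0.20, 0.9, disease = "obesity", sex = "F"))
  rg <- buildRiskogram(a, "S1", "F")
  lrs <- data.frame(disease = c("hypertension", "hypertriglyceridemia"),
                    clinical_lr = c(0.4, 2.5))
  cond <- conditionRiskogram(rg, lrs, "frs_ratio")
  tab <- records(cond)
  orig <- records(rg)
  ## genotypic combined LR bitwise-identical before and after
  expect_identical(tab$combined_lr[match(orig$disease, tab$disease)],
                   orig$combined_lr)
  ## adjusted baselines follow the probability-scale Bayes formula
  expect_equal(tab$pre_test_probability[tab$disease == "hypertension"],
               conditionFrs(0.30, 0.4))
  ## unconditioned disease keeps its row
  expect_equal(tab$pre_test_probability[tab$disease == "obesity"], 0.20)
  ## rank order equals the rank of adjusted post-test probabilities
  expect_equal(tab$rank, rank(-tab$post_test_probability,
                              ties.method = "first"))
  expect_equal(tab$rank_before[match(orig$disease, tab$disease)], orig$rank)

  ## heritability-scaled route
  lrs2 <- data.frame(disease = "obesity", clinical_lr = 1.4, h2 = 0.5)
  tab2 <- records(conditionRiskogram(rg, lrs2, "heritability_scaled"))
  expect_equal(tab2$pre_test_probability[tab2$disease == "obesity"],
               0.20 * 2 * 0.5 * 1.4)
  expect_identical(sort(tab2$combined_lr), sort(orig$combined_lr))
})

test_that("positively coupled traits yield more concordance than discordance", {
  ## direction-only assertion, pooled over seeds: when clinical traits
  ## correlate positively with the genetic liability, concordant
  ## disease-level calls must outnumber discordant ones
  conc <- disc <- 0L
  for (s in 1:20) {
    cfg <- tinyConfig(300 + s, nSubjects = 150, nSnps = 6, or = 1.4,
                      corr = 0.6, nVisits = 2)
    sim <- simulateCohort(cfg)
    k <- 0.1
    lrByGeno <- vapply(seq_len(6), function(j) {
      ef <- expectedGenotypeFreqs(cfg@alleleFreqs[j], cfg@perAlleleOR[j], k)
      ef$cases / ef$controls
    }, numeric(3))
    combined <- vapply(seq_len(nrow(sim$genotypes)), function(i)
      prod(lrByGeno[cbind(sim$genotypes[i, ] + 1L, 1:6)]), 0)
    prof <- buildClinicalProfiles(sim$clinical, cfg@traits)
    cats <- prof@traits$category[match(rownames(sim$genotypes),
                                       prof@traits$subject_id)]
    cls <- classifyConcordance(combined, cats)
    conc <- conc + sum(cls == "concordant")
    disc <- disc + sum(cls == "discordant")
  }
  expect_gt(conc, disc)
})
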