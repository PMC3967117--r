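## Independent oracles and fixture builders. Everything here is written
## to be naive and self-evident, never reusing the package's own code
## path for the quantity it checks.

## Brute-force Bayes posterior over all 3^k genotype vectors of k
## conditionally independent SNPs: P(case | g) computed by enumerating
## P(g | case) and P(g | control) as products of the per-SNP frequency
## triples and applying Bayes' rule directly.
bruteForcePosterior <- function(prevalence, caseFreqs, ctrlFreqs) {
  k <- length(caseFreqs)
  grid <- expand.grid(rep(list(0:2), k))
  post <- apply(grid, 1, function(g) {
    pCase <- prod(vapply(seq_len(k), function(j) caseFreqs[[j]][g[j] + 1], 0))
    pCtrl <- prod(vapply(seq_len(k), function(j) ctrlFreqs[[j]][g[j] + 1], 0))
    prevalence * pCase / (prevalence * pCase + (1 - prevalence) * pCtrl)
  })
  cbind(grid, post = post)
}

## Naive VCF dosage reader: plain string splitting, no vcfR.
naiveVcfDosage <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t")[[1]]
  samples <- header[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  ids <- vapply(rows, `[`, "", 3)
  out <- matrix(NA_integer_, length(samples), length(rows),
                dimnames = list(samples, ids))
  for (r in seq_along(rows)) {
    gt <- rows[[r]][-(1:9)]
    out[, r] <- vapply(strsplit(gt, "[/|]"), function(a)
      sum(a == "1"), 0L)
  }
  out
}

## Tiny catalog row builder with HWE-consistent default frequencies.
catalogRow <- function(disease = "d1", snp_id = "rs1", chrom = "chr1",
                       pos = 100L, effect_allele = "A", other_allele = "G",
                       study_id = paste0(snp_id, "_s1"),
                       ancestry = "European",
                       n_cases = 1000L, n_controls = 1000L,
                       p_value = 1e-8, block_id = paste0("blk_", snp_id),
                       fc = c(0.30, 0.50, 0.20), fn = c(0.36, 0.48, 0.16)) {
  data.frame(disease = disease, snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             study_id = study_id, ancestry = ancestry,
             n_cases = n_cases, n_controls = n_controls,
             sample_size = n_cases + n_controls, p_value = p_value,
             block_id = block_id,
             freq0_cases = fc[1], freq1_cases = fc[2], freq2_cases = fc[3],
             freq0_controls = fn[1], freq1_controls = fn[2],
             freq2_controls = fn[3], stringsAsFactors = FALSE)
}

makeCatalog <- function(...) {
  new("AssociationCatalog", records = do.call(rbind, list(...)))
}

## Random valid catalog for property tests: nSnp SNPs in nBlock blocks,
## one study each, random P-values.
randomCatalog <- function(nSnp, nBlock, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(nSnp), function(j) {
    p <- runif(1, 0.1, 0.9)
    catalogRow(snp_id = paste0("rs", j), pos = j * 100L,
               block_id = paste0("blk", sample.int(nBlock, 1)),
               p_value = 10^runif(1, -12, -1),
               fc = hweTriple(p), fn = hweTriple(p))
  })
  do.call(makeCatalog, rows)
}

hweTriple <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

## Minimal one-disease simulation config used across tests.
tinyConfig <- function(seed, nSubjects = 200, nSnps = 4, or = 1.3,
                       prevalence = 0.1, corr = 0.5, nVisits = 3,
                       visitNoiseSd = 0.3, alleleFreqs = seq(0.2, 0.5, length.out = nSnps)) {
  simulationConfig(
    nSubjects = nSubjects, diseases = "d1", nSnpsPerDisease = nSnps,
    prevalence = data.frame(disease = "d1", sex = c("F", "M"),
                            pre_test_probability = prevalence),
    alleleFreqs = alleleFreqs, perAlleleOR = or, nStudiesPerSnp = 2,
    studySizes = c(2000, 4000), nVisits = nVisits,
    traits = data.frame(trait = "m1", direction = "risk-increasing-high",
                        domain = "metabolic", linked_disease = "d1",
                        heritability = 0.5, liability_corr = corr),
    visitNoiseSd = visitNoiseSd, seed = seed)
}
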