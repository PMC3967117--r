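---
title: "Methods: integrated genetic and clinical wellness risk assessment"
author: "riskogram authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated genetic and clinical wellness risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskogram)
```

## The model

The package estimates an individual's disease risk by Bayesian updating
of a baseline ("pre-test") probability with genotype evidence, and then
places that genetic assessment next to a cohort-referenced clinical
assessment.

**Genotype likelihood ratios.** For a SNP $x$ with genotype
$g \in \{0, 1, 2\}$ (count of effect alleles) observed in $s$
case-control studies of sizes $S(i)$, the genotype LR is the
sample-size-weighted geometric mean of the per-study frequency ratios:

$$\log LR(x) \;=\; \frac{\sum_{i=1}^{s} \log\dfrac{F(g \mid \text{cases}, i)}{F(g \mid \text{controls}, i)} \; S(i)}{\sum_{i=1}^{s} S(i)}$$

The mean is taken in log space — the estimator is defined on $\log LR$,
not as a weighted mean of the ratios themselves — so a single study
reduces exactly to $F(g\mid\text{cases}) / F(g\mid\text{controls})$, and
the algebraic identity $\sum_g F(g \mid \text{controls}) \, LR(g) = 1$
holds for any single study. Only SNPs with at least one study at
$P < 10^{-6}$ in the declared ancestry are used, and within each
haplotype block (SNPs connected at $r^2 \ge 0.8$) only the most
significant SNP is kept.

**Post-test probability.** With sex-specific baseline prevalence $p$,
the subject's per-disease risk is

$$\text{post-test odds} \;=\; \frac{p}{1-p} \prod_{i=1}^{n} LR(i),
\qquad
\text{post-test probability} \;=\; \frac{\text{odds}}{1+\text{odds}}$$

over the $n$ SNPs with a called genotype; missing genotypes contribute
the neutral $LR = 1$ (the multiplicative identity) and are counted
separately. This product form is a naive-Bayes approximation: it is
exact when genotypes are independent within cases and within controls,
which the simulator enforces and real, LD-pruned panels approximate.

**Clinical z-scores and bins.** Each trait is summarised per subject as
the mean of the first three visits (fewer if fewer exist); the cohort
reference is the mean and SD (n−1 denominator) of these per-subject
means. Traits whose high values are protective are entered as their
additive inverse. The five risk levels cut the adjusted z-score at one
and two SD units: $z < -2$ very low, $[-2,-1)$ low, $[-1,1]$
intermediate, $(1,2]$ high, $> 2$ very high. Domain scores are the
unweighted mean of the domain's adjusted z-scores, binned the same way.

**Conditioning the baseline.** Two routes adjust a disease's baseline
by clinical status, leaving the genotypic LRs untouched:

* *Probability-scale Bayes update* (`conditionFrs`): with a clinical LR
  such as the subject's Framingham score over the cohort mean,
  $p' = pLR / (1 + p(LR - 1))$ — identical to odds multiplication and
  guaranteed to stay inside $(0,1)$.
* *Heritability-scaled multiplier* (`conditionHeritability`): for
  traits that are essentially the disease's endophenotype, the
  clinical contribution is scaled by trait heritability,
  $p' = p \cdot 2h^2 \cdot LR$ — with $h^2 = 0.5$ (obesity) the
  multiplier is the LR itself; with $h^2 = 0.3$
  (hypertriglyceridemia), 60% of it. This is a literal probability
  multiplication, not an odds update; it is statistically non-standard,
  can exceed 1 (we clip at $1 - 10^{-9}$ with a warning), and is
  provided as stated because the alternative — multiplying odds — is a
  different method, not a fix.

**Concordance.** The genotypic direction (combined LR against 1, with a
neutral zone $[0.95, 1.05]$) is compared with the clinical direction
(category against intermediate): same side is concordant, opposite
discordant, either side neutral indeterminate. The gridiron applies the
same rule with the genetic side expressed as a percentile category.

## Turning z-scores into clinical LRs

How an LR "for individuals with the same clinical z-score" should be
derived is genuinely open, so both defensible readings are implemented
and neither has a silent default:

* a *Gaussian-shift model*: if affected subjects' z-scores are
  $N(\delta, 1)$ and unaffected $N(0, 1)$, the density ratio is
  $LR(z) = e^{\delta z - \delta^2/2}$. Its expectation over unaffected
  subjects is exactly 1, so conditioning is calibrated in the null
  population. $\delta$ must be supplied; there is no defensible
  universal value (the end-to-end pipeline uses $\delta = 0.5$, a
  moderate separation of about half an SD, as its demonstration
  setting).
* an *empirical-bin model*: a table of half-open z-intervals with LRs
  estimated from a labelled cohort.

## Genetic percentile categories

The five-level genetic category cuts the empirical percentile of the
subject's score within the cohort at 2.5 / 16 / 84 / 97.5 — chosen to
mirror the clinical ±1/±2 SD bins, so that under a normal score
distribution the two scales would occupy the five levels identically.
A cohort of at least 20 scores is required; a degenerate (zero-variance)
distribution yields "intermediate" with a warning.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
any external data; its defaults describe the study conditions the
analysis is meant for.

**Genetics.** Each disease gets independent SNPs with risk-allele
frequencies spread over 0.1–0.5 and per-allele OR 1.2 (typical
genome-wide-significant common-variant effects); each SNP is observed in
3 case-control studies of 2,000–10,000 samples. For a SNP with allele
frequency $p$ the population genotype distribution is Hardy–Weinberg;
disease follows a logistic model on dosage whose intercept is calibrated
by root-finding so the marginal prevalence is exact, and case/control
genotype triples follow by Bayes inversion (`expectedGenotypeFreqs`).
Study counts are multinomial draws from those triples, and the attached
P-value is a chi-square test on the simulated 2×3 table, so the
curation filter acts on real sampling noise.

**Cohort sampling.** Subjects are drawn by sampling case status first
(Bernoulli at the configured prevalence) and then genotypes
conditionally on status from the same calibrated triples. This
retrospective factorization is algebraically a logistic model on
dosages — the joint case log-odds is
$\mathrm{logit}(K) + \sum_j \log(F_{c,j}(g_j)/F_{n,j}(g_j))$, linear in
each dosage with slope $\log OR_j$ — but it makes the per-allele OR and
the prevalence exact rather than approximate, keeps genotypes
conditionally independent given status (so the naive-Bayes scoring model
is exactly correct on simulated data), and leaves controls
Hardy–Weinberg to within sampling noise. The stored "true liability" is
the log-odds of disease given the full genotype vector.

**Clinical traits.** Each trait's subject-level mean is
$\rho \, \tilde\eta + \sqrt{1-\rho^2}\, \varepsilon$ with $\tilde\eta$
the standardized liability of its linked disease and
$\varepsilon \sim N(0,1)$, achieving correlation $\rho$ at the subject
level; visits add independent $N(0, \sigma_v^2)$ noise around the mean
(default $\sigma_v = 0.3$ SD units, 4 visits), which attenuates the
*visit-averaged* correlation by $1/\sqrt{1 + \sigma_v^2/m}$ for $m$
averaged visits (≈ 1% at the defaults). There is no time trend: visit
dynamics in real wellness cohorts are presentation, not part of this
model. Traits are generated on the z scale (mean 0, SD 1); no attempt is
made to match any real cohort's trait ranges or covariance, so passing
tests demonstrate the statistical machinery, not realism of any
particular clinical panel.

**Defaults as study conditions.** Five inter-related prevalent
conditions (CAD, type 2 diabetes, hypertension, obesity,
hypertriglyceridemia) with plausible sex-specific lifetime risks
(0.2–0.6); 9 SNPs per disease (a realistic per-disease count for curated
GWAS panels); a 11-trait clinical panel covering all eight wellness
domains, with heritabilities 0.50 (BMI/obesity) and 0.30
(triglycerides/hypertriglyceridemia) wired to the heritability-scaled
conditioning route.

## Numerical and degenerate-input choices

* **Zero genotype frequencies** in a study receive a Haldane-style
  correction: 0.5 is added to the affected genotype's implied count in
  *both* groups and the triples are renormalized. This keeps the log-LR
  finite without discarding the study; it is applied per study, before
  weighting, and logged.
* **Bin boundaries** are frozen as $[-2,-1)$, $[-1,1]$, $(1,2]$: each
  real z lands in exactly one bin, and ±1/±2 themselves go to the less
  extreme bin.
* **Pruning ties** (equal best P within a block) break by
  (chrom, pos, snp_id), making curation order-independent; block
  membership uses connected components (transitive closure) of the
  $r^2 \ge 0.8$ graph, since a haplotype block is a block, not a list of
  pairs. LD is never computed from genotypes — callers supply either a
  block assignment or a pairwise $r^2$ table.
* **Strand-ambiguous SNPs** (A/T, C/G) are excluded from genotype
  matching by default: an undetected strand flip would silently invert
  an LR.
* **Ancestry matching** is exact string equality, and the
  genome-wide-significant study itself must carry the matching label.
  $S(i)$ is the total study size (cases + controls).
* **Concordance neutral zones** (LR in $[0.95, 1.05]$; the intermediate
  category) are package-defined conventions for what is visually judged
  in practice.
* **Framingham scores are inputs.** The package never computes them
  (`computeFRS` refuses); they come from the published equations or a
  calculator, entering only as a subject/cohort score ratio.

## Problem sizes used by the test suite

The suite validates the calibration identity on a simulated population
of 20,000 subjects × 10 SNPs; case-control separation over 20 seeded
cohorts of 5,000 subjects × 20 SNPs at OR 1.5; Hardy–Weinberg and
prevalence convergence over 50 seeded cohorts of 5,000; bin occupancy
on 50,000 standard-normal z-scores; and exact-posterior equivalence by
enumerating all $3^5$ genotype vectors of a 5-SNP panel. These sizes
give Monte-Carlo standard errors small enough that each check is sharp
(3 SE bounds throughout) while the whole suite runs in seconds.

## Known limitations

* The multiplicative combination assumes independent, LD-pruned SNPs
  and no epistatic or genotype×environment terms; combined LRs from
  many SNPs can drift when residual LD or confounding violates this.
* The heritability-scaled route multiplies a probability and must clip;
  treat its output as a display-scale adjustment, not a calibrated
  probability.
* Percentile-based genetic categories are relative to the analysed
  cohort, not to any external reference population.
* The simulator draws independent SNPs (blocks are assigned, not
  simulated), Gaussian traits on the z scale, and no visit trends;
  conclusions about real cohorts require real data.
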