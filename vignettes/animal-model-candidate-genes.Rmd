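---
title: "Candidate-gene association with the pedigree animal model"
author: "milkQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene association with the pedigree animal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkQTL)
```

## The problem

Candidate-gene studies in dairy cattle ask whether the alleles of a handful
of SNPs in or around a gene are associated with quantitative production
traits — here the five classical 305-day milk traits (milk, fat and protein
yield in kg; fat and protein percentage). The study design is the paternal
half-sib family: roughly a thousand cows, daughters of on the order of a
hundred sires, recorded under routine DHI performance testing across herds
and years. Ignoring that family structure inflates association test
statistics badly, because daughters of the same sire share a quarter of
their additive genetic variation. The standard remedy is the **animal
model**: a linear mixed model whose random effect has covariance
proportional to the pedigree relationship matrix.

`milkQTL` implements the full analysis stack for this design:

1. the numerator relationship matrix **A** from a pedigree (tabular
   method),
2. the animal model fitted by solving Henderson's mixed-model equations
   with *supplied* variance components,
3. least-squares means per genotype or haplotype-combination class, an
   overall Wald F test, and Bonferroni-adjusted pairwise comparisons
   rendered as compact-letter displays,
4. decomposition of genotype means into additive (a), dominance (d) and
   allele-substitution (α) effects,
5. the haplotype stage: EM haplotype-frequency estimation from unphased
   genotypes, Lewontin D′ with likelihood confidence intervals,
   Gabriel-style block detection, and per-cow diplotype assignment,
6. allele-dependent transcription-factor binding-site (TFBS) scanning with
   position weight matrices, and
7. a synthetic-study generator that emulates the design with full ground
   truth, used throughout the test suite.

## The model

For one trait and one lactation the observation model is

$$ y = \mu + HYS + b\,M + G + a + e,\qquad
   a \sim N(0, \mathbf{A}\sigma_a^2),\quad e \sim N(0, \mathbf{I}\sigma_e^2), $$

where $HYS$ is the herd–year–season cross-classification (fixed), $M$ the
cow's month age at calving (covariate, months), $G$ the genotype or
haplotype-combination class (fixed factor), and $a$ the additive genetic
effect of each animal. Lactations are analysed separately; a cow's second
lactation reuses her breeding value with an independent residual, so no
permanent-environment effect is fitted.

Solutions come from Henderson's mixed-model equations

$$ \begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + \lambda \mathbf{A}^{-1}
   \end{pmatrix} \begin{pmatrix}\hat\beta\\ \hat a\end{pmatrix}
 = \begin{pmatrix}X'y\\ Z'y\end{pmatrix},\qquad
 \lambda = \sigma_e^2/\sigma_a^2 . $$

The variance components are **inputs**, not estimates: in routine practice
they come from a large national evaluation, and a candidate-gene sample of
~1200 cows adds nothing to their precision. (An EM-REML refinement was
considered and deliberately left out: with components fixed, every
downstream standard error has a closed form through the inverse coefficient
matrix, and results stay exactly reproducible across runs.) With
$\sigma_a^2 = 0$ the model degrades gracefully to ordinary least squares on
the fixed design.

Implementation notes:

* **A and A⁻¹ are dense.** At ~1200 cows plus ancestors (a few thousand
  individuals) dense algebra is trivially fast and much easier to verify
  than Henderson's sparse A-inverse rules; the tabular construction carries
  inbreeding exactly on the diagonal ($a_{ii} = 1 + F_i$).
* **Absorption.** `mmeDesign()` factorises
  $M_\lambda = Z'Z + \lambda A^{-1}$ once (Cholesky) and absorbs the random
  equations into a small fixed-effect system
  $S = X'X - X'Z M_\lambda^{-1} Z'X$, whose inverse is exactly the fixed
  block of $C^{-1}$. The factor is reusable across responses and genotype
  factors, which makes the simulation studies in the test suite cheap.
* **Least-squares means** weight HYS cells equally and evaluate $M$ at its
  sample mean; SEs come from the corresponding quadratic form in
  $C^{-1}\sigma_e^2$. HYS cells below 3 records (configurable) are pooled,
  since near-empty cells make the design ill-conditioned.
* **Tests and df.** The overall genotype test is a Wald F with numerator
  df = classes − 1 and denominator df = $N - \mathrm{rank}(X)$ (residual
  method). With variance components known, the statistic is exactly
  $\chi^2_q/q$ under normality, so the finite-denominator F is marginally
  conservative — the type-I simulation below confirms ~0.04–0.05 at
  nominal 0.05. Containment or Kenward–Roger df are out of scope.
* **Multiple comparisons.** Bonferroni within one SNP × trait × lactation
  cell (3 comparisons for 3 genotype classes), matching the superscript
  convention of dairy association tables; the overall p value is reported
  unadjusted. The compact-letter display uses the insert-and-absorb
  algorithm and is invariant to class labelling and pair order.
* Genotype classes with a single cow are retained (published tables keep
  classes like TT with n = 1) but mentioned in a message; their LSMs have
  honest, large SEs.

## Genetic effects

From the class least-squares means $\overline{AA}, \overline{AB},
\overline{BB}$ and the sample frequency $p$ of allele A:

$$ a = \tfrac{\overline{AA}-\overline{BB}}{2},\qquad
   d = \overline{AB} - \tfrac{\overline{AA}+\overline{BB}}{2},\qquad
   \alpha = a + d\,(q - p). $$

Standard errors use the delta method on the LSM covariance (the three
effects are linear in the LSMs; $p$ is treated as fixed). Allele
frequencies are taken from the analysed sample, not an external panel.

```{r effects}
computeEffects(311.33, 304.66, 301.73, p = 0.27)[, 1:3]
```

## The haplotype stage

Phase is estimated by EM over multilocus genotypes under Hardy–Weinberg
pairing, complete-case per block (the behaviour of the standard interactive
tool for this analysis). Initialisation is the linkage-equilibrium product
of allele frequencies — this avoids the symmetric saddle point except for
exactly symmetric data, where the saddle is the correct fixed point.
Convergence is declared at a log-likelihood change below 1e-6 (1000
iteration cap), and monotonicity of the log-likelihood is asserted at every
iteration.

Pairwise D′ uses the two-SNP EM frequencies; its confidence interval is
computed from the likelihood of the observed 3×3 genotype table on a grid
of D′ ∈ [0, 1] (step 0.001) with allele frequencies fixed, taking the
one-sided 5% points. Blocks follow the Gabriel confidence-interval rule at
the conventional defaults (strong LD: CI ≥ 0.70/0.98; strong recombination:
upper < 0.90; ≥ 95% of informative pairs in strong LD), with maximal
non-overlapping spans returned in map order. Within a block, haplotypes
with frequency > 0.05 are retained — rarer ones are pooled as "rare" — and
each cow receives her maximum-a-posteriori haplotype pair, with exact ties
broken lexicographically and flagged.

## TFBS scanning

Promoter SNPs can create or destroy transcription-factor binding sites.
`scanAlleles()` scores every window overlapping the SNP on both strands
against position frequency matrices (JASPAR flat format), after log-odds
conversion with a total pseudocount of 0.8 split by the background
(uniform by default — a common convention in JASPAR-compatible tooling).
Scores are min–max normalised so the consensus scores exactly 1; a site is
called at relative score ≥ 0.90, and sites present for exactly one allele
are reported as gained or lost. Numeric scores depend on the exact matrix
release used, so the package validates the *direction* of allele effects
with bundled synthetic matrices (filenames marked `_synthetic`), not
published score values.

## The synthetic study generator

`simConfig()`/`simulateStudy()` emulate the target design and keep the
ground truth:

* **Pedigree**: 110 sire families, 5–80 daughters each. Only the range and
  mean (11) of the family-size distribution are specified by the design,
  so daughters are drawn as 5 + a geometric variable with mean 6 truncated
  at 80 — right-skewed family sizes are what sire usage in commercial herds
  actually produces. Each daughter has a distinct founder dam; sires carry
  founder parents, giving the three traced generations.
* **Genotypes**: founders draw two haplotypes i.i.d. from a configured
  pool; descendants inherit whole haplotypes (no recombination — the
  candidate regions span a few kb where observed D′ is 0.98–1.00). The
  default pool is the 8-SNP/5-haplotype block at frequencies
  0.42/0.23/0.16/0.13/0.06; `irf6Pool()` provides a two-block layout with
  a freely recombining SNP between.
* **Phenotypes**: generated from the animal model itself, with
  $u = L z \sigma_a$ ($L$ the Cholesky factor of A), i.i.d. normal HYS
  effects, a uniform 22–40 month calving age, and per-SNP genotype
  contributions +a/d/−a. Default trait parameters are dairy-realistic
  (e.g. fat yield: mean 300 kg, phenotypic SD 40 kg, heritability 0.3;
  percentages at heritability 0.5); the worked effect sizes are a = 4.8 kg
  and d = −1.9 kg of fat at SNP 1. About 95% of cows get a
  first-lactation record and 55% of those a second (the second-lactation
  cows are a subset of the first — the design leaves this unstated, and a
  subset is the conservative reading).
* **Seeds**: one master seed; each stage derives a child seed
  deterministically, so a study is byte-reproducible from one integer.

What the generator does *not* emulate: genotyping error, missing
pedigree links, selection, heterogeneous variances across herds, and
genuine recombination within blocks. Passing tests therefore demonstrate
the correctness of the estimators under the stated model, not robustness
to those real-data pathologies.

## Worked example

```{r example}
cfg <- simConfig(nSires = 30, seed = 7)
study <- simulateStudy(cfg)
A <- buildA(study$pedigree)
cows <- unique(study$phenotypes$cow_id)
classes <- genotypeClasses(study$genotypes, 1, cows)
fit <- fitAnimalModel(study$phenotypes, classes, A,
                      vc = list(sigmaA2 = 480, sigmaE2 = 1120),
                      trait = "fat_kg", lactation = 1)
lsMeans(fit)
testGenotypeEffect(fit)
geneticEffects(fit, c("TT", "CT", "CC"))[, c("a", "d", "alpha")]
```

```{r blocks}
g <- GenotypeMatrix(genotypes(study$genotypes)[cows, ],
                    snpInfo(study$genotypes))
blocks <- detectBlocks(g)
blocks[[1]]
head(assignDiplotypes(g, blocks[[1]]))
```

## Numerical choices and limitations

* EM tolerance 1e-6 on the log-likelihood; D′ CI grid step 0.001; MAP
  diplotype ties broken lexicographically and flagged; rounding of
  reported frequencies is half-away-from-zero (the convention of printed
  tables), full precision internally.
* Problem sizes in the test suite were chosen to give tight Monte Carlo
  bands at interactive runtimes: gene-dropping validation of A uses 1e5
  replicates on 100-member pedigrees; the type-I simulation uses 1000
  null replicates on the full 110-sire cohort (one cohort, responses
  re-drawn — the standard conditional design); parameter recovery uses
  200 re-drawn genetic samples on one cohort; block-detection stability
  uses 40 independent cohorts per LD layout.
* Joint phasing is limited to ≤ 14 SNPs (enumerable haplotype space) —
  ample for candidate-gene blocks, not for chromosome-scale work.
* The fixed-effect design must be full rank after reference coding; a
  genotype confounded with HYS is reported as an error naming the aliased
  columns rather than silently dropped.
* Traits are simulated with independent genetic effects; multi-trait
  models and genomic (marker-based) relationship matrices are out of
  scope, as are r², four-gamete or solid-spine block rules.
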