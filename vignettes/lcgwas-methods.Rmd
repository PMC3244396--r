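---
title: "Latent-class subtyping and class-membership GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class subtyping and class-membership GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcgwas)
```

## The problem

Psychiatric case samples are heterogeneous: patients sharing an index
diagnosis (here, bipolar disorder) differ widely in their lifetime comorbid
conditions — substance abuse, alcohol dependence, panic disorder, psychotic
symptoms, and so on. If that phenotypic heterogeneity reflects genetic
heterogeneity, association signals specific to a subgroup are diluted or
lost when all cases are pooled against controls. `lcgwas` implements a
two-stage remedy:

1. **Latent class analysis (LCA)** partitions cases into unobserved classes
   based on a vector of binary comorbidity indicators.
2. **Genome-wide association** then uses each case's *membership
   probability* in a given class — rather than the crude case/control
   label — as a quantitative phenotype, tested against SNP genotypes under
   dominant, additive and recessive encodings.

A synthetic-cohort generator reproduces the relevant structure of a real
case/control sample (indicator tables for cases only, genotypes for
everyone, planted class-specific variants), so the whole pipeline is
testable without access-restricted genotype data.

## Stage 1: the latent class model

### Likelihood

For case $i$ with binary indicators $u_{i1}, \dots, u_{iJ}$ and $K$ latent
classes with mixing proportions $\pi_k$ and class-conditional endorsement
probabilities $\rho_{kj} = P(u_j = 1 \mid c = k)$, the items are assumed
conditionally independent given the class:

$$
L_i = \sum_{k=1}^{K} \pi_k \prod_{j \in \mathrm{obs}(i)}
\rho_{kj}^{\,u_{ij}} (1 - \rho_{kj})^{1 - u_{ij}} .
$$

Missing cells are simply skipped (the product runs over observed items
only), which is maximum likelihood under missing-at-random; no case is
dropped for partial data. A case must have at least one observed item to
enter a fit; posteriors for a fully missing record equal the prior $\pi$.

### Estimation

`lca_fit()` maximizes the log-likelihood by EM:

* **E-step**: posterior membership by Bayes rule.
* **M-step**: $\pi_k$ is the mean posterior; $\rho_{kj}$ is the
  posterior-weighted mean of item $j$, with missing cells excluded
  item-wise.

Because the likelihood surface is multimodal, the fit is repeated from
`n_starts` random starting values ($\rho \sim U(0.1, 0.9)$ element-wise,
$\pi$ uniform on the simplex) and the run with the highest final
log-likelihood wins. The default is 50 starts, which is ample for the
10-item problems the package targets; for a final analysis 1000 starts is
the conventional safeguard and costs only minutes. Convergence is declared
when the absolute log-likelihood gain falls below `tol = 1e-8`
(at most 1000 iterations); the log-likelihood is non-decreasing across
iterations by construction, and the test suite asserts this on every run.

Two numerical guards matter:

* **Boundary estimates.** During EM, $\rho$ is confined to
  $[10^{-6}, 1 - 10^{-6}]$ so that a class that perfectly predicts an item
  cannot zero out the likelihood mid-fit. If the unconstrained M-step lands
  exactly on 0 or 1 (an item never/always endorsed given the soft
  assignment), the reported estimate is exactly 0 or 1 — class profiles
  with structural zeros print as such.
* **Label switching.** Mixture classes are only identified up to
  permutation. Classes are canonicalized by descending endorsement of an
  *anchor item* (default `ALCDEP`, the alcohol-dependence indicator,
  which cleanly separates the canonical three-class comorbidity solution),
  falling back to descending $\pi$. This keeps class identities stable
  across starts, seeds and replicates, which every downstream table relies
  on.

### Model selection and separation

`lca_select()` fits $K = 1, \dots, K_{\max}$ and picks the smallest BIC,
$\mathrm{BIC} = -2\ell + p \ln n$ with $p = (K-1) + KJ$ free parameters.
Class separation is summarized by the relative entropy

$$
E = 1 - \frac{\sum_i \sum_k -p_{ik} \ln p_{ik}}{n \ln K} \in [0, 1],
$$

where 1 means crisp assignment. The canonical three-class comorbidity
solution this package's simulations emulate has $E \approx 0.69$ — "fair"
separation, meaning modal class assignments carry real uncertainty, which
is exactly why the membership *probability* (not the modal label) is the
default GWAS phenotype.

### Auxiliary variables

Covariates such as age and sex are deliberately kept out of the likelihood
(the class solution should be driven by the indicators alone).
`wald_auxiliary_test()` instead uses pseudo-class draws: for each of $D$
draws (default 20) a class is sampled for every case from its posterior
row, class means and their sampling variances are computed, and estimates
are pooled across draws with multiple-imputation-style variance — the
within-draw variance plus $(1 + 1/D)$ times the between-draw variance of
the means. The Wald statistic for equality of the $K$ pooled means is
referred to $\chi^2_{K-1}$; a `classes` argument restricts the comparison
to a pair while still drawing from the full posterior.

### Class-profile odds ratios

`profile_odds_ratios()` contrasts two class profiles item by item:
$\mathrm{OR}_j = \frac{\rho_{kj}/(1-\rho_{kj})}{\rho_{lj}/(1-\rho_{lj})}$.
An item at a structural boundary (endorsement exactly 0 or 1 in either
class) has undefined odds and is reported `NA`. Standard errors use the
delta method on the log odds ratio, with
$\mathrm{var}(\mathrm{logit}\,\hat\rho_{kj}) \approx
1 / (n^{\mathrm{eff}}_{kj}\, \hat\rho_{kj} (1 - \hat\rho_{kj}))$ and
$n^{\mathrm{eff}}_{kj}$ the posterior-weighted count of cases observed on
item $j$. This is the complete-data (EM) information; it ignores the
missing-information correction for class uncertainty and therefore
slightly understates the SEs. Point estimates are unaffected, and the SEs
are not used by any downstream decision.

## Stage 2: genome-wide association

### Phenotype definition

`membership_phenotype()` assigns each case its posterior probability of
belonging to the target class and fixes every control at 0 (controls have
no indicator data, hence no membership). One association scan is run per
latent class; with a 1-class fit the phenotype degenerates to the ordinary
case/control 0/1 contrast. Under this convention the mean phenotype among
major-allele homozygotes at any SNP is approximately
(cases/total) × (mean class probability), which is what per-genotype
summary tables show for the unexposed background. A modal 0/1 indicator
phenotype is available as an alternative definition.

### The correlation trend test

For each SNP the genotype is encoded under a genetic model — additive
(dosage 0/1/2), dominant (any minor allele) or recessive (minor-allele
homozygote) — and correlated with the phenotype over complete pairs
(pairwise deletion per SNP). The statistic $T = n r^2$ is referred to
$\chi^2_1$; this is the natural generalization of the Armitage trend test
to a quantitative phenotype. A SNP whose encoding is constant on the
analyzed individuals — for example zero minor-allele homozygotes under the
recessive model — is *not testable*: it is flagged and excluded from the
multiplicity count rather than given a meaningless p-value.

### Stratification correction

Population structure confounds association when both allele frequency and
phenotype differ between subpopulations. `pca_components()` implements the
EIGENSTRAT construction: each SNP is centered at $2\hat p$ and scaled by
$\sqrt{2 \hat p (1 - \hat p)}$, missing entries contribute 0 after
centering, monomorphic SNPs are skipped with a log entry, and the leading
eigenvectors of the individual-by-individual covariance are the scores.
`stratification_adjust()` residualizes *both* the encoded genotype and the
phenotype on the scores (least squares with intercept) and uses
$T = (n - K_{pc} - 1) r^2_{\mathrm{resid}}$. The default is 10 components,
the EIGENSTRAT convention; with a *known* simulated two-population
structure, 2 components suffice and avoid the slight deflation that
regressing on extra noise axes causes in small samples. Calibration is
monitored with the genomic inflation factor $\lambda$ (median observed
$\chi^2_1$ over its null median); $\lambda$ is itself a noisy estimate at
a few thousand SNPs, so calibration claims should average it over
replicates.

### Multiplicity

Bonferroni correction multiplies each p-value by the number of *testable*
SNPs for that genetic model — not by three times that number. The
per-model convention is deliberate: it matches how published genome-wide
tables in this design report corrected p-values (corrected p = raw p ×
SNP count to the printed precision), and the choice is surfaced in the
output (`n_tests` per model) rather than hidden. SNPs passing the
Bonferroni screen at level `alpha` are retested by permutation: the
phenotype vector is permuted as a whole (case/control labels travel with
it, since they are encoded in the phenotype), genotypes stay fixed, and
$p = (1 + \#\{T_{\mathrm{perm}} \ge T_{\mathrm{obs}}\}) / (B + 1)$, whose
floor at $B = 1000$ is $1/1001 \approx 0.001$. An exact Hardy–Weinberg
test (full enumeration of heterozygote configurations given the allele
counts) is available as an optional post-hoc filter; it is off by default
because in the emulated design such filtering belongs to genotype calling,
which is out of scope here.

## The synthetic cohort generator

`cohort_spec()` defaults encode the study conditions the package's
simulations emulate — a bipolar case/control sample with:

* 1000 cases, 1034 controls;
* three latent classes at proportions 26/25/49%: a substance-abuse /
  psychosis class, an alcohol-dependence class (endorsement of alcohol
  dependence fixed at 1), and a low-comorbidity class, over ten indicators
  (`r paste(colnames(default_endorsement_probs()), collapse = ", ")`);
* class ages of mean 41/41/44 years (SD 12.6/10.8/13.8), truncated at 17
  (the youngest case age in the emulated design — ages below that are
  impossible), female proportions 62/39/49%; controls form a single
  stratum (mean 52, SD 17.6, 48.6% female, truncated at 18), since
  nothing in the emulated design ties control covariates to anything;
* age missing at rate 0.008 (about 8 cases in 1000); indicators complete
  by default;
* no indicator rows for controls — matching designs where symptom-level
  interviews exist only for cases.

Genetic effects are planted *mechanically*, not through a penetrance
model: after a null Hardy–Weinberg draw, `n_forced_carriers` randomly
chosen members of the effect class are overwritten with the risk genotype
(homozygous minor for recessive and additive effects, heterozygous for
dominant), and any stray minor-allele homozygotes elsewhere are demoted to
heterozygotes for recessive/additive plants. This reproduces exactly the
observed pattern that motivates the method — risk homozygotes confined to
one latent class — and keeps the truth auditable: forced-carrier counts
are exact, never stochastic, and are never masked by simulated missingness.

Optional two-population structure uses the Balding–Nichols model:
subpopulation allele frequencies are drawn from
$\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ around the ancestral MAF $p$ at
divergence $F$ (`fst`). Subpopulation assignment is independent of case
status by default, so the uncorrected test stays calibrated; a
`case_pop2_prob` knob different from `pop2_prob` induces confounding for
testing the correction. `estimate_fst()` provides a sampling-corrected
moment estimator to verify the realized divergence.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (every SNP is drawn independently), haplotype structure, genotyping
batch effects or intensity-level artifacts, sex chromosomes, and any
dependence of control covariates on genotype. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model — not robustness to LD-induced clumping of hits or to
calling artifacts in real array data.

## Design choices on genuinely open points

* **Phenotype**: membership *probability* with controls at 0 is the
  default; the modal-indicator alternative is offered because the two
  readings coexist in this design's literature. The probability version is
  what reproduces the observed per-genotype background means.
* **Which items count as comorbidity burden**: whether psychotic symptoms
  are a comorbid diagnosis or part of the index phenotype is a judgment
  call; `comorbidity_burden()` therefore takes an explicit `burden_items`
  argument instead of hard-coding the answer.
* **All classes are scanned**, including the low-comorbidity class; a
  null result there is informative and costs little.
* **Tie-breaks**: modal assignment resolves posterior ties toward the
  lowest class index; minor-allele orientation leaves frequency-0.5 SNPs
  unflipped; the ped reader breaks allele-frequency ties alphabetically
  (the writer emits alleles so that this round-trips exactly).
* **Determinism**: a single integer seed fixes every stage; derived
  sub-seeds separate the simulation, LCA and association streams so that
  changing, say, `B` does not perturb the cohort. Two runs from the same
  config produce byte-identical report tables (asserted in the tests).

## Problem sizes used by the tests

The test suite and acceptance script are sized for a single CPU: LCA
recovery and entropy checks run 1000-case cohorts with 50 EM starts
(averaged over 5–10 seeds); BIC selection uses 10 replicates at 30 starts;
calibration and stratification properties use panels of 1500–4000
simulated SNPs with 400–800 individuals; the end-to-end planted-effect
scan uses 500 null SNPs at 500+500 individuals. These sizes were chosen
so the statistical assertions have adequate power while a full run stays
in the minutes range; all of them are parameters, and scale up directly.

## Known limitations

* Binary indicators only; ordered-categorical and count items are not
  implemented.
* Profile-OR standard errors use complete-data information (see above).
* The latent class model is fit on cases only; joint case/control mixture
  modeling is out of scope.
* No mixed-model association, imputation or LD-aware methods; the package
  tests one SNP at a time.
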