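---
title: "Mixed-stock analysis of ancient-DNA SNP genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-stock analysis of ancient-DNA SNP genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ancientmix)
```

## The problem

Archaeological fish bones can be genotyped at a handful of single-nucleotide
polymorphisms (SNPs) chosen because their allele frequencies differ sharply
among contemporary spawning populations. Given a *baseline* of modern
reference fish of known origin and a *mixture* of ancient bones of unknown
origin, genetic stock identification (GSI) estimates what fraction of the
ancient catch came from each reference population — here, Pacific herring
spawning groups with different reproductive timing (January–February,
March–April and May spawners). Because a 7-locus panel cannot reliably
separate every individual spawning aggregation, collections are aggregated
into *reporting groups* (the spawn-timing groups), and inference is reported
at that level.

`ancientmix` implements the full workflow around that estimate: genotype
input/output and validation, ancient-DNA quality control, the standard
population-genetic summaries used to sanity-check the data (heterozygosity,
F~IS~, pairwise F~ST~, Hardy–Weinberg and linkage-disequilibrium exact
tests, PCA), the Bayesian mixture model itself, and two ways of assessing
how accurate assignment can be expected to be.

## The mixture model

Let $k = 1,\dots,K$ index reference collections with reporting-group
membership $g(k)$, and let $x_{kla}$ be the observed count of allele $a$ at
locus $l$ in collection $k$. The model is *conditional*: baseline counts are
held fixed while the mixture is analyzed, and each collection's allele
frequencies enter through their posterior-predictive point values under a
per-allele Dirichlet prior with mass $\lambda$:

$$\hat p_{kla} = \frac{x_{kla} + \lambda}{\sum_a x_{kla} + 2\lambda},
\qquad \lambda = \tfrac12 .$$

$\lambda = 1/(\text{number of alleles})$ is the unit-information convention
for a biallelic locus. A mixture individual $i$ with multilocus genotype
$y_i$ has likelihood
$L_{ik} = \prod_{l \in \text{called}(i)} P(y_{il} \mid \hat p_{kl})$ under
Hardy–Weinberg proportions within collections (homozygote $\hat p^2$,
heterozygote $2\hat p_1 \hat p_2$); missing loci contribute a factor of 1,
so a fully missing genotype is uninformative rather than an error.

With mixing proportions $\pi$ over collections, latent origins $Z_i$, and a
Dirichlet prior $\pi \sim \mathrm{Dir}(\zeta)$, the Gibbs sampler iterates

1. $P(Z_i = k \mid \pi) \propto \pi_k L_{ik}$ for every mixture individual,
2. $\pi \mid Z \sim \mathrm{Dir}(\zeta + \mathrm{counts}(Z))$,

retaining all post-burn-in draws (no thinning; defaults 10,000 sweeps with
1,000 burn-in). Reporting-group proportions are deterministic aggregates of
the same draws, $\rho_g = \sum_{k: g(k)=g} \pi_k$, summarized as posterior
means with equal-tailed 95% credible intervals. Each archaeological
site/layer is always analyzed as a separate mixture, never pooled.

Defaults that the underlying study does not pin down are labeled in the
fitted object's `config`: the prior mass is symmetric $\zeta_k = 1/K$ (total
mass 1; a reporting-group-balanced alternative is available via
`prior = "group_balanced"`), intervals are equal-tailed quantiles rather
than HPD, and a single chain is run (two seeded chains compared on
$\rho$ means are an easy convergence check; the sampler is reproducible
bitwise under a fixed seed).

## Quality control

Two QC operations mirror ancient-DNA practice with TaqMan-style repeat
genotyping:

* `discrepancy_rate()` compares two genotyping replicates. The headline
  rate divides *samples with at least one mismatch* by *total samples*,
  counting only loci called in both replicates; a per-call rate is emitted
  alongside because the sample-level definition is ambiguous in parts of
  the literature.
* `filter_missing()` drops samples missing more than `max_missing_loci`
  (default 1) genotypes — on a 7-locus panel, a sample must be genotyped at
  6+ loci to survive.

`diversity()` reports observed heterozygosity, unbiased gene diversity
$\tilde H_e = \frac{2n}{2n-1}\left(1 - \sum_a p_a^2\right)$ (the plug-in
estimator is available with `unbiased = FALSE`), and
$F_{IS} = 1 - H_o/H_e$, reported as `NA` where $H_e = 0$ because the ratio
is undefined for a monomorphic cell.

## Population structure statistics

Pairwise F~ST~ is the Weir–Cockerham (1984) estimator: per-locus variance
components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals) are combined across loci as a
ratio of sums, $\hat\theta = \sum a / \sum(a+b+c)$, the WC84
recommendation. For a biallelic locus the two alleles yield identical
components, so summing over alleles rescales numerator and denominator
equally. Negative estimates are reported as computed. Significance uses a
permutation test that shuffles individuals between the two collections with
sizes fixed; $p = (1 + \#\{\theta^* \ge \theta\})/(n_{\text{perm}} + 1)$,
so $p$ can never be exactly 0 at finite permutations. The test suite checks
the estimator against an independent implementation that goes through the
ANOVA sums of squares instead of the closed-form component formulas.

The Hardy–Weinberg test is the biallelic exact test: conditional on the
observed allele counts, every compatible heterozygote count $h$ has
probability
$P(h) = \frac{n!}{n_{11}!\,h!\,n_{22}!} 2^h \frac{n_A!\,n_B!}{(2n)!}$,
and the p-value sums the probabilities of configurations no more probable
than the observed one (standard tail; a mid-p variant is off by default).
The linkage-disequilibrium test is a genotypic contingency-table
independence test evaluated by Monte-Carlo exact test
(`stats::fisher.test`, seeded); the method choice is the package's own, as
the underlying study does not describe one, and it is recorded in the
output metadata. PCA codes genotypes as allele-1 dosage, imputes missing
cells with the per-locus mean dosage (the common default for SNP PCA),
centers columns, and fixes component signs by making each component's
largest-magnitude loading positive.

## Accuracy assessment

`loo_self_assign()` scores every reference individual against the baseline
after removing its own two gene copies per locus from its collection's
counts — without that removal self-assignment is optimistically biased.
Scaled likelihoods with equal collection weights are summed within
reporting groups and the individual is assigned to the argmax group. Fully
missing individuals are tallied as unassignable rather than scored; ties
break toward the first group and are counted.

`simulate_assess()` draws allele frequencies from each collection's
Dirichlet posterior $\mathrm{Dir}(x_{kl} + \lambda)$, simulates
Hardy–Weinberg genotypes (`n` per collection per replicate), optionally
applies per-call dropout, and assigns them the same way. Sampling
frequencies from the posterior rather than reusing point estimates avoids
the optimism of resampling observed genotypes with a small panel.
Accuracies are reported per reporting group (pooled over replicates) and
per replicate, and the mean posterior probability of the true group is
included as an auxiliary column: argmax accuracy and mean posterior answer
different questions, and published "predicted accuracy" figures do not
always say which was computed. That ambiguity matters when comparing
against reported ranges: a panel whose argmax accuracy is in the
mid-nineties can have mean true-group posteriors ten points lower.

## What the synthetic generator emulates — and what it does not

`make_scenario()` encodes a two-site, two-layer archaeological study
design: 8 reference collections in 3 spawn-timing groups totalling 347
fish, 7 biallelic loci, four mixture layers of 48 bones, and per-call
genotype dropout. The preset's group-level allele frequencies were chosen
once so that the synthetic data reproduce the *scale* of the study being
emulated: one near-diagnostic locus (cross-group differential $\ge 0.8$,
modeled on a photoperiod-gene SNP that separates winter from spring
spawners), group-level F~ST~ up to roughly 0.4–0.6, leave-one-out
accuracies in the nineties, and weak within-group differentiation
(collection frequencies jitter around group frequencies with SD 0.03, so
reporting-group assignment is strong while collection-level assignment is
deliberately weak). The dropout rate defaults to the value at which a
Binomial(7, rate) missingness profile leaves 83% of samples with at most
one missing locus (`calibrate_missing_rate()` solves for it; the root is
approximately 0.108 per call).

The mixture presets are qualitative: both sites are dominated by
March–April spawners, January–February spawners are more common at the
Burton Acres analogue than the Bay Street analogue, and May spawners
appear only in the older Burton Acres layer (at 10%).

The generator deliberately omits several features of real ancient-DNA
data: dropout is independent per genotype call (no fragment-length or
damage-pattern model, no allelic dropout producing false homozygotes),
replicate discordance is a uniform per-call replacement process, reference
collections are exactly in Hardy–Weinberg equilibrium, and allele
frequencies are constant through time. Passing tests on this generator
therefore demonstrate the correctness and calibration of the *methods*, not
robustness to contamination, damage-driven genotyping error, or temporal
allele-frequency drift.

## Numerical choices and degenerate inputs

* Genotypes are stored as unordered allele pairs normalized to
  $a_1 \le a_2$; half-called genotypes are rejected at validation.
* Likelihood rows are max-shifted before exponentiation in the sampler, so
  only likelihood ratios matter and underflow cannot zero out a row.
* Monomorphic loci: He = 0 with `Fis = NA`; HWE and LD tests return p = 1;
  PCA errors only when *every* locus is monomorphic.
* F~ST~ skips loci with no called genotypes (or a single genotype) in
  either collection; a collection with fewer than 2 genotyped individuals
  at every locus is an error.
* An all-missing mixture individual has equal likelihood against every
  collection: it contributes nothing to the mixture posterior beyond the
  prior, and the assessment modules count it as unassignable instead of
  letting a tie-break manufacture an assignment.
* All stochastic entry points take a `seed`; given one, results are
  reproducible bitwise (the Gibbs core uses R's RNG).

## Problem sizes used by the test suite

The packaged tests run the full design at its native size (347 reference
fish, 4 × 48-bone layers). Simulation-heavy checks use sizes chosen to keep
the suite quick while leaving Monte-Carlo error well below the tested
effect: credible-interval coverage uses 200 replicate 60/30/10 mixtures of
48 at the default 10,000-sweep sampler; the exact-test size check uses
10,000 null replicates of 40 individuals; simulated-accuracy checks pool at
least 10,000 simulated individuals; and the Gibbs-versus-enumeration check
runs 20,000 retained sweeps on a 2-collection, 3-individual, 2-locus
instance where the posterior is computable by exhaustive enumeration.

## Known limitations

* The conditional model ignores uncertainty in which *baseline* samples
  exist (it propagates allele-frequency uncertainty only through
  $\lambda$-smoothed predictive frequencies held fixed during MCMC); a
  fully Bayesian treatment that updates baseline frequencies from mixture
  individuals is out of scope.
* No bias correction of mixing proportions (parametric-bootstrap style) is
  provided.
* Only biallelic loci are supported, and LD statistics requiring phase
  (D′, r²) are not computed.
* With 7 loci, collection-level proportions within a reporting group are
  only weakly identified; interpret `summary(fit, level = "collection")`
  accordingly.
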