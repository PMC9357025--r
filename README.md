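# ancientmix

Genetic stock identification (GSI) for ancient-DNA samples genotyped at
small panels of biallelic SNPs, with the full population-genetic workflow
around it.

## The problem

Forage fish such as Pacific herring (*Clupea pallasii*) form genetically
distinct populations that spawn at different times of year. Bones from
archaeological middens can be genotyped at a few SNPs whose allele
frequencies separate those spawning groups, and a mixed-stock analysis then
estimates which populations ancient fisheries actually harvested. The
audience is population geneticists and archaeogeneticists who have (a) a
modern *baseline* — reference individuals of known origin, grouped into
collections and aggregated *reporting groups* — and (b) one or more
*mixtures* of individuals of unknown origin (e.g., one archaeological
site/layer each), genotyped at the same loci.

`ancientmix` provides:

* genotype I/O and validation (wide CSV and genepop dialects),
* ancient-DNA QC: replicate-genotyping discrepancy rates and a
  missingness filter (drop samples missing more than one locus),
* diversity statistics (H<sub>o</sub>, unbiased H<sub>e</sub>,
  F<sub>IS</sub>), pairwise Weir–Cockerham F<sub>ST</sub> with permutation
  tests, biallelic Hardy–Weinberg exact tests, genotypic
  linkage-disequilibrium tests, and dosage PCA,
* the Bayesian conditional GSI mixture model, fitted by Gibbs sampling,
* leave-one-out and simulation-based assessment of assignment accuracy,
* a synthetic-data generator reproducing a two-site, two-layer
  archaeological study design with full ground truth, and
* a one-call pipeline (`run_pipeline()`) that chains all stages from a
  config list or YAML file.

## The model

With baseline allele counts `x[k,l,a]` for collection `k`, locus `l`,
allele `a`, and per-allele prior mass λ = 1/2, mixture individuals are
scored against posterior-predictive frequencies
`p̂ = (x + λ) / (Σx + 2λ)` under Hardy–Weinberg proportions; missing loci
contribute nothing. Mixing proportions π over collections get a Dirichlet
prior (mass 1/K per collection by default) and the Gibbs sampler alternates

1. `Z_i ~ Categorical(π_k · L_ik)` — latent origin of each mixture
   individual,
2. `π ~ Dirichlet(ζ + counts(Z))`,

with 10,000 sweeps and 1,000 burn-in by default. Reporting-group
proportions `ρ_g = Σ_{k∈g} π_k` are summarized as posterior means with
equal-tailed 95% credible intervals. F<sub>ST</sub> is the Weir–Cockerham
(1984) θ with loci combined by ratio of sums; the HWE test is the exact
conditional test on heterozygote counts.

## Worked example

Simulate a study-sized dataset (347 reference fish in 8 collections and 3
spawn-timing groups at 7 loci; one archaeological layer of 48 bones with
ancient-DNA dropout), run QC, and estimate the layer's composition:

```r
library(ancientmix)

scn      <- make_scenario(seed = 7)          # ground truth: 25/65/10 mixture
ref      <- sample_reference(scn, seed = 8)
bones    <- sample_mixture(scn, "burton_early", seed = 9)$samples
bones_qc <- filter_missing(bones, max_missing_loci = 1)
attr(bones_qc, "qc")[c("n_in", "n_retained")]
#> $n_in
#> [1] 48
#> $n_retained
#> [1] 40

baseline <- build_baseline(ref)
fit <- infer_mixture(baseline, bones_qc, n_iter = 10000, burn_in = 1000,
                     seed = 10)
summary(fit)
#>     unit  mean     lo    hi
#> 1 JanFeb 0.182 0.0796 0.315
#> 2 MarApr 0.632 0.4764 0.779
#> 3    May 0.185 0.0797 0.322
```

The posterior means recover the simulated truth (0.25 / 0.65 / 0.10):
roughly two-thirds of the layer is March–April spawners, and the 95%
credible intervals cover the true proportions for all three groups. The
panel's expected assignment power and the divergence behind it:

```r
loo_self_assign(ref)
#> gsi_assessment (loo): overall accuracy 0.971
#>   group   n accuracy mean_posterior_true
#>  JanFeb 131    0.985               0.963
#>  MarApr 131    0.939               0.911
#>     May  85    1.000               0.949

wc_fst(ref, c("ref_ma1", "ref_may1"))$theta
#> [1] 0.340413
```

`run_pipeline(list(simulate = list(preset = "herring"), seed = 1),
out_dir = "out")` runs every stage (QC → diversity → F<sub>ST</sub> →
HWE/LD → PCA → GSI per layer → accuracy assessment) and writes per-stage
CSVs plus a machine-readable `summary.json`. A thin command-line wrapper
lives at `inst/cli/ancientmix.R`.

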