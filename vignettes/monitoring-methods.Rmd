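---
title: "Genetic and demographic monitoring: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic and demographic monitoring: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

popgenmon implements the combined genetic and demographic monitoring
workflow used in conservation assessments of small, fragmented vertebrate
populations — the running example throughout is the endangered San
Francisco gartersnake, monitored at seven sites with SNP panels and daily
capture–mark–recapture surveys. This vignette is the package's account of
the science: the models, their assumptions, the tunable parameters, the
numerical choices, and what the validation suite does and does not show.

## The genotype data model

All genetic analyses run on a `geno_matrix`: an individuals × loci matrix
of alternate-allele dosages (0, 1, 2, `NA`) with per-individual site
("population") and sampling-period labels. Inputs arrive via `read_vcf()`
(biallelic diploid records only; multi-allelic records are skipped with a
warning because every estimator here is defined for biallelic SNPs) or the
TSV dialect of `read_genotype_tsv()`, which round-trips bit-exactly and is
the interchange format of the simulators and the pipeline.

Two filters mirror standard RAD-panel practice:

* `filter_by_presence(g, min_fraction = 0.8)` keeps loci genotyped in at
  least 80% of the individuals of *every* population. The per-population
  reading is the default because presence thresholds are intended to
  guarantee information at every site; a pooled mode is available
  (`per_population = FALSE`). The boundary is inclusive and the filter is
  idempotent.
* `screen_maf(g, pcrit = 0.05)` removes loci whose minor-allele frequency
  falls strictly below `pcrit`; a frequency exactly at `pcrit` is retained,
  matching the "exclude alleles with frequency < Pcrit" convention of
  effective-size software. `pcrit = 0.05` is the conventional screen ahead
  of both Ne estimators, balancing bias from rare alleles against
  information loss.

## Diversity statistics

Per population (and period), `diversity_table()` reports the column set of
a standard SNP diversity table:

* `n`: mean number of genotyped individuals per locus.
* `ho`: observed heterozygosity, heterozygotes / genotyped.
* `he`: plug-in expected heterozygosity `1 − p² − q²`.
* `pi`: nucleotide diversity at variant sites, the unbiased
  pairwise-difference estimator `(2n/(2n−1)) (1 − p² − q²)`.
* `ar`: allelic richness rarefied to `g_copies` gene copies by
  hypergeometric rarefaction,
  `Ar = Σ_a [1 − C(2n − n_a, g)/C(2n, g)]`.

Using the plug-in estimator for `he` and the small-sample-corrected
estimator for `pi` is deliberate: it reproduces the `pi ≥ he` ordering that
RAD-pipeline summary tables show, and the pair brackets the true expected
heterozygosity. The rarefaction depth defaults to the smallest number of
non-missing gene copies over all groups ("rarefied by the lowest number of
gene copies per site"), and is exposed as a parameter because site-level
and cluster-level analyses legitimately use different baselines. Loci
entirely missing within a group are excluded from that group's means.

## Differentiation and isolation by distance

`wc_theta()` implements the Weir–Cockerham (1984) variance-component
estimator of F_ST for diploid data: per-locus components `a` (among
populations), `b` (among individuals within populations) and `c` (within
individuals), combined across loci as a ratio of sums
`θ = Σa / Σ(a+b+c)`. Ratio-of-sums is the standard multi-locus combination
for this estimator and is robust to low-information loci; negative
estimates are reported as computed, since truncation would bias averages
and published tables keep the sign. Loci monomorphic across the compared
populations carry no information and are skipped. Sample sizes enter per
locus, so missing genotypes are handled exactly rather than by imputation.

Significance uses a permutation test of individual site labels within a
pair, with the add-one rule `p = (1 + #{θ* ≥ θ}) / (n_perm + 1)`, and a
Bonferroni-corrected α for the number of pairs (`bonferroni_alpha()` takes
the number of tests explicitly rather than inferring it, because published
tables do not always use the obvious divisor).

`mantel_test()` correlates pairwise θ with great-circle distance in km
(haversine on WGS84 decimal degrees), permuting population labels jointly
on rows and columns (1000 permutations by default; the permutation engine
is vegan's). The regression/correlation is on raw θ versus km — not
θ/(1−θ) — matching how such relationships are usually plotted for
conservation audiences.

## Effective population size

### Single-sample LD method

`ld_ne()` estimates contemporary Ne from the linkage disequilibrium among
unlinked SNPs under random mating. For each locus pair the composite
(Burrows) disequilibrium is computed from unphased dosages,

    Δ̂ = S/(S−1) · [ (1/(2S)) Σᵢ xᵢ yᵢ − 2 p̂ q̂ ],   r̂² = Δ̂² / (p̂(1−p̂) q̂(1−q̂)),

with individuals missing at either locus excluded pairwise and each pair's
`r̂²` weighted by its own sample size. The `S/(S−1)` factor is the standard
small-sample correction of the Burrows estimator; it matters because the
downstream bias correction assumes it. The expected sampling contribution
is subtracted at the harmonic-mean sample size,

    E[r²_sample] = 1/S + 3.19/S²                (S ≥ 30)
                 = 0.0018 + 0.907/S + 4.44/S²   (S < 30)

and the drift signal `r̂²_drift = mean r̂² − E[r²_sample]` is inverted with
the matching quadratic solution (`(1/3 + √(1/9 − 2.76 r̂²'))/(2 r̂²')` for
S ≥ 30 and the 0.618/5.24 coefficients below 30). These are the published
random-mating formulas of the LD-Ne software lineage, including the
separate small-sample regime. A non-positive drift signal means the data
carry no evidence against an arbitrarily large population and maps to
`Inf`, never to a negative estimate.

Confidence intervals are a delete-one-individual jackknife
("jackknife across samples") on the `r̂²_drift` scale, transformed through
the Ne formula; the upper bound becomes `Inf` whenever the interval
crosses zero drift. Jackknifing individuals rather than locus pairs
respects the dependence structure among overlapping pairs.

### Two-sample temporal method

`temporal_fc()` computes Nei–Tajima's standardized variance of
allele-frequency change per locus, `Fc = (1/K) Σ_a (x_a − y_a)² /
((x_a+y_a)/2 − x_a y_a)`, skipping loci fixed for the same allele in both
samples, and averages loci weighted by independent alleles (equally, for
biallelic loci). `temporal_ne()` applies the plan-II moment correction

    N̂e = t / (2 (F̂c − 1/(2S₀) − 1/(2Sₜ)))

with `Inf` when sampling noise explains all the observed change. The
elapsed generations `t` is a **required** argument: generation time is
study knowledge (for a snake with overlapping generations it is itself an
estimate), and no default could be defensible. Chi-squared intervals on
`F̂c` (df = independent alleles) transform monotonically to Ne bounds.
Sampling plan II (sampling without replacement before reproduction) is the
only implemented plan, matching the default of the software this mirrors.

`ne_na_ratio()` forms the effective-to-adult ratio, preferring the
temporal point estimate when finite (it is typically more precise), else
the LD estimate, and reports at 2 decimals with ties rounded away from
zero — the rounding convention of published tables (`round_half_up()`;
note 0.125 must print as 0.13).

## Bayesian abundance estimation by data augmentation

`build_augmented_data()` pads the observed capture histories with all-zero
pseudo-histories to a fixed pool `M`; `fit_cmr()` then samples the
closed-population multinomial N-mixture posterior with JAGS:

* `z_i ~ Bernoulli(ψ)`, `ψ ~ Uniform(0,1)`: inclusion in the realized
  population; `N_s = Σ z_i [g_i = s]`.
* multi-site pools share one augmentation pool with latent categorical
  site membership `g_i ~ Cat(π)`, `π ~ Dirichlet(1,…,1)` — the model
  allocates undetected animals among sites, sharing capture-process
  information; per-site pools remain available by fitting sites singly.
* `logit p_{i,d} = logit(p̄) + a_{s(i)} + b_{s(i),d} + e_i + β_temp T_{s,d}
  + β_sex male_i + β_svl SVL_i + β_behav c_{i,d}` with `p̄ ~ Uniform(0,1)`,
  `β ~ Normal(0, 3.16)` and half-Cauchy(1) priors on the random-effect
  SDs. Date effects are nested within site because sites are trapped over
  different windows. The behavioural covariate `c_{i,d}` is 1 iff the
  individual was *observed* captured on day d−1 (a trap response defined
  on data, not latent state), with `c_{i,1} = 0`.
* Unknown sex is imputed from a site-level Bernoulli with uniform prior;
  missing standardized SVL from a standard normal. Covariates are centred
  and scaled by the observed-data mean and SD. The individual random
  effect applies to pseudo-individuals too — exchangeability between
  observed and unobserved animals is what justifies augmentation, at the
  price of `M` extra latent effects.

Defaults mirror the monitoring study (5 chains × 200,000 iterations,
10,000 burn-in, thin 10); every simulation in the test suite passes much
shorter explicit chains, sized so that the enumeration oracle and coverage
checks bound the Monte-Carlo error. Convergence is summarised with PSRF
and effective sample size, with a warning above PSRF 1.1; a posterior
piling up at the pool capacity aborts with advice to raise `M` (the
augmentation prior truncates N at M, so a binding pool invalidates the
fit).

Summaries follow the reporting conventions of the study: `posterior_mode()`
(ties toward the smaller count — conservative for abundance),
`hpdi()` (shortest contiguous window containing ⌈level·n⌉ sorted draws),
`covariate_evidence()` (fraction of draws sharing the median's sign,
"strong" at ≥ 0.9), and `sex_ratio_posterior()` (per-draw M/F including
imputed sexes; "biased" iff the 95% HPDI excludes 1; draws with zero
females are reported as a fraction rather than silently dropped).

`huggins_fit()` is kept as a distinct, separately testable estimator: the
conditional likelihood divides each observed history's probability by
`p*_i = 1 − Π_d (1 − p_{i,d})` and recovers abundance by Horvitz–Thompson
summation `N̂ = Σ 1/p̂*_i`, with sex and fixed occasion effects. The two
approaches answer the same question through different likelihoods, which
is exactly why both are exposed. An occasion with zero captures cannot
identify its own effect and is folded into the intercept with a warning.

`na_sexratio_regression()` is ordinary least squares of per-site sex ratio
on modal abundance, reporting adjusted R² (which can legitimately be
negative for uninformative fits) and the two-sided slope p-value, with an
explicit site-exclusion argument for outlier sensitivity analyses.

## The genetic-rescue decision framework

`inbreeding_coefficient()` computes `F = 1 − Ho(recipient)/He(source)`:
observed heterozygosity for the recipient (so that both drift and
non-random mating register) against expected heterozygosity for the
source. In `rescue_table()` the source's "expected heterozygosity" is
taken from the nucleotide-diversity column by default: π *is* the unbiased
expected-heterozygosity estimator, and this choice is the one that
reconciles the published derived table with its published inputs. The
plug-in `he` column is available via `source_he = "he"`.

Four source scenarios per recipient, restricted to the recipient's
regional cluster: nearest neighbour (great-circle), largest Ne, highest
He, largest adult abundance. When the recipient is itself the argmax the
scenario is reported as not applicable (the dash convention). He ties are
broken by π, then allelic richness, then name — richness is the natural
secondary diversity criterion, and this ordering reproduces the published
source choices.

Erosion flags: `small` = (Na < 100 **and** Ne < 100) — small now and small
for multiple generations; `erosion` = F > 0.10, strict. The 10% threshold
is the default (a 0.01 variant appears in some methodological texts and is
selectable via `f_threshold`); `isolated` is an external input from
clustering analyses, not recomputed here.

The bundled `sfgs_*()` tables carry the published per-site summaries. The
coordinates in them are synthetic stand-ins — precise localities of an
endangered, collected species are properly unpublished — constructed to
preserve the published nearest-neighbour ordering, which is the only
property the rescue scenarios consume.

## The simulators, and what passing tests show

`simulate_wright_fisher()` has two modes because two different properties
of real data matter to different estimators:

* **frequency mode**: per-deme allele frequencies evolve by symmetric
  island-model migration then binomial resampling of 2N gene copies; loci
  are independent; samples are assembled under Hardy–Weinberg (with an
  optional inbreeding knob for stress-testing). This matches the
  assumptions of the drift-decay law, the temporal method and the
  variance-component θ, and is cheap at thousands of loci.
* **individual mode**: a single deme of N diploids reproduces by random
  union of gametes with Mendelian transmission and free recombination.
  Finite-population reproduction physically generates the inter-locus
  disequilibrium (E[r²_drift] ≈ 1/(3Ne)) that the LD method estimates; a
  frequency-based simulator with independent loci carries *no* such
  signal, so LD-Ne validation must use this mode.

`simulate_capture_histories()` shares its linear predictor with
`fit_cmr()`, assigns sex and SVL, and keeps never-captured individuals in
the truth record. Missing genotypes are dropped uniformly at random — the
simplest defensible mechanism when the real missingness process is
unknown.

What the validation suite shows: the estimators recover truth under their
own assumptions (unlinked neutral loci, random mating, population closure,
homogeneous or modelled capture heterogeneity), at the study's sample
sizes. What it does not show: robustness to linked loci, age structure and
overlapping generations, non-random mating, tag loss, or informative
missingness. Those are properties of real data the simulators deliberately
do not emulate, and results on real panels inherit the corresponding
caveats (e.g. temporal Ne with overlapping generations is biased unless t
is chosen on a generation scale, which is why t is user-supplied).

## Numerical choices and degenerate inputs

* Rarefaction uses `lchoose` differences, stable at thousands of copies.
* Presence/MAF boundary comparisons carry a 1e−12 tolerance so that
  fractions like 8/10 compare correctly under binary floating point.
* θ components are computed per locus with per-locus sample sizes; loci
  with a single represented population, or monomorphic overall, return
  `NA` components and are excluded from the ratio of sums.
* `ne_from_drift()` clamps a negative discriminant to zero before the
  square root (the quadratic has no real root when the drift signal
  exceeds its theoretical maximum at tiny Ne).
* HPDI ties take the first (lowest) minimal window; posterior-mode ties
  take the smaller value.
* The pipeline (`run_pipeline()`) isolates stage failures, embeds the
  config hash and seed in every output header, and skips stages whose
  inputs are not configured rather than failing the run.

## Validation problem sizes

The shipped tests size their simulations to keep the full suite fast
while leaving the Monte-Carlo error well inside the asserted tolerances:
abundance-coverage runs use 50 replicates of (N = 100, D = 10, p = 0.2,
M = 300) with single short chains; LD-Ne recovery uses 20 replicates of
(Ne = 50, S = 30, L = 200); temporal recovery 20 replicates of (Ne = 100,
t = 10, S = 50, L = 500); the drift-decay check 2000 loci; type-I
calibrations 200 replicates at 99–199 permutations. These sizes were
chosen once, from the standard error of each quantity, not tuned to
outcomes.
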