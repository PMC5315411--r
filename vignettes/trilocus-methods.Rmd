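---
title: "Methods: three-locus risk analysis for canine dermatomyositis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-locus risk analysis for canine dermatomyositis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the data model

Canine dermatomyositis (DMS) segregates in collies and Shetland sheepdogs
with a three-locus architecture: a *PAN2* missense risk allele **A**, a
*MAP3K7CL* indel risk allele **B**, and the DLA class II haplotype
*DRB1\*002:01/DQA1\*009:01/DQB1\*001:01* as risk allele **C** (any other
DRB1 allele counts as **c**). A cohort is one row per dog: breed,
case/control status, unphased genotypes at the two autosomal loci, a pair
of DLA haplotypes, an optional age at onset (months; cases only) and a
merle-coat flag. Because every observed DLA haplotype carries a unique
DRB1 allele, full haplotypes are inferred from DRB1 alone via a small
editable lookup (`dla_haplotype_table()`); the risk status of a haplotype
is a pure function of its DRB1 allele. Dogs with exactly one typed DLA
haplotype are rejected at load time rather than imputed — the cost of a
dropped record is smaller than the bias of guessing a second haplotype in
populations where one haplotype approaches fixation.

The status vocabulary distinguishes screened GWAS-grade `control` dogs
(eight years or older, family history screened) from
`unaffected_unscreened` dogs (age-qualified only). Association and
penetrance analyses accept both by default and declare the choice through
their `statuses` argument.

## Exact association machinery

All case–control comparisons are exact. The two-tailed Fisher p-value
follows the point-probability rule: the sum over all tables with the
observed margins of hypergeometric probabilities not exceeding that of
the observed table (with the standard `1 + 1e-7` relative guard against
floating-point ties). This convention reproduces the reference DLA
association table at printed precision (including a non-significant
0.4454 exactly), whereas the doubling rule does not. Odds-ratio
confidence intervals are Woolf (log-normal):
`exp(log OR ± z_{1-α/2}·√(1/a+1/b+1/c+1/d))`, chosen because it
reproduces all three published intervals to two decimals. Zero cells
leave the OR undefined unless the Haldane +0.5 correction is requested,
and then the result is flagged.

Haplotype-level tables use 2n counting (each diploid dog contributes two
haplotype observations); homozygosity tables count dogs. When one
haplotype exceeds 90% frequency in a stratum the association is flagged
low-power — near-fixation, as in collies, leaves essentially no
heterogeneity to test.

The per-genotype "versus population" test is the exact binomial test of
a genotype's case count against the cohort-wide disease rate
(p₀ = 132/522 ≈ 0.253 in the reference cohort). This convention was
chosen over a Fisher genotype-versus-rest test because it reproduces the
published per-genotype p-values at printed precision (0.253 for a
genotype observed once in a case; 0.348 for 0/6); the Fisher variant
remains available via `method = "fisher_rest"`.

## Penetrance and risk classification

Penetrance per three-locus genotype is cases/(cases+controls) with the
Clopper–Pearson exact interval (beta-quantile inversion; closed forms
`1-(α/2)^{1/n}` and `(α/2)^{1/n}` at the boundaries). Genotypes observed
fewer than five times are left unclassified. The risk bands are
`[0, 0.25)` low, `[0.25, 0.75)` moderate, `[0.75, 1]` high: the observed
penetrance ranges in the reference cohort (<6%, 33–50%, 90–100%) leave
wide gaps, and these cut points reproduce every published label without
ambiguity while remaining round numbers. Genotypes containing `cc`
remain classifiable when observed at least five times. The
moderate-plus-high classes cover 117 of the 132 reference cases (88.6%);
an abstract-level figure of 93% is not recoverable from the genotype
table itself, so the package reports the computed fraction only.

## The hierarchical Bayesian epistasis model

Within a DLA stratum (CC or Cc), cell (i, j) of the PAN2×MAP3K7CL grid
contributes `n_cases_ij ~ Binomial(n_ij, p_ij)` with

```
logit(p_ij) = intercept + addA_i + domA_i + addB_j + domB_j
              + add×add_ij + add×dom_ij + dom×add_ij + dom×dom_ij
```

Additive codes are (+1, 0, −1) for (homozygous risk, het, homozygous
wild type) and dominance codes (0, 1, 0); the four epistatic covariates
are the pairwise products. This orthogonal coding follows the classical
variance-decomposition framework; the nine-term model is exactly
saturated on the 3×3 grid and alternative codings would only rescale
coefficients (the p_ij surface is invariant). Cells with fewer than five
dogs are excluded from the likelihood and reported as missing.

The intercept and all genetic coefficients share a N(0, σ) prior with
σ ~ half-Cauchy(0, 25) — the positive half, since σ is a scale. This
hierarchical prior is what keeps p_ij inside (0, 1) for cells with zero
cases or zero controls. Sampling is by Gibbs/Metropolis MCMC (JAGS); the
reference schedule is 4 chains × 50,000 iterations, 20,000 warm-up,
thinned to every 20th draw (6,000 retained), and every component is
configurable. Convergence is monitored by split Gelman–Rubin R-hat with
1.05 as the adequacy bound; exceeding it flags the run but still returns
it. Draws are reproducible bit-for-bit given (seed, schedule, backend
version); reproducibility across samplers is not promised.

### Quantifying the epistatic departure

Two comparisons against a "strictly additive" expectation are provided,
and they are not interchangeable. `additive_expectation()` evaluates,
per posterior draw of the full fit, the surface implied by the
main-effect components alone (interactions zeroed); at the (AA, BB)
double homozygote the gap to the full surface is carried entirely by the
additive-by-additive term. Refitting a model *constrained* to zero
interactions (`interactions = FALSE`) is also supported, but comparing
two separately fitted, separately shrunk posteriors can invert the sign
of small departures: on sparse grids the constrained fit extrapolates
monotone margins into a saturated cell more aggressively than the full
model, whose hierarchical prior shrinks a 22/0 cell away from 1. The
within-fit decomposition is therefore the package's preferred statement
of epistasis direction; both are exercised in the test suite.

A related caution applies to comparing the CC and Cc surfaces cell by
cell: in the reference cohort two cells (Aa bb and AA bb) have slightly
*higher* observed case fractions under Cc than CC, so a blanket
"CC ≥ Cc wherever a wild-type allele is present" does not hold cellwise
at the posterior mean — the data themselves, not the model, are the
reason. The direction holds clearly wherever the B risk allele is
present.

## The Weibull onset model

Onset ages y (months) in risk-allele-count class i (A and B alleles
summed, 0–4; DLA pooled) follow `y ~ Weibull(shape r, scale e^{-b_i})`,
`b_i ~ N(0, σ)`, σ ~ half-Cauchy(0, 25), `r ~ Exponential(0.001)`. The
class median is `e^{-b_i}·ln(2)^{1/r}` and the mean `e^{-b_i}·Γ(1+1/r)`;
these formulas fix the reading that r is the shape and `e^{-b_i}` the
scale (source texts sometimes label them inversely; the formulas govern).
Summaries are computed per draw and then aggregated — never plugged in at
posterior means. Ages are treated as fully observed event times;
right-censoring is a documented extension, off by default, appropriate
if never-affected carriers were followed prospectively.

## GWAS, LD and interval demarcation

Quality control removes samples below 95% call rate first, then SNPs
below 95% call rate, below 5% minor-allele frequency, or out of
Hardy–Weinberg equilibrium in control dogs at p < 1e-4. The HWE test is
the conditional exact test (enumeration of heterozygote counts given
allele counts) rather than chi-square, which misbehaves near the MAF
boundary. Association is Fisher's exact test under a dominant model
(carriers of the panel minor allele versus non-carriers) — the exact
kernel is shared with the association module. The Bonferroni threshold
is α/n tests; genomic inflation λ is the median observed 1-df chi-square
quantile over 0.4549.

LD with a lead SNP is the phase-free composite estimate: squared Pearson
correlation of genotype dosages, computed in controls by default. No EM
phasing is needed per pair, matching unphased array data. A candidate
interval spans all SNPs with r² ≥ 0.6 and extends on each side to the
first *associated* flanking SNP in lower LD (association threshold
parameterized, Bonferroni by default); missing flanks truncate at the
chromosome end (start clamps to 1) and flag the interval. Between two
specific loci — Merle/*PMEL* and *PAN2* — LD is summarized as D′ from
EM-estimated haplotype frequencies (the only EM in the package; double
heterozygotes are the single ambiguous class), with a 1-df likelihood
ratio test against independence. Merle-patterned dogs are encoded Mm,
non-merle mm. |D′| is reported. Coordinates are 1-based inclusive
throughout, with 0-based half-open BED emitted by `as_bed()`.

## Pooled-heterozygosity sweep scan

Windows "creep": they accrue consecutive SNPs while the accumulated span
stays within 1 Mb, with inter-SNP gaps over 10 kb contributing nothing
to the span (the alternative reading — breaking the window at large gaps
— is available via `gap_mode = "break"`, and an overlapping sliding mode
via `mode = "sliding"`; the exact advance rule is not recoverable from
the source text, so both readings ship and the default is recorded here,
not asserted as the original authors' choice). Windows with fewer than
50 SNPs never enter the statistics. Pooled heterozygosity is
`Hp = 2·Σn_major·Σn_minor/(Σn_major+Σn_minor)²` (sums over the window's
pooled allele counts), Z-transformed across retained windows; windows
with −ZHp > 3.4 are flagged and adjacent flags merge into regions.
Major/minor labels are defined by the counts themselves, so ties are
harmless.

## Variant filtering

Filters operate on biallelic records (multi-allelic VCF rows are split)
and commute as set operations: interval restriction (boundaries
inclusive), segregation patterns (per-sample required states, where
`hom` means reference/reference *or* alternate/alternate — the widened
reading used on chromosome 10; `hom_alt` gives the strict reading used
on chromosome 31), exon ± 10 bp splice capture, and uniqueness against
other-breed call sets and a known-variant catalog. A missing call at a
required sample drops the variant and is counted separately. The
expressed-in-skin annotation is accepted as an input column, never
computed — read alignment is out of scope.

## What the generators emulate — and what they do not

The synthetic cohort draws loci independently under Hardy–Weinberg
within breed (the three risk loci sit on different chromosomes), with A
and B frequencies implied by the reference genotype counts, DLA
haplotype frequencies from the observed control distributions, disease
status Bernoulli(penetrance of the three-locus genotype), and Weibull
onset ages for cases. The published per-breed allele-frequency summaries
(collie A 42%/B 5%; Shetland sheepdog A 25%/B 38%) are not exactly
consistent with the genotype table, so the generator defaults to the
table-implied frequencies for internal consistency and exposes the
published values as an alternative parameterization. The penetrance map
assigns moderate/high genotypes their observed penetrance and 0.02 to
low or unclassified genotypes; onset uses shape 1.6 with class medians
18.5, 9 and 5 months for 2/3/4 risk alleles — the outer medians are the
published class medians, the middle one an interpolation, and the shape
a value typical of early-life onset distributions (chosen once, here).
The single deliberate LD exception is Merle/*PAN2* repulsion, generated
at the haplotype level against a target D′ of 0.998.

`simulate_table3_cohort()` reproduces the reference genotype counts
*exactly* (only order, onset ages and merle flags depend on the seed);
it is the fixture behind every exact reproduction test. The SNP panel
generator uses a first-order neighbour-copy process for LD, which gives
geometric r² decay but no block structure or recombination hotspots; the
pooled-counts generator uses a 1/k neutral-like spectrum with binomial
thinning inside the sweep. Passing tests on these inputs therefore
demonstrate correctness of the statistical machinery, not robustness to
real-data pathologies (batch effects, cryptic relatedness, call-rate
structure correlated with phenotype).

## Numerical choices and problem sizes

Floating-point ties in exact-test tail sums use the conventional
`1 + 1e-7` relative guard. EM for haplotype frequencies starts at
linkage equilibrium and stops at a 1e-12 maximum frequency change.
Chain RNGs are seeded deterministically from the user seed. The test
suite runs the Bayesian models at 4 × 6,000/2,000/thin-4 (4,000 retained
draws) for routine checks and 4 × 20,000/5,000/thin-10 for the sparse
Cc stratum, with split R-hat < 1.05 asserted where inference matters;
parameter-recovery simulations use 200 observations per cell/class, the
sweep operating characteristics 100 replicates of 10,000 SNPs on a 60 Mb
chromosome, and the null GWAS calibration 10,000 SNPs × 160 dogs. These
sizes were chosen so that Monte-Carlo error is comfortably below the
tolerances being asserted.

## Known limitations

- Genome-scale association p-values (1e-8 and beyond) require the
  original array data and are out of scope; the package's GWAS is
  validated on synthetic panels by localization and calibration
  properties instead.
- The epistasis model is per-stratum; a joint model with a C main effect
  and C-by-locus interactions would use the data more efficiently but is
  not what the reference analysis did.
- Onset ages are uncensored by assumption; cohorts with unaffected
  carriers followed to a fixed age would need the censoring extension.
- D′ significance uses a 1-df LRT, adequate at the sample sizes here;
  permutation is preferable for very rare alleles.
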