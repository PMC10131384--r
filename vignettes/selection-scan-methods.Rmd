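---
title: "Methods: two-level selection analysis of candidate gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level selection analysis of candidate gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical methods implemented in `sweepscan`,
the assumptions behind them, the tunable parameters and their defaults, the
design of the synthetic-data generator, and the numerical and design
decisions taken where conventions genuinely diverge.

## Overview

The package implements a two-level analysis of selection on a candidate
gene set:

1. **Recent selection in structured populations** (timescale of roughly the
   last hundred thousand years in humans): a genome scan over phased
   haplotypes combining within-population iHS, cross-population xpEHH,
   per-SNP Weir & Cockerham F~ST~ with frequency-binned empirical
   thresholds, the population branch statistic (PBS), clustering of extreme
   scores in 51-SNP windows, and an intersection decision rule restricted
   to exonic SNPs.
2. **Long-timescale selection across a phylogeny** (millions of years): the
   decision layer of the branch-site likelihood-ratio test — the LRT
   statistic from externally fitted codon-model log-likelihoods, the
   chi-square(1) mixture p/2, and Bonferroni correction. The codon-model
   maximum-likelihood fits themselves (branch-site model A against the
   omega2 = 1 null) are external-tool computations and are consumed, not
   re-implemented.

A supporting two-proportion Z test compares disease incidence between
populations. A forward Wright–Fisher simulator generates phased
multi-population cohorts with known ground truth so the entire pipeline is
exercised, calibrated and tested without external data.

## Haplotype statistics

**EHH.** For a core SNP and a carrier set (derived carriers, ancestral
carriers, or all haplotypes pooled), EHH at extent $j$ is the probability
that two randomly drawn carriers are identical over the interval between
the core and $j$: $\mathrm{EHH}(j) = \sum_h \binom{k_h}{2} / \binom{n}{2}$
over the sub-haplotype groups $h$ at $j$. The identity interval excludes
the core column itself, so EHH is exactly 1 at the core for every carrier
class — including the pooled class, where the convention matters. The
curve extends in each direction until it first drops below a cutoff
(default 0.05, the convention of the standard scan tools) or hits the
chromosome edge.

**iHH and iHS.** iHH is the trapezoidal integral of EHH against physical
position (bp), summed over both arms. Only trapezoids whose *both*
endpoints are at or above the cutoff contribute; the first below-cutoff
point is dropped without interpolation — a simple rule applied identically
in iHS and xpEHH. Unstandardized
$\mathrm{iHS} = \ln(\mathrm{iHH}_{\text{ancestral}} /
\mathrm{iHH}_{\text{derived}})$. Cores are skipped, with machine-readable
reason codes, when an allele class has fewer than 2 carriers
(`monomorphic`), when the curve runs off the chromosome before reaching the
cutoff (`edge` — scoring such cores would bias iHH downward), when an
inter-site gap exceeds `max_gap` (default 200 kb, the standard tool
default) before the cutoff, or when an integrated area is zero
(`zero_area`).

**xpEHH.** Both populations' iHH are computed over *all* haplotypes
(alleles pooled at the core), and the truncation extent for both is set by
where the combined two-population EHH first falls below the cutoff, so the
two integrals cover the same interval. Unstandardized
$\mathrm{xpEHH} = \ln(\mathrm{iHH}_A / \mathrm{iHH}_B)$; positive values
indicate longer haplotypes — candidate selection — in population A, and the
sign attributes the signal to a population in the decision rule.

**Standardization.** Raw scores are standardized within bins of the core
SNP's derived-allele frequency: default 100 equal-width bins for iHS and a
single genome-wide bin for xpEHH (whether the original analyses binned
xpEHH is not documented; both are supported). Bins with fewer than 20
scores are merged with their nearest occupied neighbour (ties toward lower
frequency), deterministically. Standardization uses population moments
(divide by $n$), so the per-bin mean-0/variance-1 identity is exact to
floating point — a property the tests assert at 1e-6 — and a bin with zero
variance leaves its scores undefined rather than infinite.

## Differentiation statistics

**Weir & Cockerham F~ST~ (1984).** Per site, haplotype pairs are recombined
into diploid genotypes and the two-population variance-component estimator
returns $a$ (among populations), $b$ (among individuals within populations),
$c$ (within individuals) and $F_{ST} = a/(a+b+c)$. Negative estimates are
legitimate small-sample behaviour and are preserved in the empirical
distributions. Because F~ST~ is strongly frequency-dependent, outlier flags
are assigned within pooled-MAF bins (width 0.05 over [0, 0.5], sparse bins
merged at the same floor of 20): a site is flagged iff its F~ST~ is
*strictly greater* than its bin's empirical top-5% threshold. Ties never
flag; the rule is conservative and deterministic.

**PBS.** $T = -\ln(1 - F_{ST})$, with F~ST~ clamped into
$[0, 1 - 10^{-12}]$ before the transform (negative estimates clamp to 0, so
$T \ge 0$; the clamping never touches the raw F~ST~ used in the outlier
test). $\mathrm{PBS} = (T^{\text{test,sister}} + T^{\text{test,outgroup}} -
T^{\text{sister,outgroup}})/2$; all six role assignments of a three-way
comparison are obtained by relabeling. Natural log is used (the source
method's convention). The outgroup is a configuration label, and PBS is
simply not defined for comparisons in which the outgroup would be the test
or sister population. Top-5% flags use the genome-wide empirical threshold
per comparison, strict inequality again.

**Empirical quantiles.** Every threshold (top-percent windows, binned
F~ST~, PBS) uses the inverse-ECDF quantile (R's `type = 1`): the threshold
is an order statistic of the data, duplicating the data leaves it
unchanged, and "top 5% of 100 distinct values" flags exactly 5. An
interpolating quantile definition satisfies none of these exactly.

## Windowing and the decision rule

Extreme haplotype scores cluster under sweeps, so per track (statistic ×
population or pair) the scan counts SNPs with |standardized score| > 2 in
sliding windows of 51 consecutive scored SNPs (step 1, per chromosome;
sliding rather than tiling maximizes sensitivity and avoids phase
artifacts). Windows whose count strictly exceeds the genome-wide top-1%
count threshold qualify; a SNP is a *haplotype hit* iff it exceeds the
score cutoff and lies in at least one qualifying window.

The final call, per SNP and population: a haplotype hit there (iHS is
intrinsically within-population; an xpEHH hit is attributed to the
population on the positive side of the score), **and** a high F~ST~ in at
least `fst_k` pairwise comparisons involving that population (default 1 —
"any one pair"; configurable up to "all pairs"), **and** exonic location.
PBS values and their top-5% flags are attached as corroboration: a
candidate lacking a high PBS is reported with `pbs_high = FALSE` rather
than vetoed, since discordance between the haplotype/F~ST~ evidence and PBS
is informative but rare; a strict mode makes PBS gating. Every empirical
threshold used is emitted in a thresholds report, and every output file
embeds the resolved configuration, so a run is reproducible from its
outputs.

## The branch-site LRT layer and the incidence test

The LRT statistic is $2(\ln L_A - \ln L_B)$; small negative values arising
from external optimizer noise are allowed and clamp to zero inside the
p-value. Under the null the statistic follows a 50:50 mixture of a point
mass at zero and $\chi^2_1$, so $p/2$ — half the $\chi^2_1$ upper tail — is
used; it lives in $[0, 0.5]$. Bonferroni correction defaults to the
per-branch family (the number of genes tested on the same foreground
branch), the natural reading when branches are tested separately; the
family size is configurable because the original family is not documented.

The incidence Z statistic is the pooled-proportion two-sample test
$z = (c_1/n_1 - c_2/n_2) / \sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$ with
$\hat p = (c_1+c_2)/(n_1+n_2)$. The printed form of the statistic takes
the absolute difference; the signed version is retained alongside because
the pairwise comparisons are directional. Case counts are the input unit.
The packaged fixture back-derives crude counts from published per-100,000
rates and registry person totals; published rates are age-standardized,
ASR computation is out of scope, and the fixture is documented (and named)
as derived.

## The synthetic cohort generator

A discrete-generation forward Wright–Fisher simulator with: infinite-sites
mutation (at most one mutation per bp position; collisions redrawn),
Poisson-distributed crossovers per meiosis, deme splits by copying the
parent deme, symmetric migration (each parent drawn from a random other
deme with a per-gene-copy probability), and an optional hard sweep under
genic selection (fitness 1, 1+s, 1+2s) planted as a new mutation at a focal
position; a lost sweep restarts from a snapshot taken at onset (bounded at
100 retries). The ancestral state is the founding population's allele, so
polarization of the emitted VCF (INFO/AA) is exact by construction.
Random-number streams are derived per (generation, deme, retry) from the
master seed, so a fixed seed is bit-reproducible and adding a deme does not
perturb the others.

**Study conditions.** The canonical cohort (`simulate_study()`) and the
reasoning behind each choice:

- *Three demes of N = 500 diploids* (test, sister, outgroup), 200
  haplotypes sampled per deme — a desk-scale rendering of three continental
  groups with an outgroup, at sample sizes comparable per population to a
  large public phased panel.
- *Genome of three chromosomes*: chr1 (200 kb) carries the optional sweep
  at its centre; chr2 and chr3 (100 kb each) are neutral. The top-percent
  window, binned-F~ST~ and PBS thresholds are *empirical genome-wide
  distributions*; a lone candidate region cannot supply its own background
  — the outlier quantiles would degenerate onto the signal itself (the
  strict `>` rule then flags nothing when the signal plateau reaches the
  quantile, and sweep SNPs crowd their own frequency bin in the F~ST~
  test). Pooling neutral chromosomes into the distributions reproduces the
  genome-to-signal proportions the method assumes.
- *mu = 1e-6 /bp/gen* (theta ≈ 0.002/bp): gives a genome-like density of
  MAF-passing SNPs (~7/kb) so that 51-SNP windows span a few kb.
- *rec = 1.5e-6 /bp/gen*: scaled up relative to a human per-bp map so
  haplotype homozygosity decays well inside a 200 kb region, while the
  sweep footprint, roughly $s/(r \ln 2Ns) \approx 9$ kb, spans about one
  window and remains a small fraction of the simulated genome — the same
  proportions that make the method work at full scale.
- *Migration 5e-4 per gene copy per generation*: continental-scale gene
  flow; it also keeps fixed differences (F~ST~ exactly 1.0) rare, which
  matters because a strict empirical threshold degenerates when a bin's
  top values are exact ties — isolated-deme artifacts, not a property of
  real data.
- *Splits 300 (sister) and 600 (outgroup) generations before present*:
  pairwise F~ST~ around 0.15–0.3 at these drift scales, qualitatively the
  continental range.
- *Sweep: s = 0.05, onset 200 generations before present*: at sampling
  time the sweep is typically at high frequency or freshly fixed — the
  regime the two haplotype tests jointly target (iHS for ongoing, xpEHH
  for near-fixed sweeps).
- *Burn-in 4N generations* from a monomorphic founder: heterozygosity
  reaches ~86% of mutation–drift equilibrium; adequate for a background
  distribution, and stated here as the package's choice of problem size.
- *Exons*: 2 kb on a 4 kb period (50% coding coverage — a gene-dense
  regime, matching a scan restricted to a candidate gene set), phased so
  the planted focal variant is exonic, i.e. the selected variant is a
  coding variant.

**What the generator does not emulate**: realistic human demography
(growth, bottlenecks, admixture), a variable recombination map, background
selection, soft sweeps, genotyping or phasing error, and ascertainment
bias. Passing the recovery tests therefore demonstrates that the pipeline
detects hard sweeps under idealized structured-population conditions — not
that it would achieve the same power or specificity on real cohort data,
where demography and map variation are the dominant confounders the
original empirical-outlier design works around.

**Replicate study sizes.** The recovery analysis uses 50 sweep and 50
neutral cohorts at the conditions above (about 7 s per cohort end-to-end
on one core); recovery means a final call in the sweep deme within 10 kb
of the planted focal position. The generator's iHS-elevation check is run
on *ongoing* sweeps (earlier onset, still segregating at sampling):
iHS is a test for sweeps that have not reached fixation, and once the
sweep fixes the within-deme contrast moves to xpEHH — whose focal-region
sign check runs at the near-fixation conditions. The coalescent-expectation and
F~ST~-ranking checks of the simulator run at much smaller scale (N = 50 to
100, 4 kb regions, 100–200 replicates) where their analytic expectations
are sharp.

## Numerical choices and degenerate inputs

- Distances are physical bp throughout; no genetic map (none is used by
  the original analyses; the standard tools fall back to physical maps).
- Sites with any missing genotype are dropped at VCF read time (no
  documented missing-data policy exists to follow; the package's policy is
  explicit and logged).
- Ancestral-allele annotations: uppercase = high confidence; lowercase is
  excluded by default (configurable), mirroring the annotation practice of
  the public phased panels; AA matching neither REF nor ALT excludes the
  site and is counted in the polarization report.
- VCF positions are 1-based, BED intervals 0-based half-open; conversion
  happens in exactly one place (`annotate_regions()`), where 1-based
  position $p$ is inside $(s, e)$ iff $s \le p-1 < e$.
- Monomorphic cores, zero-variance bins, degenerate window-count
  distributions and undefined F~ST~/PBS all carry explicit reason codes or
  warnings instead of NA-silent propagation.
- MAF filtering is inclusive (`>=` 0.05). The shared cross-population site
  list keeps sites with pooled MAF >= 0.05; iHS additionally requires the
  within-population MAF, since a site fixed within one population has no
  within-population haplotype contrast.

## Known limitations

- The two-population Weir & Cockerham estimator only (no Hudson or Nei
  variants; no windowed F~ST~ — the outlier test is per-SNP by design).
- xpEHH standardization defaults to a single genome-wide bin; per-bin
  standardization is available but not the default.
- The simulator is forward-in-time and desk-scale; very long regions or
  large N are out of its intended envelope.
- The branch-site layer consumes log-likelihoods; it cannot detect
  problems upstream in alignment or model fitting.
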