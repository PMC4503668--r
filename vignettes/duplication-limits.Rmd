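---
title: "Mutation limits and population genetics of segregating tandem duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation limits and population genetics of segregating tandem duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplimits)
```

## The scientific problem

Tandem duplications create new gene structures — whole-gene copies, genes
that recruit non-coding sequence, chimeric genes formed when a breakpoint
falls inside a gene — and are raw material for adaptation. Whether
evolution can actually use them depends on two quantities: how much
duplication variation is *standing* in a population right now, and how long
a population must wait for a *new* duplication at a locus where one is
needed. `duplimits` implements the calculus that answers both questions
from resequenced panels of inbred lines, together with the spectrum
corrections, diversity scans, and detection models such panels require.

The package is organized as a workflow (`analysis/01...08`) over a set of
exported functions; every computation lives in the package and is unit- and
property-tested, and a synthetic-data module generates all inputs so the
whole pipeline runs without external data.

## Models and procedures

### Site frequency spectra and their two corrections

A sample SFS counts variants by derived-allele frequency class
$i = 1..n-1$. Two biases specific to duplication panels are corrected:

**Reference-discovery ascertainment.** Duplications are discovered as
divergently oriented read pairs relative to a reference genome, so a
variant carried by the reference individual is invisible. A variant at
population proportion class $i$ of $n$ (reference included, here $n = 21$)
is detectable with probability $(n-i)/n$; inverting,

$$x_i = \frac{y_i\, n/(n-i)}{\sum_i y_i\, n/(n-i)}.$$

The printed form of this normalization sums to $n-2$, which would leave
$x_{n-1}$ undefined while corrected classes up to $n-1$ are reported; we
treat that bound as a typo and sum to $n-1$ by default
(`correct_ascertainment(sum_upper = "n-2")` restores the printed bound).
`simulate_reference_discovery()` is the forward model, used by the
round-trip tests.

**Ancestral-state mispolarization.** When polarity is read off an outgroup
genome, an independent mutation on the outgroup lineage flips class $i$
into $n-i$ with probability

$$k = \left[\left(\tfrac{\kappa}{2+\kappa}\right)^2 +
\tfrac12\left(\tfrac{2}{2+\kappa}\right)^2\right] D_{net}, \qquad
D_{net} = Div_{x,y} - \pi_x,$$

which at the Drosophila transition/transversion ratio $\kappa = 2$ is
$\tfrac38 D_{net}$. The observed spectrum is the mixture
$S_{i,obs} = S_i(1-k) + S_{n-i}k$, inverted exactly by

$$E[S_i] = \frac{S_{i,obs}(1-k) - S_{n-i,obs}\,k}{1-2k},$$

singular at $k = \tfrac12$ (hence the generator and corrector both reject
$k \ge 0.5$). Negative corrected counts — possible on noisy data — are
clipped to zero with a warning. `mix_polarization()` followed by
`correct_polarization()` is an exact algebraic identity, tested to machine
precision on 1000 random spectra.

Spectra with unequal effective sample sizes are made comparable by
hypergeometric projection (`project_sfs()`), and contrasts use Wilcoxon
rank-sum, Kolmogorov–Smirnov, or a high-frequency 2×2 chi-square on
per-variant frequency lists (each variant contributes its class once; this
is the only reading consistent with rank statistics of the reported
magnitude). The chi-square applies no continuity correction by default;
both choices are exposed.

### Windowed diversity and the sweep footprint

`window_stats()` computes $\theta_\pi$, Watterson's $\theta_W$, and
Tajima's $D$ in 5 kb windows sliding by 500 bp, dividing by *callable*
sites (the coverage/quality mask) rather than window length, and flagging
windows with fewer than 4000 callable bp invalid. $D$ uses the standard
constants with $n$ = sampled sequences and is reported missing when
$S = 0$. Diversity is z-scaled per chromosome (sample standard deviation,
$n-1$) so chromosomes can be pooled; quantiles use R's default type-7
convention. Both conventions are documented here because the source
procedures leave them open.

Features anchor at their midpoint (intervals) or position (SNPs); the
focal window is the valid window whose center is nearest the anchor, and
at most one feature is kept per focal window so a single unusual window is
not counted twice. `sweep_test()` is the one-tailed (less) rank test of
duplication focal diversity against SNP focal diversity;
`low_diversity_features()` returns features in the $q = 0.05$ tail.
Centromeric and other exclusion intervals are a required configuration
input — they are genome-specific coordinates, not inferable.

### Population-wide duplication abundance

With $a_m = \sum_{i=1}^{m} 1/i$, the coalescent extrapolation treats the
population as a sample of $2N_e$ chromosomes:

$$E[S_{pop}] = S_{sample}\frac{a_{2N_e}}{a_{n-1}}, \qquad
\mathrm{Var} = \theta\, a_{2N_e} + \theta^2 \sum_{i\le 2N_e} 1/i^2,$$

with $\theta = S_{sample}/a_{n-1}$ and $S_{sample}$ first deflated by the
validated 3.9% false-positive rate. Harmonic sums are exact up to $10^6$
terms and use the asymptotic expansion beyond (continuous to better than
$10^{-9}$ relative). The assumption-free companion is Chao1,
$S_{obs} + S_1^2/(2S_2)$, with the standard variance
$S_2(r^2/2 + r^3 + r^4/4)$, $r = S_1/S_2$ — the variance expression printed
in the source is typographically garbled, so the standard form is
implemented. When $S_2 = 0$ the bias-corrected point estimate is used and
the variance is reported `NA`.

### The mutation-limits calculus

From neutral short-intron diversity $\theta_\pi$ and the per-site mutation
rate $\mu = 5.8\times10^{-9}$: $N_e = \theta_\pi/(4\mu)$; per-gene
effective rates $\mu_g = \theta_{\pi,g}/(4N_e)$ by structural class; the
probability a sweep starts from standing variation (Hermisson–Pennings,
additive),

$$P_{sgv} = 1 - e^{-\theta_\pi \ln(1 + 2N_e s)};$$

the establishment time of a deterministic sweep from new mutations
$T_e = 1/(\theta_\pi s)$ (a lower bound; 12 generations per year for year
conversions); the sojourn time $2\ln N_e$ of alleles destined for loss;
and the nearly neutral threshold $1/(4N_e)$. Shared polymorphism across a
species split of $t$ generations has probability $e^{-t/2N_e}$, and the
convergence of duplicated-gene sets across species is tested with an exact
binomial (`shared_gene_test()`), one-tailed (greater) by default since the
question is directional. `limits_report()` assembles the whole table from
the printed inputs; $N_e$ is computed unrounded by default with a
printed-rounded override for reproducing specific published cells.

**Reproduction notes.** Three families of published values are not
recoverable from the published formulas with the published inputs, and the
package deliberately reports the formula values instead: (i) the
duplication-class $P_{sgv}$ cells (e.g. 2.23% for whole-gene duplications
in *D. yakuba*, where the closed form with $\theta_\pi = 0.00277$ and
$N_e = 5.93\times10^5$ gives 2.57%); (ii) the SNP-column $P_{sgv}$ at
$s = 0.20$ for *D. simulans* (printed 30.1%, formula 30.7% — the other
three SNP cells reproduce to <0.05 percentage points); (iii) the
cross-species binomial $P = 2.812\times10^{-8}$, which is exactly R's
two-sided `binom.test(56, 478, p = 0.0525)` with the proportion
845/16082 pre-rounded to four decimals, while the directional exact upper
tail with the unrounded proportion is $2.64\times10^{-8}$. The published
"at most 6800" population total similarly exceeds the point estimate of
the printed extrapolation formula (≈5582); the estimator reports point and
variance and makes no attempt to reconstruct the upper bound.

### Residual heterozygosity HMM

Nominally inbred isofemale lines retain heterozygous tracts (segregating
inversions suppress their loss). Detection uses a two-state HMM over
per-site het/hom calls: prior $(0.5, 0.5)$, switch probability $10^{-10}$,
and emissions read state-per-row as P(het call | het state) $= \theta =
0.01$ (the scaled mutation rate) and P(het call | hom state) $= \varepsilon
= 0.001$ (genotyping error) — the only orientation in which $\theta$
functions as a 1% heterozygosity rate. Decoding is Viterbi in log space
(mandatory: the $10^{-10}$ transitions underflow linear space within a few
thousand sites), implemented in C++ for megabase sequences, with ties
broken toward the homozygous state. Observations are generated per
callable base; non-callable bases should be encoded hom (uninformative) so
genomic distances stay physical — a skip mode is available by passing only
callable positions with their coordinates.

Decoded het runs within 100 kb are clustered and segments ≥ 10 kb
retained. The source wording ("retained … clustered") reads filter-first,
but clustering exists to rescue fragmented tracts, so merge-first is the
default and both orders are exposed and tested. Segments padded by 1 kb
mask strains out of overlapping duplication calls' denominators
(`mask_features()` feeding `build_sfs()`; calls with fewer than 15 strains
remaining are dropped).

### Genome-coverage Monte Carlo

Two simulations bound how much of a genome standing duplication variation
can reach: the number of duplications (lengths resampled from the observed
distribution, starts uniform on $[0, L-\ell]$, no wraparound) needed to
cover 10/25/50/90% of a chromosome, and the fraction spanned by a fixed
number of duplications. Union coverage is tracked exactly with merged
interval lists rather than sampling grids, with a doubling-chunk bisection
to find the exact crossing draw. Chromosomes run on independent RNG
substreams derived from the chromosome name, so a chromosome simulated
alone reproduces its slice of a multi-chromosome run. The published
13.4%/9.7% unsampled-genome figures depend on the supplementary empirical
length tables and therefore reproduce only when those tables are supplied
as the sampler input.

### Duplication classification

`classify_duplications()` computes, per overlapped gene, coverage of the
genomic start-to-stop span (not spliced CDS length — "from start to stop").
A call is *chimeric* when a boundary falls strictly inside any gene span
(the breakpoint rule dominates, so a call covering gene A wholly but
ending inside gene B is chimeric), *whole-gene* when some gene is covered
≥ 90% with no internal breakpoint (the threshold applies per overlapped
gene), else *intergenic*. Genes hit by 4+ independent calls are mutational
hotspots and excluded from rate estimation. The "recruited non-coding"
class requires upstream structural annotation and is accepted as an input
label, never inferred from interval logic. Ortholog maps for cross-species
intersection must be one-to-one; inference is out of scope.

## What the synthetic data does and does not emulate

The generators reproduce the *marginal* statistical structure the methods
assume: Poisson class counts $\theta L/i$ for neutral spectra, a
configurable duplication frequency law (neutral $1/i$ by default, with a
singleton-tilted option mirroring the observed excess), Bernoulli het
calls at $\theta = 0.01$ / $\varepsilon = 0.001$ inside/outside planted
tracts, class-swap mispolarization at rate $k$, and log-uniform
duplication lengths capped at 25 kb. They do **not** simulate coalescent
genealogies with recombination or linkage between sites, mutation-rate
heterogeneity along the genome, or read-level artifacts. Passing tests
therefore certify the estimators and corrections against their own model
assumptions — they do not certify robustness to linked selection,
demography, or calling artifacts in real panels.

## Numerical choices and problem sizes

Default analysis and test scales were chosen as the smallest sizes at
which Monte-Carlo error is comfortably below the assertion tolerances: two
3 Mb arms and 1400 calls for the workflow; 1 Mb chromosomes × 100
replicates for HMM recovery (base-level recall and precision ≥ 0.95);
$10^5$ variants for the ascertainment round trip; 120-window genomes × 60
replicates for the sweep-test power study (planted troughs of one
window-level standard deviation, computed analytically from the Poisson
class model). The ascertainment round trip is scored with a Monte-Carlo
calibrated chi-square: the correction's $n/(n-i)$ weights inflate class
variances far beyond multinomial, so a naive goodness-of-fit reference
distribution would reject a correct implementation; the statistic is
instead ranked against 499 replicates simulated under the true spectrum.

Other numerical decisions: all intervals are 0-based half-open internally
(BED matches on disk; GFF3 converts on I/O); duplication sample
frequencies are counted among the 20 non-reference strains while the
ascertainment panel size is 21; the extrapolation's $a$-terms use $n = 20$;
ascertainment correction precedes projection by default (the order is an
argument); Viterbi ties resolve to homozygous; zero-variance chromosomes
are an error in z-scaling rather than silently producing NaN.

## Limitations

Beyond the synthetic-data caveats above: the estimators assume a panmictic
population at equilibrium (both study species show expansion signals, so
extrapolations are conservative bounds, not point predictions); $P_{sgv}$
assumes additivity and previously neutral standing variation; $T_e$
assumes every mutation at the locus is beneficial, making it a lower
bound; and the coverage simulations ignore mutational clustering, which
makes their genome-span answers conservative in the direction the analysis
relies on.
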