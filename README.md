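# dispersalkit

Population-genetic inference of **how far individuals disperse each
generation** and **how many migrants distant populations exchange**, for
continuously distributed sessile organisms — built for reduced-representation
(e.g. ddRAD) genotypes of reef corals, applicable to any taxon with mapped,
georeferenced samples.

## What it computes

At the neighborhood scale, the package uses isolation-by-distance (IbD)
theory. An identity-probability genetic distance between individual pairs
(analogous to F<sub>ST</sub>/(1−F<sub>ST</sub>), Rousset's â),

    d_ij = Σ_l (Qw − Qb) / Σ_l (1 − Qw),

regressed on log distance (2D habitat) or distance (1D), has slope *b* =
1/NS, the reciprocal neighborhood size. With a density *D* of breeding
adults, the per-generation axial dispersal distance is

    σ = 1/√(4πDb)   (2D)        σ = 1/√(4Db)   (1D)

with NS = 4πDσ² (2D) or 4Dσ² (1D), a neighborhood radius of 2σ, and a
Laplace dispersal kernel with mean displacement σ/√2. Slope uncertainty
(locus bootstrap), permutation significance, and Monte-Carlo propagation of
slope × density uncertainty into σ are included.

At the range scale, it builds folded two-population joint allele frequency
spectra (singletons/doubletons masked) and converts fitted diffusion-model
parameters (θ, ν₁, ν₂, M₁₂, M₂₁, T) into natural units: N<sub>ref</sub> =
θ/(4μL), Nₑᵢ = νᵢN<sub>ref</sub>, mᵢⱼ = Mᵢⱼ/(2N<sub>ref</sub>), Nₑm = Nₑ·m,
and divergence time in years.

Supporting modules: VCF input (variant-only and all-sites dialects), the
standard RADseq filtering cascade, clone (ramet) detection by allelic
similarity, VIF-based linkage pruning, windowed nucleotide diversity with
invariant sites, expected heterozygosity and F<sub>IS</sub>, rarefied
allelic richness and private alleles, pairwise Weir–Cockerham F<sub>ST</sub>,
LD-based contemporary Nₑ (Burrows' composite r²), and a forward
continuous-space simulator with known ground truth that backs the test
suite.

## Worked example

Simulate a population with known dispersal (σ = 20 m, 600 colonies on a
600 m square), then run the IbD chain:

```r
library(dispersalkit)

sim <- simulate_spatial(model = "2D", extent = 600, n_individuals = 600,
                        sigma_true = 20, n_loci = 300, n_generations = 150,
                        n_sample = 150, seed = 42)
gd  <- genetic_distance_matrix(sim$gm)
xd  <- geographic_distance_matrix(sim$samples, mode = "planar")
fit <- ibd_regression(gd, xd, model = "2D", min_distance = 1, max_distance = 300)
fit
#> IbD fit (2D): b = 0.253 [NA, NA], intercept = -0.8397, n_pairs = 4926, p = NA

sigma_hat <- sigma_from_slope(fit$b, sim$truth$density, model = "2D")
signif(sigma_hat, 3)
#> [1] 13.7
```

The slope is steep because the simulated neighborhood is tiny (NS = 1/b ≈ 4
colonies); the recovered σ of 13.7 m is within a factor of two of the true
20 m, which is the accuracy the method is calibrated to deliver. From a
fitted σ, the derived quantities are one-liners:

```r
neighborhood_radius(sigma_hat)          # 2*sigma, meters
laplace_kernel(sigma_hat)$mean_distance # sigma/sqrt(2), meters
```

With real data, replace the simulator with `read_genotypes("snps.vcf.gz")` +
`read_sample_table("samples.csv")`, estimate densities from census plots
(`census_density()`) or LD-Nₑ over reef area (`effective_density()`), and
propagate uncertainty with `propagate_sigma()`. `run_pipeline(config, dir)`
chains every stage from a single JSON/list configuration and writes a
reproducibility manifest. See the vignette
(`vignettes/dispersal-and-gene-flow.Rmd`) for the model, assumptions and
design decisions.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantity from
scratch — the 2D axial dispersal distance implied by an IbD slope of 0.0032
(per log-meter) and a census density of 0.046 colonies/m² — by running the
installed package, and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
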