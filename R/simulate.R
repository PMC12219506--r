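#' Forward continuous-space population simulation
#'
#' Non-overlapping generations at constant size N on a line (1D) or square
#' (2D) of the given extent. Each offspring picks a first parent uniformly at
#' random, takes its natal position as the parent position plus one kernel
#' draw per axis (axial standard deviation `sigma_true`, reflected at the
#' boundaries), and picks its second parent with probability proportional to
#' the kernel density at that parent's distance from the natal position — so
#' both parent-offspring displacements have axial sd ~ sigma_true, matching
#' the sigma that isolation-by-distance theory estimates. Biallelic loci
#' mutate symmetrically at `mutation_rate` per allele copy per generation.
#'
#' @param model `"2D"` or `"1D"`.
#' @param extent habitat side length / line length, meters.
#' @param n_individuals constant population size N.
#' @param sigma_true axial dispersal distance, meters (0 allowed: offspring
#'   stay at the parent position).
#' @param kernel `"gaussian"` or `"laplace"` per-axis displacement kernel.
#' @param n_loci number of biallelic loci (transmitted independently — free
#'   recombination).
#' @param mutation_rate symmetric per-copy per-generation flip rate.
#' @param n_generations generations to run after the random initial state.
#' @param n_sample individuals genotyped at the final generation (default
#'   all).
#' @param seed integer RNG seed.
#' @return List: `gm` (a [genotype_matrix()], one contig per locus),
#'   `samples` (data.frame sample, population, site, x, y), `truth` (list of
#'   all generator parameters plus the realized census density).
#' @export
simulate_spatial <- function(model = c("2D", "1D"), extent = 1000,
                             n_individuals = 2000, sigma_true = 20,
                             kernel = c("gaussian", "laplace"),
                             n_loci = 500, mutation_rate = 1e-3,
                             n_generations = 200, n_sample = NULL, seed = 1) {
  model <- match.arg(model)
  kernel <- match.arg(kernel)
  stopifnot(extent > 0, n_individuals >= 2, sigma_true >= 0, n_loci >= 1,
            mutation_rate >= 0, mutation_rate < 1, n_generations >= 1)
  if (sigma_true >= extent) {
    warning("sigma_true >= extent: expect panmixia, no IbD signal")
  }
  set.seed(seed)
  N <- n_individuals
  ndim <- if (model == "2D") 2L else 1L
  pos <- matrix(stats::runif(N * ndim, 0, extent), N, ndim)
  p0 <- stats::runif(n_loci, 0.2, 0.8)
  geno <- matrix(stats::rbinom(N * n_loci, 2, rep(p0, each = N)), N, n_loci)

  kdraw <- function(n) {
    if (kernel == "gaussian") stats::rnorm(n, 0, sigma_true)
    else laplace_kernel(max(sigma_true, .Machine$double.eps))$rdraw(n) *
      (sigma_true > 0)
  }
  reflect <- function(x) {
    # fold into [0, extent] (repeat for rare multi-bounce draws)
    while (any(x < 0 | x > extent)) {
      x <- ifelse(x < 0, -x, x)
      x <- ifelse(x > extent, 2 * extent - x, x)
    }
    x
  }

  for (gen in seq_len(n_generations)) {
    par1 <- sample.int(N, N, replace = TRUE)
    newpos <- pos[par1, , drop = FALSE] +
      matrix(kdraw(N * ndim), N, ndim)
    newpos <- apply(newpos, 2, reflect)
    if (!is.matrix(newpos)) newpos <- matrix(newpos, N, ndim)
    par2 <- pick_kernel_parent(newpos, pos, sigma_true, kernel)
    # transmit one allele from each parent, per locus
    h1 <- (matrix(stats::runif(N * n_loci), N, n_loci) < geno[par1, , drop = FALSE] / 2) + 0L
    h2 <- (matrix(stats::runif(N * n_loci), N, n_loci) < geno[par2, , drop = FALSE] / 2) + 0L
    geno <- h1 + h2
    if (mutation_rate > 0) {
      flip01 <- matrix(stats::rbinom(N * n_loci, 2L - geno, mutation_rate), N, n_loci)
      flip10 <- matrix(stats::rbinom(N * n_loci, geno, mutation_rate), N, n_loci)
      geno <- geno + flip01 - flip10
    }
    pos <- newpos
  }

  take <- if (is.null(n_sample)) seq_len(N) else sample.int(N, min(n_sample, N))
  ids <- sprintf("sim%04d", seq_along(take))
  loci <- data.frame(contig = sprintf("locus%04d", seq_len(n_loci)),
                     pos = 1L, ref = "A", alt = "T")
  gm <- genotype_matrix(geno[take, , drop = FALSE], loci, samples = ids)
  samples <- data.frame(sample = ids, population = "sim", site = "sim",
                        x = pos[take, 1],
                        y = if (ndim == 2) pos[take, 2] else 0)
  truth <- list(model = model, extent = extent, n_individuals = N,
                sigma_true = sigma_true, kernel = kernel, n_loci = n_loci,
                mutation_rate = mutation_rate, n_generations = n_generations,
                seed = seed,
                density = if (model == "2D") N / extent^2 else N / extent)
  list(gm = gm, samples = samples, truth = truth)
}

# second parent chosen with probability proportional to the kernel density at
# its distance from each natal position
pick_kernel_parent <- function(natal, parent_pos, sigma, kernel) {
  N <- nrow(natal)
  if (sigma <= 0) {
    # degenerate kernel: nearest parent (the first parent itself, typically)
    return(vapply(seq_len(N), function(i) {
      d2 <- rowSums((parent_pos - matrix(natal[i, ], nrow(parent_pos),
                                         ncol(parent_pos), byrow = TRUE))^2)
      which.min(d2)
    }, 0L))
  }
  out <- integer(N)
  pp <- parent_pos
  for (i in seq_len(N)) {
    d2 <- (pp[, 1] - natal[i, 1])^2
    if (ncol(pp) == 2) d2 <- d2 + (pp[, 2] - natal[i, 2])^2
    w <- if (kernel == "gaussian") exp(-d2 / (2 * sigma^2))
         else exp(-sqrt(2 * d2) / sigma)
    s <- sum(w)
    if (s <= 0) w <- rep(1, nrow(pp)) else w <- w / s
    out[i] <- sample.int(nrow(pp), 1L, prob = w)
  }
  out
}

#' Two-deme Wright-Fisher divergence with asymmetric migration
#'
#' Both demes start from a common ancestral allele-frequency pool, then
#' evolve as Wright-Fisher populations of constant sizes ne1, ne2 exchanging
#' migrants: each generation a fraction `m12` of deme 1's offspring draw both
#' parents from deme 2, and vice versa for `m21`. Loci are independent
#' (free recombination), with optional symmetric mutation.
#'
#' @param ne1,ne2 deme sizes (diploid individuals, >= 2).
#' @param m12 fraction of deme 1 replaced by migrants from deme 2 per
#'   generation (in [0, 1)); `m21` likewise into deme 2.
#' @param n_loci number of biallelic loci.
#' @param n_generations generations since divergence.
#' @param sample_sizes diploid samples taken per deme at the end.
#' @param mutation_rate symmetric per-copy flip rate (default 0).
#' @param seed RNG seed.
#' @return List: `gm` (samples from both demes; one contig per locus),
#'   `pop_map` (data.frame sample, population), `truth`.
#' @export
simulate_two_demes <- function(ne1 = 200, ne2 = 200, m12 = 0.005, m21 = 0.005,
                               n_loci = 2000, n_generations = 300,
                               sample_sizes = c(30, 30), mutation_rate = 0,
                               seed = 1) {
  stopifnot(ne1 >= 2, ne2 >= 2, m12 >= 0, m12 < 1, m21 >= 0, m21 < 1,
            n_loci >= 1, n_generations >= 1)
  set.seed(seed)
  p0 <- stats::runif(n_loci, 0.1, 0.9)
  g1 <- matrix(stats::rbinom(ne1 * n_loci, 2, rep(p0, each = ne1)), ne1, n_loci)
  g2 <- matrix(stats::rbinom(ne2 * n_loci, 2, rep(p0, each = ne2)), ne2, n_loci)

  offspring <- function(gs, n) {
    # one haploid allele from each of two random parents in the source deme
    if (n == 0) return(NULL)
    h <- function() {
      par <- sample.int(nrow(gs), n, replace = TRUE)
      (matrix(stats::runif(n * ncol(gs)), n, ncol(gs)) < gs[par, , drop = FALSE] / 2) + 0L
    }
    h() + h()
  }
  mutate <- function(g, u) {
    if (u <= 0) return(g)
    g + matrix(stats::rbinom(length(g), 2L - g, u), nrow(g)) -
      matrix(stats::rbinom(length(g), g, u), nrow(g))
  }
  for (gen in seq_len(n_generations)) {
    mig1 <- stats::runif(ne1) < m12   # deme-1 offspring with deme-2 parents
    mig2 <- stats::runif(ne2) < m21
    n1m <- sum(mig1); n2m <- sum(mig2)
    new1 <- rbind(offspring(g1, ne1 - n1m), offspring(g2, n1m))
    new2 <- rbind(offspring(g2, ne2 - n2m), offspring(g1, n2m))
    g1 <- mutate(new1, mutation_rate)
    g2 <- mutate(new2, mutation_rate)
  }
  s1 <- sample.int(ne1, min(sample_sizes[1], ne1))
  s2 <- sample.int(ne2, min(sample_sizes[2], ne2))
  geno <- rbind(g1[s1, , drop = FALSE], g2[s2, , drop = FALSE])
  ids <- sprintf("d%d_%03d", rep(1:2, c(length(s1), length(s2))),
                 c(seq_along(s1), seq_along(s2)))
  loci <- data.frame(contig = sprintf("locus%05d", seq_len(n_loci)),
                     pos = 1L, ref = "A", alt = "T")
  gm <- genotype_matrix(geno, loci, samples = ids)
  pop_map <- data.frame(sample = ids,
                        population = rep(c("deme1", "deme2"),
                                         c(length(s1), length(s2))))
  truth <- list(ne1 = ne1, ne2 = ne2, m12 = m12, m21 = m21, n_loci = n_loci,
                n_generations = n_generations, mutation_rate = mutation_rate,
                seed = seed)
  list(gm = gm, pop_map = pop_map, truth = truth)
}

#' Single-deme Wright-Fisher simulation (for LD-Ne validation)
#'
#' @param ne diploid population size.
#' @param n_loci independent biallelic loci.
#' @param n_generations generations to run.
#' @param n_sample diploid individuals sampled at the end.
#' @param seed RNG seed.
#' @return List: `gm`, `truth`.
#' @export
simulate_wright_fisher <- function(ne = 100, n_loci = 2000,
                                   n_generations = 30, n_sample = 50,
                                   seed = 1) {
  sim <- simulate_two_demes(ne1 = ne, ne2 = 2, m12 = 0, m21 = 0,
                            n_loci = n_loci, n_generations = n_generations,
                            sample_sizes = c(n_sample, 0), seed = seed)
  keep <- sim$pop_map$population == "deme1"
  list(gm = gm_subset(sim$gm, samples = which(keep)),
       truth = list(ne = ne, n_loci = n_loci,
                    n_generations = n_generations, seed = seed))
}

#' Inject clonal duplicates and random missingness
#'
#' Appends near-duplicate copies of randomly chosen samples with a planted
#' genotype discordance rate, then masks calls at random. Returns the
#' provenance of every planted artifact so detection can be scored.
#'
#' @param gm a [genotype_matrix()].
#' @param clone_pairs number of duplicates to plant (<= number of samples).
#' @param discordance fraction of loci at which a duplicate's genotype is
#'   redrawn at random (in [0, 1)).
#' @param missing_rate fraction of all calls set to missing (in [0, 1)).
#' @param seed RNG seed.
#' @return List: `gm` (augmented), `planted` (data.frame original, clone),
#'   `missing_rate`.
#' @export
inject_artifacts <- function(gm, clone_pairs = 0, discordance = 0,
                             missing_rate = 0, seed = 1) {
  stopifnot(discordance >= 0, discordance < 1,
            missing_rate >= 0, missing_rate < 1)
  if (clone_pairs > length(gm$samples)) stop("clone_pairs exceeds sample count")
  set.seed(seed)
  calls <- gm$calls
  samples <- gm$samples
  planted <- NULL
  if (clone_pairs > 0) {
    src <- sample(seq_along(gm$samples), clone_pairs)
    clones <- gm$calls[src, , drop = FALSE]
    if (discordance > 0) {
      flip <- matrix(stats::runif(length(clones)) < discordance, nrow(clones))
      clones[flip] <- sample(0:2, sum(flip), replace = TRUE)
    }
    clone_ids <- paste0(gm$samples[src], "_clone")
    calls <- rbind(calls, clones)
    samples <- c(samples, clone_ids)
    planted <- data.frame(original = gm$samples[src], clone = clone_ids)
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < missing_rate, nrow(calls))
    calls[drop] <- NA_integer_
  }
  out <- genotype_matrix(calls, gm$loci, samples = samples)
  list(gm = out, planted = planted, missing_rate = missing_rate)
}

#' Write simulated data as VCF + samples.csv + truth.json
#'
#' @param sim output of [simulate_spatial()] or [simulate_two_demes()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(sim$gm, file.path(dir, "genotypes.vcf"))
  meta <- if (!is.null(sim$samples)) sim$samples else sim$pop_map
  utils::write.csv(meta, file.path(dir, "samples.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
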