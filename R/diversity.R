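#' Windowed nucleotide diversity with invariant sites
#'
#' Per site, with k non-missing allele copies of which c carry the alternate
#' allele, the number of differing unordered copy pairs is c*(k-c) and the
#' number of comparisons is choose(k, 2). Windows of `window` bp (per contig,
#' anchored at position 1) report pi = sum(diffs)/sum(comps); the combined
#' value is the ratio of total sums, i.e. count-weighted across windows, which
#' makes it invariant to the window partition. Omitting invariant sites
#' inflates pi, hence the all-sites genotype matrix input.
#'
#' @param gm an all-sites [genotype_matrix()].
#' @param pop optional character vector of sample ids (default all samples).
#' @param window window size in bp (default 1000).
#' @return List: `combined` (overall pi), `windows` (data.frame contig,
#'   start, end, n_sites, diffs, comps, pi; pi is `NA` where a window has no
#'   comparisons).
#' @export
pi_windowed <- function(gm, pop = NULL, window = 1000) {
  stopifnot(window >= 1)
  if (!is.null(pop)) gm <- gm_subset(gm, samples = pop)
  g <- gm$calls
  k <- 2 * colSums(!is.na(g))
  c_alt <- colSums(g, na.rm = TRUE)
  diffs <- c_alt * (k - c_alt)
  comps <- k * (k - 1) / 2
  win <- (gm$loci$pos - 1) %/% window
  key <- paste(gm$loci$contig, win, sep = "\r")
  agg <- rowsum(cbind(diffs, comps, n_sites = 1), key)
  ord <- rownames(agg)
  parts <- strsplit(ord, "\r", fixed = TRUE)
  wdf <- data.frame(contig = vapply(parts, `[`, "", 1),
                    start = as.numeric(vapply(parts, `[`, "", 2)) * window + 1,
                    n_sites = agg[, "n_sites"],
                    diffs = agg[, "diffs"], comps = agg[, "comps"])
  wdf$end <- wdf$start + window - 1
  wdf$pi <- ifelse(wdf$comps > 0, wdf$diffs / wdf$comps, NA_real_)
  rownames(wdf) <- NULL
  total_comps <- sum(comps)
  list(combined = if (total_comps > 0) sum(diffs) / total_comps else NA_real_,
       windows = wdf[, c("contig", "start", "end", "n_sites", "diffs", "comps", "pi")])
}

#' Expected heterozygosity and inbreeding coefficient
#'
#' Computed on loci with no missing calls within the population (a stricter
#' per-population mask: missing data bias per-site heterozygosity). Per site,
#' He = 1 - p^2 - q^2 and Ho = fraction of heterozygotes. `he` is the mean He
#' over all retained sites, invariant sites contributing 0 (so the value is
#' per callable site); `fis` = 1 - mean(Ho)/mean(He) over variant sites with
#' He > 0 (a ratio of means, avoiding per-site 0/0).
#'
#' @param gm an all-sites [genotype_matrix()].
#' @param pop optional sample id subset.
#' @return List: `he`, `fis` (`NA` when there is no variant site), `n_sites`
#'   (retained), `n_variant`.
#' @export
he_fis <- function(gm, pop = NULL) {
  if (!is.null(pop)) gm <- gm_subset(gm, samples = pop)
  g <- gm$calls
  complete <- colSums(is.na(g)) == 0
  g <- g[, complete, drop = FALSE]
  if (ncol(g) == 0) return(list(he = NA_real_, fis = NA_real_, n_sites = 0L, n_variant = 0L))
  p <- colMeans(g) / 2
  he_site <- 1 - p^2 - (1 - p)^2
  ho_site <- colMeans(g == 1L)
  variant <- he_site > 0
  fis <- if (any(variant)) 1 - mean(ho_site[variant]) / mean(he_site[variant]) else NA_real_
  list(he = mean(he_site), fis = fis,
       n_sites = ncol(g), n_variant = sum(variant))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of g gene
#' copies: per locus AR = sum over alleles of 1 - C(N - N_k, g)/C(N, g),
#' where N is the number of non-missing copies and N_k the count of allele k.
#' Loci with fewer than g copies are dropped (and counted).
#'
#' @param gm a [genotype_matrix()] of biallelic loci.
#' @param pop optional sample id subset.
#' @param g standardized gene-copy count (>= 1).
#' @return List: `ar` (mean over usable loci), `per_locus`, `n_dropped`.
#' @export
allelic_richness <- function(gm, pop = NULL, g) {
  stopifnot(g >= 1)
  if (!is.null(pop)) gm <- gm_subset(gm, samples = pop)
  cnt <- allele_counts(gm)
  usable <- cnt$total >= g
  N <- cnt$total[usable]
  Nk <- cnt$alt[usable]
  ar <- rarefied_presence(Nk, N, g) + rarefied_presence(N - Nk, N, g)
  list(ar = mean(ar), per_locus = ar, n_dropped = sum(!usable))
}

# P(allele with Nk copies out of N appears in a subsample of g copies)
rarefied_presence <- function(Nk, N, g) {
  1 - exp(lchoose(N - Nk, g) - lchoose(N, g))
}

#' Rarefied private allele counts
#'
#' For each population j, locus and allele k, the expected contribution of a
#' private allele in standardized subsamples of g copies from every
#' population: P(present in j) * prod over other populations of P(absent).
#' Loci with fewer than g non-missing copies in any population are dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param pop_map named character vector or data.frame(sample, population)
#'   assigning samples to populations (>= 2 populations).
#' @param g standardized gene-copy count.
#' @return Named numeric vector: expected rarefied private allelic richness
#'   per population (sum over loci and alleles), with attribute `n_loci`.
#' @export
private_alleles <- function(gm, pop_map, g) {
  pops <- pop_assignments(gm, pop_map)
  lev <- unique(pops)
  if (length(lev) < 2) stop("need at least two populations")
  counts <- lapply(lev, function(p) allele_counts(gm_subset(gm, samples = which(pops == p))))
  L <- nrow(gm$loci)
  N <- matrix(vapply(counts, function(x) x$total, numeric(L)), nrow = L)
  usable <- rowSums(N >= g) == length(lev)
  if (!any(usable)) stop("no locus has >= g copies in every population")
  out <- numeric(length(lev))
  names(out) <- lev
  for (allele in c("alt", "ref")) {
    Nk <- matrix(vapply(seq_along(lev), function(i) {
      x <- counts[[i]]
      if (allele == "alt") x$alt else x$total - x$alt
    }, numeric(L)), nrow = L)
    pres <- vapply(seq_along(lev), function(i) {
      rarefied_presence(Nk[usable, i], N[usable, i], g)
    }, numeric(sum(usable)))
    pres <- matrix(pres, ncol = length(lev))
    for (i in seq_along(lev)) {
      absent_others <- apply((1 - pres)[, -i, drop = FALSE], 1, prod)
      out[i] <- out[i] + sum(pres[, i] * absent_others)
    }
  }
  attr(out, "n_loci") <- sum(usable)
  out
}

pop_assignments <- function(gm, pop_map) {
  if (is.data.frame(pop_map)) {
    pops <- pop_map$population[match(gm$samples, pop_map$sample)]
  } else {
    pops <- unname(pop_map[gm$samples])
  }
  if (anyNA(pops)) stop("population missing for sample ",
                        gm$samples[which(is.na(pops))[1]])
  as.character(pops)
}

#' Pairwise Weir-Cockerham FST
#'
#' The multi-locus ratio-of-sums theta estimator (Weir & Cockerham 1984) for
#' each pair of populations, using per-locus variance components computed
#' from allele frequencies and observed heterozygosities with per-locus
#' non-missing sample sizes. Negative estimates are reported as computed.
#'
#' @param gm a [genotype_matrix()] of biallelic loci.
#' @param pop_map see [private_alleles()]; each population needs >= 2
#'   samples.
#' @return Symmetric matrix of theta values (diagonal `NA`).
#' @export
pairwise_fst <- function(gm, pop_map) {
  pops <- pop_assignments(gm, pop_map)
  lev <- unique(pops)
  if (length(lev) < 2) stop("need at least two populations")
  if (any(table(pops) < 2)) stop("every population needs at least two samples")
  out <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)) for (j in seq_along(lev)) if (i < j) {
    th <- wc_theta_two_pops(gm_subset(gm, samples = which(pops == lev[i])),
                            gm_subset(gm, samples = which(pops == lev[j])))
    out[i, j] <- out[j, i] <- th
  }
  out
}

#' Weir-Cockerham theta for two populations (multi-locus ratio of sums)
#'
#' @param gm1,gm2 `genotype_matrix` objects over the same loci.
#' @return Scalar theta.
#' @export
wc_theta_two_pops <- function(gm1, gm2) {
  stopifnot(nrow(gm1$loci) == nrow(gm2$loci))
  comp <- function(gm) {
    g <- gm$calls
    n <- colSums(!is.na(g))
    p <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  a1 <- comp(gm1); a2 <- comp(gm2)
  ok <- a1$n >= 1 & a2$n >= 1 & !is.na(a1$p) & !is.na(a2$p)
  if (!any(a1$n > 0)) stop("population 1 has no non-missing calls")
  if (!any(a2$n > 0)) stop("population 2 has no non-missing calls")
  r <- 2
  n1 <- a1$n[ok]; n2 <- a2$n[ok]
  p1 <- a1$p[ok]; p2 <- a2$p[ok]
  h1 <- a1$h[ok]; h2 <- a2$h[ok]
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  usable <- is.finite(a) & is.finite(b) & is.finite(cc) & nbar > 1 & nc > 0
  sum(a[usable]) / sum((a + b + cc)[usable])
}

#' Per-population diversity report
#'
#' One row per population with the standard within-population metrics:
#' nucleotide diversity (all-sites pi), expected heterozygosity, inbreeding
#' coefficient, rarefied allelic richness and rarefied private allele count.
#' Populations with fewer than `min_n` samples are excluded, mirroring common
#' practice of reporting diversity only where sample sizes support it.
#'
#' @param gm an all-sites [genotype_matrix()].
#' @param pop_map see [private_alleles()].
#' @param window pi window size in bp.
#' @param g rarefaction gene-copy count; `"auto"` uses
#'   2 * (smallest included population size - 1).
#' @param min_n minimum samples per included population (default 8).
#' @return data.frame: population, n, pi, he, fis, ar, pa.
#' @export
diversity_report <- function(gm, pop_map, window = 1000, g = "auto", min_n = 8) {
  pops <- pop_assignments(gm, pop_map)
  tab <- table(pops)
  keep_pops <- names(tab)[tab >= min_n]
  if (length(keep_pops) == 0) stop("no population reaches min_n samples")
  if (identical(g, "auto")) g <- 2 * (min(tab[keep_pops]) - 1)
  sub <- gm_subset(gm, samples = which(pops %in% keep_pops))
  subpops <- pops[pops %in% keep_pops]
  variant <- gm_subset(sub, loci = which(!sub$invariant))
  pa <- if (length(keep_pops) >= 2) {
    private_alleles(variant, stats::setNames(subpops, sub$samples), g = g)
  } else stats::setNames(rep(NA_real_, length(keep_pops)), keep_pops)
  rows <- lapply(keep_pops, function(p) {
    sel <- which(subpops == p)
    hf <- he_fis(sub, pop = sel)
    data.frame(population = p, n = length(sel),
               pi = pi_windowed(sub, pop = sel, window = window)$combined,
               he = hf$he, fis = hf$fis,
               ar = allelic_richness(variant, pop = sel, g = g)$ar,
               pa = unname(pa[p]))
  })
  out <- do.call(rbind, rows)
  attr(out, "g") <- g
  out
}
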