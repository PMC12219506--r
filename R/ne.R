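#' Burrows' composite LD across locus pairs
#'
#' For each pair of loci on different contigs (approximately unlinked), the
#' composite gametic disequilibrium is estimated from unphased genotype dose
#' columns X, Y in \{0, 1, 2\} as
#'
#'   Delta = n/(n-1) * ( mean(X*Y)/2 - 2*p*q )
#'
#' with p, q the alt allele frequencies at the two loci over jointly
#' non-missing samples, and the squared composite correlation
#' r^2 = Delta^2 / ((p(1-p) + D_A)(q(1-q) + D_B)), where D_A and D_B are the
#' within-locus Hardy-Weinberg disequilibria (homozygote excess) — the
#' denominator form whose sampling expectation under independence matches
#' the published 1/S + 3.19/S^2. The summary is the mean r^2 across pairs
#' weighted by the pairwise sample size.
#'
#' @param gm a [genotype_matrix()].
#' @param pop optional sample id subset (a single population).
#' @param maf_cutoff loci with overall minor allele frequency below this are
#'   excluded (default 0.02).
#' @param unlinked_only when `TRUE` (default), use only pairs of loci on
#'   different contigs.
#' @return List: `r2_mean` (weighted), `n_pairs`, `s_harmonic` (harmonic mean
#'   pairwise sample size) and `n_loci`.
#' @export
burrows_r2 <- function(gm, pop = NULL, maf_cutoff = 0.02, unlinked_only = TRUE) {
  if (!is.null(pop)) gm <- gm_subset(gm, samples = pop)
  cnt <- allele_counts(gm)
  maf <- ifelse(cnt$total > 0, pmin(cnt$alt, cnt$total - cnt$alt) / cnt$total, 0)
  keep <- maf >= maf_cutoff & cnt$total >= 4
  if (sum(keep) < 2) stop("fewer than two loci pass the MAF cutoff")
  gm <- gm_subset(gm, loci = which(keep))
  g <- gm$calls
  m <- (!is.na(g)) + 0
  g0 <- g; g0[is.na(g0)] <- 0L
  n <- crossprod(m)                        # pairwise sample sizes
  sxy <- crossprod(g0)                     # sum X*Y over joint samples
  px <- crossprod(g0, m) / (2 * n)         # p of row locus within joint samples
  py <- t(px)
  hom <- ((g == 2L) & !is.na(g)) + 0
  hx <- crossprod(hom, m) / n              # alt-homozygote freq, joint samples
  dax <- hx - px^2                         # within-locus HW disequilibrium
  day <- t(dax)
  delta <- (n / (n - 1)) * (sxy / (2 * n) - 2 * px * py)
  denom <- (px * (1 - px) + dax) * (py * (1 - py) + day)
  r2 <- delta^2 / denom
  use <- upper.tri(r2) & n >= 2 & denom > 0
  if (unlinked_only) {
    same <- outer(gm$loci$contig, gm$loci$contig, "==")
    use <- use & !same
  }
  if (!any(use)) stop("no qualifying locus pairs")
  w <- n[use]
  list(r2_mean = sum(r2[use] * w) / sum(w),
       n_pairs = sum(use),
       s_harmonic = length(w) / sum(1 / w),
       n_loci = ncol(g))
}

#' LD effective population size from mean composite r^2
#'
#' Subtracts the sampling expectation of r^2 from the observed weighted mean
#' and inverts the drift relation for a randomly mating population. With
#' harmonic mean sample size S >= 30: E[r2_sample] = 1/S + 3.19/S^2 and
#' Ne = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2'); for S < 30 the small-sample
#' constants are E[r2_sample] = 0.0018 + 0.907/S + 4.44/S^2 and
#' Ne = (0.308 + sqrt(0.308^2 - 2.08 r2'))/(2 r2') (Waples 2006 bias-corrected
#' forms). r2' <= 0 or a negative discriminant yields `Inf` (a drift signal
#' too small to resolve).
#'
#' @param r2_mean weighted mean composite r^2 (see [burrows_r2()]).
#' @param s_harmonic harmonic mean sample size.
#' @return List of class `ne_estimate`: `ne` (possibly `Inf`), `r2_mean`,
#'   `r2_sample_expectation`, `r2_drift`, `s_harmonic`.
#' @export
ne_from_r2 <- function(r2_mean, s_harmonic) {
  stopifnot(r2_mean >= 0, s_harmonic > 0)
  if (s_harmonic >= 30) {
    exp_samp <- 1 / s_harmonic + 3.19 / s_harmonic^2
    aa <- 1 / 3; bb <- 1 / 9; cc <- 2.76
  } else {
    exp_samp <- 0.0018 + 0.907 / s_harmonic + 4.44 / s_harmonic^2
    aa <- 0.308; bb <- 0.308^2; cc <- 2.08
  }
  r2p <- r2_mean - exp_samp
  ne <- if (r2p <= 0 || bb - cc * r2p < 0) {
    if (r2p > 0) warning("negative discriminant; Ne reported as infinite")
    Inf
  } else {
    (aa + sqrt(bb - cc * r2p)) / (2 * r2p)
  }
  structure(list(ne = ne, r2_mean = r2_mean, r2_sample_expectation = exp_samp,
                 r2_drift = r2p, s_harmonic = s_harmonic),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("LD-Ne: %.4g (r2 = %.5g, sampling = %.5g, S = %.1f)\n",
              x$ne, x$r2_mean, x$r2_sample_expectation, x$s_harmonic))
  invisible(x)
}

#' One-call LD-Ne estimate for a population
#'
#' @inheritParams burrows_r2
#' @return An `ne_estimate` with `n_pairs` added.
#' @export
estimate_ne <- function(gm, pop = NULL, maf_cutoff = 0.02, unlinked_only = TRUE) {
  r2 <- burrows_r2(gm, pop = pop, maf_cutoff = maf_cutoff,
                   unlinked_only = unlinked_only)
  est <- ne_from_r2(r2$r2_mean, r2$s_harmonic)
  est$n_pairs <- r2$n_pairs
  est
}
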