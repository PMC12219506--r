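#' Site-level filtering cascade
#'
#' Applies the standard RADseq site filters in a fixed, logged order:
#' individual calls with read depth outside `[depth_min, depth_max]` are set
#' to missing first, then sites failing the missingness, minor allele count
#' (MAC) and minor allele frequency (MAF) thresholds are dropped. MAC and MAF
#' are computed on the minor allele over non-missing calls and apply to
#' variant sites only; invariant sites (all-sites dialect) are subject to the
#' depth and missingness filters. A site passes MAC/MAF when the minor-allele
#' statistic is greater than or equal to the threshold (an exact 50:50 tie is
#' a pass).
#'
#' @param gm a [genotype_matrix()].
#' @param mac_min minimum minor allele count (default 3).
#' @param depth_min,depth_max per-call read depth bounds (defaults 5, 100);
#'   ignored when the matrix carries no depths.
#' @param max_site_missing maximum tolerated fraction of missing calls per
#'   site (default 0.5, strict: a site is dropped when missingness exceeds
#'   the threshold).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return A filtered `genotype_matrix` with attribute `filter_log`, a
#'   data.frame of sites remaining after each step.
#' @export
filter_sites <- function(gm, mac_min = 3, depth_min = 5, depth_max = 100,
                         max_site_missing = 0.5, maf_min = 0.01) {
  stopifnot(mac_min >= 0, depth_min >= 0, depth_max >= depth_min,
            max_site_missing >= 0, max_site_missing <= 1, maf_min >= 0)
  log <- data.frame(step = "input", n_sites = nrow(gm$loci))

  if (!is.null(gm$depths)) {
    bad <- !is.na(gm$depths) & (gm$depths < depth_min | gm$depths > depth_max)
    gm$calls[bad] <- NA_integer_
  }
  log <- rbind(log, data.frame(step = "depth_mask", n_sites = nrow(gm$loci)))

  keep <- site_missingness(gm) <= max_site_missing
  gm <- gm_subset(gm, loci = keep)
  log <- rbind(log, data.frame(step = "missingness", n_sites = nrow(gm$loci)))

  cnt <- allele_counts(gm)
  minor_count <- pmin(cnt$alt, cnt$total - cnt$alt)
  keep <- gm$invariant | minor_count >= mac_min
  gm <- gm_subset(gm, loci = keep)
  log <- rbind(log, data.frame(step = "mac", n_sites = nrow(gm$loci)))

  cnt <- allele_counts(gm)
  maf <- ifelse(cnt$total > 0, pmin(cnt$alt, cnt$total - cnt$alt) / cnt$total, 0)
  keep <- gm$invariant | maf >= maf_min
  gm <- gm_subset(gm, loci = keep)
  log <- rbind(log, data.frame(step = "maf", n_sites = nrow(gm$loci)))

  if (nrow(gm$loci) == 0) stop("no sites survive filtering")
  attr(gm, "filter_log") <- log
  gm
}

allele_counts <- function(gm) {
  list(alt = colSums(gm$calls, na.rm = TRUE),
       total = 2L * colSums(!is.na(gm$calls)))
}

#' Remove samples with excess missing data
#'
#' @param gm a [genotype_matrix()].
#' @param max_sample_missing samples whose missing-call fraction strictly
#'   exceeds this are removed (a sample at exactly the threshold is kept).
#' @return A `genotype_matrix` with attribute `removed_samples`.
#' @export
filter_samples <- function(gm, max_sample_missing = 0.3) {
  stopifnot(max_sample_missing >= 0, max_sample_missing <= 1)
  miss <- sample_missingness(gm)
  keep <- miss <= max_sample_missing
  if (!any(keep)) stop("all samples exceed the missingness threshold")
  out <- gm_subset(gm, samples = which(keep))
  attr(out, "removed_samples") <- gm$samples[!keep]
  out
}
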