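#' Individual pairwise genetic distance (Rousset's a-hat style)
#'
#' An identity-probability estimator of genetic distance between diploid
#' individuals, analogous to FST/(1 - FST) for individual pairs. For a pair
#' (i, j) and locus l, let Qw(l) be the mean over the two individuals of the
#' within-individual identity (1 if homozygous, 0 if heterozygous) and Qb(l)
#' the mean identity over the four cross-individual allele pairings. The
#' distance is a ratio of sums over loci non-missing in both individuals:
#'
#'   d_ij = sum_l (Qw - Qb) / sum_l (1 - Qw)
#'
#' Under isolation by distance this quantity is expected to increase linearly
#' with distance (1D habitat) or log-distance (2D habitat), with slope
#' 1/(neighborhood size).
#'
#' @param gm a [genotype_matrix()] of biallelic loci, at least two samples.
#' @return A symmetric matrix of distances; `NA` where a pair shares no locus
#'   or both members are homozygous at every shared locus (zero denominator).
#'   The number of such excluded pairs is in attribute `n_undefined`.
#' @export
genetic_distance_matrix <- function(gm) {
  if (length(gm$samples) < 2) stop("need at least two samples")
  g <- gm$calls
  m <- (!is.na(g)) + 0
  p <- g / 2
  p[is.na(p)] <- 0
  hom <- ((g == 0L | g == 2L) & !is.na(g)) + 0
  # sums over jointly non-missing loci, all as crossproducts
  q1 <- tcrossprod(p * m)                 # sum p_i p_j
  q0 <- tcrossprod((1 - p) * m)           # sum (1-p_i)(1-p_j)
  qb <- q1 + q0
  hm <- tcrossprod(hom, m)                # sum hom_i over shared loci
  qw <- (hm + t(hm)) / 2
  shared <- tcrossprod(m)
  num <- qw - qb
  den <- shared - qw
  d <- num / den
  undef <- shared == 0 | den <= 0
  d[undef] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(gm$samples, gm$samples)
  attr(d, "n_undefined") <- sum(undef[upper.tri(undef)])
  d
}

#' Pairwise geographic distances between samples
#'
#' @param st sample table (see [read_sample_table()]).
#' @param mode `"haversine"` (lat/lon decimal degrees, mean Earth radius
#'   6,371,000 m) or `"planar"` (Euclidean on x/y meters).
#' @return Symmetric matrix of distances in meters.
#' @export
geographic_distance_matrix <- function(st, mode = c("haversine", "planar")) {
  mode <- match.arg(mode)
  if (mode == "planar") {
    if (!all(c("x", "y") %in% names(st))) stop("planar mode needs x/y columns")
    bad <- !is.finite(st$x) | !is.finite(st$y)
    if (any(bad)) stop("missing coordinates for sample ", st$sample[which(bad)[1]])
    d <- as.matrix(stats::dist(cbind(st$x, st$y)))
  } else {
    if (!all(c("lat", "lon") %in% names(st))) stop("haversine mode needs lat/lon columns")
    bad <- !is.finite(st$lat) | !is.finite(st$lon)
    if (any(bad)) stop("missing coordinates for sample ", st$sample[which(bad)[1]])
    R <- 6371000
    phi <- st$lat * pi / 180
    lam <- st$lon * pi / 180
    n <- nrow(st)
    dphi <- outer(phi, phi, "-")
    dlam <- outer(lam, lam, "-")
    a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
    a <- pmin(pmax(a, 0), 1)
    d <- 2 * R * asin(sqrt(a))
  }
  dimnames(d) <- list(st$sample, st$sample)
  d
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of pairwise genetic distance on geographic distance
#' (1D model) or its natural log (2D model), over unordered pairs. Pairs
#' closer than `min_distance` (guarding log(0)), farther than `max_distance`,
#' or with missing genetic distance are excluded. The slope `b` estimates
#' 1/NS, the reciprocal neighborhood size; significance should come from
#' [mantel_permutation_p()], not OLS standard errors, because pairs sharing
#' an individual are not independent.
#'
#' @param gdist genetic distance matrix ([genetic_distance_matrix()]).
#' @param xdist geographic distance matrix, meters.
#' @param model `"2D"` (regress on log meters) or `"1D"` (meters).
#' @param min_distance exclude pairs closer than this (default 1 m).
#' @param max_distance exclude pairs farther than this (default `Inf`). The
#'   linearity of the IbD relation holds best for distances between roughly
#'   sigma and a fraction of the study extent, so restricting the window is
#'   often appropriate.
#' @return List of class `ibd_fit`: `model`, `b`, `intercept`, `n_pairs`,
#'   plus `ci_low`/`ci_high`/`p_value` slots filled by
#'   [slope_ci_bootstrap()] / [mantel_permutation_p()] callers.
#' @export
ibd_regression <- function(gdist, xdist, model = c("2D", "1D"),
                           min_distance = 1, max_distance = Inf) {
  model <- match.arg(model)
  stopifnot(all(dim(gdist) == dim(xdist)))
  ut <- upper.tri(gdist)
  y <- gdist[ut]
  x <- xdist[ut]
  keep <- !is.na(y) & is.finite(x) & x >= min_distance & x <= max_distance
  y <- y[keep]
  x <- x[keep]
  if (length(y) < 3) stop("fewer than 3 usable pairs for IbD regression")
  if (model == "2D") x <- log(x)
  if (stats::var(x) == 0) stop("zero variance in (transformed) distances")
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  structure(list(model = model, b = b, intercept = a, n_pairs = length(y),
                 ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                 min_distance = min_distance, max_distance = max_distance),
            class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat(sprintf("IbD fit (%s): b = %.4g [%.4g, %.4g], intercept = %.4g, n_pairs = %d, p = %.4g\n",
              x$model, x$b, x$ci_low, x$ci_high, x$intercept, x$n_pairs, x$p_value))
  invisible(x)
}

#' Bootstrap confidence interval for the IbD slope
#'
#' Resamples loci with replacement, recomputes the genetic distance matrix
#' and the regression slope for each replicate, and returns percentile
#' 2.5/97.5 bounds. Degenerate replicates (all-missing distance matrices,
#' zero-variance regressions) are skipped and counted; more than 10% failures
#' is an error.
#'
#' @param gm a [genotype_matrix()].
#' @param st sample table aligned with `gm$samples`.
#' @param model,min_distance,max_distance as in [ibd_regression()].
#' @param mode geographic distance mode, see [geographic_distance_matrix()].
#' @param n_boot number of replicates (default 1000, minimum 100).
#' @param seed integer RNG seed.
#' @return List with `ci_low`, `ci_high`, `draws` (slope replicates) and
#'   `n_failed`.
#' @export
slope_ci_bootstrap <- function(gm, st, model = c("2D", "1D"),
                               min_distance = 1, max_distance = Inf,
                               mode = c("haversine", "planar"),
                               n_boot = 1000, seed = 1) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  stopifnot(n_boot >= 100)
  st <- st[match(gm$samples, st$sample), , drop = FALSE]
  xdist <- geographic_distance_matrix(st, mode)
  L <- nrow(gm$loci)
  set.seed(seed)
  draws <- rep(NA_real_, n_boot)
  for (r in seq_len(n_boot)) {
    li <- sample.int(L, L, replace = TRUE)
    draws[r] <- tryCatch({
      gdist <- genetic_distance_matrix(gm_subset(gm, loci = li))
      ibd_regression(gdist, xdist, model, min_distance, max_distance)$b
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(draws))
  if (n_failed > 0.1 * n_boot) stop("more than 10% of bootstrap replicates failed")
  ci <- stats::quantile(draws, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(ci_low = ci[1], ci_high = ci[2], draws = draws[!is.na(draws)],
       n_failed = n_failed)
}

#' Permutation (Mantel-type) significance of the IbD slope
#'
#' Permutes sample locations jointly (rows/columns of the geographic matrix)
#' and recomputes the slope; one-tailed
#' p = (1 + #\{slope_perm >= slope_obs\}) / (n_perm + 1).
#'
#' @param gdist,xdist,model,min_distance,max_distance as in
#'   [ibd_regression()].
#' @param n_perm number of permutations (default 999, minimum 99).
#' @param seed integer RNG seed.
#' @return The p-value (numeric scalar) with attribute `slope_obs`.
#' @export
mantel_permutation_p <- function(gdist, xdist, model = c("2D", "1D"),
                                 min_distance = 1, max_distance = Inf,
                                 n_perm = 999, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_perm >= 99)
  obs <- ibd_regression(gdist, xdist, model, min_distance, max_distance)$b
  n <- nrow(gdist)
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    pi_ <- sample.int(n)
    b <- tryCatch(
      ibd_regression(gdist, xdist[pi_, pi_], model, min_distance, max_distance)$b,
      error = function(e) NA_real_)
    if (!is.na(b) && b >= obs) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  attr(p, "slope_obs") <- obs
  p
}

#' Full IbD analysis for one dataset
#'
#' Convenience wrapper: genetic distances, geographic distances, OLS fit,
#' locus-bootstrap CI and permutation p-value in one call.
#'
#' @inheritParams slope_ci_bootstrap
#' @param n_perm permutations for the significance test.
#' @return An `ibd_fit` with `ci_low`, `ci_high`, `p_value` filled in and the
#'   bootstrap slope draws in `$boot_draws`.
#' @export
ibd_analysis <- function(gm, st, model = c("2D", "1D"), min_distance = 1,
                         max_distance = Inf, mode = c("haversine", "planar"),
                         n_boot = 1000, n_perm = 999, seed = 1) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  st <- st[match(gm$samples, st$sample), , drop = FALSE]
  gdist <- genetic_distance_matrix(gm)
  xdist <- geographic_distance_matrix(st, mode)
  fit <- ibd_regression(gdist, xdist, model, min_distance, max_distance)
  ci <- slope_ci_bootstrap(gm, st, model, min_distance, max_distance, mode,
                           n_boot = n_boot, seed = seed)
  fit$ci_low <- ci$ci_low
  fit$ci_high <- ci$ci_high
  fit$boot_draws <- ci$draws
  fit$p_value <- as.numeric(mantel_permutation_p(gdist, xdist, model,
                                                 min_distance, max_distance,
                                                 n_perm = n_perm, seed = seed + 1))
  fit
}
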