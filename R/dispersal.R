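#' Axial dispersal distance from an IbD slope and a density
#'
#' Under isolation-by-distance theory the regression slope b of individual
#' genetic distance on (log-)distance relates to the per-generation axial
#' dispersal distance sigma and the effective density D of breeding adults:
#'
#'   2D habitat:  sigma = 1 / sqrt(4 * pi * D * b)   (D in individuals/m^2)
#'   1D habitat:  sigma = 1 / sqrt(4 * D * b)        (D in individuals/m)
#'
#' @param b IbD regression slope (must be positive: a non-positive slope
#'   carries no IbD signal and sigma is undefined).
#' @param D density, individuals per m^2 (2D) or per m (1D); either a number
#'   or a [density_estimate()] whose `model` must match.
#' @param model `"2D"` or `"1D"`.
#' @return Sigma in meters.
#' @export
sigma_from_slope <- function(b, D, model = c("2D", "1D")) {
  model <- match.arg(model)
  if (inherits(D, "density_estimate")) {
    if (D$model != model) stop("density model does not match IbD model")
    D <- D$value
  }
  if (any(b <= 0)) stop("no IbD signal; sigma undefined for b <= 0")
  stopifnot(all(D > 0))
  if (model == "2D") 1 / sqrt(4 * pi * D * b) else 1 / sqrt(4 * D * b)
}

#' Neighborhood size
#'
#' The effective number of breeding adults within a radius of twice the axial
#' dispersal distance: NS = 4 pi D sigma^2 (2D) or NS = 4 D sigma^2 (1D).
#' Both forms reduce algebraically to NS = 1/b, so the slope-only and
#' (D, sigma) entry points must agree.
#'
#' @param b IbD slope (used when `sigma` is `NULL`).
#' @param model `"2D"` or `"1D"`.
#' @param D,sigma alternative parameterization: density and axial dispersal
#'   distance.
#' @return Neighborhood size (count of individuals).
#' @export
neighborhood_size <- function(b = NULL, model = c("2D", "1D"),
                              D = NULL, sigma = NULL) {
  model <- match.arg(model)
  if (!is.null(D) && !is.null(sigma)) {
    if (inherits(D, "density_estimate")) D <- D$value
    stopifnot(all(D > 0), all(sigma > 0))
    return(if (model == "2D") 4 * pi * D * sigma^2 else 4 * D * sigma^2)
  }
  if (is.null(b)) stop("supply either b or both D and sigma")
  if (any(b <= 0)) stop("no IbD signal; neighborhood size undefined for b <= 0")
  1 / b
}

#' Neighborhood radius
#'
#' Populations separated by more than twice the axial dispersal distance are
#' expected to be demographically isolated; the dispersal neighborhood is a
#' circle of radius 2 * sigma.
#'
#' @param sigma axial dispersal distance, meters (> 0).
#' @return Radius in meters.
#' @export
neighborhood_radius <- function(sigma) {
  stopifnot(all(sigma > 0))
  2 * sigma
}

#' Laplacian dispersal kernel calibrated by sigma
#'
#' Density p(x) = 1/(sigma*sqrt(2)) * exp(-sqrt(2)|x|/sigma) over the real
#' line, i.e. a Laplace distribution with scale sigma/sqrt(2) so that the
#' axial standard deviation equals sigma. The mean (absolute) dispersal
#' distance under this kernel is sigma/sqrt(2).
#'
#' @param sigma axial dispersal distance, meters (> 0).
#' @return List of class `laplace_kernel`: `sigma`, `scale`,
#'   `mean_distance`, and functions `pdf(x)`, `cdf(x)`, `quantile(q)`,
#'   `rdraw(n)`.
#' @export
laplace_kernel <- function(sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  b <- sigma / sqrt(2)
  pdf <- function(x) exp(-abs(x) / b) / (2 * b)
  cdf <- function(x) ifelse(x < 0, 0.5 * exp(x / b), 1 - 0.5 * exp(-x / b))
  qf <- function(q) {
    stopifnot(all(q >= 0 & q <= 1))
    ifelse(q < 0.5, b * log(2 * q), -b * log(2 * (1 - q)))
  }
  rdraw <- function(n) qf(stats::runif(n))
  structure(list(sigma = sigma, scale = b, mean_distance = b,
                 pdf = pdf, cdf = cdf, quantile = qf, rdraw = rdraw),
            class = "laplace_kernel")
}

#' @export
print.laplace_kernel <- function(x, ...) {
  cat(sprintf("Laplace dispersal kernel: sigma = %.4g m, mean distance = %.4g m\n",
              x$sigma, x$mean_distance))
  invisible(x)
}

#' Density estimates (census or effective)
#'
#' `census_density` turns per-site colony counts into an areal (2D) or linear
#' (1D) density: per-site density = count * taxon_fraction / area, summarized
#' as the median across sites, with uncertainty draws from a site-level
#' bootstrap (resample sites with replacement, take the median of each
#' resample). `effective_density` divides effective population sizes by
#' habitat extent; with several populations the per-population densities form
#' the draw pool and the value is their median.
#'
#' The 1D (linear) census density is the areal density times a habitat strip
#' width in meters; linear density is a modeling abstraction, so the width is
#' an explicit knob with no claim of a canonical value.
#'
#' @param counts per-site colony counts.
#' @param areas per-site surveyed areas, m^2 (all > 0).
#' @param taxon_fraction per-site fraction of counted colonies belonging to
#'   the focal taxon (default 1).
#' @param model `"2D"` or `"1D"`.
#' @param strip_width habitat strip width in meters (1D only).
#' @param n_boot site-bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `density_estimate`: `kind`, `model`, `value`,
#'   `draws`.
#' @export
census_density <- function(counts, areas, taxon_fraction = 1,
                           model = c("2D", "1D"), strip_width = 1,
                           n_boot = 1000, seed = 1) {
  model <- match.arg(model)
  stopifnot(length(counts) == length(areas))
  if (any(areas <= 0)) stop("zero or negative plot area")
  taxon_fraction <- rep_len(taxon_fraction, length(counts))
  stopifnot(all(taxon_fraction >= 0 & taxon_fraction <= 1))
  dens <- counts * taxon_fraction / areas
  if (model == "1D") dens <- dens * strip_width
  set.seed(seed)
  draws <- replicate(n_boot, stats::median(sample(dens, replace = TRUE)))
  density_estimate("census", model, stats::median(dens), draws)
}

#' @rdname census_density
#' @param ne per-population effective sizes (> 0).
#' @param extent per-population habitat extents, m^2 (2D) or m (1D), > 0.
#' @export
effective_density <- function(ne, extent, model = c("2D", "1D")) {
  model <- match.arg(model)
  stopifnot(all(ne > 0), all(extent > 0))
  dens <- ne / extent
  density_estimate("effective", model, stats::median(dens), dens)
}

#' @rdname census_density
#' @param kind `"census"` or `"effective"`.
#' @param value point density (> 0).
#' @param draws plausible values for uncertainty propagation (all > 0).
#' @export
density_estimate <- function(kind, model, value, draws = value) {
  stopifnot(kind %in% c("census", "effective"), model %in% c("2D", "1D"),
            value > 0, all(draws > 0))
  structure(list(kind = kind, model = model, value = value, draws = draws),
            class = "density_estimate")
}

#' Monte-Carlo propagation of slope and density uncertainty into sigma
#'
#' Draws IbD slopes and densities independently, converts each draw into
#' sigma, neighborhood size (1/b), neighborhood radius (2 sigma) and
#' Laplace-kernel mean distance (sigma/sqrt(2)), and summarizes each as the
#' median and interquartile range of the joint distribution. Non-positive
#' slope draws are rejected and counted (more than 50% rejections is an
#' error). The number of modes of the sigma distribution is reported, since
#' mixtures of per-population densities can make it multimodal.
#'
#' @param b_draws sample of IbD slopes (e.g. bootstrap replicates, or draws
#'   from a lognormal matched to a reported median and CI; see
#'   [lognormal_slope_draws()]).
#' @param D a [density_estimate()] (its `draws` are resampled), or a single
#'   positive number.
#' @param model `"2D"` or `"1D"`.
#' @param n_mc Monte-Carlo iterations (default 10000).
#' @param seed RNG seed.
#' @return List of class `dispersal_estimate`: per-quantity `median` and
#'   `iqr` (`sigma`, `ns`, `radius`, `kernel_mean_distance`), `n_rejected`,
#'   `sigma_modes` (count), and the raw `sigma_draws`.
#' @export
propagate_sigma <- function(b_draws, D, model = c("2D", "1D"),
                            n_mc = 10000, seed = 1) {
  model <- match.arg(model)
  if (!inherits(D, "density_estimate")) D <- density_estimate("census", model, D)
  b_draws <- as.numeric(b_draws)
  n_rejected <- sum(b_draws <= 0)
  if (n_rejected > 0.5 * length(b_draws)) stop("more than 50% of slope draws are non-positive")
  b_draws <- b_draws[b_draws > 0]
  if (length(b_draws) == 0) stop("no positive slope draws")
  set.seed(seed)
  b <- b_draws[sample.int(length(b_draws), n_mc, replace = TRUE)]
  d <- D$draws[sample.int(length(D$draws), n_mc, replace = TRUE)]
  sigma <- sigma_from_slope(b, d, model)
  ns <- 1 / b
  summ <- function(x) list(median = stats::median(x),
                           iqr = unname(stats::quantile(x, c(0.25, 0.75))))
  structure(list(model = model,
                 sigma = summ(sigma), ns = summ(ns),
                 radius = summ(2 * sigma),
                 kernel_mean_distance = summ(sigma / sqrt(2)),
                 n_rejected = n_rejected,
                 sigma_modes = count_density_modes(sigma),
                 sigma_draws = sigma),
            class = "dispersal_estimate")
}

#' @export
print.dispersal_estimate <- function(x, ...) {
  f <- function(s) sprintf("%.3g [%.3g, %.3g]", s$median, s$iqr[1], s$iqr[2])
  cat(sprintf(paste0("dispersal_estimate (%s): sigma = %s m, NS = %s, ",
                     "radius = %s m, kernel mean = %s m, modes = %d\n"),
              x$model, f(x$sigma), f(x$ns), f(x$radius),
              f(x$kernel_mean_distance), x$sigma_modes))
  invisible(x)
}

#' Count modes of a positive-valued sample
#'
#' Kernel density on the log scale; local maxima whose height exceeds 10% of
#' the global maximum count as modes. A coarse diagnostic for multimodality
#' of propagated sigma distributions.
#'
#' @param x positive numeric sample.
#' @return Integer mode count (>= 1).
#' @export
count_density_modes <- function(x) {
  if (length(unique(x)) == 1) return(1L)
  d <- stats::density(log(x))
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[peaks] > 0.1 * max(y))
}

#' Lognormal slope draws matched to a reported median and 95% CI
#'
#' When raw bootstrap replicates are unavailable, slope uncertainty can be
#' approximated by a lognormal with meanlog = log(median) and sdlog chosen so
#' that the 2.5/97.5 quantile ratio matches the reported CI:
#' sdlog = log(ci_high/ci_low) / (2 * 1.96).
#'
#' @param median_b reported median slope (> 0).
#' @param ci_low,ci_high reported 95% CI bounds (0 < ci_low < ci_high).
#' @param n number of draws.
#' @param seed RNG seed.
#' @return Numeric vector of slope draws.
#' @export
lognormal_slope_draws <- function(median_b, ci_low, ci_high, n = 10000, seed = 1) {
  stopifnot(median_b > 0, ci_low > 0, ci_high > ci_low)
  sdlog <- log(ci_high / ci_low) / (2 * stats::qnorm(0.975))
  set.seed(seed)
  stats::rlnorm(n, meanlog = log(median_b), sdlog = sdlog)
}
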