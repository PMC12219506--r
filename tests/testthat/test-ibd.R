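test_that("genetic distance matches hand-computed identity probabilities", {
  # single heterozygous locus in both individuals
  gm <- gm_fixture(matrix(c(1L, 1L), 2, 1))
  expect_equal(genetic_distance_matrix(gm)[1, 2], -0.5)
  # opposite homozygotes at one locus plus double het at another
  gm2 <- gm_fixture(rbind(c(0L, 1L), c(2L, 1L)))
  expect_equal(genetic_distance_matrix(gm2)[1, 2], 0.5)
  # no shared loci -> NA row
  g3 <- rbind(c(0L, 1L, 2L), c(NA, NA, NA), c(0L, 1L, 1L))
  d3 <- genetic_distance_matrix(gm_fixture(g3))
  expect_true(all(is.na(d3[2, -2])))
  expect_equal(attr(d3, "n_undefined"), 2L)
  # both homozygous everywhere -> zero denominator -> NA
  g4 <- rbind(c(0L, 2L), c(2L, 0L))
  expect_true(is.na(genetic_distance_matrix(gm_fixture(g4))[1, 2]))
})

test_that("genetic distance agrees with the brute-force loop oracle", {
  gm <- random_gm(6, 30, miss = 0.15, seed = 13)
  d <- genetic_distance_matrix(gm)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j], brute_genetic_distance(gm$calls, i, j),
                 tolerance = 1e-12)
  }
})

test_that("geographic distances: haversine and planar", {
  st <- data.frame(sample = c("a", "b", "c"),
                   lat = c(10, 11, 10), lon = c(30, 30, 30))
  d <- geographic_distance_matrix(st, "haversine")
  expect_equal(d[1, 3], 0)
  expect_equal(d[1, 2], 6371000 * pi / 180, tolerance = 1e-6)
  stp <- data.frame(sample = c("a", "b"), x = c(0, 3), y = c(0, 4))
  expect_equal(geographic_distance_matrix(stp, "planar")[1, 2], 5)
  expect_error(geographic_distance_matrix(
    data.frame(sample = c("a", "b"), lat = c(NA, 1), lon = c(0, 0))), "a")
})

test_that("ibd_regression recovers a noiseless line and applies exclusions", {
  n <- 10
  st <- data.frame(sample = sprintf("s%02d", 1:n),
                   x = exp(seq(0, 5, length.out = n)), y = 0)
  xd <- geographic_distance_matrix(st, "planar")
  gd <- 0.01 + 0.004 * log(pmax(xd, 1e-9))
  diag(gd) <- 0
  fit <- ibd_regression(gd, xd, "2D", min_distance = 0.5)
  expect_equal(fit$b, 0.004, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.01, tolerance = 1e-9)
  expect_equal(fit$n_pairs, choose(n, 2))

  # pair at identical coordinates is excluded under the log model
  st2 <- st; st2$x[2] <- st2$x[1]
  xd2 <- geographic_distance_matrix(st2, "planar")
  fit2 <- ibd_regression(gd, xd2, "2D", min_distance = 0.5)
  expect_equal(fit2$n_pairs, choose(n, 2) - 1L)

  # 1D model regresses on raw distance
  gd1 <- 0.2 + 3e-5 * xd
  fit1 <- ibd_regression(gd1, xd, "1D", min_distance = 0)
  expect_equal(fit1$b, 3e-5, tolerance = 1e-12)

  expect_error(ibd_regression(gd[1:2, 1:2], xd[1:2, 1:2], "2D"), "fewer than 3")
  xeq <- matrix(10, n, n); diag(xeq) <- 0
  expect_error(ibd_regression(gd, xeq, "2D"), "zero variance")
})

test_that("regression is invariant to sample order and all-missing loci", {
  gm <- random_gm(12, 80, seed = 17)
  set.seed(17)
  st <- data.frame(sample = gm$samples, x = runif(12, 0, 100), y = runif(12, 0, 100))
  xd <- geographic_distance_matrix(st, "planar")
  b0 <- ibd_regression(genetic_distance_matrix(gm), xd, "2D")$b

  per <- sample(12)
  gmp <- gm_subset(gm, samples = per)
  xdp <- geographic_distance_matrix(st[per, ], "planar")
  expect_equal(ibd_regression(genetic_distance_matrix(gmp), xdp, "2D")$b, b0,
               tolerance = 1e-12)

  gm_aug <- genotype_matrix(cbind(gm$calls, NA_integer_),
                            rbind(gm$loci, data.frame(contig = "cx", pos = 1,
                                                      ref = "A", alt = "T")),
                            samples = gm$samples)
  expect_equal(ibd_regression(genetic_distance_matrix(gm_aug), xd, "2D")$b, b0,
               tolerance = 1e-12)
})

test_that("locus bootstrap CI degenerates correctly and is seed-deterministic", {
  # all loci identical -> distances invariant to resampling -> zero-width CI
  one <- rbind(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(1L, 2L), c(0L, 0L))
  gm <- gm_fixture(one[, rep(1L, 8)])
  st <- data.frame(sample = gm$samples, x = c(1, 10, 100, 1000, 5000), y = 0)
  ci <- slope_ci_bootstrap(gm, st, "2D", mode = "planar", n_boot = 100, seed = 4)
  expect_equal(ci$ci_low, ci$ci_high, tolerance = 1e-12)
  b <- ibd_regression(genetic_distance_matrix(gm),
                      geographic_distance_matrix(st, "planar"), "2D")$b
  expect_equal(ci$ci_low, b, tolerance = 1e-12)

  gm2 <- random_gm(10, 60, seed = 23)
  st2 <- data.frame(sample = gm2$samples, x = exp(seq(0, 6, length.out = 10)), y = 0)
  c1 <- slope_ci_bootstrap(gm2, st2, "2D", mode = "planar", n_boot = 120, seed = 8)
  c2 <- slope_ci_bootstrap(gm2, st2, "2D", mode = "planar", n_boot = 120, seed = 8)
  expect_identical(c1, c2)
  expect_lte(c1$ci_low, c1$ci_high)
})

test_that("locus bootstrap CI covers the large-locus-limit slope", {
  # world with a deterministic allele-frequency cline; the 'true' slope is the
  # infinite-locus limit, estimated once from a very large locus set
  make_world <- function(L, seed) {
    set.seed(seed)
    n <- 20
    x <- seq(5, 2000, length.out = n)
    p <- outer(x / max(x), rep(1, L)) * 0.5 + 0.25
    g <- matrix(rbinom(n * L, 2, p), n, L)
    list(gm = gm_fixture(g), st = data.frame(sample = sprintf("s%02d", 1:n),
                                             x = x, y = 0))
  }
  big <- make_world(20000, seed = 1)
  b_true <- ibd_regression(genetic_distance_matrix(big$gm),
                           geographic_distance_matrix(big$st, "planar"), "2D")$b
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    w <- make_world(300, seed = 100 + r)
    ci <- slope_ci_bootstrap(w$gm, w$st, "2D", mode = "planar",
                             n_boot = 200, seed = r)
    if (ci$ci_low <= b_true && b_true <= ci$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 0.8 * n_rep)   # scaled-down percentile-coverage check
})

test_that("permutation p-value: trivial cases and type-I calibration", {
  n <- 12
  st <- data.frame(sample = sprintf("s%02d", 1:n),
                   x = exp(seq(0, 5, length.out = n)), y = 0)
  xd <- geographic_distance_matrix(st, "planar")
  gd <- 0.01 + 0.004 * log(xd); diag(gd) <- 0
  p <- mantel_permutation_p(gd, xd, "2D", n_perm = 199, seed = 2)
  expect_equal(as.numeric(p), 1 / 200)   # observed slope maximal

  gconst <- matrix(0.3, n, n); diag(gconst) <- 0
  pc <- mantel_permutation_p(gconst, xd, "2D", n_perm = 99, seed = 2)
  expect_gte(as.numeric(pc), 0.99)       # slope 0 everywhere, ties count

  # null calibration: genetic distances independent of location
  rejections <- 0
  n_runs <- 60
  for (r in seq_len(n_runs)) {
    gm <- random_gm(10, 40, seed = 500 + r)
    gd0 <- genetic_distance_matrix(gm)
    set.seed(900 + r)
    st0 <- data.frame(sample = gm$samples, x = runif(10, 1, 1000), y = runif(10, 1, 1000))
    p0 <- mantel_permutation_p(gd0, geographic_distance_matrix(st0, "planar"),
                               "2D", n_perm = 99, seed = r)
    if (as.numeric(p0) <= 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 9)   # binomial(60, 0.05) upper tail
})

test_that("fitted 2D slope decreases as true sigma increases", {
  slopes <- sapply(c(5, 20, 80), function(sig) {
    sim <- simulate_spatial(model = "2D", extent = 400, n_individuals = 300,
                            sigma_true = sig, n_loci = 150, mutation_rate = 1e-3,
                            n_generations = 80, n_sample = 100, seed = 37)
    gd <- genetic_distance_matrix(sim$gm)
    xd <- geographic_distance_matrix(sim$samples, "planar")
    ibd_regression(gd, xd, "2D", min_distance = 1, max_distance = 200)$b
  })
  expect_true(all(diff(slopes) < 0))
  expect_gt(slopes[1], 0)
})
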