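test_that("read_genotypes parses variant-only and all-sites dialects", {
  rows <- list(
    vcf_row("chr1", 100, "A", "T", "0/1:10", "0/0:12"),
    vcf_row("chr1", 200, "C", ".", "0/0:9", "0/0:8"),     # invariant
    vcf_row("chr1", 300, "G", "GA", "0/1:10", "1/1:11"),  # indel
    vcf_row("chr1", 400, "T", "A,C", "1/2:10", "0/1:9"),  # multi-allelic
    vcf_row("chr2", 500, "G", "C", "./.:.", "1|1:15"),
    vcf_row("chr2", 600, "A", "G", "0/0:4", "0/1:7"))
  path <- write_vcf_fixture(rows, c("S1", "S2"))

  gm <- read_genotypes(path, mode = "variant")
  expect_equal(dim(gm), c(2L, 3L))           # indel, multiallelic, invariant out
  expect_equal(unname(gm$calls["S1", ]), c(1L, NA, 0L))
  expect_equal(unname(gm$calls["S2", ]), c(0L, 2L, 1L))
  expect_equal(unname(gm$depths["S1", ]), c(10L, NA, 4L))
  expect_false(any(gm$invariant))

  gma <- read_genotypes(path, mode = "all-sites")
  expect_equal(dim(gma), c(2L, 4L))
  expect_equal(sum(gma$invariant), 1L)
  expect_true(all(gma$calls[, gma$invariant] == 0L))
  excl <- attr(gma, "excluded")
  expect_equal(unname(excl["multiallelic"]), 1L)
  expect_equal(unname(excl["indel"]), 1L)
})

test_that("read_genotypes rejects unreadable files and non-diploid calls", {
  expect_error(read_genotypes(tempfile()), "cannot read")
  path <- write_vcf_fixture(list(vcf_row("chr1", 10, "A", "T", "0/1:9", "1:9")),
                            c("S1", "S2"))
  expect_error(read_genotypes(path), "non-diploid.*chr1:10")
})

test_that("genotype matrix round-trips through the TSV dialect", {
  gm <- random_gm(6, 15, miss = 0.15, seed = 3,
                  contig = rep(c("c1", "c2", "c3"), each = 5), pos = rep(1:5, 3))
  path <- tempfile(fileext = ".tsv")
  write_genotype_tsv(gm, path)
  back <- read_genotype_tsv(path)
  expect_equal(back$calls, gm$calls)
  expect_equal(back$loci, gm$loci)
  expect_equal(back$samples, gm$samples)
})

test_that("filter_sites drops MAC, MAF and missingness violations in order", {
  # boundary: alt-allele count 2 fails mac_min = 3
  gm <- gm_fixture(matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), 10, 1))
  expect_error(filter_sites(gm), "no sites survive")

  # 10-sample site with 6 missing fails max_site_missing = 0.5
  g <- matrix(rep(c(0L, 1L), each = 10), 10, 2)
  g[1:6, 2] <- NA
  out <- filter_sites(gm_fixture(g), mac_min = 0, maf_min = 0)
  expect_equal(dim(out)[2], 1L)

  # planted violations: 20 sites, 4 MAC + 3 MAF + 2 missingness fail -> 11 left
  set.seed(42)
  n <- 40
  build <- function(minor_count, miss = 0) {
    g <- rep(0L, n)
    g[seq_len(minor_count)] <- 1L
    if (miss > 0) g[sample(n, miss)] <- NA_integer_
    g
  }
  cols <- c(lapply(1:4, function(i) build(2)),           # MAC 2 < 3
            lapply(1:3, function(i) build(3)),           # MAF 3/80 < 0.05
            lapply(1:2, function(i) build(10, miss = 25)),  # 62.5% missing
            lapply(1:11, function(i) build(8)))             # pass (MAF 0.1)
  g <- do.call(cbind, cols)
  out <- filter_sites(gm_fixture(g), mac_min = 3, max_site_missing = 0.5,
                      maf_min = 0.05)
  expect_equal(dim(out)[2], 11L)
  lg <- attr(out, "filter_log")
  expect_equal(lg$n_sites, c(20, 20, 18, 14, 11))

  # depth masking happens before site filters
  gmd <- genotype_matrix(matrix(1L, 4, 1),
                         data.frame(contig = "c", pos = 1, ref = "A", alt = "T"),
                         samples = letters[1:4],
                         depths = matrix(c(2, 2, 2, 10), 4, 1))
  expect_error(filter_sites(gmd, mac_min = 0, maf_min = 0,
                            max_site_missing = 0.5), "no sites survive")
})

test_that("filter_sites is idempotent", {
  gm <- random_gm(20, 60, miss = 0.2, seed = 11)
  once <- filter_sites(gm, mac_min = 3, maf_min = 0.05, max_site_missing = 0.15)
  twice <- filter_sites(once, mac_min = 3, maf_min = 0.05, max_site_missing = 0.15)
  expect_equal(twice$calls, once$calls)
  expect_equal(twice$loci, once$loci)
})

test_that("filter_samples removes on strict threshold exceedance", {
  g <- matrix(0L, 5, 10)
  for (i in 1:5) g[i, seq_len(c(0, 1, 3, 5, 9)[i])] <- NA_integer_
  gm <- gm_fixture(g)
  out <- filter_samples(gm, max_sample_missing = 0.3)
  expect_equal(out$samples, gm$samples[1:3])   # 0.3 itself is retained
  expect_equal(attr(out, "removed_samples"), gm$samples[4:5])
  expect_error(filter_samples(gm_subset(gm, samples = 2:5), 0), "all samples")
})

test_that("allelic similarity matches its definition and a brute-force oracle", {
  gm <- gm_fixture(rbind(c(0, 0, 1, 2), c(1, 0, 1, 2)))
  expect_equal(allelic_similarity(gm)[1, 2], (0.5 + 3) / 4)   # share one allele
  gm2 <- gm_fixture(rbind(c(0, 0), c(2, 2)))
  expect_equal(allelic_similarity(gm2)[1, 2], 0)
  gm3 <- gm_fixture(rbind(c(1, 2, 0), c(1, 2, 0)))
  expect_equal(allelic_similarity(gm3)[1, 2], 1)

  gm4 <- random_gm(5, 20, miss = 0.2, seed = 7)
  sim <- allelic_similarity(gm4)
  for (i in 1:4) for (j in (i + 1):5) {
    gi <- gm4$calls[i, ]; gj <- gm4$calls[j, ]
    ok <- !is.na(gi) & !is.na(gj)
    expected <- if (!any(ok)) NA_real_ else mean(1 - abs(gi[ok] - gj[ok]) / 2)
    expect_equal(sim[i, j], expected, tolerance = 1e-12)
  }
  # pair with zero joint coverage is NA
  g5 <- rbind(c(0L, NA), c(NA, 1L), c(1L, 1L))
  expect_true(is.na(allelic_similarity(gm_fixture(g5))[1, 2]))
})

test_that("detect_clones resolves groups transitively and keeps least-missing member", {
  expect_equal(length(detect_clones(diag(3) * 0 + diag(3),
                                    c(a = 0, b = 0, c = 0))$removed), 0)

  # planted duplicate with 0.5% discordance on 4000 loci
  base <- random_gm(6, 4000, seed = 5)
  art <- inject_artifacts(base, clone_pairs = 1, discordance = 0.005, seed = 9)
  sim <- allelic_similarity(art$gm)
  rep_ <- detect_clones(sim, sample_missingness(art$gm), threshold = 0.99)
  expect_equal(nrow(rep_$pairs), 1L)
  expect_setequal(unlist(rep_$pairs[, 1:2]),
                  c(art$planted$original, art$planted$clone))
  expect_length(rep_$removed, 1)   # never removes both members of a pair
  expect_gt(rep_$pairs$similarity, 0.99)
  expect_lt(rep_$pairs$similarity, 1)

  # clonal triplet: two removals, least-missing kept
  g <- matrix(rep(c(0L, 1L, 2L), 40), 1, 120)
  trip <- rbind(g, g, g, (g + 1L) %% 3L)
  trip[2, 1:30] <- NA; trip[3, 1:10] <- NA
  gmt <- gm_fixture(trip)
  rpt <- detect_clones(allelic_similarity(gmt), sample_missingness(gmt))
  expect_setequal(rpt$removed, c("s02", "s03"))
  expect_equal(sort(rpt$similarity_sorted, decreasing = TRUE),
               rpt$similarity_sorted)
})

test_that("prune_linked removes collinear loci and leaves independent ones", {
  set.seed(21)
  n <- 40
  base <- rbinom(n, 2, 0.5)
  dup <- cbind(base, base, rbinom(n, 2, 0.5))
  gm <- gm_fixture(dup, contig = rep("c1", 3), pos = 1:3)
  out <- prune_linked(gm, window = 3, step = 1, vif_max = 2)
  expect_equal(dim(out)[2], 2L)   # exactly one of the duplicates removed

  indep <- random_gm(60, 30, seed = 31, contig = rep("c1", 30), pos = 1:30)
  kept <- prune_linked(indep, window = 10, step = 3, vif_max = 2)
  expect_equal(dim(kept)[2], 30L)

  # pairwise R^2 = 0.6 -> VIF 2.5 > 2: at least one of three removed,
  # verified against brute-force VIF on the same window
  set.seed(55)
  z <- rnorm(500)
  mk <- function() {
    x <- sqrt(0.6) * z + sqrt(0.4) * rnorm(500)
    as.integer(cut(x, quantile(x, c(0, .25, .75, 1)), include.lowest = TRUE)) - 1L
  }
  cor_gm <- gm_fixture(cbind(mk(), mk(), mk()), contig = rep("c1", 3), pos = 1:3)
  imp <- scale(cor_gm$calls, center = TRUE, scale = FALSE)
  brute_vif <- sapply(1:3, function(j) {
    r2 <- summary(lm(imp[, j] ~ imp[, -j]))$r.squared
    1 / (1 - r2)
  })
  expect_equal(vif_in_window(imp), brute_vif, tolerance = 1e-8)
  if (max(brute_vif) > 2) {
    pruned <- prune_linked(cor_gm, window = 3, step = 1, vif_max = 2)
    expect_lt(dim(pruned)[2], 3L)
  }

  # re-scan: no surviving window exceeds vif_max
  big <- random_gm(50, 40, seed = 77, contig = rep("c1", 40), pos = 1:40)
  big$calls[, 2] <- big$calls[, 1]
  big$calls[, 20] <- big$calls[, 19]
  pruned <- prune_linked(big, window = 8, step = 2, vif_max = 2)
  imp2 <- scale(pruned$calls, center = TRUE, scale = FALSE)
  L <- ncol(imp2)
  for (s in seq(1, max(1, L - 7), by = 2)) {
    win <- s:min(s + 7, L)
    expect_true(all(vif_in_window(imp2[, win, drop = FALSE]) <= 2 + 1e-8))
  }
})
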