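# In-code fixtures shared across test files. All data are generated here;
# nothing binary is stored in the repository.

# genotype_matrix from a plain samples x loci integer matrix, one SNP per
# contig unless positions are supplied
gm_fixture <- function(calls, contig = NULL, pos = NULL, samples = NULL) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  loci <- data.frame(
    contig = if (is.null(contig)) sprintf("c%03d", seq_len(L)) else contig,
    pos = if (is.null(pos)) rep(1L, L) else pos,
    ref = "A", alt = "T")
  genotype_matrix(calls, loci,
                  samples = if (is.null(samples)) sprintf("s%02d", seq_len(nrow(calls))) else samples)
}

# random biallelic genotypes under HWE with optional missingness
random_gm <- function(n, L, miss = 0, seed = 1, contig = NULL, pos = NULL) {
  set.seed(seed)
  p <- runif(L, 0.1, 0.9)
  g <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  if (miss > 0) g[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
  gm_fixture(g, contig = contig, pos = pos)
}

# write a small VCF text file; rows are character vectors of fields
write_vcf_fixture <- function(rows, samples, path = tempfile(fileext = ".vcf"),
                              with_dp = TRUE) {
  fmt <- if (with_dp) "GT:DP" else "GT"
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=1000000>",
           "##contig=<ID=chr2,length=1000000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (with_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r) paste(r, collapse = "\t"), "")
  writeLines(c(hdr, body), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, ...) {
  c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT:DP", ...)
}

# exact identity-probability recurrence for two demes exchanging an actual
# fraction m of individuals per generation (independent oracle for the
# simulated equilibrium FST); Q_init is the initial identity-in-state
fst_two_deme_oracle <- function(N, m, u, gens, Q_init) {
  x <- 1 / (2 * N)
  a <- (1 - m)^2 + m^2
  b <- 2 * m * (1 - m)
  Q0 <- Q_init; Q1 <- Q_init
  for (g in seq_len(gens)) {
    t0 <- (1 - u)^2 * (a * (x + (1 - x) * Q0) + b * Q1)
    t1 <- (1 - u)^2 * (b * (x + (1 - x) * Q0) + a * Q1)
    Q0 <- t0; Q1 <- t1
  }
  (Q0 - Q1) / (1 - Q1)
}

# brute-force per-pair genetic distance (independent loop oracle)
brute_genetic_distance <- function(calls, i, j) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(calls))) {
    gi <- calls[i, l]; gj <- calls[j, l]
    if (is.na(gi) || is.na(gj)) next
    qw <- ((gi %in% c(0, 2)) + (gj %in% c(0, 2))) / 2
    pi_ <- gi / 2; pj <- gj / 2
    qb <- pi_ * pj + (1 - pi_) * (1 - pj)
    num <- num + (qw - qb)
    den <- den + (1 - qw)
  }
  if (den <= 0) NA_real_ else num / den
}

# enumeration oracle: P(allele with k copies of N present in a g-subsample)
enum_presence <- function(k, N, g) {
  subs <- utils::combn(N, g)
  mean(apply(subs, 2, function(s) any(s <= k)))   # copies 1..k carry the allele
}
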