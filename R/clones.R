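#' Pairwise allelic similarity
#'
#' For each pair of samples, the mean over jointly non-missing loci of a
#' per-locus score: 1 when the genotypes are identical, 0.5 when they share
#' exactly one allele (e.g. 0/0 vs 0/1, or 0/1 vs 1/1), 0 otherwise. This is
#' the statistic whose distribution shows a sharp break between clonal
#' (ramet) pairs and ordinary kin when asexual reproduction is present.
#'
#' Equivalently, score = 1 - |g_i - g_j| / 2 for alt-allele counts g, which
#' is how it is computed here.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return A symmetric matrix with unit diagonal; `NA` for pairs with no
#'   jointly non-missing locus.
#' @export
allelic_similarity <- function(gm) {
  if (length(gm$samples) < 2) stop("need at least two samples")
  g <- gm$calls
  m <- !is.na(g)
  g0 <- g
  g0[!m] <- 0L
  mm <- m + 0
  shared <- tcrossprod(mm)                       # jointly non-missing loci
  # sum over shared loci of |gi - gj| via (gi - gj)^2 decomposition is wrong
  # for values in {0,1,2} (|d| != d^2 when |d| = 2), so split by indicator:
  # |gi - gj| = (gi^2 - 2 gi gj + gj^2) ... use two tcrossprods on het/dose
  # instead: sum|gi-gj| = sum(gi+gj) - 2*sum(min(gi,gj)); min is not bilinear
  # either. Use the exact decomposition over the 3 genotype states.
  I0 <- (g0 == 0L & m) + 0; I1 <- (g0 == 1L & m) + 0; I2 <- (g0 == 2L & m) + 0
  # |a-b| lookup: (0,1)=1 (0,2)=2 (1,2)=1
  absdiff <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    2 * tcrossprod(I0, I2) + 2 * tcrossprod(I2, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1)
  sim <- 1 - absdiff / (2 * shared)
  sim[shared == 0] <- NA_real_
  diag(sim) <- 1
  dimnames(sim) <- list(gm$samples, gm$samples)
  sim
}

#' Detect clonal (ramet) groups from an allelic similarity matrix
#'
#' Pairs at or above `threshold` are reported as clonal; groups are resolved
#' transitively (connected components), and from each group every member but
#' the one with the least missing data is slated for removal.
#'
#' @param sim symmetric similarity matrix in `[0, 1]` (see
#'   [allelic_similarity()]).
#' @param missingness named per-sample missing-call fraction (used to choose
#'   the member to keep).
#' @param threshold similarity cutoff, default 0.99.
#' @return A list of class `clonal_report`: `pairs` (data.frame sample_a,
#'   sample_b, similarity), `threshold`, `removed` (character), and
#'   `similarity_sorted` (all off-diagonal values, decreasing) for inspecting
#'   the distribution break.
#' @export
detect_clones <- function(sim, missingness, threshold = 0.99) {
  ids <- rownames(sim)
  n <- nrow(sim)
  ut <- which(upper.tri(sim) & !is.na(sim) & sim >= threshold, arr.ind = TRUE)
  pairs <- data.frame(sample_a = ids[ut[, 1]], sample_b = ids[ut[, 2]],
                      similarity = sim[ut])
  # union-find over clonal edges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(ut[k, 1]); b <- find(ut[k, 2])
    if (a != b) parent[a] <- b
  }
  removed <- character(0)
  if (nrow(pairs) > 0) {
    comp <- vapply(seq_len(n), find, 0L)
    for (cc in unique(comp[ut[, 1]])) {
      members <- which(comp == cc)
      if (length(members) < 2) next
      keep <- members[which.min(missingness[ids[members]])]
      removed <- c(removed, ids[setdiff(members, keep)])
    }
  }
  structure(list(pairs = pairs, threshold = threshold, removed = removed,
                 similarity_sorted = sort(sim[upper.tri(sim)], decreasing = TRUE)),
            class = "clonal_report")
}

#' @export
print.clonal_report <- function(x, ...) {
  cat(sprintf("clonal_report: %d pair(s) >= %.3g; removing %d sample(s)\n",
              nrow(x$pairs), x$threshold, length(x$removed)))
  invisible(x)
}

#' Serialize a clonal report to JSON
#' @param report a `clonal_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clonal_report <- function(report, path) {
  jsonlite::write_json(list(threshold = report$threshold,
                            pairs = report$pairs,
                            removed = report$removed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
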