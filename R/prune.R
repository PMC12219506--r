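#' Prune loci in linkage via variance inflation factors
#'
#' Sliding-window VIF pruning in the style of PLINK's `--indep`: within each
#' window of `window` loci (advanced by `step`, never spanning contigs), the
#' locus with the highest variance inflation factor is removed repeatedly
#' until all VIFs are at or below `vif_max`. The VIF of a locus is
#' 1/(1 - R^2) from the OLS regression of its mean-imputed genotype on the
#' other (mean-imputed) loci in the window; rank-deficient regressions are
#' handled by the QR pseudo-solution (R^2 from the projection onto the column
#' space), so perfect collinearity yields an infinite VIF. Monomorphic loci
#' have VIF defined as 1. Removals are permanent across windows.
#'
#' @param gm a [genotype_matrix()] with loci sorted by (contig, pos).
#' @param window window size in loci (default 50).
#' @param step window advance in loci (default 5).
#' @param vif_max VIF threshold (default 2).
#' @return A pruned `genotype_matrix` with attribute `removed_loci` (integer
#'   indices into the input loci).
#' @export
prune_linked <- function(gm, window = 50, step = 5, vif_max = 2) {
  stopifnot(window >= 2, step >= 1, vif_max >= 1)
  o <- order(gm$loci$contig, gm$loci$pos)
  if (any(o != seq_along(o))) gm <- gm_subset(gm, loci = o)
  g <- gm$calls
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  imp <- g
  for (j in seq_len(ncol(g))) imp[is.na(imp[, j]), j] <- mu[j]
  imp <- scale(imp, center = TRUE, scale = FALSE)

  alive <- rep(TRUE, ncol(g))
  for (contig in unique(gm$loci$contig)) {
    idx <- which(gm$loci$contig == contig)
    start <- 1
    repeat {
      win <- idx[seq(start, min(start + window - 1, length(idx)))]
      win_alive <- win[alive[win]]
      while (length(win_alive) >= 2) {
        v <- vif_in_window(imp[, win_alive, drop = FALSE])
        if (max(v) <= vif_max) break
        drop <- win_alive[which.max(v)]
        alive[drop] <- FALSE
        win_alive <- win[alive[win]]
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + step
    }
  }
  out <- gm_subset(gm, loci = which(alive))
  attr(out, "removed_loci") <- which(!alive)
  out
}

#' Variance inflation factors within a block of loci
#'
#' @param x centered numeric matrix (samples x loci), already mean-imputed.
#' @return Numeric vector of VIFs (1 for zero-variance columns, `Inf` for
#'   perfectly collinear ones).
#' @export
vif_in_window <- function(x) {
  p <- ncol(x)
  vapply(seq_len(p), function(j) {
    y <- x[, j]
    tss <- sum(y^2)
    if (tss < 1e-12) return(1)            # monomorphic
    X <- x[, -j, drop = FALSE]
    fit <- qr(X)
    res <- qr.resid(fit, y)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}
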