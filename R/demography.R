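#' Folded two-population joint allele frequency spectrum
#'
#' Each biallelic SNP contributes one count (or hypergeometric projection
#' weights, when `projection` is given and calls are missing) to the cell
#' indexed by its alternate-allele counts in the two populations; the
#' spectrum is then folded on the combined minor allele: a cell (i, j) with
#' combined count i + j above half the total copies is added into its fold
#' partner (2*n1 - i, 2*n2 - j), and an exact half-count tie goes to the
#' lexicographically smaller cell of the pair. Cells with combined minor
#' count between 1 and `mask_low` are masked (singletons/doubletons carry
#' most genotyping error and are often pre-filtered).
#'
#' @param gm a [genotype_matrix()] of biallelic SNPs.
#' @param pop1,pop2 disjoint character vectors of sample ids (or integer
#'   indices).
#' @param mask_low mask cells with combined minor count <= this (default 2).
#' @param projection optional `c(n1, n2)` diploid sizes to project down to;
#'   without it, sites with any missing call in either population are
#'   dropped.
#' @return List of class `folded_jafs`: `counts` ((2*n1+1) x (2*n2+1)
#'   matrix, row i = minor count i-1 in pop1), `mask` (logical, TRUE =
#'   masked), `n1`, `n2`, `n_sites_used`, `n_sites_dropped`.
#' @export
build_folded_jafs <- function(gm, pop1, pop2, mask_low = 2, projection = NULL) {
  i1 <- if (is.character(pop1)) match(pop1, gm$samples) else pop1
  i2 <- if (is.character(pop2)) match(pop2, gm$samples) else pop2
  if (anyNA(i1) || anyNA(i2)) stop("unknown sample id in pop1/pop2")
  if (length(intersect(i1, i2)) > 0) stop("populations must be disjoint")
  g <- gm$calls[, !gm$invariant, drop = FALSE]
  if (ncol(g) == 0) {
    warning("monomorphic input; empty spectrum")
  }
  g1 <- g[i1, , drop = FALSE]
  g2 <- g[i2, , drop = FALSE]
  if (is.null(projection)) {
    n1 <- length(i1); n2 <- length(i2)
    ok <- colSums(is.na(g1)) == 0 & colSums(is.na(g2)) == 0
    c1 <- colSums(g1[, ok, drop = FALSE])
    c2 <- colSums(g2[, ok, drop = FALSE])
    S <- matrix(0, 2 * n1 + 1, 2 * n2 + 1)
    for (s in seq_along(c1)) S[c1[s] + 1, c2[s] + 1] <- S[c1[s] + 1, c2[s] + 1] + 1
    dropped <- sum(!ok)
  } else {
    n1 <- projection[1]; n2 <- projection[2]
    k1 <- 2 * colSums(!is.na(g1)); a1 <- colSums(g1, na.rm = TRUE)
    k2 <- 2 * colSums(!is.na(g2)); a2 <- colSums(g2, na.rm = TRUE)
    ok <- k1 >= 2 * n1 & k2 >= 2 * n2
    S <- matrix(0, 2 * n1 + 1, 2 * n2 + 1)
    for (s in which(ok)) {
      w1 <- stats::dhyper(0:(2 * n1), a1[s], k1[s] - a1[s], 2 * n1)
      w2 <- stats::dhyper(0:(2 * n2), a2[s], k2[s] - a2[s], 2 * n2)
      S <- S + outer(w1, w2)
    }
    dropped <- sum(!ok)
  }
  half <- (2 * n1 + 2 * n2) / 2
  Fm <- matrix(0, nrow(S), ncol(S))
  for (i in 0:(2 * n1)) for (j in 0:(2 * n2)) {
    v <- S[i + 1, j + 1]
    if (v == 0) next
    tot <- i + j
    fi <- 2 * n1 - i; fj <- 2 * n2 - j
    if (tot < half) {
      Fm[i + 1, j + 1] <- Fm[i + 1, j + 1] + v
    } else if (tot > half) {
      Fm[fi + 1, fj + 1] <- Fm[fi + 1, fj + 1] + v
    } else {
      # tie: lexicographically smaller of (i,j) and (fi,fj)
      if (i < fi || (i == fi && j <= fj)) {
        Fm[i + 1, j + 1] <- Fm[i + 1, j + 1] + v
      } else {
        Fm[fi + 1, fj + 1] <- Fm[fi + 1, fj + 1] + v
      }
    }
  }
  combined <- outer(0:(2 * n1), 0:(2 * n2), "+")
  mask <- combined >= 1 & combined <= mask_low
  dimnames(Fm) <- list(0:(2 * n1), 0:(2 * n2))
  structure(list(counts = Fm, mask = mask, n1 = n1, n2 = n2,
                 n_sites_used = sum(S), n_sites_dropped = dropped),
            class = "folded_jafs")
}

#' @export
print.folded_jafs <- function(x, ...) {
  cat(sprintf("folded_jafs: %d x %d (n1 = %d, n2 = %d diploids), %.4g sites, %d masked cells\n",
              nrow(x$counts), ncol(x$counts), x$n1, x$n2, x$n_sites_used, sum(x$mask)))
  invisible(x)
}

#' Write a folded JAFS as a dense TSV matrix plus mask sidecar
#'
#' @param jafs a `folded_jafs`.
#' @param path output TSV path; the mask goes to `paste0(path, ".mask")`.
#' @return `path`, invisibly.
#' @export
write_jafs_tsv <- function(jafs, path) {
  utils::write.table(jafs$counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(jafs$mask + 0, paste0(path, ".mask"), sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Convert diffusion-model parameters into natural units
#'
#' Fitted two-population divergence-with-migration parameters are scaled by
#' the ancestral reference size. With theta = 4 * Nref * mu * L:
#'
#'   Nref    = theta / (4 mu L)
#'   Ne_i    = nu_i * Nref
#'   m_12    = M12 / (2 Nref)   (fraction of population 1 replaced by
#'                               migrants from population 2, per generation)
#'   m_21    = M21 / (2 Nref)
#'   Nem_ij  = Ne_i * m_ij      (migrants per generation into population i)
#'   t_years = 2 * Nref * T * g
#'
#' Doubling mu halves Nref, both Ne and t_years and doubles both m, leaving
#' Nem invariant — so comparisons of migrant numbers are robust to mutation
#' rate uncertainty even though migration rates are not.
#'
#' @param theta scaled mutation parameter (> 0).
#' @param nu1,nu2 daughter sizes relative to Nref (> 0).
#' @param M12,M21 scaled migration rates (2 * Nref * m), >= 0.
#' @param T_scaled divergence time in 2*Nref generations (> 0).
#' @param mu per-base per-generation mutation rate (default 1.2e-8).
#' @param L callable sequence length in bases — the all-sites span, not the
#'   SNP count (> 0).
#' @param g generation time in years (default 3).
#' @return List of class `demographic_estimates`: `nref`, `ne1`, `ne2`,
#'   `m12`, `m21`, `nem12`, `nem21`, `t_years`, `mu`, `L`, `g`.
#' @export
convert_params <- function(theta, nu1, nu2, M12, M21, T_scaled,
                           mu = 1.2e-8, L, g = 3) {
  stopifnot(theta > 0, nu1 > 0, nu2 > 0, M12 >= 0, M21 >= 0, T_scaled > 0,
            mu > 0, g > 0)
  if (missing(L) || L <= 0) stop("callable length L must be positive")
  nref <- theta / (4 * mu * L)
  ne1 <- nu1 * nref
  ne2 <- nu2 * nref
  m12 <- M12 / (2 * nref)
  m21 <- M21 / (2 * nref)
  structure(list(nref = nref, ne1 = ne1, ne2 = ne2, m12 = m12, m21 = m21,
                 nem12 = ne1 * m12, nem21 = ne2 * m21,
                 t_years = 2 * nref * T_scaled * g, mu = mu, L = L, g = g),
            class = "demographic_estimates")
}

#' @export
print.demographic_estimates <- function(x, ...) {
  cat(sprintf(paste0("demographic_estimates: Nref = %.4g, Ne1 = %.4g, Ne2 = %.4g,\n",
                     "  m12 = %.3g, m21 = %.3g, Nem12 = %.3g, Nem21 = %.3g, T = %.4g yr\n"),
              x$nref, x$ne1, x$ne2, x$m12, x$m21, x$nem12, x$nem21, x$t_years))
  invisible(x)
}

#' Migrants per generation
#'
#' Gene flow as the number of migrant individuals entering the recipient
#' population each generation: Nem = Ne_recipient * m.
#'
#' @param ne_recipient effective size of the recipient population (> 0).
#' @param m per-generation migrant fraction (>= 0).
#' @param signif_digits significant digits for reporting (default 3);
#'   use `Inf` for full precision.
#' @return Migrant count per generation.
#' @export
migrants_per_generation <- function(ne_recipient, m, signif_digits = 3) {
  stopifnot(all(ne_recipient > 0), all(m >= 0))
  x <- ne_recipient * m
  if (is.finite(signif_digits)) signif(x, signif_digits) else x
}

#' Convert a table of fitted diffusion-model parameters
#'
#' Reads a CSV with columns `pair` (optional label), `theta`, `nu1`, `nu2`,
#' `M12`, `M21`, `T`, `L` and optional per-row `mu`, `g`, and converts each
#' row with [convert_params()].
#'
#' @param path CSV path, or a data.frame with those columns.
#' @param mu,g defaults applied where the table has no such column.
#' @return data.frame with one row per pair: nref, ne1, ne2, m12, m21,
#'   nem12, nem21, t_years.
#' @export
convert_params_table <- function(path, mu = 1.2e-8, g = 3) {
  df <- if (is.character(path)) utils::read.csv(path, stringsAsFactors = FALSE) else path
  need <- c("theta", "nu1", "nu2", "M12", "M21", "T", "L")
  if (!all(need %in% names(df))) {
    stop("parameter table needs columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    est <- convert_params(df$theta[i], df$nu1[i], df$nu2[i], df$M12[i],
                          df$M21[i], df$T[i],
                          mu = if ("mu" %in% names(df)) df$mu[i] else mu,
                          L = df$L[i],
                          g = if ("g" %in% names(df)) df$g[i] else g)
    data.frame(pair = if ("pair" %in% names(df)) df$pair[i] else paste0("pair", i),
               nref = est$nref, ne1 = est$ne1, ne2 = est$ne2,
               m12 = est$m12, m21 = est$m21,
               nem12 = est$nem12, nem21 = est$nem21, t_years = est$t_years)
  })
  do.call(rbind, rows)
}
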