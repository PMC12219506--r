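#' Genotype matrix container
#'
#' A `genotype_matrix` holds diploid biallelic genotypes as a samples x loci
#' matrix of alternate-allele counts (0, 1, 2 or `NA` for missing), together
#' with per-locus metadata, optional read depths and a per-locus invariant
#' flag (sites at which no alternate allele was observed, carried along so
#' that diversity statistics can be computed over the full callable length).
#'
#' @param calls integer matrix, samples x loci, values in \{0, 1, 2, NA\}.
#' @param loci data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`; one row per locus. For invariant sites `alt` may be `"."`.
#' @param samples character vector of unique sample ids; defaults to
#'   `rownames(calls)`.
#' @param depths optional matrix of non-negative read depths, same shape as
#'   `calls`.
#' @param invariant logical per-locus flag; defaults to "no alternate allele
#'   observed among non-missing calls".
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, samples = rownames(calls),
                            depths = NULL, invariant = NULL) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  samples <- as.character(samples)
  stopifnot(nrow(calls) == length(samples), ncol(calls) == nrow(loci))
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  loci <- data.frame(contig = as.character(loci$contig),
                     pos = as.integer(loci$pos),
                     ref = as.character(loci$ref),
                     alt = as.character(loci$alt),
                     stringsAsFactors = FALSE)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    stopifnot(all(dim(depths) == dim(calls)))
    if (any(depths < 0, na.rm = TRUE)) stop("negative read depth")
  }
  if (is.null(invariant)) {
    alt_seen <- colSums(calls > 0, na.rm = TRUE) > 0
    invariant <- !alt_seen
  }
  dimnames(calls) <- list(samples, locus_ids(loci))
  if (!is.null(depths)) dimnames(depths) <- dimnames(calls)
  structure(list(samples = samples, loci = loci, calls = calls,
                 depths = depths, invariant = as.logical(invariant)),
            class = "genotype_matrix")
}

locus_ids <- function(loci) {
  if (nrow(loci) == 0) return(character(0))
  paste0(loci$contig, ":", loci$pos, "_", loci$ref, "/", loci$alt)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d invariant), %.1f%% missing\n",
              length(x$samples), nrow(x$loci), sum(x$invariant),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample and/or locus index
#'
#' @param gm a `genotype_matrix`.
#' @param samples,loci index vectors (integer, logical or sample-id character
#'   for samples); missing means keep all.
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_along(gm$samples) else samples
  if (is.character(si)) si <- match(si, gm$samples)
  li <- if (is.null(loci)) seq_len(nrow(gm$loci)) else loci
  genotype_matrix(gm$calls[si, li, drop = FALSE],
                  gm$loci[li, , drop = FALSE],
                  samples = gm$samples[si],
                  depths = if (!is.null(gm$depths)) gm$depths[si, li, drop = FALSE],
                  invariant = gm$invariant[li])
}

#' Per-sample and per-site missingness fractions
#' @param gm a `genotype_matrix`.
#' @return For `sample_missingness`, a named numeric vector over samples; for
#'   `site_missingness`, a numeric vector over loci.
#' @export
sample_missingness <- function(gm) rowMeans(is.na(gm$calls))

#' @rdname sample_missingness
#' @export
site_missingness <- function(gm) colMeans(is.na(gm$calls))

#' Round-trip a genotype matrix through a TSV dialect
#'
#' Samples as rows, loci as columns (`contig:pos_ref/alt` headers), values
#' 0/1/2/NA. Depths and the invariant flag are not serialized.
#'
#' @param gm a `genotype_matrix`.
#' @param path output / input file path.
#' @return `read_genotype_tsv` returns a `genotype_matrix`;
#'   `write_genotype_tsv` returns `path` invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(sample = gm$samples, gm$calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- df$sample
  calls <- as.matrix(df[, -1, drop = FALSE])
  ids <- colnames(calls)
  m <- regmatches(ids, regexec("^(.*):([0-9]+)_([^/]*)/(.*)$", ids))
  loci <- data.frame(contig = vapply(m, `[`, "", 2),
                     pos = as.integer(vapply(m, `[`, "", 3)),
                     ref = vapply(m, `[`, "", 4),
                     alt = vapply(m, `[`, "", 5))
  genotype_matrix(calls, loci, samples = samples)
}
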