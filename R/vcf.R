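#' Read diploid genotypes from a VCF file
#'
#' Parses a VCF 4.x file (gzip accepted) into a [genotype_matrix()]. Two
#' dialects are supported: `"variant"` keeps biallelic SNPs only, while
#' `"all-sites"` additionally keeps monomorphic records (ALT absent or `.`)
#' flagged as invariant, so that downstream diversity statistics can use the
#' full callable length. Indels and multi-allelic records are excluded in
#' both modes; in all-sites mode their counts are retained in the
#' `"excluded"` attribute so the callable span can be accounted for.
#'
#' @param path path to a VCF (optionally bgzip/gzip compressed).
#' @param mode `"variant"` or `"all-sites"`.
#' @return A `genotype_matrix` with attribute `excluded`, a named integer
#'   vector counting records dropped per reason.
#' @export
read_genotypes <- function(path, mode = c("variant", "all-sites")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt1 <- rep(".", length(n_alt))
  has_alt <- n_alt >= 1
  alt1[has_alt] <- vapply(which(has_alt), function(i) {
    as.character(alt_list[[i]][1])
  }, "")
  alt1[alt1 == ""] <- "."

  # ploidy check before any exclusion, naming the offending record
  bad_ploidy <- !grepl("^\\.$|^\\./\\.$|^\\.\\|\\.$|^[0-9]+[/|][0-9]+$", gt)
  # a bare single allele ("0") or triploid ("0/0/1") both fail the pattern;
  # fully missing forms are allowed
  if (any(bad_ploidy)) {
    bad_ploidy <- matrix(bad_ploidy, nrow(gt), ncol(gt))
    i <- which(bad_ploidy, arr.ind = TRUE)[1, ]
    stop(sprintf("non-diploid genotype '%s' at %s:%d",
                 gt[i[1], i[2]], contig[i[1]], pos[i[1]]))
  }

  multi <- n_alt > 1
  invariant <- alt1 == "." | !has_alt
  indel <- nchar(ref) != 1 |
    (!invariant & vapply(seq_along(n_alt), function(i) {
      any(nchar(as.character(alt_list[[i]])) != 1) && !multi[i]
    }, TRUE))
  # multi-allelic records containing an indel allele count once, as multi
  indel[multi] <- FALSE
  star <- alt1 == "*"

  keep <- !multi & !indel & !star
  if (mode == "variant") keep <- keep & !invariant
  excluded <- c(multiallelic = sum(multi), indel = sum(indel & !multi),
                spanning_deletion = sum(star),
                invariant = if (mode == "variant") sum(invariant & !multi & !indel) else 0L)

  if (!any(keep)) stop("no usable records in VCF: ", path)
  gt <- gt[keep, , drop = FALSE]
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt))
  miss <- gt %in% c(".", "./.", ".|.")
  gsub_gt <- gt
  counts[!miss] <- vapply(strsplit(gsub_gt[!miss], "[/|]"), function(a) {
    sum(as.integer(a) > 0)
  }, 0L)
  dp <- VariantAnnotation::geno(vcf)$DP
  depths <- if (!is.null(dp)) t(dp[keep, , drop = FALSE])

  loci <- data.frame(contig = contig[keep], pos = pos[keep],
                     ref = ref[keep], alt = alt1[keep])
  gm <- genotype_matrix(t(counts), loci, samples = colnames(gt),
                        depths = depths, invariant = invariant[keep])
  attr(gm, "excluded") <- excluded
  gm
}

#' Read a sample metadata table
#'
#' Expects a CSV with at least `sample` plus either geographic coordinates
#' (`lat`, `lon` decimal degrees) or planar coordinates (`x`, `y` meters);
#' optional `population`, `site`, `depth` columns are carried through.
#'
#' @param path CSV file path.
#' @return A data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(st)
}

validate_sample_table <- function(st) {
  if (!"sample" %in% names(st)) stop("sample table needs a 'sample' column")
  if (anyDuplicated(st$sample)) stop("duplicate sample ids in sample table")
  if (all(c("lat", "lon") %in% names(st))) {
    if (any(abs(st$lat) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
    if (any(abs(st$lon) > 180, na.rm = TRUE)) stop("longitude outside [-180, 180]")
  } else if (!all(c("x", "y") %in% names(st))) {
    stop("sample table needs lat/lon or x/y coordinates")
  }
  st
}

#' Write a genotype matrix as a minimal VCF 4.2 text file
#'
#' Emits GT (and DP when present) for all samples. Invariant loci are written
#' with ALT "." so the all-sites dialect round-trips.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path (plain text; not compressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=dispersalkit_%s",
                   as.character(utils::packageVersion("dispersalkit"))),
           paste0("##contig=<ID=", unique(gm$loci$contig), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
  ok <- !is.na(gm$calls)
  gt[ok] <- code[as.character(gm$calls[ok])]
  o <- order(gm$loci$contig, gm$loci$pos)
  body <- vapply(o, function(j) {
    paste(c(gm$loci$contig[j], gm$loci$pos[j], ".", gm$loci$ref[j],
            gm$loci$alt[j], ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
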