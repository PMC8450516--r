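#' Construct a variant table
#'
#' A variant table is the package's representation of a set of biallelic
#' SNPs: a data.frame with columns `chrom` (label, e.g. "chr3"), `pos`
#' (1-based position), `rsid`, `ref` and `alt` (single-nucleotide alleles).
#' Positions are always 1-based; peak intervals are 0-based half-open (BED
#' convention), and the single conversion point between the two lives in
#' [build_index()].
#'
#' @param chrom chromosome labels.
#' @param pos 1-based positions (positive integers).
#' @param rsid variant identifiers (non-empty, unique).
#' @param ref,alt single-character nucleotide codes, `ref != alt` per row.
#' @return a validated data.frame of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, rsid,
                          ref = rep("G", length(pos)),
                          alt = rep("A", length(pos))) {
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  rsid = as.character(rsid), ref = as.character(ref),
                  alt = as.character(alt), stringsAsFactors = FALSE)
  validate_variants(v)
}

#' Validate a variant table
#'
#' @param v a data.frame with columns chrom, pos, rsid, ref, alt.
#' @return `v`, invisibly classed as `variant_table`, or an error.
#' @export
validate_variants <- function(v) {
  sf_assert(all(c("chrom", "pos", "rsid", "ref", "alt") %in% names(v)),
            "variant table must have columns chrom, pos, rsid, ref, alt")
  sf_assert(all(v$pos >= 1L), "variant positions must be >= 1 (1-based)")
  sf_assert(all(nzchar(v$rsid)), "rsid must be non-empty")
  sf_assert(!anyDuplicated(v$rsid), "rsid values must be unique")
  sf_assert(all(v$ref != v$alt), "ref and alt alleles must differ")
  class(v) <- unique(c("variant_table", class(v)))
  v
}

#' Read a tiered tag-SNP catalog
#'
#' Reads a tab-separated catalog of GWAS sentinel ("tag") SNPs with header
#' columns `rsid`, `chrom`, `pos`, `pvalue` and assigns each row to a
#' significance tier: `genome_wide` for p < 5e-8 and `subthreshold` for
#' 5e-8 <= p < 1e-5. Rows at or above 1e-5 are dropped; the number dropped
#' is attached as attribute `n_dropped` and reported via a message.
#'
#' @param path path to the catalog file.
#' @return a data.frame of class `tag_catalog` with columns rsid, chrom,
#'   pos, pvalue, tier, plus attribute `n_dropped`.
#' @export
read_tag_catalog <- function(path) {
  sf_assert(file.exists(path), paste0("catalog file not found: ", path),
            "snpfunnel_io_error")
  d <- read.delim(path, stringsAsFactors = FALSE)
  sf_assert(all(c("rsid", "chrom", "pos", "pvalue") %in% names(d)),
            "tag catalog needs header columns rsid, chrom, pos, pvalue",
            "snpfunnel_parse_error")
  tier_tag_catalog(d)
}

#' Tier a tag-SNP table by GWAS significance
#'
#' @param d data.frame with columns rsid, chrom, pos, pvalue.
#' @param subthreshold_max upper p-value bound; rows at or above it are
#'   dropped (default 1e-5).
#' @param genomewide_max genome-wide significance bound (default 5e-8).
#' @return `tag_catalog` data.frame; see [read_tag_catalog()].
#' @export
tier_tag_catalog <- function(d, subthreshold_max = 1e-5,
                             genomewide_max = 5e-8) {
  sf_assert(all(d$pvalue > 0 & d$pvalue <= 1),
            "tag p-values must lie in (0, 1]")
  keep <- d$pvalue < subthreshold_max
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " tag SNP(s) dropped with p >= ", subthreshold_max)
  d <- d[keep, , drop = FALSE]
  d$pos <- as.integer(d$pos)
  d$tier <- ifelse(d$pvalue < genomewide_max, "genome_wide", "subthreshold")
  rownames(d) <- NULL
  attr(d, "n_dropped") <- n_dropped
  class(d) <- unique(c("tag_catalog", class(d)))
  d
}

#' Write a tag-SNP catalog
#'
#' @param catalog a `tag_catalog` or compatible data.frame.
#' @param path destination path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_tag_catalog <- function(catalog, path) {
  cols <- intersect(c("rsid", "chrom", "pos", "pvalue"), names(catalog))
  write.table(catalog[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
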