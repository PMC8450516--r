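#' Construct a genotype matrix
#'
#' Samples-by-variants matrix of alternate-allele dosages in {0, 1, 2}.
#' Missing calls are `NA` — a distinct sentinel never conflated with dosage
#' 0, because call-rate QC counts it. When `phased = TRUE`, per-sample
#' haplotypes are carried as two 0/1 allele matrices whose sum must equal
#' the dosage codes.
#'
#' @param codes integer matrix (samples x variants) with values 0, 1, 2 or
#'   `NA`; rownames are sample ids.
#' @param variants a [variant_table()] describing the columns, in order.
#' @param samples sample identifiers; defaults to `rownames(codes)`.
#' @param phased logical; are haplotypes known?
#' @param hap1,hap2 0/1 matrices of per-haplotype alleles (phased only).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, variants, samples = rownames(codes),
                            phased = FALSE, hap1 = NULL, hap2 = NULL) {
  variants <- validate_variants(variants)
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  sf_assert(ncol(codes) == nrow(variants),
            "codes must have one column per variant")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(codes)))
  sf_assert(length(samples) == nrow(codes),
            "one sample id per row of codes")
  sf_assert(all(codes %in% c(0L, 1L, 2L) | is.na(codes)),
            "genotype codes must be 0, 1, 2 or NA")
  rownames(codes) <- samples
  colnames(codes) <- variants$rsid
  if (phased) {
    sf_assert(!is.null(hap1) && !is.null(hap2),
              "phased genotype matrix requires hap1 and hap2")
    sf_assert(all(dim(hap1) == dim(codes)) && all(dim(hap2) == dim(codes)),
              "haplotype matrices must match codes dimensions")
    ok <- is.na(codes) | (hap1 + hap2 == codes)
    sf_assert(all(ok), "haplotype alleles must sum to the genotype code")
    dimnames(hap1) <- dimnames(hap2) <- dimnames(codes)
  }
  structure(list(samples = as.character(samples), variants = variants,
                 codes = codes, phased = isTRUE(phased),
                 hap1 = hap1, hap2 = hap2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d sample(s) x %d variant(s), %s>\n",
              length(x$samples), nrow(x$variants),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix by variant
#'
#' @param gm a `genotype_matrix`.
#' @param rsids variant identifiers to keep, in the given order.
#' @return a `genotype_matrix` restricted to `rsids`.
#' @export
subset_variants <- function(gm, rsids) {
  idx <- match(rsids, gm$variants$rsid)
  sf_assert(!anyNA(idx), "rsid(s) absent from genotype matrix",
            "snpfunnel_lookup_error")
  genotype_matrix(gm$codes[, idx, drop = FALSE],
                  validate_variants(gm$variants[idx, , drop = FALSE]),
                  samples = gm$samples, phased = gm$phased,
                  hap1 = if (gm$phased) gm$hap1[, idx, drop = FALSE],
                  hap2 = if (gm$phased) gm$hap2[, idx, drop = FALSE])
}

#' Stack two genotype matrices over samples (same variants)
#'
#' Used by the two-stage workflow to pool individual-level data. Variants
#' are intersected by rsid; sample ids must not collide.
#'
#' @param a,b `genotype_matrix` objects.
#' @return unphased pooled `genotype_matrix`.
#' @export
rbind_genotypes <- function(a, b) {
  shared <- intersect(a$variants$rsid, b$variants$rsid)
  sf_assert(length(shared) > 0, "no shared variants to pool")
  sf_assert(!any(a$samples %in% b$samples),
            "sample ids collide between pooled genotype matrices")
  a <- subset_variants(a, shared); b <- subset_variants(b, shared)
  genotype_matrix(rbind(a$codes, b$codes), a$variants,
                  samples = c(a$samples, b$samples))
}

# ---- genotype TSV dialect ---------------------------------------------------
# header comments: "##phased=true|false" and one "##variant=rsid,chrom,pos,
# ref,alt" line per column; then "sample<TAB>rs1<TAB>rs2..." and body cells
# in {0,1,2,NA} (unphased) or "a|b" (phased).

#' Read genotypes from TSV or VCF
#'
#' The TSV dialect is `sample<TAB>rs1<TAB>rs2...` with cells in
#' {0, 1, 2, NA}; `##variant=` comment lines carry variant coordinates and
#' `##phased=true` switches cells to `a|b` haplotype pairs. VCF intake uses
#' the GT field only (diploid calls; `.` becomes missing); the matrix is
#' flagged phased only when every GT separator is `|`.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  sf_assert(file.exists(path), paste0("genotype file not found: ", path),
            "snpfunnel_io_error")
  if (format == "vcf") return(read_genotypes_vcf(path))
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "##") & nzchar(lines)]
  sf_assert(length(body) >= 1, "genotype TSV has no header line",
            "snpfunnel_parse_error")
  phased <- any(grepl("^##phased=true$", meta))
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  sf_assert(header[1] == "sample",
            "genotype TSV header must start with 'sample'",
            "snpfunnel_parse_error")
  rsids <- header[-1]
  vmeta <- sub("^##variant=", "", meta[startsWith(meta, "##variant=")])
  if (length(vmeta) > 0) {
    vm <- do.call(rbind, strsplit(vmeta, ",", fixed = TRUE))
    variants <- variant_table(vm[, 2], as.integer(vm[, 3]), vm[, 1],
                              vm[, 4], vm[, 5])
    variants <- validate_variants(
      variants[match(rsids, variants$rsid), , drop = FALSE])
  } else {
    variants <- variant_table(rep("chrUn", length(rsids)),
                              seq_along(rsids), rsids)
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad) > 0)
    sf_abort(sprintf("inconsistent column count on data row %d of %s",
                     bad[1], path), "snpfunnel_parse_error")
  samples <- vapply(rows, `[[`, "", 1L)
  cells <- matrix(unlist(lapply(rows, `[`, -1L)),
                  nrow = length(rows), byrow = TRUE)
  if (phased) {
    miss <- cells == "NA" | cells == ".|."
    a1 <- suppressWarnings(as.integer(sub("\\|.*", "", cells)))
    a2 <- suppressWarnings(as.integer(sub(".*\\|", "", cells)))
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    sf_assert(all(is.na(a1) | a1 %in% 0:1), "phased cells must be 'a|b'",
              "snpfunnel_parse_error")
    codes <- a1 + a2
    genotype_matrix(matrix(codes, nrow = length(samples)), variants,
                    samples = samples, phased = TRUE,
                    hap1 = matrix(a1, nrow = length(samples)),
                    hap2 = matrix(a2, nrow = length(samples)))
  } else {
    codes <- suppressWarnings(as.integer(cells))
    codes[cells == "NA"] <- NA_integer_
    genotype_matrix(matrix(codes, nrow = length(samples)), variants,
                    samples = samples)
  }
}

read_genotypes_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  sf_assert(!is.null(gt), "VCF has no GT field", "snpfunnel_parse_error")
  gt_chr <- as.character(gt)
  sf_assert(all(grepl("^(\\.|[01])([/|](\\.|[01]))?$", gt_chr)),
            "only diploid biallelic GT calls are supported",
            "snpfunnel_unsupported_error")
  sf_assert(all(grepl("[/|]", gt_chr)),
            "only diploid GT calls are supported",
            "snpfunnel_unsupported_error")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  sf_assert(length(alt) == nrow(gt),
            "multi-allelic VCF records are not supported",
            "snpfunnel_unsupported_error")
  variants <- variant_table(as.character(GenomicRanges::seqnames(rr)),
                            GenomicRanges::start(rr), rownames(gt),
                            as.character(rr$REF), alt)
  a1c <- sub("[/|].*", "", gt_chr); a2c <- sub(".*[/|]", "", gt_chr)
  a1 <- suppressWarnings(as.integer(a1c)); a2 <- suppressWarnings(as.integer(a2c))
  codes <- a1 + a2  # NA whenever either allele is "."
  dim(codes) <- dim(gt)
  phased <- all(grepl("\\|", gt_chr))
  samples <- colnames(gt)
  codes <- t(codes)  # VCF is variants x samples
  if (phased) {
    h1 <- t(matrix(a1, nrow = nrow(gt))); h2 <- t(matrix(a2, nrow = nrow(gt)))
    genotype_matrix(codes, variants, samples = samples, phased = TRUE,
                    hap1 = h1, hap2 = h2)
  } else {
    genotype_matrix(codes, variants, samples = samples)
  }
}

#' Write genotypes in the package TSV dialect
#'
#' Round-trips with [read_genotypes()]: variant coordinates travel in
#' `##variant=` header comments and the phased flag in `##phased=`.
#'
#' @param gm a `genotype_matrix`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("##phased=%s", tolower(gm$phased)), con)
  v <- gm$variants
  writeLines(sprintf("##variant=%s,%s,%d,%s,%s",
                     v$rsid, v$chrom, v$pos, v$ref, v$alt), con)
  writeLines(paste(c("sample", v$rsid), collapse = "\t"), con)
  if (gm$phased) {
    cells <- matrix(paste0(gm$hap1, "|", gm$hap2), nrow = nrow(gm$codes))
    cells[is.na(gm$codes)] <- "NA"
  } else {
    cells <- matrix(as.character(gm$codes), nrow = nrow(gm$codes))
    cells[is.na(cells)] <- "NA"
  }
  writeLines(paste(gm$samples,
                   apply(cells, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

# ---- phenotype table --------------------------------------------------------

PHENO_COLS <- c("sample", "status", "age", "sex", "smoking", "histology",
                "stage")

#' Construct / validate a phenotype table
#'
#' One row per sample: `status` in {case, control}, `age` in years, `sex`
#' in {male, female}, `smoking` in {smoker, nonsmoker, unknown},
#' `histology` in {adeno, scc, other} for cases and `NA` for controls,
#' `stage` in {stage1, stage2}.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame, classed `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  sf_assert(all(PHENO_COLS %in% names(df)),
            paste("phenotype table needs columns:",
                  paste(PHENO_COLS, collapse = ", ")))
  sf_assert(!anyDuplicated(df$sample), "every sample appears once")
  sf_assert(all(df$status %in% c("case", "control")),
            "status must be 'case' or 'control'")
  sf_assert(all(df$sex %in% c("male", "female")),
            "sex must be 'male' or 'female'")
  sf_assert(all(df$smoking %in% c("smoker", "nonsmoker", "unknown")),
            "smoking must be smoker/nonsmoker/unknown")
  sf_assert(all(is.na(df$histology) |
                  df$histology %in% c("adeno", "scc", "other")),
            "histology must be adeno/scc/other or NA")
  sf_assert(all(is.na(df$histology[df$status == "control"])),
            "histology must be NA for controls")
  sf_assert(all(df$stage %in% c("stage1", "stage2")),
            "stage must be 'stage1' or 'stage2'")
  class(df) <- unique(c("phenotype_table", class(df)))
  df
}

#' Read a phenotype table (tab-separated)
#' @param path input file with header `sample status age sex smoking
#'   histology stage`.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  sf_assert(file.exists(path), paste0("phenotype file not found: ", path),
            "snpfunnel_io_error")
  d <- read.delim(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  d$sample <- as.character(d$sample)
  phenotype_table(d)
}

#' Write a phenotype table (tab-separated)
#' @param phen a `phenotype_table`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phen, path) {
  write.table(as.data.frame(phen)[, PHENO_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
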