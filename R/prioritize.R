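# The candidate-selection funnel: tiered tag SNPs -> LD expansion ->
# open-chromatin overlap -> histone-mark overlap, with per-stage counts.

#' Run the variant-prioritization funnel
#'
#' Stage order: (1) tally the catalog tiers; (2) expand every tag through
#' [ld_expand()] against the reference panel, de-duplicating variants that
#' tag multiple loci by rsid (all tags kept as provenance, maximal r2
#' retained; tags pass through as their own proxies with r2 = 1); (3) keep
#' variants inside open-chromatin peaks; (4) keep variants also inside
#' histone-mark peaks. The two peak sets are applied in succession, not as
#' a joint requirement on a single interval. Tags absent from the panel
#' are logged and skipped. Output ordering is deterministic (chrom, pos).
#'
#' @param catalog a `tag_catalog` (see [read_tag_catalog()]).
#' @param panel a [genotype_matrix()] reference panel.
#' @param atac open-chromatin [peak_set()].
#' @param h3k27ac histone-mark [peak_set()].
#' @param r2_min LD retention threshold, strict (default 0.2).
#' @param window_bp LD search half-window (default 500000).
#' @param autosomes_only restrict peak filtering to chr1-22 (default TRUE).
#' @return object of class `pipeline_report`.
#' @export
run_funnel <- function(catalog, panel, atac, h3k27ac, r2_min = 0.2,
                       window_bp = 500000L, autosomes_only = TRUE) {
  sf_assert(all(c("rsid", "tier") %in% names(catalog)),
            "catalog must be a tiered tag catalog")
  n_gw <- sum(catalog$tier == "genome_wide")
  n_sub <- sum(catalog$tier == "subthreshold")
  skipped_tags <- character()
  expansions <- list()
  for (k in seq_len(nrow(catalog))) {
    tag <- catalog$rsid[k]
    exp_k <- tryCatch(ld_expand(tag, panel, r2_min, window_bp),
                      snpfunnel_lookup_error = function(e) NULL)
    if (is.null(exp_k)) {
      skipped_tags <- c(skipped_tags, tag)
      next
    }
    expansions[[length(expansions) + 1L]] <- exp_k
  }
  ld_all <- if (length(expansions)) do.call(rbind, expansions) else
    data.frame(rsid = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), tag = character(),
               r2 = numeric(), dprime = numeric(), n_used = integer())
  # de-duplicate by rsid: keep max r2, remember every tag
  if (nrow(ld_all) > 0) {
    ord <- order(ld_all$rsid, -ld_all$r2)
    ld_all <- ld_all[ord, , drop = FALSE]
    tags_by_rsid <- vapply(
      split(ld_all$tag, ld_all$rsid),
      function(x) paste(sort(unique(x)), collapse = ","), "")
    dedup <- ld_all[!duplicated(ld_all$rsid), , drop = FALSE]
    dedup$tags <- tags_by_rsid[dedup$rsid]
    dedup$tag <- NULL
  } else {
    dedup <- ld_all
    dedup$tags <- character(0)
    dedup$tag <- NULL
  }
  ld_variants <- validate_variants(
    data.frame(chrom = dedup$chrom, pos = dedup$pos, rsid = dedup$rsid,
               ref = dedup$ref, alt = dedup$alt,
               stringsAsFactors = FALSE))
  atac_idx <- build_index(atac, autosomes_only = autosomes_only)
  in_ocr <- filter_variants(ld_variants, atac_idx)
  h3k_idx <- build_index(h3k27ac, autosomes_only = autosomes_only)
  cand <- filter_variants(validate_variants(
    in_ocr[, c("chrom", "pos", "rsid", "ref", "alt"), drop = FALSE]),
    h3k_idx)
  atac_hits <- in_ocr$n_hits[match(cand$rsid, in_ocr$rsid)]
  meta_idx <- match(cand$rsid, dedup$rsid)
  candidates <- data.frame(
    rsid = cand$rsid, chrom = cand$chrom, pos = cand$pos,
    ref = cand$ref, alt = cand$alt,
    tags = dedup$tags[meta_idx], max_r2 = dedup$r2[meta_idx],
    atac_hits = atac_hits, h3k27ac_hits = cand$n_hits,
    stringsAsFactors = FALSE)
  ord <- order(norm_chrom(candidates$chrom), candidates$pos,
               candidates$rsid)
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL
  counts <- c(n_tags_total = n_gw + n_sub, n_tags_genomewide = n_gw,
              n_tags_subthreshold = n_sub,
              n_tags_skipped = length(skipped_tags),
              n_ld_variants = nrow(dedup), n_in_ocr = nrow(in_ocr),
              n_candidates = nrow(candidates))
  sf_assert(counts[["n_candidates"]] <= counts[["n_in_ocr"]] &&
              counts[["n_in_ocr"]] <= counts[["n_ld_variants"]],
            "funnel counts must be monotone non-increasing")
  structure(list(counts = counts, candidates = candidates,
                 skipped_tags = skipped_tags,
                 params = c(r2_min = r2_min, window_bp = window_bp)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(format_funnel_summary(x), sep = "\n")
  invisible(x)
}

format_funnel_summary <- function(report) {
  cn <- report$counts
  c("Variant prioritization funnel",
    "=============================",
    sprintf("tag SNPs:            %d (%d genome-wide, %d subthreshold)",
            cn[["n_tags_total"]], cn[["n_tags_genomewide"]],
            cn[["n_tags_subthreshold"]]),
    sprintf("tags absent from panel: %d", cn[["n_tags_skipped"]]),
    sprintf("after LD expansion (r2 > %g, +/-%d bp): %d variants",
            report$params[["r2_min"]],
            as.integer(report$params[["window_bp"]]),
            cn[["n_ld_variants"]]),
    sprintf("within open chromatin:  %d", cn[["n_in_ocr"]]),
    sprintf("also under H3K27ac:     %d candidates",
            cn[["n_candidates"]]))
}

#' Write a funnel report to disk
#'
#' Produces three files under `dir`: `summary.txt` (human-readable funnel
#' accounting), `candidates.tsv` (machine-readable candidate table with
#' provenance columns) and `counts.tsv` (stage counts). [read_report()]
#' reconstructs the report from them.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) sf_abort(paste0("cannot create report directory: ", dir),
                    "snpfunnel_io_error")
  writeLines(format_funnel_summary(report), file.path(dir, "summary.txt"))
  write.table(report$candidates, file.path(dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cn <- report$counts
  write.table(data.frame(stage = names(cn), count = as.integer(cn)),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  params <- report$params
  write.table(data.frame(param = names(params), value = params),
              file.path(dir, "params.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a funnel report written by [write_report()]
#'
#' @param dir report directory.
#' @return a `pipeline_report` (skipped tag identities are not persisted;
#'   their count is).
#' @export
read_report <- function(dir) {
  cand_path <- file.path(dir, "candidates.tsv")
  counts_path <- file.path(dir, "counts.tsv")
  sf_assert(file.exists(cand_path) && file.exists(counts_path),
            paste0("not a report directory: ", dir), "snpfunnel_io_error")
  candidates <- read.delim(cand_path, stringsAsFactors = FALSE,
                           colClasses = c(tags = "character"))
  if (nrow(candidates) == 0) candidates$tags <- character(0)
  cn <- read.delim(counts_path, stringsAsFactors = FALSE)
  counts <- setNames(as.integer(cn$count), cn$stage)
  pr <- read.delim(file.path(dir, "params.tsv"), stringsAsFactors = FALSE)
  structure(list(counts = counts, candidates = candidates,
                 skipped_tags = character(counts[["n_tags_skipped"]]),
                 params = setNames(pr$value, pr$param)),
            class = "pipeline_report")
}
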