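#' Build an interval index over a peak set
#'
#' Converts BED-convention intervals (0-based half-open) into 1-based
#' closed ranges — the package's single coordinate conversion point — and
#' wraps them in a `GRanges` so membership queries use the nested
#' containment list machinery of IRanges rather than a linear scan. A
#' 1-based SNP position `p` overlaps a BED interval `(s, e]` iff
#' `s < p <= e`, i.e. iff `p` falls in the closed range `[s + 1, e]`.
#' Chromosome labels are normalized with [norm_chrom()].
#'
#' @param peaks a [peak_set()].
#' @param autosomes_only drop intervals off chr1-chr22 (default TRUE, since
#'   accessibility segment counts are conventionally reported on autosomes).
#' @return object of class `interval_index`.
#' @export
build_index <- function(peaks, autosomes_only = TRUE) {
  sf_assert(inherits(peaks, "peak_set"), "peaks must be a peak_set")
  ints <- peaks$intervals
  if (autosomes_only && nrow(ints) > 0)
    ints <- ints[is_autosome(ints$chrom), , drop = FALSE]
  gr <- if (nrow(ints) == 0) {
    GenomicRanges::GRanges()
  } else {
    GenomicRanges::GRanges(
      seqnames = norm_chrom(ints$chrom),
      ranges = IRanges::IRanges(start = ints$start + 1, end = ints$end))
  }
  structure(list(name = peaks$name, gr = gr,
                 intervals = ints, autosomes_only = autosomes_only),
            class = "interval_index")
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf("<interval_index over '%s': %d interval(s)>\n",
              x$name, length(x$gr)))
  invisible(x)
}

variant_granges <- function(v) {
  GenomicRanges::GRanges(seqnames = norm_chrom(v$chrom),
                         ranges = IRanges::IRanges(start = v$pos,
                                                   width = 1L))
}

#' Test whether a variant lies inside any indexed peak
#'
#' @param v one-row [variant_table()] (or a list with chrom and pos).
#' @param idx an [build_index()] result.
#' @return list with `hit` (logical) and `intervals` (data.frame of the
#'   source intervals containing the position, BED coordinates).
#' @export
variant_in_peaks <- function(v, idx) {
  v <- as.data.frame(v)[1, , drop = FALSE]
  if (length(idx$gr) == 0)
    return(list(hit = FALSE, intervals = idx$intervals[0, , drop = FALSE]))
  q <- variant_granges(v)
  GenomeInfoDb::seqlevels(q) <- union(GenomeInfoDb::seqlevels(idx$gr),
                                      GenomeInfoDb::seqlevels(q))
  ov <- GenomicRanges::findOverlaps(q, idx$gr)
  hits <- S4Vectors::subjectHits(ov)
  list(hit = length(hits) > 0,
       intervals = idx$intervals[hits, , drop = FALSE])
}

#' Filter variants to those inside indexed peaks
#'
#' Order-preserving subset of `vs`; each retained variant is annotated with
#' the number of peak intervals containing it (`n_hits`) and the hit
#' intervals themselves (attribute `hits`, a list column-free data.frame
#' keyed by rsid). Filtering is monotone and idempotent.
#'
#' @param vs a [variant_table()].
#' @param idx an [build_index()] result.
#' @return the retained subset of `vs` with an `n_hits` column.
#' @export
filter_variants <- function(vs, idx) {
  vs <- as.data.frame(vs)
  if (nrow(vs) == 0 || length(idx$gr) == 0) {
    out <- vs[integer(0), , drop = FALSE]
    out$n_hits <- integer(0)
    attr(out, "hits") <- list()
    return(out)
  }
  q <- variant_granges(vs)
  GenomeInfoDb::seqlevels(q) <- union(GenomeInfoDb::seqlevels(idx$gr),
                                      GenomeInfoDb::seqlevels(q))
  ov <- GenomicRanges::findOverlaps(q, idx$gr)
  qh <- S4Vectors::queryHits(ov)
  keep <- sort(unique(qh))
  out <- vs[keep, , drop = FALSE]
  out$n_hits <- as.integer(table(factor(qh, levels = keep)))
  hit_list <- split(S4Vectors::subjectHits(ov), qh)
  attr(out, "hits") <- setNames(
    lapply(hit_list, function(i) idx$intervals[i, , drop = FALSE]),
    vs$rsid[keep])
  rownames(out) <- NULL
  out
}
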