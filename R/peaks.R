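#' Construct a peak set
#'
#' A peak set holds genomic intervals from an accessibility or histone-mark
#' assay in BED convention: 0-based, half-open `[start, end)`. Intervals are
#' kept exactly as provided (overlaps and duplicates included).
#'
#' @param chrom chromosome labels.
#' @param start 0-based inclusive starts (non-negative).
#' @param end exclusive ends, `end > start` per interval.
#' @param name label for the peak set (e.g. "ATAC", "H3K27ac").
#' @param score optional per-interval score (narrowPeak signalValue).
#' @return object of class `peak_set`: list with `name` and a data.frame
#'   `intervals` (chrom, start, end, score).
#' @export
peak_set <- function(chrom, start, end, name = "peaks", score = NA_real_) {
  sf_assert(length(chrom) == length(start) && length(start) == length(end),
            "chrom, start and end must have equal length")
  start <- as.numeric(start); end <- as.numeric(end)
  sf_assert(all(start >= 0), "peak coordinates must be non-negative")
  sf_assert(all(start < end), "peak intervals require start < end")
  ints <- data.frame(chrom = as.character(chrom), start = start, end = end,
                     score = rep_len(as.numeric(score), length(start)),
                     stringsAsFactors = FALSE)
  structure(list(name = name, intervals = ints), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set '%s': %d interval(s) on %d chromosome(s)>\n",
              x$name, nrow(x$intervals),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Number of intervals in a peak set
#' @param x a `peak_set`.
#' @param ... ignored.
#' @export
length.peak_set <- function(x) nrow(x$intervals)

#' Read a BED or narrowPeak file into a peak set
#'
#' Parses BED3+ (at least three tab-separated columns) or ENCODE narrowPeak
#' (exactly ten columns; column 7, signalValue, is stored as the interval
#' score). Lines starting with `track`, `browser` or `#`, and blank lines,
#' are skipped. Coordinates follow the BED convention (0-based half-open)
#' and chromosome labels are preserved verbatim.
#'
#' @param path path to the file.
#' @param dialect `"bed3plus"` or `"narrowpeak"`.
#' @param name peak-set label; defaults to the file name without extension.
#' @return a [peak_set()].
#' @export
read_bed <- function(path, dialect = c("bed3plus", "narrowpeak"),
                     name = NULL) {
  dialect <- match.arg(dialect)
  sf_assert(file.exists(path), paste0("BED file not found: ", path),
            "snpfunnel_io_error")
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  data_idx <- which(!grepl("^(track|browser|#)", lines) & nzchar(lines))
  if (length(data_idx) == 0)
    return(peak_set(character(), numeric(), numeric(), name = name))
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_fields <- if (dialect == "narrowpeak") 10L else 3L
  bad <- which(if (dialect == "narrowpeak") nf != 10L else nf < 3L)
  if (length(bad) > 0)
    sf_abort(sprintf(
      "malformed %s line %d in %s: expected %s %d tab-separated fields, got %d",
      dialect, data_idx[bad[1]], path,
      if (dialect == "narrowpeak") "exactly" else "at least",
      min_fields, nf[bad[1]]), "snpfunnel_parse_error")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    sf_abort(sprintf("malformed coordinate on line %d in %s",
                     data_idx[bad[1]], path), "snpfunnel_parse_error")
  bad <- which(start >= end)
  if (length(bad) > 0)
    sf_abort(sprintf("start >= end on line %d in %s",
                     data_idx[bad[1]], path), "snpfunnel_validation_error")
  score <- if (dialect == "narrowpeak")
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
  else NA_real_
  peak_set(chrom, start, end, name = name, score = score)
}

#' Write a peak set as BED3 (plus score column when present)
#'
#' @param peaks a `peak_set`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  ints <- peaks$intervals
  out <- ints[, c("chrom", "start", "end")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  if (any(!is.na(ints$score))) {
    out$name <- paste0(peaks$name, "_", seq_len(nrow(ints)))
    out$score2 <- 0L
    out$strand <- "."
    out$signal <- ifelse(is.na(ints$score), 0, ints$score)
    out$p <- -1L
    out$q <- -1L
    out$summit <- -1L
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
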