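# Internal helpers shared across modules.

# Classed conditions so callers/tests can distinguish failure modes.
sf_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "snpfunnel_error", "error")))
}

sf_assert <- function(cond, msg, class = "snpfunnel_validation_error") {
  if (!isTRUE(cond)) sf_abort(msg, class)
}

#' Normalize chromosome labels
#'
#' Strips an optional "chr" prefix so that labels from mixed sources
#' ("chr3" vs "3") compare equal. Matching elsewhere is exact string
#' equality after this normalization.
#'
#' @param x character vector of chromosome labels.
#' @return character vector without the "chr" prefix.
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

# Autosome test on normalized labels: pure integer 1..22.
is_autosome <- function(chrom) {
  x <- norm_chrom(chrom)
  grepl("^[0-9]+$", x) & suppressWarnings(as.integer(x)) >= 1L &
    suppressWarnings(as.integer(x)) <= 22L
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
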