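# Two-locus linkage disequilibrium from unphased genotypes.
#
# Haplotype frequencies are estimated by the classic EM for a pair of
# biallelic loci: every two-locus genotype class determines its two
# haplotypes except the double heterozygote, which is split between the
# AB/ab and Ab/aB phase resolutions in proportion to their current
# likelihood. "A"/"B" denote the alternate (dosage-coded) alleles at the
# two loci.

#' EM haplotype-frequency estimation for two biallelic loci
#'
#' @param g1,g2 integer vectors of alternate-allele dosages (0/1/2, `NA`
#'   missing) at the two loci, same samples in the same order.
#' @param tol convergence tolerance: maximum absolute change in any
#'   haplotype frequency between iterations (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return object of class `haplotype_freqs`: `f_AB`, `f_Ab`, `f_aB`,
#'   `f_ab`, `loglik`, `loglik_trace`, `iterations`, `converged`, `n_used`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- as.integer(g1[keep]); g2 <- as.integer(g2[keep])
  n <- length(g1)
  if (n < 2)
    sf_abort("need >= 2 samples with both loci called",
             "snpfunnel_insufficient_data")
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2)
    sf_abort("monomorphic locus in the joint non-missing subset: LD undefined",
             "snpfunnel_monomorphic_error")
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  em_from_table(tab, tol = tol, max_iter = max_iter)
}

# EM on a 3x3 genotype count table (rows: dosage at locus 1, cols: locus 2).
em_from_table <- function(tab, tol = 1e-10, max_iter = 1000L) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  # phase-unambiguous haplotype counts
  k <- c(AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
         Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
         aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
         ab = 2 * tab[1, 1] + tab[2, 1] + tab[1, 2])
  ndh <- tab[2, 2]
  pA <- (k[["AB"]] + k[["Ab"]] + ndh) / (2 * n)
  pB <- (k[["AB"]] + k[["aB"]] + ndh) / (2 * n)
  # start at linkage equilibrium
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  names(f) <- c("AB", "Ab", "aB", "ab")
  ll <- em_loglik(tab, f)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- f[["AB"]] * f[["ab"]] + f[["Ab"]] * f[["aB"]]
    w <- if (denom > 0) f[["AB"]] * f[["ab"]] / denom else 0.5
    cnt <- k + ndh * c(w, 1 - w, 1 - w, w)
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    ll <- em_loglik(tab, f)
    trace <- c(trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(f_AB = f[["AB"]], f_Ab = f[["Ab"]], f_aB = f[["aB"]],
                 f_ab = f[["ab"]], loglik = ll, loglik_trace = trace,
                 iterations = iter, converged = converged, n_used = n),
            class = "haplotype_freqs")
}

# Multinomial log-likelihood of a 3x3 genotype table under haplotype
# frequencies f = (AB, Ab, aB, ab), assuming random union of haplotypes.
em_loglik <- function(tab, f) {
  p <- genotype_class_probs(f)
  obs <- as.vector(tab)
  sum(obs[obs > 0] * log(p[obs > 0]))
}

genotype_class_probs <- function(f) {
  fAB <- f[["AB"]]; fAb <- f[["Ab"]]; faB <- f[["aB"]]; fab <- f[["ab"]]
  # rows: locus-1 dosage 0,1,2; cols: locus-2 dosage 0,1,2 (as.vector order)
  matrix(c(fab^2,            2 * fAb * fab,            fAb^2,
           2 * faB * fab,    2 * (fAB * fab + fAb * faB), 2 * fAB * fAb,
           faB^2,            2 * fAB * faB,            fAB^2),
         nrow = 3, byrow = FALSE)
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat(sprintf(
    "<haplotype_freqs: AB=%.4f Ab=%.4f aB=%.4f ab=%.4f (n=%d, %s in %d it)>\n",
    x$f_AB, x$f_Ab, x$f_aB, x$f_ab, x$n_used,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' LD statistics from haplotype frequencies
#'
#' `D = f_AB - p_A p_B`; `D'` is `D` scaled by its bound given the allele
#' frequencies (`min(p_A(1-p_B), (1-p_A)p_B)` for positive `D`,
#' `min(p_A p_B, (1-p_A)(1-p_B))` for negative; 0 when `D = 0`); and
#' `r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))`.
#'
#' @param h a [em_haplotype_freqs()] result (or list with the four `f_*`).
#' @return object of class `ld_stats` with `D`, `dprime`, `r2`, `p_A`,
#'   `p_B`.
#' @export
ld_stats <- function(h) {
  pA <- h$f_AB + h$f_Ab
  pB <- h$f_AB + h$f_aB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    sf_abort("allele frequency on the boundary: LD undefined",
             "snpfunnel_monomorphic_error")
  D <- h$f_AB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(D = D, dprime = dprime, r2 = r2, p_A = pA, p_B = pB),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("<ld_stats: D=%.4f D'=%.4f r2=%.4f>\n", x$D, x$dprime, x$r2))
  invisible(x)
}

# r2/D' between two panel columns; NULL when EM preconditions fail.
pair_ld <- function(gm, rsid1, rsid2) {
  i <- match(rsid1, gm$variants$rsid); j <- match(rsid2, gm$variants$rsid)
  h <- em_haplotype_freqs(gm$codes[, i], gm$codes[, j])
  s <- ld_stats(h)
  list(h = h, stats = s)
}

#' Expand a tag SNP into its LD neighborhood
#'
#' Computes r-squared between the tag and every panel variant on the same
#' chromosome within `window_bp`, retaining those with `r2 > r2_min`
#' (strict, matching the conventional "r^2 > 0.2" screen). The tag itself
#' is always returned with r2 = 1. Variants failing EM preconditions
#' (monomorphic, insufficient overlap) are skipped and logged in the
#' `skipped` attribute.
#'
#' @param tag rsid of the tag variant (must be present in `panel`).
#' @param panel a [genotype_matrix()] reference panel.
#' @param r2_min retention threshold, strict inequality (default 0.2).
#' @param window_bp half-width of the physical search window in base pairs
#'   (default 500000).
#' @return data.frame (rsid, chrom, pos, ref, alt, tag, r2, dprime,
#'   n_used) with attribute `skipped`.
#' @export
ld_expand <- function(tag, panel, r2_min = 0.2, window_bp = 500000L) {
  ti <- match(tag, panel$variants$rsid)
  if (is.na(ti))
    sf_abort(paste0("tag SNP not in panel: ", tag), "snpfunnel_lookup_error")
  v <- panel$variants
  tv <- v[ti, ]
  cand <- which(norm_chrom(v$chrom) == norm_chrom(tv$chrom) &
                  abs(v$pos - tv$pos) <= window_bp)
  rows <- list()
  skipped <- character()
  for (i in cand) {
    if (i == ti) {
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = tv$rsid, chrom = tv$chrom, pos = tv$pos, ref = tv$ref,
        alt = tv$alt, tag = tag, r2 = 1, dprime = 1,
        n_used = sum(!is.na(panel$codes[, ti])), stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch(pair_ld(panel, tag, v$rsid[i]),
                    snpfunnel_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped <- c(skipped, setNames(res, v$rsid[i]))
      next
    }
    if (res$stats$r2 > r2_min)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = v$rsid[i], chrom = v$chrom[i], pos = v$pos[i],
        ref = v$ref[i], alt = v$alt[i], tag = tag, r2 = res$stats$r2,
        dprime = res$stats$dprime, n_used = res$h$n_used,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rsid = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), tag = character(),
               r2 = numeric(), dprime = numeric(), n_used = integer())
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Find the best LD proxy for a variant
#'
#' Searches the panel for the non-target variant with maximal r-squared at
#' or above `r2_min`. Ties are broken by smallest positional distance, then
#' lexicographic rsid. Used when a variant cannot be genotyped and a
#' perfect or near-perfect substitute is needed.
#'
#' @param target rsid of the variant needing a proxy.
#' @param panel a [genotype_matrix()].
#' @param r2_min minimum acceptable r-squared (default 0.8).
#' @return one-row data.frame (rsid, chrom, pos, r2, dprime, n_used), or
#'   `NULL` if no variant qualifies.
#' @export
find_proxy <- function(target, panel, r2_min = 0.8) {
  ti <- match(target, panel$variants$rsid)
  if (is.na(ti))
    sf_abort(paste0("target SNP not in panel: ", target),
             "snpfunnel_lookup_error")
  v <- panel$variants
  best <- NULL
  for (i in seq_len(nrow(v))) {
    if (i == ti) next
    res <- tryCatch(pair_ld(panel, target, v$rsid[i]),
                    snpfunnel_error = function(e) NULL)
    if (is.null(res) || res$stats$r2 < r2_min) next
    cand <- data.frame(rsid = v$rsid[i], chrom = v$chrom[i], pos = v$pos[i],
                       r2 = res$stats$r2, dprime = res$stats$dprime,
                       n_used = res$h$n_used, stringsAsFactors = FALSE)
    if (is.null(best)) { best <- cand; next }
    d_new <- abs(cand$pos - v$pos[ti]); d_old <- abs(best$pos - v$pos[ti])
    if (cand$r2 > best$r2 ||
        (cand$r2 == best$r2 && (d_new < d_old ||
          (d_new == d_old && cand$rsid < best$rsid))))
      best <- cand
  }
  best
}
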