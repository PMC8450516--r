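# Association scans, the two-stage screen/validate/combine workflow, and
# stratified analyses.

effect_row <- function(rsid, model, crude = NULL, adj = NULL,
                       note = NA_character_) {
  data.frame(
    rsid = rsid, model = model,
    crude_or = if (is.null(crude)) NA_real_ else crude$odds_ratio,
    crude_ci_low = if (is.null(crude)) NA_real_ else crude$ci_low,
    crude_ci_high = if (is.null(crude)) NA_real_ else crude$ci_high,
    crude_p = if (is.null(crude)) NA_real_ else crude$pvalue,
    haldane = if (is.null(crude)) NA else crude$haldane,
    adj_or = if (is.null(adj)) NA_real_ else adj$odds_ratio,
    adj_ci_low = if (is.null(adj)) NA_real_ else adj$ci_low,
    adj_ci_high = if (is.null(adj)) NA_real_ else adj$ci_high,
    adj_p = if (is.null(adj)) NA_real_ else adj$pvalue,
    adj_n = if (is.null(adj)) NA_integer_ else adj$n_used,
    adj_converged = if (is.null(adj)) NA else
      attr(adj, "fit")$converged,
    note = note, stringsAsFactors = FALSE)
}

#' Per-SNP association scan
#'
#' For every SNP: genotype counts by group, control-HWE p, case/control
#' MAF, a 2-df Pearson chi-square on the 3x2 genotype distribution, and —
#' per genetic model — crude and covariate-adjusted odds ratios side by
#' side. Per-SNP failures (all-missing genotypes, monomorphic SNPs,
#' separation) are reported as flagged rows with a `note`; the scan never
#' aborts.
#'
#' @param gm a [genotype_matrix()].
#' @param phen a [phenotype_table()] covering the samples.
#' @param models subset of [genetic_models()].
#' @param covariates adjustment set for the logistic fits (subset of
#'   c("age", "sex", "smoking")).
#' @return data.frame of class `assoc_scan`, one row per SNP x model, with
#'   per-SNP columns repeated (maf_case, maf_control, hwe_control_p,
#'   geno_chi2, geno_p).
#' @export
assoc_scan <- function(gm, phen, models = genetic_models(),
                       covariates = c("age", "sex", "smoking")) {
  phen_rows <- phen[match(gm$samples, phen$sample), , drop = FALSE]
  sf_assert(!anyNA(phen_rows$sample),
            "every genotyped sample needs a phenotype row")
  out <- list()
  for (i in seq_len(nrow(gm$variants))) {
    rs <- gm$variants$rsid[i]
    g <- gm$codes[, i]
    counts <- tabulate_counts(gm, phen, rs)
    maf <- function(cc) {
      tot <- 2 * sum(cc)
      if (tot == 0) NA_real_ else (cc[["HT"]] + 2 * cc[["HV"]]) / tot
    }
    hwe_p <- tryCatch(hwe_test(counts)$pvalue,
                      snpfunnel_error = function(e) NA_real_)
    gchi <- tryCatch(
      pearson_chi2(rbind(counts$case, counts$control)),
      snpfunnel_error = function(e) NULL)
    snp_rows <- lapply(models, function(m) {
      crude <- tryCatch(crude_or(m, counts),
                        snpfunnel_error = function(e) NULL)
      adj <- tryCatch(adjusted_or(g, phen_rows, m, covariates),
                      snpfunnel_error = function(e) NULL,
                      error = function(e) NULL)
      note <- if (is.null(crude) && is.null(adj)) "estimation_failed"
              else NA_character_
      effect_row(rs, m, crude, adj, note)
    })
    snp <- do.call(rbind, snp_rows)
    if (length(models) > 0) {
      snp$maf_case <- maf(counts$case)
      snp$maf_control <- maf(counts$control)
      snp$hwe_control_p <- hwe_p
      snp$geno_chi2 <- if (is.null(gchi)) NA_real_ else gchi$statistic
      snp$geno_p <- if (is.null(gchi)) NA_real_ else gchi$pvalue
      snp$call_rate <- call_rate(counts)
    }
    out[[length(out) + 1L]] <- snp
  }
  res <- if (length(out)) do.call(rbind, out) else
    effect_row("x", "additive")[0, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- unique(c("assoc_scan", class(res)))
  res
}

#' Two-stage screen / validate / combine analysis
#'
#' Stage-1 SNPs whose adjusted p-value under the screening model falls
#' below `screen_alpha` are promoted; promoted SNPs are re-tested in the
#' independent stage-2 sample under all requested models, and a combined
#' analysis pools the individual-level data of both stages. Promoted SNPs
#' absent from stage 2 are reported as unvalidatable.
#'
#' @param stage1_scan an [assoc_scan()] result for stage 1.
#' @param stage1_data,stage2_data lists with elements `genotypes` (a
#'   [genotype_matrix()]) and `phenotypes` (a [phenotype_table()]).
#' @param screen_alpha promotion threshold on the stage-1 adjusted p
#'   (default 0.1).
#' @param screen_model model whose adjusted p is screened (default
#'   "additive").
#' @param models models for the stage-2 and combined analyses.
#' @param covariates adjustment set.
#' @return object of class `two_stage_report`: `promoted`,
#'   `unvalidatable`, `stage2` and `combined` scans, and `pooled_counts`
#'   (per promoted SNP, element-wise sums of the stage counts).
#' @export
two_stage <- function(stage1_scan, stage1_data, stage2_data,
                      screen_alpha = 0.1, screen_model = "additive",
                      models = genetic_models(),
                      covariates = c("age", "sex", "smoking")) {
  sf_assert(screen_alpha >= 0 && screen_alpha <= 1,
            "screen_alpha must lie in [0, 1]")
  s1 <- stage1_scan[stage1_scan$model == screen_model, , drop = FALSE]
  promoted <- s1$rsid[!is.na(s1$adj_p) & s1$adj_p < screen_alpha]
  unvalidatable <- setdiff(promoted,
                           stage2_data$genotypes$variants$rsid)
  testable <- setdiff(promoted, unvalidatable)
  stage2_scan <- combined_scan <- NULL
  pooled_counts <- list()
  if (length(testable) > 0) {
    gm2 <- subset_variants(stage2_data$genotypes, testable)
    stage2_scan <- assoc_scan(gm2, stage2_data$phenotypes, models,
                              covariates)
    gm1 <- subset_variants(stage1_data$genotypes, testable)
    gmc <- rbind_genotypes(gm1, gm2)
    phenc <- phenotype_table(rbind(
      as.data.frame(stage1_data$phenotypes)[, PHENO_COLS],
      as.data.frame(stage2_data$phenotypes)[, PHENO_COLS]))
    combined_scan <- assoc_scan(gmc, phenc, models, covariates)
    pooled_counts <- setNames(lapply(testable, function(rs) {
      sum_counts(tabulate_counts(gm1, stage1_data$phenotypes, rs),
                 tabulate_counts(gm2, stage2_data$phenotypes, rs))
    }), testable)
  }
  structure(list(promoted = promoted, unvalidatable = unvalidatable,
                 screen_alpha = screen_alpha, screen_model = screen_model,
                 stage1 = stage1_scan, stage2 = stage2_scan,
                 combined = combined_scan, pooled_counts = pooled_counts),
            class = "two_stage_report")
}

#' @export
print.two_stage_report <- function(x, ...) {
  cat(sprintf(
    "<two_stage_report: %d promoted at %s p < %g (%d unvalidatable)>\n",
    length(x$promoted), x$screen_model, x$screen_alpha,
    length(x$unvalidatable)))
  invisible(x)
}

#' Stratified association analysis
#'
#' Repeats the adjusted analysis within strata of one factor. Histology
#' strata keep the cases of one tumour subtype together with all controls
#' (subtypes are case-only); smoking strata exclude samples with unknown
#' smoking; the stratifying factor is removed from the adjustment set.
#' Strata without both cases and controls are skipped and logged in the
#' `skipped` attribute.
#'
#' @param gm a [genotype_matrix()].
#' @param phen a [phenotype_table()].
#' @param by one of "histology", "smoking", "sex".
#' @param models subset of [genetic_models()].
#' @param covariates full adjustment set; the stratifier is dropped from
#'   it automatically.
#' @return data.frame: an [assoc_scan()] per stratum with a `stratum`
#'   column, plus attribute `skipped`.
#' @export
stratified_analysis <- function(gm, phen, by = c("histology", "smoking",
                                                 "sex"),
                                models = genetic_models(),
                                covariates = c("age", "sex", "smoking")) {
  by <- match.arg(by)
  phen_rows <- phen[match(gm$samples, phen$sample), , drop = FALSE]
  strata <- switch(by,
    histology = {
      subtypes <- unique(stats::na.omit(phen_rows$histology))
      setNames(lapply(subtypes, function(s)
        phen_rows$status == "control" |
          (!is.na(phen_rows$histology) & phen_rows$histology == s)),
        as.character(subtypes))
    },
    smoking = {
      lv <- intersect(c("smoker", "nonsmoker"), unique(phen_rows$smoking))
      setNames(lapply(lv, function(s) phen_rows$smoking == s), lv)
    },
    sex = {
      lv <- intersect(c("male", "female"), unique(phen_rows$sex))
      setNames(lapply(lv, function(s) phen_rows$sex == s), lv)
    })
  cov_use <- setdiff(covariates, by)
  out <- list()
  skipped <- character()
  for (s in names(strata)) {
    sel <- strata[[s]]
    ph <- phen_rows[sel, , drop = FALSE]
    if (!any(ph$status == "case") || !any(ph$status == "control")) {
      skipped <- c(skipped, s)
      next
    }
    sub <- genotype_matrix(gm$codes[sel, , drop = FALSE], gm$variants,
                           samples = gm$samples[sel])
    sc <- assoc_scan(sub, phenotype_table(ph), models, cov_use)
    sc$stratum <- s
    out[[length(out) + 1L]] <- sc
  }
  res <- if (length(out)) do.call(rbind, out) else NULL
  attr(res, "skipped") <- skipped
  res
}
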