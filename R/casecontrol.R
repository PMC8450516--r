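# QC, contingency-table tests and genetic-model effect estimates.
#
# Genotype categories follow the usual case-control shorthand: HW
# (wild-type homozygote, dosage 0), HT (heterozygote, 1), HV (variant
# homozygote, 2). The risk allele is always taken to be the variant (alt)
# allele, even when its frequency exceeds 0.5.

Z95 <- 1.959964  # two-sided 95% Wald quantile

#' The five genetic models
#'
#' `homozygous` compares HV vs HW (heterozygotes excluded), `heterozygous`
#' HT vs HW (variant homozygotes excluded), `dominant` HT+HV vs HW,
#' `recessive` HV vs HW+HT, and `additive` uses allele dosage 0/1/2.
#'
#' @return character vector of model names.
#' @export
genetic_models <- function() {
  c("homozygous", "heterozygous", "dominant", "recessive", "additive")
}

#' Per-group genotype counts for one SNP
#'
#' @param case,control length-3 vectors `c(HW, HT, HV)`.
#' @param case_missing,control_missing numbers of failed calls.
#' @return object of class `genotype_counts`.
#' @export
genotype_counts <- function(case, control, case_missing = 0L,
                            control_missing = 0L) {
  sf_assert(length(case) == 3 && length(control) == 3,
            "case and control counts must be c(HW, HT, HV)")
  sf_assert(all(c(case, control, case_missing, control_missing) >= 0),
            "counts must be non-negative")
  structure(list(case = setNames(as.numeric(case), c("HW", "HT", "HV")),
                 control = setNames(as.numeric(control),
                                    c("HW", "HT", "HV")),
                 missing = c(case = as.numeric(case_missing),
                             control = as.numeric(control_missing))),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf(
    "<genotype_counts: cases %s | controls %s | missing %d/%d>\n",
    paste(x$case, collapse = "/"), paste(x$control, collapse = "/"),
    x$missing[["case"]], x$missing[["control"]]))
  invisible(x)
}

#' Tabulate genotype counts for one SNP from individual-level data
#'
#' @param gm a [genotype_matrix()].
#' @param phen a [phenotype_table()] covering `gm$samples`.
#' @param rsid the SNP.
#' @return a [genotype_counts()].
#' @export
tabulate_counts <- function(gm, phen, rsid) {
  i <- match(rsid, gm$variants$rsid)
  sf_assert(!is.na(i), paste0("rsid not in genotype matrix: ", rsid),
            "snpfunnel_lookup_error")
  g <- gm$codes[, i]
  status <- phen$status[match(gm$samples, phen$sample)]
  sf_assert(!anyNA(status), "every genotyped sample needs a phenotype row")
  cnt <- function(grp) tabulate(g[status == grp] + 1L, 3L)
  genotype_counts(cnt("case"), cnt("control"),
                  sum(is.na(g) & status == "case"),
                  sum(is.na(g) & status == "control"))
}

#' Call rate of a SNP
#' @param counts a [genotype_counts()].
#' @return typed / (typed + missing) over both groups.
#' @export
call_rate <- function(counts) {
  typed <- sum(counts$case) + sum(counts$control)
  typed / (typed + sum(counts$missing))
}

sum_counts <- function(a, b) {
  genotype_counts(a$case + b$case, a$control + b$control,
                  a$missing[["case"]] + b$missing[["case"]],
                  a$missing[["control"]] + b$missing[["control"]])
}

new_test_result <- function(statistic, df, pvalue) {
  structure(list(statistic = statistic, df = df, pvalue = pvalue),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test: stat=%.4f df=%s p=%.4g>\n", x$statistic,
              format(x$df), x$pvalue))
  invisible(x)
}

#' Hardy-Weinberg goodness-of-fit test
#'
#' One-degree-of-freedom chi-square comparing observed genotype counts to
#' the proportions expected at the observed allele frequency. By convention
#' this QC test is run on controls.
#'
#' @param counts a [genotype_counts()] (its control counts are used) or a
#'   length-3 numeric vector `c(HW, HT, HV)`.
#' @return a `test_result` (statistic, df = 1, pvalue).
#' @export
hwe_test <- function(counts) {
  o <- if (inherits(counts, "genotype_counts")) counts$control
       else as.numeric(counts)
  sf_assert(length(o) == 3 && all(o >= 0), "need counts c(HW, HT, HV)")
  n <- sum(o)
  sf_assert(n >= 1, "no typed individuals", "snpfunnel_insufficient_data")
  q <- (o[2] + 2 * o[3]) / (2 * n)  # variant allele frequency
  if (q <= 0 || q >= 1)
    sf_abort("monomorphic genotype counts: HWE test undefined",
             "snpfunnel_monomorphic_error")
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((o - e)^2 / e)
  new_test_result(stat, 1L, pchisq(stat, 1L, lower.tail = FALSE))
}

#' Quality-control filter over SNPs
#'
#' Drops a SNP when its control genotypes deviate from Hardy-Weinberg
#' equilibrium at `hwe_alpha`, or when its overall call rate falls below
#' `call_rate_min`. A SNP failing both accumulates both reasons.
#'
#' @param counts_by_snp named list of [genotype_counts()].
#' @param call_rate_min minimum call rate (default 0.90).
#' @param hwe_alpha control-HWE exclusion level (default 0.05).
#' @return list with `kept` (the surviving sub-list), `dropped`
#'   (data.frame rsid, reason) and `stats` (per-SNP call_rate and hwe_p).
#' @export
qc_filter <- function(counts_by_snp, call_rate_min = 0.90,
                      hwe_alpha = 0.05) {
  sf_assert(!is.null(names(counts_by_snp)),
            "counts_by_snp must be a named list")
  drops <- list()
  cr <- hp <- setNames(numeric(length(counts_by_snp)),
                       names(counts_by_snp))
  for (rs in names(counts_by_snp)) {
    cc <- counts_by_snp[[rs]]
    cr[rs] <- call_rate(cc)
    hp[rs] <- tryCatch(hwe_test(cc)$pvalue,
                       snpfunnel_error = function(e) NA_real_)
    if (cr[rs] < call_rate_min)
      drops[[length(drops) + 1L]] <- data.frame(rsid = rs,
                                                reason = "CALL_RATE")
    if (!is.na(hp[rs]) && hp[rs] < hwe_alpha)
      drops[[length(drops) + 1L]] <- data.frame(rsid = rs, reason = "HWE")
  }
  dropped <- if (length(drops)) do.call(rbind, drops) else
    data.frame(rsid = character(), reason = character())
  list(kept = counts_by_snp[setdiff(names(counts_by_snp), dropped$rsid)],
       dropped = dropped,
       stats = data.frame(rsid = names(counts_by_snp), call_rate = cr,
                          hwe_p = hp, row.names = NULL))
}

#' Pearson chi-square test on an r x c contingency table
#'
#' No continuity correction; df = (r-1)(c-1).
#'
#' @param tab numeric matrix of counts.
#' @return a `test_result`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  sf_assert(all(tab >= 0), "contingency counts must be non-negative")
  sf_assert(nrow(tab) >= 2 && ncol(tab) >= 2,
            "need at least 2 rows and 2 columns")
  sf_assert(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
            "zero marginal in contingency table")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  new_test_result(stat, df, pchisq(stat, df, lower.tail = FALSE))
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' @param mean1,sd1,n1 group-1 summaries.
#' @param mean2,sd2,n2 group-2 summaries.
#' @return a `test_result` (two-sided).
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sf_assert(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
  sf_assert(sd1 > 0 && sd2 > 0, "standard deviations must be positive")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  new_test_result(tstat, df, 2 * pt(-abs(tstat), df))
}

new_effect <- function(or, lo, hi, p, model, adjusted, covariates,
                       haldane = FALSE, n_used = NA_integer_) {
  structure(list(odds_ratio = or, ci_low = lo, ci_high = hi, pvalue = p,
                 model = model, adjusted = adjusted,
                 covariates = covariates, haldane = haldane,
                 n_used = n_used),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<%s %s OR %.2f (%.2f-%.2f) p=%.3g%s>\n",
              if (x$adjusted) "adjusted" else "crude", x$model,
              x$odds_ratio, x$ci_low, x$ci_high, x$pvalue,
              if (x$haldane) " [Haldane]" else ""))
  invisible(x)
}

# Collapse genotype counts to a 2x2 exposure table for a genetic model.
# Returns matrix rows = (exposed, unexposed), cols = (case, control).
collapse_2x2 <- function(model, counts) {
  ca <- counts$case; co <- counts$control
  switch(model,
    homozygous  = rbind(c(ca[["HV"]], co[["HV"]]),
                        c(ca[["HW"]], co[["HW"]])),
    heterozygous = rbind(c(ca[["HT"]], co[["HT"]]),
                         c(ca[["HW"]], co[["HW"]])),
    dominant    = rbind(c(ca[["HT"]] + ca[["HV"]], co[["HT"]] + co[["HV"]]),
                        c(ca[["HW"]], co[["HW"]])),
    recessive   = rbind(c(ca[["HV"]], co[["HV"]]),
                        c(ca[["HW"]] + ca[["HT"]], co[["HW"]] + co[["HT"]])),
    additive    = rbind(c(2 * ca[["HV"]] + ca[["HT"]],
                          2 * co[["HV"]] + co[["HT"]]),
                        c(2 * ca[["HW"]] + ca[["HT"]],
                          2 * co[["HW"]] + co[["HT"]])),
    sf_abort(paste0("unknown genetic model: ", model),
             "snpfunnel_validation_error"))
}

#' Crude odds ratio under a genetic model
#'
#' Collapses the genotype counts to a 2x2 table with the variant-allele
#' category as exposure (for the additive model, by allele counting), then
#' computes `OR = ad/bc`, a 95% Wald CI on the log scale, and a p-value
#' from the uncorrected 2x2 Pearson chi-square. When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied to the OR
#' and CI and flagged in the result.
#'
#' @param model one of [genetic_models()].
#' @param counts a [genotype_counts()].
#' @return an `effect_estimate` (`adjusted = FALSE`).
#' @export
crude_or <- function(model, counts) {
  model <- match.arg(model, genetic_models())
  t22 <- collapse_2x2(model, counts)
  sf_assert(all(colSums(t22) > 0) && all(rowSums(t22) >= 0),
            "empty case or control group")
  haldane <- any(t22 == 0)
  tt <- if (haldane) t22 + 0.5 else t22
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  se <- sqrt(sum(1 / tt))
  p <- tryCatch(pearson_chi2(t22)$pvalue, snpfunnel_error = function(e) NA_real_)
  new_effect(or, exp(log(or) - Z95 * se), exp(log(or) + Z95 * se), p,
             model, adjusted = FALSE, covariates = character(),
             haldane = haldane,
             n_used = as.integer(sum(counts$case) + sum(counts$control)))
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Plain iteratively reweighted least squares with a deviance-change
#' stopping rule (default 1e-8, at most 25 iterations) and an explicit
#' score check: a fit is reported converged only when the maximum absolute
#' component of the score vector is below `grad_tol`. Diverging
#' coefficients or fitted probabilities pinned to 0/1 (separation) yield
#' `converged = FALSE` rather than silent output.
#'
#' @param y 0/1 outcome vector.
#' @param X design matrix including an intercept column.
#' @param tol deviance-change tolerance.
#' @param max_iter iteration cap.
#' @param grad_tol score-vector tolerance for declaring convergence.
#' @return object of class `logistic_fit`: `coefficients`,
#'   `standard_errors`, `vcov`, `deviance`, `n_used`, `iterations`,
#'   `converged`, `separation`, `grad_max`.
#' @export
fit_logistic <- function(y, X, tol = 1e-8, max_iter = 25L,
                         grad_tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  sf_assert(length(y) == nrow(X), "y and X must agree in length")
  sf_assert(all(y %in% c(0, 1)), "outcome must be 0/1")
  sf_assert(!anyNA(X) && !anyNA(y),
            "design and outcome must be complete cases")
  n <- length(y); p <- ncol(X)
  beta <- numeric(p)
  dev_old <- Inf
  separation <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-10) && max(abs(beta)) > 15) { separation <- TRUE; break }
    z <- eta + (y - mu) / pmax(w, 1e-10)
    fit <- lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (anyNA(beta))
      sf_abort("singular design matrix in logistic fit",
               "snpfunnel_validation_error")
    mu <- plogis(drop(X %*% beta))
    dev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu, 1e-300)))
    grad_max <- max(abs(drop(crossprod(X, y - mu))))
    if ((abs(dev_old - dev) < tol && grad_max < grad_tol) ||
        iter >= max_iter) break
    dev_old <- dev
  }
  mu <- plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  grad_max <- max(abs(drop(crossprod(X, y - mu))))
  deviance <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                         (1 - y) * log(pmax(1 - mu, 1e-300)))
  converged <- !separation && grad_max < grad_tol && iter <= max_iter
  structure(list(coefficients = setNames(drop(beta), colnames(X)),
                 standard_errors = setNames(sqrt(diag(vc)), colnames(X)),
                 vcov = vc, deviance = deviance,
                 n_used = n, iterations = iter, converged = converged,
                 separation = separation, grad_max = grad_max),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit: n=%d, %s in %d it, max|score|=%.2g>\n",
              x$n_used,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$grad_max))
  print(round(rbind(coef = x$coefficients, se = x$standard_errors), 4))
  invisible(x)
}

# Genotype coding per model for regression; NA drops the sample
# (homozygous/heterozygous models compare two genotype classes only).
code_genotype <- function(g, model) {
  switch(model,
    homozygous  = ifelse(g == 1L, NA_real_, as.numeric(g == 2L)),
    heterozygous = ifelse(g == 2L, NA_real_, as.numeric(g == 1L)),
    dominant    = as.numeric(g >= 1L),
    recessive   = as.numeric(g == 2L),
    additive    = as.numeric(g),
    sf_abort(paste0("unknown genetic model: ", model),
             "snpfunnel_validation_error"))
}

# Build outcome + design for an adjusted fit. Samples with unknown smoking
# are excluded whenever smoking is among the covariates; incomplete cases
# are dropped. Covariate coding: age in years (untransformed), sex
# female=0/male=1, smoking nonsmoker=0/smoker=1.
design_for <- function(g, phen_rows, model,
                       covariates = c("age", "sex", "smoking")) {
  x <- code_genotype(g, model)
  y <- as.numeric(phen_rows$status == "case")
  cols <- list(`(Intercept)` = rep(1, length(y)), genotype = x)
  keep <- !is.na(x)
  for (cv in covariates) {
    col <- switch(cv,
      age = as.numeric(phen_rows$age),
      sex = as.numeric(phen_rows$sex == "male"),
      smoking = ifelse(phen_rows$smoking == "unknown", NA_real_,
                       as.numeric(phen_rows$smoking == "smoker")),
      sf_abort(paste0("unknown covariate: ", cv),
               "snpfunnel_validation_error"))
    cols[[cv]] <- col
    keep <- keep & !is.na(col)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X <- X[keep, , drop = FALSE]
  # constant covariates carry no information and would make the design
  # singular; drop them (never the intercept or the genotype term)
  const <- vapply(seq_len(ncol(X)), function(j)
    j > 2 && length(unique(X[, j])) < 2, TRUE)
  list(y = y[keep], X = X[, !const, drop = FALSE])
}

#' Covariate-adjusted odds ratio under a genetic model
#'
#' Fits [fit_logistic()] with the model-coded genotype term plus the
#' requested covariates and reports the Wald OR, 95% CI and p-value of the
#' genotype coefficient.
#'
#' @param g alternate-allele dosages for one SNP (0/1/2/NA), one per row of
#'   `phen_rows`.
#' @param phen_rows phenotype rows aligned with `g`.
#' @param model one of [genetic_models()].
#' @param covariates subset of c("age", "sex", "smoking").
#' @return an `effect_estimate` (`adjusted = TRUE`) with the fit attached
#'   as attribute `fit`.
#' @export
adjusted_or <- function(g, phen_rows, model,
                        covariates = c("age", "sex", "smoking")) {
  model <- match.arg(model, genetic_models())
  d <- design_for(g, phen_rows, model, covariates)
  sf_assert(length(d$y) > 0 && length(unique(d$y)) == 2,
            "need both cases and controls after exclusions",
            "snpfunnel_insufficient_data")
  fit <- fit_logistic(d$y, d$X)
  b <- fit$coefficients[["genotype"]]
  se <- fit$standard_errors[["genotype"]]
  z <- b / se
  est <- new_effect(exp(b), exp(b - Z95 * se), exp(b + Z95 * se),
                    2 * pnorm(-abs(z)), model, adjusted = TRUE,
                    covariates = covariates, n_used = fit$n_used)
  attr(est, "fit") <- fit
  est
}
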