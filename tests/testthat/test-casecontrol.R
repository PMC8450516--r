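# HWE, QC, contingency tests, crude ORs, logistic regression.

test_that("hwe_test: exact-HWE counts give chi2 = 0, p = 1", {
  r <- hwe_test(c(250, 500, 250))
  expect_equal(r$statistic, 0)
  expect_equal(r$pvalue, 1)
})

test_that("hwe_test matches a direct-formula recomputation", {
  # stage-2 control genotypes of the validated SNP: 583/707/197
  o <- c(583, 707, 197); n <- sum(o)
  q <- (o[2] + 2 * o[3]) / (2 * n)
  expect_equal(q, 1101 / 2974)  # variant-allele frequency
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((o - e)^2 / e)
  r <- hwe_test(o)
  expect_equal(r$statistic, stat, tolerance = 1e-12)
  expect_equal(r$pvalue, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gt(r$pvalue, 0.05)  # passes the QC threshold

  # all heterozygotes: chi2 equals n
  r <- hwe_test(c(0, 100, 0))
  expect_equal(r$statistic, 100, tolerance = 1e-9)
  expect_error(hwe_test(c(10, 0, 0)),
               class = "snpfunnel_monomorphic_error")
})

test_that("qc_filter drops on call rate and control HWE with reasons", {
  at_hwe <- genotype_counts(c(90, 80, 30), c(250, 500, 250))
  low_cr <- genotype_counts(c(50, 30, 8), c(60, 40, 10),
                            case_missing = 12, control_missing = 12)
  expect_lt(call_rate(low_cr), 0.90)
  off_hwe <- genotype_counts(c(90, 80, 30), c(400, 100, 300))
  both <- genotype_counts(c(40, 30, 8), c(300, 50, 250),
                          case_missing = 40, control_missing = 60)
  qc <- qc_filter(list(good = at_hwe, cr = low_cr, hwe = off_hwe,
                       both = both))
  expect_setequal(names(qc$kept), "good")
  expect_equal(qc$dropped$reason[qc$dropped$rsid == "cr"], "CALL_RATE")
  expect_equal(qc$dropped$reason[qc$dropped$rsid == "hwe"], "HWE")
  expect_setequal(qc$dropped$reason[qc$dropped$rsid == "both"],
                  c("CALL_RATE", "HWE"))
})

test_that("pearson_chi2 reproduces published demographic chi-squares", {
  smoking_combined <- matrix(c(881, 788, 932, 1198, 17, 15), 3, 2,
                             byrow = TRUE)
  # recomputation from the printed counts gives 30.95486; the source
  # prints 30.96 (agreement to the last printed digit, not exact)
  expect_equal(pearson_chi2(smoking_combined)$statistic, 30.95486,
               tolerance = 1e-6)
  expect_lt(abs(pearson_chi2(smoking_combined)$statistic - 30.96), 0.01)
  smoking_stage1 <- matrix(c(145, 160, 198, 311, 5, 8), 3, 2,
                           byrow = TRUE)
  expect_equal(round(pearson_chi2(smoking_stage1)$statistic, 2), 5.91)
  sex_stage2 <- matrix(c(967, 1006, 515, 516), 2, 2, byrow = TRUE)
  expect_equal(round(pearson_chi2(sex_stage2)$statistic, 2), 0.24)
})

test_that("pearson_chi2: identical row proportions, closed form, errors", {
  expect_equal(pearson_chi2(matrix(c(30, 60, 10, 20), 2, 2))$statistic, 0)
  set.seed(3)
  for (rep in 1:20) {
    t22 <- matrix(sample(1:80, 4, TRUE), 2, 2)
    got <- pearson_chi2(t22)
    expect_equal(got$statistic,
                 oracle_chi2_2x2(t22[1, 1], t22[1, 2], t22[2, 1],
                                 t22[2, 2]), tolerance = 1e-10)
    # and against the standard library implementation, uncorrected
    ref <- suppressWarnings(chisq.test(t22, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$pvalue, ref$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2, 2)),
               class = "snpfunnel_validation_error")
})

test_that("two_sample_t behaves and brackets the printed age p-value", {
  expect_equal(two_sample_t(50, 5, 30, 50, 5, 30)$statistic, 0)
  expect_equal(two_sample_t(50, 5, 30, 50, 5, 30)$pvalue, 1)
  p1 <- two_sample_t(56.3, 7.8, 348, 55.2, 9.7, 479)$pvalue
  expect_gte(p1, 0.07); expect_lte(p1, 0.09)
  # doubling n with the same summaries strengthens the evidence
  p2 <- two_sample_t(56.3, 7.8, 696, 55.2, 9.7, 958)$pvalue
  expect_lt(p2, p1)
})

test_that("crude ORs reproduce the published combined genetic models", {
  cc <- genotype_counts(c(632, 839, 303), c(770, 931, 261))
  rec <- crude_or("recessive", cc)
  expect_equal(round(rec$odds_ratio, 2), 1.34)
  expect_equal(round(rec$ci_low, 2), 1.12)
  expect_equal(round(rec$ci_high, 2), 1.61)
  expect_equal(round(crude_or("dominant", cc)$odds_ratio, 2), 1.17)
  expect_equal(round(crude_or("additive", cc)$odds_ratio, 2), 1.17)
})

test_that("crude OR properties: null, inversion, Haldane", {
  same <- genotype_counts(c(100, 80, 20), c(100, 80, 20))
  for (m in genetic_models())
    expect_equal(crude_or(m, same)$odds_ratio, 1)
  cc <- genotype_counts(c(60, 85, 35), c(90, 70, 20))
  for (m in genetic_models()) {
    fwd <- crude_or(m, cc)
    swp <- crude_or(m, genotype_counts(cc$control, cc$case))
    expect_equal(swp$odds_ratio, 1 / fwd$odds_ratio, tolerance = 1e-12)
  }
  zero <- genotype_counts(c(50, 30, 0), c(60, 25, 5))
  est <- crude_or("recessive", zero)
  expect_true(est$haldane)
  expect_equal(est$odds_ratio, (0.5 * (85 + 0.5)) / ((80 + 0.5) * 5.5),
               tolerance = 1e-12)
})

test_that("fit_logistic agrees with glm and flags separation", {
  set.seed(77)
  n <- 400
  X <- cbind(1, rbinom(n, 2, 0.4), rnorm(n, 55, 8),
             rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "genotype", "age", "sex")
  y <- rbinom(n, 1, plogis(-2 + 0.3 * X[, 2] + 0.03 * X[, 3]))
  fit <- fit_logistic(y, X)
  ref <- glm.fit(X, y, family = binomial())
  expect_true(fit$converged)
  expect_lt(fit$grad_max, 1e-6)
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  expect_equal(fit$deviance, ref$deviance, tolerance = 1e-6)
  # standard errors against the glm information matrix
  w <- ref$weights
  se_ref <- unname(sqrt(diag(solve(crossprod(X * sqrt(w))))))
  expect_equal(unname(fit$standard_errors), se_ref, tolerance = 1e-5)
  # perfectly separated outcome
  ys <- as.numeric(X[, 2] > 0)
  fs <- fit_logistic(ys, X[, 1:2])
  expect_false(fs$converged)
  expect_true(fs$separation)
})

test_that("balanced null fixture: intercept = logit(case fraction)", {
  # every genotype class is 60% case / 40% control
  g <- rep(c(0, 1, 2), each = 20)
  yy <- rep(c(rep(1, 12), rep(0, 8)), 3)
  fit <- fit_logistic(yy, cbind(1, g))
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.6),
               tolerance = 1e-8)
})

test_that("no-covariate additive fit matches the score-equation oracle", {
  set.seed(123)
  for (rep in 1:3) {
    n <- 300
    x <- rbinom(n, 2, 0.35)
    y <- rbinom(n, 1, plogis(-0.3 + 0.25 * x))
    fit <- fit_logistic(y, cbind(1, x))
    b1 <- oracle_logistic_1param(y, x)
    expect_equal(unname(fit$coefficients[2]), b1, tolerance = 1e-5)
  }
})

test_that("adjusted OR equals crude OR when covariates are constant", {
  set.seed(42)
  ch <- simulate_cohort(cohort_spec(300, 300, odds_ratio = 1.4,
                                    unknown_smoking_rate = 0, seed = 6))
  ph <- as.data.frame(ch$phenotypes)
  ph$age <- 50; ph$sex <- "male"; ph$smoking <- "smoker"
  g <- ch$genotypes$codes[, 1]
  counts <- tabulate_counts(ch$genotypes,
                            phenotype_table(ph), "snp01")
  for (m in c("dominant", "recessive")) {
    crude <- crude_or(m, counts)
    # constant covariate columns are dropped internally, so the adjusted
    # fit collapses to the crude 2x2 odds ratio
    adj <- adjusted_or(g, ph, m)
    expect_equal(adj$odds_ratio, crude$odds_ratio, tolerance = 1e-6)
  }
})

test_that("null simulation: genotype CI covers 0 at the nominal rate", {
  seeds <- 5000 + seq_len(200)
  cover <- vapply(seeds, function(sd) {
    ch <- simulate_cohort(cohort_spec(200, 200, odds_ratio = 1,
                                      unknown_smoking_rate = 0,
                                      seed = sd))
    est <- adjusted_or(ch$genotypes$codes[, 1],
                       as.data.frame(ch$phenotypes), "additive")
    fit <- attr(est, "fit")
    b <- fit$coefficients[["genotype"]]
    se <- fit$standard_errors[["genotype"]]
    abs(b) <= 1.96 * se
  }, TRUE)
  # binomial 95% band around 0.95 with 200 replicates
  expect_gte(sum(cover), 184)
  expect_lte(sum(cover), 197)
})
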