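# Synthetic inputs with known ground truth: haplotype panels with
# controlled pairwise LD to an anchor variant, case-control cohorts drawn
# retrospectively from a logistic disease model, peak sets with planted
# variant overlaps, and tag catalogs.

#' Specify a haplotype block
#'
#' Describes `n_variants` SNPs on one chromosome: the first is the anchor
#' (e.g. a tag SNP); every other variant has a target pairwise LD with the
#' anchor, expressed as r-squared or D-prime. Feasibility of each target is
#' checked against the D bound implied by the allele frequencies.
#'
#' @param positions 1-based positions, strictly increasing; the anchor is
#'   the first.
#' @param anchor_freq alternate-allele frequency of the anchor, in (0, 1).
#' @param targets numeric vector, one per non-anchor variant: target r2 (in
#'   `[0, 1]`) or D' (in `[-1, 1]`) to the anchor.
#' @param measure "r2" or "dprime".
#' @param variant_freqs alternate-allele frequencies of the non-anchor
#'   variants (default: all equal to `anchor_freq`).
#' @param chrom chromosome label.
#' @param rsids variant identifiers (default sim1..simK, anchor first).
#' @return object of class `block_spec` with the implied haplotype
#'   distribution for each (anchor, variant) pair.
#' @export
block_spec <- function(positions, anchor_freq, targets,
                       measure = c("r2", "dprime"),
                       variant_freqs = NULL, chrom = "chr1",
                       rsids = NULL) {
  measure <- match.arg(measure)
  n <- length(positions)
  sf_assert(n >= 1 && all(diff(positions) > 0),
            "positions must be strictly increasing")
  sf_assert(length(targets) == n - 1,
            "one LD target per non-anchor variant")
  sf_assert(anchor_freq > 0 && anchor_freq < 1,
            "anchor_freq must lie strictly in (0, 1)")
  if (is.null(variant_freqs)) variant_freqs <- rep(anchor_freq, n - 1)
  sf_assert(length(variant_freqs) == n - 1 &&
              all(variant_freqs > 0 & variant_freqs < 1),
            "variant_freqs must lie strictly in (0, 1)")
  if (is.null(rsids)) rsids <- sprintf("sim%d", seq_len(n))
  pA <- anchor_freq
  haplo <- lapply(seq_len(max(n - 1, 0)), function(j) {
    pB <- variant_freqs[j]
    D <- target_to_D(targets[j], measure, pA, pB)
    c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
      aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
  })
  structure(list(chrom = chrom, positions = as.integer(positions),
                 rsids = rsids, anchor_freq = pA,
                 variant_freqs = variant_freqs, targets = targets,
                 measure = measure, haplo = haplo),
            class = "block_spec")
}

# Convert a target r2 or D' into the raw D coefficient, checking the
# feasibility bound Dmax = min(pA(1-pB), (1-pA)pB) (positive association).
target_to_D <- function(target, measure, pA, pB) {
  dmax_pos <- min(pA * (1 - pB), (1 - pA) * pB)
  dmax_neg <- min(pA * pB, (1 - pA) * (1 - pB))
  if (measure == "dprime") {
    sf_assert(abs(target) <= 1, "D' targets must lie in [-1, 1]")
    return(if (target >= 0) target * dmax_pos else target * dmax_neg)
  }
  sf_assert(target >= 0 && target <= 1, "r2 targets must lie in [0, 1]")
  D <- sqrt(target * pA * (1 - pA) * pB * (1 - pB))
  if (D > dmax_pos + 1e-12)
    sf_abort(sprintf(
      "infeasible r2 target %g at frequencies (%g, %g): needs D = %.4g but Dmax = %.4g",
      target, pA, pB, D, dmax_pos), "snpfunnel_spec_error")
  D
}

#' Solve for the companion allele frequency matching an (r2, D') pair
#'
#' Given the anchor frequency and a desired combination of r-squared and
#' D-prime (both positive), finds the variant allele frequency `pB` at
#' which a single D satisfies both definitions, by uniroot on
#' `sqrt(r2 pA qA pB qB) - dprime * Dmax(pB)`.
#'
#' @param pA anchor alternate-allele frequency.
#' @param r2 target r-squared in (0, 1].
#' @param dprime target D-prime in (0, 1].
#' @return the frequency `pB` in (0, 1).
#' @export
solve_pair_freq <- function(pA, r2, dprime) {
  f <- function(pB)
    sqrt(r2 * pA * (1 - pA) * pB * (1 - pB)) -
      dprime * min(pA * (1 - pB), (1 - pA) * pB)
  # search on the pB <= pA branch where Dmax = (1-pA) pB is attainable
  lo <- 1e-6; hi <- pA
  if (f(lo) * f(hi) > 0) hi <- 1 - 1e-6
  sf_assert(f(lo) * f(hi) <= 0,
            "no companion frequency satisfies this (r2, D') pair",
            "snpfunnel_spec_error")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a phased haplotype panel from a block specification
#'
#' Draws `2 * n_individuals` haplotypes: the anchor allele is Bernoulli at
#' the anchor frequency and every other variant is drawn conditionally on
#' the anchor allele from its pair haplotype distribution, independently
#' across variants given the anchor. Realized pairwise LD to the anchor
#' converges to the targets as n grows.
#'
#' @param spec a [block_spec()].
#' @param n_individuals number of diploid samples.
#' @param seed RNG seed (fixed seed gives byte-identical output).
#' @return a phased [genotype_matrix()].
#' @export
simulate_haplotypes <- function(spec, n_individuals, seed = 1L) {
  sf_assert(inherits(spec, "block_spec"), "spec must be a block_spec")
  n <- length(spec$positions)
  with_seed(seed, {
    draw_hap <- function(m) {
      anchor <- rbinom(m, 1L, spec$anchor_freq)
      h <- matrix(0L, nrow = m, ncol = n)
      h[, 1] <- anchor
      for (j in seq_len(n - 1)) {
        f <- spec$haplo[[j]]
        pA <- spec$anchor_freq
        p_b_given_A <- f[["AB"]] / pA
        p_b_given_a <- f[["aB"]] / (1 - pA)
        pr <- ifelse(anchor == 1L, p_b_given_A, p_b_given_a)
        h[, j + 1] <- rbinom(m, 1L, pmin(pmax(pr, 0), 1))
      }
      h
    }
    h1 <- draw_hap(n_individuals)
    h2 <- draw_hap(n_individuals)
    v <- variant_table(rep(spec$chrom, n), spec$positions, spec$rsids)
    genotype_matrix(h1 + h2, v,
                    samples = sprintf("H%04d", seq_len(n_individuals)),
                    phased = TRUE, hap1 = h1, hap2 = h2)
  })
}

#' Bind genotype matrices side by side (same samples)
#'
#' Convenience for assembling a multi-block reference panel.
#'
#' @param ... `genotype_matrix` objects with identical samples.
#' @return a single `genotype_matrix` (unphased unless all inputs phased).
#' @export
cbind_genotypes <- function(...) {
  gms <- list(...)
  sf_assert(length(gms) >= 1, "need at least one genotype matrix")
  samples <- gms[[1]]$samples
  for (g in gms)
    sf_assert(identical(g$samples, samples),
              "cbind_genotypes requires identical samples")
  variants <- validate_variants(
    do.call(rbind, lapply(gms, function(g) as.data.frame(g$variants))))
  codes <- do.call(cbind, lapply(gms, `[[`, "codes"))
  phased <- all(vapply(gms, `[[`, TRUE, "phased"))
  genotype_matrix(codes, variants, samples = samples, phased = phased,
                  hap1 = if (phased) do.call(cbind, lapply(gms, `[[`, "hap1")),
                  hap2 = if (phased) do.call(cbind, lapply(gms, `[[`, "hap2")))
}

#' Specify a synthetic case-control cohort
#'
#' Defaults mirror a typical East-Asian NSCLC case-control study: control
#' MAF 0.37, additive OR 1.17, matched age (normal, mean 55, sd 8.5,
#' truncated to 30-80 years) and sex (64% male), population smoking
#' prevalence 0.40 with smoking OR 1.45 (which induces roughly 48% vs 39%
#' smokers in cases vs controls through the disease model).
#'
#' @param n_case,n_control target sample sizes.
#' @param control_maf alternate-allele frequency (HWE) in the virtual
#'   population; may be a vector for several independent SNPs.
#' @param model genetic model of the planted effect.
#' @param odds_ratio planted per-SNP effect (recycled against
#'   `control_maf`).
#' @param or_sex,or_smoking,or_age covariate odds ratios (age per year).
#' @param male_prev,smoking_prev population covariate prevalences.
#' @param unknown_smoking_rate fraction relabelled smoking-unknown.
#' @param missing_rate per-call genotype missingness.
#' @param pop_multiplier virtual-population size as a multiple of
#'   `n_case + n_control`.
#' @param stage stage label written to the phenotype table.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case, n_control, control_maf = 0.37,
                        model = "additive", odds_ratio = 1.17,
                        or_sex = 1.0, or_smoking = 1.45, or_age = 1.0,
                        male_prev = 0.64, smoking_prev = 0.40,
                        unknown_smoking_rate = 0.008, missing_rate = 0,
                        pop_multiplier = 4, stage = "stage1", seed = 1L) {
  k <- max(length(control_maf), length(odds_ratio))
  control_maf <- rep_len(control_maf, k)
  odds_ratio <- rep_len(odds_ratio, k)
  sf_assert(all(control_maf > 0 & control_maf < 1),
            "control_maf must lie strictly in (0, 1)")
  sf_assert(all(odds_ratio > 0) && or_sex > 0 && or_smoking > 0 &&
              or_age > 0, "odds ratios must be positive")
  sf_assert(all(c(smoking_prev, male_prev, missing_rate,
                  unknown_smoking_rate) >= 0 &
                  c(smoking_prev, male_prev, missing_rate,
                    unknown_smoking_rate) <= 1),
            "rates must lie in [0, 1]")
  model <- match.arg(model, genetic_models())
  structure(list(n_case = n_case, n_control = n_control,
                 control_maf = control_maf, model = model,
                 odds_ratio = odds_ratio, or_sex = or_sex,
                 or_smoking = or_smoking, or_age = or_age,
                 male_prev = male_prev, smoking_prev = smoking_prev,
                 unknown_smoking_rate = unknown_smoking_rate,
                 missing_rate = missing_rate,
                 pop_multiplier = pop_multiplier, stage = stage,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a retrospective case-control cohort
#'
#' Draws a virtual population with HWE genotypes and covariates, assigns
#' disease by the logistic model `logit P = b0 + log(OR_g) x(g) +
#' log(OR_sex) male + log(OR_smoke) smoker + log(OR_age) age`, with `b0`
#' tuned by bisection so the population case fraction is ~50% (maximizing
#' both sampling pools), then samples `n_case` cases and `n_control`
#' controls without replacement. Retrospective sampling leaves the planted
#' odds ratios as the estimands of logistic regression. Histology is
#' assigned to cases at realistic subtype shares (65% adenocarcinoma, 27%
#' squamous, 8% other).
#'
#' @param spec a [cohort_spec()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `phenotypes`
#'   (a [phenotype_table()]).
#' @export
simulate_cohort <- function(spec) {
  sf_assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  k <- length(spec$control_maf)
  with_seed(spec$seed, {
    N <- ceiling(spec$pop_multiplier * (spec$n_case + spec$n_control))
    g <- vapply(spec$control_maf, function(q)
      rbinom(N, 2L, q), integer(N))
    g <- matrix(as.integer(g), nrow = N)
    male <- rbinom(N, 1L, spec$male_prev)
    age <- rnorm(N, 55, 8.5)
    while (any(bad <- age < 30 | age > 80))
      age[bad] <- rnorm(sum(bad), 55, 8.5)
    age <- round(age, 1)
    smoker <- rbinom(N, 1L, spec$smoking_prev)
    # genotype score in the disease model; the genotype-class-restricted
    # models act through an indicator of their exposure class
    sim_code <- function(gg) switch(spec$model,
      homozygous = as.numeric(gg == 2L),
      heterozygous = as.numeric(gg == 1L),
      code_genotype(gg, spec$model))
    x <- vapply(seq_len(k), function(j) sim_code(g[, j]), numeric(N))
    lin <- drop(x %*% log(spec$odds_ratio)) +
      log(spec$or_sex) * male + log(spec$or_smoking) * smoker +
      log(spec$or_age) * age
    # bisection on the intercept for a ~50% population case fraction
    f <- function(b0) mean(plogis(b0 + lin)) - 0.5
    lo <- -50; hi <- 50
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-10) break
    }
    b0 <- (lo + hi) / 2
    y <- rbinom(N, 1L, plogis(b0 + lin))
    if (sum(y) < spec$n_case || sum(1 - y) < spec$n_control)
      sf_abort(paste0(
        "virtual population too small to sample the requested cohort; ",
        "increase pop_multiplier"), "snpfunnel_sampling_error")
    idx <- c(sample(which(y == 1L), spec$n_case),
             sample(which(y == 0L), spec$n_control))
    n <- length(idx)
    status <- c(rep("case", spec$n_case), rep("control", spec$n_control))
    smoking <- ifelse(smoker[idx] == 1L, "smoker", "nonsmoker")
    if (spec$unknown_smoking_rate > 0) {
      unk <- runif(n) < spec$unknown_smoking_rate
      smoking[unk] <- "unknown"
    }
    histology <- rep(NA_character_, n)
    is_case <- status == "case"
    histology[is_case] <- sample(c("adeno", "scc", "other"),
                                 sum(is_case), replace = TRUE,
                                 prob = c(0.65, 0.27, 0.08))
    samples <- sprintf("%s_%05d", spec$stage, seq_len(n))
    codes <- g[idx, , drop = FALSE]
    if (spec$missing_rate > 0)
      codes[matrix(runif(length(codes)) < spec$missing_rate,
                   nrow = n)] <- NA_integer_
    v <- variant_table(rep("chr1", k),
                       seq_len(k) * 100000L + 1000000L,
                       sprintf("snp%02d", seq_len(k)))
    phen <- phenotype_table(data.frame(
      sample = samples, status = status, age = age[idx],
      sex = ifelse(male[idx] == 1L, "male", "female"),
      smoking = smoking, histology = histology, stage = spec$stage,
      stringsAsFactors = FALSE))
    list(genotypes = genotype_matrix(codes, v, samples = samples),
         phenotypes = phen)
  })
}

#' Simulate peak sets with planted variant overlaps
#'
#' Designates `floor(fraction_in_atac * n)` of the given variants to lie
#' inside open-chromatin peaks, and `floor(fraction_also_h3k27ac * k)` of
#' those to lie inside histone-mark peaks as well. Peaks are placed to
#' contain exactly their designated variant (clipped against neighbouring
#' variants so no other variant slips in) and decoy peaks containing no
#' variant are added to each set. The ground-truth membership table is
#' returned for funnel testing.
#'
#' @param variants a [variant_table()].
#' @param fraction_in_atac,fraction_also_h3k27ac fractions in [0, 1].
#' @param peak_width nominal peak width in bp (> 0).
#' @param seed RNG seed.
#' @param n_decoys decoy peaks per set (default 50).
#' @return list with `atac`, `h3k27ac` (both [peak_set()]) and `truth`
#'   (data.frame rsid, in_atac, in_h3k27ac).
#' @export
simulate_peaks <- function(variants, fraction_in_atac,
                           fraction_also_h3k27ac, peak_width = 400L,
                           seed = 1L, n_decoys = 50L) {
  sf_assert(fraction_in_atac >= 0 && fraction_in_atac <= 1 &&
              fraction_also_h3k27ac >= 0 && fraction_also_h3k27ac <= 1,
            "fractions must lie in [0, 1]")
  if (peak_width < 1)
    sf_abort("peak_width must be a positive number of base pairs",
             "snpfunnel_spec_error")
  v <- as.data.frame(variants)
  n <- nrow(v)
  with_seed(seed, {
    n_atac <- floor(fraction_in_atac * n)
    atac_rs <- sort(sample(v$rsid, n_atac))
    n_h3k <- floor(fraction_also_h3k27ac * n_atac)
    h3k_rs <- sort(sample(atac_rs, n_h3k))
    place <- function(rsids) {
      if (length(rsids) == 0)
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric()))
      rows <- lapply(rsids, function(rs) {
        i <- which(v$rsid == rs)
        pos <- v$pos[i]
        same <- v[norm_chrom(v$chrom) == norm_chrom(v$chrom[i]), ]
        prev_pos <- max(c(0, same$pos[same$pos < pos]))
        next_pos <- min(c(Inf, same$pos[same$pos > pos]))
        off <- sample.int(peak_width, 1L)  # start = pos - off, in BED terms
        s <- max(pos - off, prev_pos)      # s >= prev_pos keeps prev out
        e <- min(s + peak_width, next_pos - 1)
        e <- max(e, pos)                   # always contain pos: s < pos <= e
        data.frame(chrom = v$chrom[i], start = s, end = e)
      })
      do.call(rbind, rows)
    }
    decoys <- function() {
      if (n_decoys == 0)
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric()))
      base <- max(v$pos) + 100L * peak_width
      starts <- base + (seq_len(n_decoys) - 1L) * 3L * peak_width +
        sample.int(peak_width, n_decoys, replace = TRUE)
      data.frame(chrom = rep(v$chrom[1], n_decoys), start = starts,
                 end = starts + peak_width)
    }
    a <- rbind(place(atac_rs), decoys())
    h <- rbind(place(h3k_rs), decoys())
    list(atac = peak_set(a$chrom, a$start, a$end, name = "ATAC"),
         h3k27ac = peak_set(h$chrom, h$start, h$end, name = "H3K27ac"),
         truth = data.frame(rsid = v$rsid,
                            in_atac = v$rsid %in% atac_rs,
                            in_h3k27ac = v$rsid %in% h3k_rs,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a tiered tag-SNP catalog
#'
#' @param n_genomewide,n_subthreshold tag counts per significance tier.
#' @param chroms chromosome labels to cycle tags over.
#' @param spacing_bp distance between consecutive tag positions on the
#'   same chromosome.
#' @param seed RNG seed.
#' @return a `tag_catalog` data.frame.
#' @export
simulate_tag_catalog <- function(n_genomewide = 21L, n_subthreshold = 7L,
                                 chroms = paste0("chr", 1:7),
                                 spacing_bp = 2000000L, seed = 1L) {
  n <- n_genomewide + n_subthreshold
  with_seed(seed, {
    p <- c(runif(n_genomewide, 1e-12, 4.9e-8),
           runif(n_subthreshold, 6e-8, 9.9e-6))
    chrom <- rep_len(chroms, n)
    pos <- integer(n)
    for (cc in unique(chrom)) {
      i <- which(chrom == cc)
      pos[i] <- 10000000L + (seq_along(i) - 1L) * spacing_bp
    }
    tier_tag_catalog(data.frame(
      rsid = sprintf("tag%02d", seq_len(n)), chrom = chrom, pos = pos,
      pvalue = p, stringsAsFactors = FALSE))
  })
}

#' Simulate a complete funnel world with planted ground truth
#'
#' Builds everything [run_funnel()] consumes: a tiered tag catalog, a
#' phased reference panel in which each tag anchors a haplotype block with
#' both high-LD (clearly above the retention threshold) and low-LD
#' (clearly below) companions, and ATAC/H3K27ac peak sets with planted
#' overlaps across all panel variants. The planted candidate set — the
#' variants that pass LD retention by construction AND lie in both peak
#' sets — is returned for exact-recovery testing.
#'
#' @param n_genomewide,n_subthreshold tag tier counts (defaults 21 and 7).
#' @param n_samples panel individuals per block.
#' @param high_r2,low_r2 construction targets on either side of the
#'   retention threshold (defaults 0.8 and 0.02).
#' @param n_high,n_low companions per tag at each target.
#' @param fraction_in_atac,fraction_also_h3k27ac planted peak fractions.
#' @param peak_width peak width in bp.
#' @param maf shared allele frequency of the block variants.
#' @param seed RNG seed.
#' @return list: `catalog`, `panel`, `atac`, `h3k27ac`, `truth` (per-panel
#'   variant membership), `planted_candidates` (character rsids).
#' @export
simulate_funnel_world <- function(n_genomewide = 21L, n_subthreshold = 7L,
                                  n_samples = 600L, high_r2 = 0.8,
                                  low_r2 = 0.02, n_high = 2L, n_low = 2L,
                                  fraction_in_atac = 0.5,
                                  fraction_also_h3k27ac = 0.5,
                                  peak_width = 400L, maf = 0.3,
                                  seed = 1L) {
  seeds <- derive_seeds(seed, 2L + n_genomewide + n_subthreshold)
  catalog <- simulate_tag_catalog(n_genomewide, n_subthreshold,
                                  seed = seeds[1])
  n_tags <- nrow(catalog)
  blocks <- vector("list", n_tags)
  ld_pass <- character()
  for (k in seq_len(n_tags)) {
    targets <- c(rep(high_r2, n_high), rep(low_r2, n_low))
    offsets <- seq_len(n_high + n_low) * 1500L
    rsids <- c(catalog$rsid[k],
               sprintf("%s_v%d", catalog$rsid[k], seq_along(targets)))
    spec <- block_spec(positions = c(catalog$pos[k],
                                     catalog$pos[k] + offsets),
                       anchor_freq = maf, targets = targets,
                       measure = "r2", chrom = catalog$chrom[k],
                       rsids = rsids)
    blocks[[k]] <- simulate_haplotypes(spec, n_samples,
                                       seed = seeds[2L + k])
    ld_pass <- c(ld_pass, rsids[1:(1 + n_high)])
  }
  panel <- do.call(cbind_genotypes, blocks)
  pk <- simulate_peaks(panel$variants, fraction_in_atac,
                       fraction_also_h3k27ac, peak_width,
                       seed = seeds[2])
  planted <- pk$truth$rsid[pk$truth$in_atac & pk$truth$in_h3k27ac &
                             pk$truth$rsid %in% ld_pass]
  list(catalog = catalog, panel = panel, atac = pk$atac,
       h3k27ac = pk$h3k27ac, truth = pk$truth,
       planted_candidates = sort(planted))
}
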