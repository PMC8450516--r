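# Independent oracles used by the suite. These deliberately do NOT reuse
# package internals: each is a second, brute-force implementation.

# linear-scan overlap oracle: 1-based pos p is inside BED (s, e] iff s < p <= e
brute_overlap <- function(chrom, pos, intervals) {
  hits <- which(sub("^chr", "", intervals$chrom) == sub("^chr", "", chrom) &
                  intervals$start < pos & pos <= intervals$end)
  hits
}

# second, independent narrowPeak parser (10 whitespace-split fields)
oracle_parse_narrowpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- unlist(strsplit(l, "\t"))
    stopifnot(length(f) == 10)
    data.frame(chrom = f[1], start = as.numeric(f[2]),
               end = as.numeric(f[3]), score = as.numeric(f[7]))
  })
  do.call(rbind, out)
}

# multinomial log-likelihood of a 3x3 genotype table given haplotype freqs
# (rows dosage at locus 1, cols locus 2); independent re-derivation
oracle_loglik <- function(tab, fAB, fAb, faB, fab) {
  P <- rbind(
    c(fab^2,          2 * faB * fab,                 faB^2),
    c(2 * fAb * fab,  2 * (fAB * fab + fAb * faB),   2 * fAB * faB),
    c(fAb^2,          2 * fAB * fAb,                 fAB^2))
  sum(tab[tab > 0] * log(P[tab > 0]))
}

# hierarchical grid search over (fAB, fAb, faB), fab = 1 - sum; reaches
# ~5e-4 resolution, well below the 5e-3 comparison tolerance
# vectorized log-likelihood over a grid of (fAB, fAb, faB) rows
oracle_loglik_grid <- function(tab, g) {
  fAB <- g[, 1]; fAb <- g[, 2]; faB <- g[, 3]
  fab <- pmax(1 - fAB - fAb - faB, 0)
  P <- cbind(fab^2, 2 * fAb * fab, fAb^2,            # g2 = 0 col of tab?
             2 * faB * fab, 2 * (fAB * fab + fAb * faB), 2 * fAB * fAb,
             faB^2, 2 * fAB * faB, fAB^2)
  # columns follow as.vector(tab) order: (g1 = 0,1,2) x (g2 = 0,1,2)
  obs <- as.vector(tab)
  drop(log(pmax(P, 1e-300)) %*% obs)
}

oracle_grid_em <- function(tab) {
  eval_grid <- function(g) {
    ll <- oracle_loglik_grid(tab, g)
    g[which.max(ll), ]
  }
  # pass 1: full simplex at step 0.05
  ax <- seq(0, 1, by = 0.05)
  g <- as.matrix(expand.grid(ax, ax, ax))
  g <- g[rowSums(g) <= 1 + 1e-12, , drop = FALSE]
  best <- eval_grid(g)
  # refine around the incumbent: 0.01, 0.002, 0.0004
  step <- 0.05
  for (rep in 1:3) {
    new_step <- step / 5
    ax <- lapply(best, function(c0)
      pmin(pmax(seq(c0 - step, c0 + step, by = new_step), 0), 1))
    g <- as.matrix(expand.grid(ax))
    g <- g[rowSums(g) <= 1 + 1e-12, , drop = FALSE]
    best <- eval_grid(g)
    step <- new_step
  }
  c(fAB = best[[1]], fAb = best[[2]], faB = best[[3]],
    fab = 1 - sum(best))
}

# draw a random 3x3 genotype table implied by random haplotype freqs
random_geno_table <- function(n = 150) {
  f <- as.numeric(stats::rgamma(4, shape = 1.5)); f <- f / sum(f)
  h1 <- sample(1:4, n, replace = TRUE, prob = f)
  h2 <- sample(1:4, n, replace = TRUE, prob = f)
  A <- c(1, 1, 0, 0); B <- c(1, 0, 1, 0)  # 1=AB 2=Ab 3=aB 4=ab
  g1 <- A[h1] + A[h2]; g2 <- B[h1] + B[h2]
  table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
}

# closed-form 2x2 chi-square
oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# one-parameter additive logistic fit solved by bisection on the score
# equation sum(x_i (y_i - plogis(b0 + b1 x_i))) = 0 with profile intercept
oracle_logistic_1param <- function(y, x) {
  score_b1 <- function(b1) {
    # profile out the intercept at this slope by inner bisection
    f0 <- function(b0) sum(y - plogis(b0 + b1 * x))
    lo <- -50; hi <- 50
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f0(mid) > 0) lo <- mid else hi <- mid
    }
    b0 <- (lo + hi) / 2
    sum(x * (y - plogis(b0 + b1 * x)))
  }
  lo <- -10; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (score_b1(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# small helpers shared across test files
make_phen <- function(n_case, n_control, stage = "stage1", seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  status <- c(rep("case", n_case), rep("control", n_control))
  data.frame(
    sample = sprintf("%s_s%04d", stage, seq_len(n)),
    status = status,
    age = round(runif(n, 40, 70), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    smoking = sample(c("smoker", "nonsmoker"), n, replace = TRUE),
    histology = ifelse(status == "case",
                       sample(c("adeno", "scc"), n, replace = TRUE), NA),
    stage = stage, stringsAsFactors = FALSE)
}
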