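# Independent brute-force oracles used across the test files. These
# deliberately re-derive each quantity from first principles (explicit
# normal equations, factorial enumeration, exhaustive window scans)
# rather than calling the package's own code paths.

# Explicit normal-equations OLS: returns the coefficient, SE, t and chi2
# for the named column of the design matrix.
oracle_ols <- function(y, X, which_col) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtXinv))
  j <- if (is.character(which_col)) match(which_col, colnames(X)) else which_col
  t_stat <- unname(beta[j] / se[j])
  list(beta = unname(beta[j]), se = unname(se[j]), t = t_stat,
       chi2 = t_stat^2, df = df)
}

# Exact HWE p by direct factorial enumeration of all heterozygote counts
# compatible with the allele counts (valid for small n).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_A <- 2 * n_AA + n_Aa
  hets <- seq(min(n_a, n_A) %% 2, min(n_a, n_A), by = 2)
  prob <- sapply(hets, function(h) {
    naa <- (n_a - h) / 2
    nAA <- (n_A - h) / 2
    if (naa < 0 || nAA < 0 || naa != round(naa)) return(0)
    exp(lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
          h * log(2) + lfactorial(n_a) + lfactorial(n_A) -
          lfactorial(2 * n))
  })
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hets)]
  sum(prob[prob <= p_obs + 1e-12])
}

# r^2 from known phased haplotype counts (h11, h10, h01, h00).
oracle_r2_from_haplotypes <- function(h) {
  h <- h / sum(h)
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# Exhaustive minimal set cover for a tagging instance: smallest number of
# tags covering all SNPs at r2 >= thr.
oracle_min_cover_size <- function(r2m, thr) {
  n <- nrow(r2m)
  covers <- r2m >= thr
  for (k in 1:n) {
    sets <- utils::combn(n, k, simplify = FALSE)
    for (s in sets) {
      if (all(apply(covers[, s, drop = FALSE], 1, any))) return(k)
    }
  }
  n
}

# Independent PWM window scorer: recomputes pseudocounted probabilities
# and min-max normalized log2-odds from the count matrix directly.
oracle_relative_score <- function(counts, pseudocount, bg, window) {
  p <- sweep(counts + pseudocount * bg, 2, colSums(counts) + pseudocount, "/")
  lo <- log2(p / bg)
  b <- strsplit(window, "")[[1]]
  idx <- match(b, c("A", "C", "G", "T"))
  s <- sum(lo[cbind(idx, seq_along(b))])
  if (!is.finite(s)) return(0)
  smin <- sum(apply(lo, 2, function(cl) min(cl[is.finite(cl)])))
  smax <- sum(apply(lo, 2, max))
  if (smax == smin) return(1)
  min(1, max(0, (s - smin) / (smax - smin)))
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Exhaustive best-window search over both strands for windows overlapping
# the variant interval [v0, v1] (0-based).
oracle_best_window <- function(counts, pseudocount, bg, seqc, v0, v1) {
  L <- ncol(counts)
  starts <- max(0, v0 - L + 1):min(nchar(seqc) - L, v1)
  best <- list(score = -1)
  for (st in c("+", "-")) {
    for (s in starts) {
      w <- substr(seqc, s + 1, s + L)
      if (grepl("[^ACGT]", w)) next
      sc <- oracle_relative_score(counts, pseudocount, bg,
                                  if (st == "+") w else oracle_revcomp(w))
      if (sc > best$score + 1e-12) best <- list(score = sc, offset = s,
                                                strand = st)
    }
  }
  best
}

# Random small genotype fixture with exact dosages.
rand_genotypes <- function(n, m, maf = 0.3, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, maf), n, m)
  # ensure polymorphism in every column
  for (j in seq_len(m)) {
    if (length(unique(d[, j])) == 1) d[1:2, j] <- c(0, 1)
  }
  genotype_matrix(d)
}

# Small aligned phenotype/covariate bundle for association fits.
make_assoc_bundle <- function(n = 30, beta = 0, noise_sd = 1, seed = 1,
                              trait = "volume") {
  cfg <- sim_config(n_subjects = n, n_snps = 2, seed = seed,
                    noise_sd = noise_sd,
                    effect_map = if (beta != 0)
                      data.frame(snp = 1, roi = "lh.SMG", trait = trait,
                                 beta = beta) else NULL)
  g <- simulate_genotypes(cfg)
  tab <- simulate_roi_phenotypes(g, cfg, traits = trait)
  list(genotypes = g, phenotypes = tab$phenotypes,
       covariates = tab$covariates, cfg = cfg)
}
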