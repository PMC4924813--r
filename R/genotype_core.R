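#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds minor-allele dosages (0/1/2, `NA` for missing)
#' for a set of subjects at a set of SNPs, together with per-SNP allele
#' labels. The dosage counts copies of the *minor* allele, so a positive
#' regression coefficient downstream means the minor allele increases the
#' trait.
#'
#' @param dosages integer matrix, subjects in rows, SNPs in columns. Row and
#'   column names are used as subject and SNP identifiers when
#'   `subject_ids`/`snp_ids` are not given.
#' @param subject_ids,snp_ids character vectors of unique identifiers.
#' @param allele_labels data frame with columns `snp`, `major`, `minor`
#'   giving the base labels for each SNP; defaults to generic "A"/"B".
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages,
                            subject_ids = rownames(dosages),
                            snp_ids = colnames(dosages),
                            allele_labels = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(subject_ids)) {
    subject_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  if (is.null(snp_ids)) {
    snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(subject_ids)) stop("duplicate subject IDs")
  if (anyDuplicated(snp_ids)) stop("duplicate SNP IDs")
  if (length(subject_ids) != nrow(dosages)) {
    stop("subject_ids length does not match dosage rows")
  }
  if (length(snp_ids) != ncol(dosages)) {
    stop("snp_ids length does not match dosage columns")
  }
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (is.null(allele_labels)) {
    allele_labels <- data.frame(snp = snp_ids, major = "A", minor = "B",
                                stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp", "major", "minor") %in% names(allele_labels)))
  if (!setequal(allele_labels$snp, snp_ids)) {
    stop("allele_labels must cover exactly the SNPs in the matrix")
  }
  allele_labels <- allele_labels[match(snp_ids, allele_labels$snp), ,
                                 drop = FALSE]
  rownames(dosages) <- subject_ids
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages,
                 subject_ids = subject_ids,
                 snp_ids = snp_ids,
                 allele_labels = allele_labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.1f%% missing)\n",
              length(x$subject_ids), length(x$snp_ids),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

.snp_column <- function(genotypes, snp) {
  if (!snp %in% genotypes$snp_ids) {
    stop(sprintf("SNP '%s' not present in genotype matrix", snp))
  }
  genotypes$dosages[, snp]
}

#' Minor allele frequency of one SNP
#'
#' Computes the frequency of the labelled minor allele among non-missing
#' calls, folding to the interval \[0, 0.5\]. When the labelled "minor"
#' allele is in fact the more common one, the frequency is folded and the
#' relabeling recorded in the `"folded"` attribute so the dosage direction
#' remains reconstructible.
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp SNP identifier.
#' @return frequency in \[0, 0.5\], with attribute `folded` (logical).
#' @export
minor_allele_frequency <- function(genotypes, snp) {
  d <- .snp_column(genotypes, snp)
  d <- d[!is.na(d)]
  if (!length(d)) stop(sprintf("SNP '%s' has no non-missing calls", snp))
  f <- sum(d) / (2 * length(d))
  folded <- f > 0.5
  if (folded) f <- 1 - f
  structure(f, folded = folded)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test of Hardy-Weinberg proportions for a biallelic SNP: the
#' p-value sums, over all heterozygote counts compatible with the observed
#' allele counts, the conditional probabilities no larger than that of the
#' observed heterozygote count (the standard exact SNP-HWE construction).
#' Probabilities are computed by full enumeration on the log scale, so the
#' test is exact at any sample size this pipeline sees.
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp SNP identifier.
#' @param midp if `TRUE`, use the mid-p variant (half weight on the
#'   observed configuration).
#' @return p-value in (0, 1\], with attribute `monomorphic` (logical).
#'   Monomorphic SNPs return p = 1 with a warning.
#' @export
hwe_test <- function(genotypes, snp, midp = FALSE) {
  d <- .snp_column(genotypes, snp)
  d <- d[!is.na(d)]
  if (length(d) < 3) stop("need at least 3 non-missing calls for HWE test")
  n_aa <- sum(d == 2)
  n_ab <- sum(d == 1)
  n_bb <- sum(d == 0)
  hwe_exact_from_counts(n_bb, n_ab, n_aa, midp = midp)
}

#' Exact HWE p-value from genotype counts
#'
#' @param n_AA,n_Aa,n_aa counts of the three genotype classes.
#' @param midp use the mid-p variant.
#' @return p-value in (0, 1\], attribute `monomorphic`.
#' @export
hwe_exact_from_counts <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa          # minor-ish allele count
  n_A <- 2 * n_AA + n_Aa
  if (n_a == 0 || n_A == 0) {
    warning("monomorphic SNP: HWE p-value set to 1")
    return(structure(1, monomorphic = TRUE))
  }
  rare <- min(n_a, n_A)
  # heterozygote count must have the parity of the rare allele count
  het_obs <- n_Aa
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_Aa = h | allele counts) up to a shared constant:
  #   2^h * rare! * common! / ( ((rare-h)/2)! h! ((common-h)/2)! )
  logp <- vapply(hets, function(h) {
    h * log(2) - lgamma((rare - h) / 2 + 1) - lgamma(h + 1) -
      lgamma((2 * n - rare - h) / 2 + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(het_obs, hets)]
  keep <- prob <= p_obs + 1e-12
  p <- sum(prob[keep])
  if (midp) p <- p - p_obs / 2
  structure(min(1, max(p, .Machine$double.xmin)), monomorphic = FALSE)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Estimates the squared allelic correlation between two SNPs. The default
#' `em_haplotype` method resolves the double-heterozygote phase ambiguity
#' with an EM algorithm over the four two-locus haplotype frequencies
#' (initialised at linkage equilibrium, iterated until the largest
#' frequency change is below 1e-8 or 100 iterations) and reports
#' r2 = D^2 / (pA pa pB pb). The `dosage_correlation` fallback is the
#' squared Pearson correlation of the dosage vectors. Subjects missing
#' either genotype are dropped (complete cases per pair).
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_a,snp_b SNP identifiers.
#' @param method `"em_haplotype"` (default) or `"dosage_correlation"`.
#' @return a data frame (one row) with columns `snp_a`, `snp_b`, `r2`,
#'   `n_used`, `method`.
#' @export
pairwise_r2 <- function(genotypes, snp_a, snp_b,
                        method = c("em_haplotype", "dosage_correlation")) {
  method <- match.arg(method)
  da <- .snp_column(genotypes, snp_a)
  db <- .snp_column(genotypes, snp_b)
  keep <- !is.na(da) & !is.na(db)
  da <- da[keep]; db <- db[keep]
  if (length(da) < 5) stop("need at least 5 complete-case subjects")
  for (nm in c(a = snp_a, b = snp_b)) {
    d <- if (nm == snp_a) da else db
    if (length(unique(d)) == 1L) {
      stop(sprintf("SNP '%s' is monomorphic in the complete cases; r2 undefined",
                   nm))
    }
  }
  r2 <- if (identical(snp_a, snp_b)) {
    1.0
  } else if (method == "dosage_correlation") {
    stats::cor(da, db)^2
  } else {
    em_haplotype_r2(da, db)
  }
  data.frame(snp_a = snp_a, snp_b = snp_b,
             r2 = min(1, max(0, r2)), n_used = length(da),
             method = method, stringsAsFactors = FALSE)
}

# EM estimate of r^2 from unphased dosage vectors at two biallelic loci.
# Dosages count the "1" allele at each locus; only the double heterozygote
# has ambiguous phase.
em_haplotype_r2 <- function(da, db, tol = 1e-8, max_iter = 100) {
  n <- length(da)
  tab <- table(factor(da, levels = 0:2), factor(db, levels = 0:2))
  pA <- mean(da) / 2  # freq of allele counted at locus A
  pB <- mean(db) / 2
  # haplotype freqs: h11 carries both counted alleles
  h <- c(h11 = pA * pB, h10 = pA * (1 - pB),
         h01 = (1 - pA) * pB, h00 = (1 - pA) * (1 - pB))
  n_dh <- tab["1", "1"]  # double heterozygotes: phase unknown
  # known haplotype counts from unambiguous genotypes
  base <- c(
    h11 = 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"],
    h10 = 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"],
    h01 = 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"],
    h00 = 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"]
  )
  for (iter in seq_len(max_iter)) {
    # E step: split double heterozygotes between cis (11/00) and trans (10/01)
    p_cis <- h["h11"] * h["h00"]
    p_trans <- h["h10"] * h["h01"]
    w <- if (p_cis + p_trans > 0) p_cis / (p_cis + p_trans) else 0.5
    cnt <- base + n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / (2 * n)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  pA <- h["h11"] + h["h10"]
  pB <- h["h11"] + h["h01"]
  D <- h["h11"] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  unname(D^2 / denom)
}

#' All pairwise r-squared values
#'
#' @param genotypes a [genotype_matrix()].
#' @param method passed to [pairwise_r2()].
#' @return symmetric matrix of r2 values with unit diagonal.
#' @export
ld_matrix <- function(genotypes, method = "em_haplotype") {
  snps <- genotypes$snp_ids
  m <- diag(1, length(snps))
  dimnames(m) <- list(snps, snps)
  if (length(snps) > 1) {
    for (i in seq_len(length(snps) - 1)) {
      for (j in seq(i + 1, length(snps))) {
        r2 <- pairwise_r2(genotypes, snps[i], snps[j], method = method)$r2
        m[i, j] <- m[j, i] <- r2
      }
    }
  }
  m
}

#' Greedy tag-SNP selection
#'
#' Pairwise greedy set cover: repeatedly pick the SNP that covers the most
#' still-uncovered SNPs at `r2 >= threshold` (a SNP always covers itself),
#' until every SNP is covered. Ties are broken by lower SNP index. This is
#' the pairwise tagging mode of standard taggers; multi-marker tags are out
#' of scope.
#'
#' @param r2_matrix symmetric r2 matrix with unit diagonal (e.g. from
#'   [ld_matrix()]).
#' @param threshold r2 threshold in (0, 1\] (the conventional default is
#'   0.8).
#' @return list with `tags` (ordered character vector of tag SNPs) and
#'   `coverage` (data frame `snp`, `tag`, `r2_to_tag`).
#' @export
greedy_tag_selection <- function(r2_matrix, threshold = 0.8) {
  m <- as.matrix(r2_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("r2_matrix must be symmetric")
  }
  if (any(abs(diag(m) - 1) > 1e-8)) stop("r2_matrix must have unit diagonal")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  snps <- rownames(m)
  if (is.null(snps)) snps <- paste0("snp", seq_len(nrow(m)))
  covers <- m >= threshold
  uncovered <- rep(TRUE, nrow(m))
  tags <- integer(0)
  tag_of <- integer(nrow(m))
  while (any(uncovered)) {
    gain <- colSums(covers & uncovered)
    pick <- which.max(gain)  # which.max takes the first (lowest index) tie
    tags <- c(tags, pick)
    newly <- covers[, pick] & uncovered
    tag_of[newly] <- pick
    uncovered[newly] <- FALSE
  }
  coverage <- data.frame(snp = snps,
                         tag = snps[tag_of],
                         r2_to_tag = m[cbind(seq_along(tag_of), tag_of)],
                         stringsAsFactors = FALSE)
  list(tags = snps[tags], coverage = coverage)
}

#' Genotype QC report
#'
#' Per-SNP minor allele frequency, exact HWE p-value, call rate, and
#' pass/fail flags at the supplied thresholds. Thresholds are exposed
#' rather than fixed because published QC pipelines rarely state every
#' cutoff; the default MAF floor of 0.15 matches common-variant tagging
#' designs.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency.
#' @param hwe_alpha HWE p-value below which a SNP fails.
#' @param call_rate_min minimum fraction of non-missing calls.
#' @return data frame: `snp`, `maf`, `hwe_p`, `call_rate`, `pass_maf`,
#'   `pass_hwe`, `pass_call_rate`, `pass`.
#' @export
qc_report <- function(genotypes, maf_min = 0.15, hwe_alpha = 0.001,
                      call_rate_min = 0.9) {
  rows <- lapply(genotypes$snp_ids, function(s) {
    d <- .snp_column(genotypes, s)
    cr <- mean(!is.na(d))
    maf <- tryCatch(as.numeric(minor_allele_frequency(genotypes, s)),
                    error = function(e) NA_real_)
    hp <- tryCatch(
      suppressWarnings(as.numeric(hwe_test(genotypes, s))),
      error = function(e) NA_real_)
    data.frame(snp = s, maf = maf, hwe_p = hp, call_rate = cr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass_maf <- !is.na(out$maf) & out$maf >= maf_min
  out$pass_hwe <- !is.na(out$hwe_p) & out$hwe_p >= hwe_alpha
  out$pass_call_rate <- out$call_rate >= call_rate_min
  out$pass <- out$pass_maf & out$pass_hwe & out$pass_call_rate
  out
}
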