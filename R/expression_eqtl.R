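#' Construct an expression matrix with sample maps
#'
#' Holds normalized (log-scale) expression values for brain samples, with
#' each sample mapped to exactly one individual and one brain region.
#'
#' @param values numeric matrix, samples in rows, probes in columns; row
#'   names are sample IDs.
#' @param sample_map data frame with columns `sample_id`,
#'   `individual_id`, `region` covering every row of `values`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_map) {
  values <- as.matrix(values)
  stopifnot(all(c("sample_id", "individual_id", "region") %in%
                  names(sample_map)))
  if (anyDuplicated(sample_map$sample_id)) stop("duplicate sample IDs")
  if (is.null(rownames(values))) rownames(values) <- sample_map$sample_id
  if (!setequal(rownames(values), sample_map$sample_id)) {
    stop("sample_map must cover exactly the samples in the value matrix")
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  sample_map <- sample_map[match(rownames(values), sample_map$sample_id), ]
  structure(list(values = values,
                 sample_ids = rownames(values),
                 probe_ids = colnames(values),
                 sample_map = sample_map),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d probes, %d individuals\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_map$individual_id))))
  invisible(x)
}

#' Average a probe's expression within individuals
#'
#' Unweighted arithmetic mean of a probe's expression over each
#' individual's regional samples. The result does not depend on sample
#' ordering; with one sample per individual it is the identity.
#'
#' @param expr an [expression_matrix()].
#' @param probe probe identifier.
#' @return named numeric vector, one value per distinct individual
#'   (names are individual IDs, in first-appearance order).
#' @export
average_by_individual <- function(expr, probe) {
  if (!probe %in% expr$probe_ids) {
    stop(sprintf("probe '%s' not present", probe))
  }
  v <- expr$values[, probe]
  ind <- expr$sample_map$individual_id
  means <- tapply(v, ind, mean)
  out <- as.vector(means[unique(ind)])
  names(out) <- unique(ind)
  out
}

#' eQTL regression of averaged expression on genotype dosage
#'
#' Simple linear regression of per-individual averaged expression on
#' minor-allele dosage, with Wald t and two-sided p. No covariates are
#' included by default, matching a single-probe candidate-variant test;
#' a covariate hook is provided for completeness.
#'
#' @param expr_by_individual named numeric vector as returned by
#'   [average_by_individual()].
#' @param genotypes a [genotype_matrix()] with one row per individual, or
#'   a named dosage vector.
#' @param snp SNP identifier (ignored when `genotypes` is a vector).
#' @param probe probe identifier, recorded in the output.
#' @param covariates optional data frame of per-individual covariates
#'   (individual ID column 1); default none.
#' @return one-row data frame: `probe`, `snp`, `n_individuals`, `slope`,
#'   `se`, `t_stat`, `p`, `direction_allele` (allele label whose count
#'   increases fitted expression).
#' @export
fit_eqtl <- function(expr_by_individual, genotypes, snp = NULL,
                     probe = "probe", covariates = NULL) {
  if (inherits(genotypes, "genotype_matrix")) {
    if (is.null(snp)) snp <- genotypes$snp_ids[1]
    dos <- genotypes$dosages[, snp]
    names(dos) <- genotypes$subject_ids
    lab <- genotypes$allele_labels[
      genotypes$allele_labels$snp == snp, , drop = FALSE]
  } else {
    dos <- genotypes
    if (is.null(snp)) snp <- "snp"
    lab <- data.frame(major = "major", minor = "minor")
  }
  ids <- intersect(names(expr_by_individual), names(dos))
  if (length(ids)) {
    e <- expr_by_individual[ids]; d <- dos[ids]
  } else {
    # unnamed vectors: align positionally
    e <- expr_by_individual; d <- dos
    if (length(e) != length(d)) stop("expression and dosage lengths differ")
  }
  keep <- !is.na(e) & !is.na(d)
  e <- e[keep]; d <- d[keep]
  if (length(e) < 5) stop("need at least 5 complete cases")
  if (stats::var(d) == 0) stop("zero dosage variance; eQTL fit undefined")
  X <- cbind(1, dosage = d)
  if (!is.null(covariates)) {
    cv <- covariates[match(names(e), covariates[[1]]), -1, drop = FALSE]
    X <- cbind(X, as.matrix(cv))
  }
  fit <- stats::lm.fit(X, e)
  df <- length(e) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  slope <- unname(fit$coefficients["dosage"])
  tval <- if (se > 0) slope / se else 0
  data.frame(probe = probe, snp = snp, n_individuals = length(e),
             slope = slope, se = se, t_stat = tval,
             p = 2 * stats::pt(-abs(tval), df),
             direction_allele = if (slope >= 0) lab$minor[1] else lab$major[1],
             stringsAsFactors = FALSE)
}

#' Lack-of-fit F-test around a linear fit
#'
#' Partitions the residual sum of squares from the straight-line fit of
#' `y` on `x` into pure error (within repeated `x` levels) and lack of
#' fit, and tests `F = (SS_lof / df_lof) / (SS_pe / df_pe)`. When no `x`
#' level is replicated there is no pure-error term; the function then
#' falls back to the overall regression F-test and flags the fallback.
#'
#' @param x predictor with (ideally) repeated levels.
#' @param y response.
#' @return list: `F`, `p`, `df1`, `df2`, `ss_lof`, `ss_pe`, `fallback`
#'   (`TRUE` when the overall regression F was used).
#' @export
lack_of_fit_f_test <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 observations")
  lev <- factor(x)
  if (nlevels(lev) < 2) stop("x must have at least 2 distinct levels")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  group_means <- tapply(y, lev, mean)
  ss_pe <- sum((y - group_means[lev])^2)
  df_pe <- length(y) - nlevels(lev)
  if (df_pe == 0) {
    # no replicated level: overall regression F
    s <- summary(fit)
    Fv <- unname(s$fstatistic[1])
    return(list(F = Fv, p = stats::pf(Fv, s$fstatistic[2], s$fstatistic[3],
                                      lower.tail = FALSE),
                df1 = unname(s$fstatistic[2]), df2 = unname(s$fstatistic[3]),
                ss_lof = NA_real_, ss_pe = NA_real_, fallback = TRUE))
  }
  ss_lof <- max(ss_res - ss_pe, 0)
  df_lof <- nlevels(lev) - 2
  if (df_lof == 0 || ss_res < 1e-12) {
    # two levels fit a line exactly, or a perfect fit: no lack of fit
    return(list(F = 0, p = 1, df1 = df_lof, df2 = df_pe,
                ss_lof = ss_lof, ss_pe = ss_pe, fallback = FALSE))
  }
  if (ss_pe == 0) {
    # curvature with zero within-level noise: infinite evidence
    return(list(F = Inf, p = 0, df1 = df_lof, df2 = df_pe,
                ss_lof = ss_lof, ss_pe = ss_pe, fallback = FALSE))
  }
  Fv <- (ss_lof / df_lof) / (ss_pe / df_pe)
  list(F = Fv, p = stats::pf(Fv, df_lof, df_pe, lower.tail = FALSE),
       df1 = df_lof, df2 = df_pe, ss_lof = ss_lof, ss_pe = ss_pe,
       fallback = FALSE)
}

#' Screen transcription factors for correlation with a target transcript
#'
#' For each TF probe, computes the Pearson correlation between
#' per-individual averaged TF expression and averaged target expression,
#' with significance from the lack-of-fit style F-test of the regression
#' of target on TF (for continuous TF expression without replicated
#' levels this is the overall regression F, flagged as such) and a
#' Bonferroni multiplier of `n_tests`. Zero-variance TF vectors are
#' reported as `NA` with a reason rather than failing the screen.
#'
#' @param expr an [expression_matrix()].
#' @param tf_probes character vector of TF probe IDs.
#' @param target_probe target probe ID.
#' @param n_tests Bonferroni multiplier; must be at least
#'   `length(tf_probes)` (use the size of the full motif-annotated TF
#'   panel screened, e.g. 127).
#' @return data frame sorted by `p_raw`: `tf`, `r`, `r2`, `p_raw`,
#'   `p_bonferroni`, `n_tests`, `flag`.
#' @export
tf_correlation_screen <- function(expr, tf_probes, target_probe, n_tests) {
  if (n_tests < length(tf_probes)) {
    stop("n_tests must be >= number of TF probes screened")
  }
  target <- average_by_individual(expr, target_probe)
  rows <- lapply(tf_probes, function(tf) {
    tfv <- average_by_individual(expr, tf)
    if (stats::var(tfv) == 0 || stats::var(target) == 0) {
      return(data.frame(tf = tf, r = NA_real_, r2 = NA_real_,
                        p_raw = NA_real_, p_bonferroni = NA_real_,
                        n_tests = n_tests, flag = "zero_variance",
                        stringsAsFactors = FALSE))
    }
    r <- stats::cor(tfv, target)
    lof <- lack_of_fit_f_test(tfv, target)
    data.frame(tf = tf, r = r, r2 = r^2, p_raw = lof$p,
               p_bonferroni = min(1, lof$p * n_tests),
               n_tests = n_tests,
               flag = if (lof$fallback) "overall_F" else "lack_of_fit_F",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_raw), , drop = FALSE]
}
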