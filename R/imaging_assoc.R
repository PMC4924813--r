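#' Association model specification
#'
#' Describes the covariate-adjusted additive model fitted for each
#' SNP-ROI pair:
#' `trait(ROI) = alpha + beta1 * dosage + covariates + global measure + e`.
#' The discovery-style default adjusts for age, sex, ethnicity,
#' handedness and the trait-matched global measure; a validation-style
#' specification is expressed purely through the `covariates` argument
#' (include `scanner`, drop `handedness`) with no code change.
#'
#' @param trait `"volume"`, `"surface_area"` or `"thickness"`.
#' @param roi_set ROIs to aggregate over; defaults to
#'   [default_roi_set()] for the trait (subcortical/white-matter ROIs are
#'   volume-only).
#' @param covariates named character vector: names are covariate column
#'   names, values are `"continuous"` or `"categorical"`.
#' @param global_covariate column name of the trait-matched whole-brain
#'   measure; defaults to `<trait>.global`.
#' @return an `assoc_model_spec` object.
#' @export
assoc_model_spec <- function(trait = c("volume", "surface_area", "thickness"),
                             roi_set = NULL,
                             covariates = c(age = "continuous",
                                            sex = "categorical",
                                            ethnicity = "categorical",
                                            handedness = "categorical"),
                             global_covariate = NULL) {
  trait <- match.arg(trait)
  if (is.null(roi_set)) roi_set <- default_roi_set(trait)
  if (!length(roi_set)) stop("roi_set must be non-empty")
  if (trait != "volume" &&
      any(roi_set %in% c("CC", "lh.tempWM"))) {
    stop("CC and lh.tempWM are volume-only ROIs (no surface area/thickness)")
  }
  if (length(covariates) &&
      !all(covariates %in% c("continuous", "categorical"))) {
    stop("covariate kinds must be 'continuous' or 'categorical'")
  }
  if (is.null(global_covariate)) global_covariate <- paste0(trait, ".global")
  structure(list(trait = trait, roi_set = roi_set,
                 covariates = covariates,
                 global_covariate = global_covariate),
            class = "assoc_model_spec")
}

# Assemble the nuisance design matrix (intercept + covariates + global
# measure) for the aligned subject set. Categorical covariates are
# dummy-coded against the first level in lexicographic order.
.nuisance_design <- function(phenotypes, covariates, spec) {
  n <- nrow(covariates)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in names(spec$covariates)) {
    if (!nm %in% names(covariates)) {
      stop(sprintf("covariate '%s' not found in covariate table", nm))
    }
    v <- covariates[[nm]]
    if (spec$covariates[[nm]] == "continuous") {
      X <- cbind(X, stats::setNames(as.numeric(v), NULL))
      colnames(X)[ncol(X)] <- nm
    } else {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1]) {
        X <- cbind(X, as.numeric(v == l))
        colnames(X)[ncol(X)] <- paste0(nm, l)
      }
    }
  }
  g <- spec$global_covariate
  if (!is.null(g) && nzchar(g)) {
    src <- if (g %in% names(phenotypes)) phenotypes else covariates
    if (!g %in% names(src)) {
      stop(sprintf("global covariate '%s' not found", g))
    }
    X <- cbind(X, as.numeric(src[[g]]))
    colnames(X)[ncol(X)] <- g
  }
  X
}

# Align phenotype, covariate and genotype tables on their shared
# subjects. Subject ID column is column 1 of each table. The shared IDs
# are put in a canonical (radix-sorted) order so permutation streams do
# not depend on the row order of the input tables.
.align_subjects <- function(phenotypes, genotypes, covariates) {
  ids <- Reduce(intersect, list(genotypes$subject_ids,
                                phenotypes[[1]], covariates[[1]]))
  ids <- sort(ids, method = "radix")
  if (!length(ids)) stop("no subjects shared across tables")
  list(ids = ids,
       phenotypes = phenotypes[match(ids, phenotypes[[1]]), , drop = FALSE],
       covariates = covariates[match(ids, covariates[[1]]), , drop = FALSE],
       dosages = genotypes$dosages[match(ids, genotypes$subject_ids), ,
                                   drop = FALSE])
}

# Core OLS for one genotype vector against one phenotype, given the
# nuisance design. Returns the genotype coefficient's estimate, SE, t,
# chi2 = t^2, p and the complete-case count.
.ols_geno <- function(y, g, X) {
  keep <- stats::complete.cases(y, g, X)
  y <- y[keep]; g <- g[keep]; X <- X[keep, , drop = FALSE]
  Xf <- cbind(X, genotype = g)
  p <- ncol(Xf)
  if (length(y) < p + 2) stop("too few complete-case subjects for the design")
  qrf <- qr(Xf)
  if (qrf$rank < p) {
    bad <- colnames(Xf)[qrf$pivot[seq(qrf$rank + 1, p)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrf, y)
  res <- y - Xf %*% coefs
  df <- length(y) - p
  sigma2 <- sum(res^2) / df
  piv <- qrf$pivot
  XtXinv <- matrix(NA_real_, p, p)
  XtXinv[piv, piv] <- chol2inv(qr.R(qrf))
  se <- sqrt(sigma2 * XtXinv[p, p])
  beta <- unname(coefs["genotype"])
  tval <- if (se > 0) beta / se else 0
  if (sigma2 == 0 && beta == 0) tval <- 0
  list(beta = beta, se = se, t = tval, chi2 = tval^2, df_resid = df,
       p = 2 * stats::pt(-abs(tval), df), n_used = length(y))
}

#' Fit the additive model for one SNP-ROI pair
#'
#' Ordinary least squares of the ROI measure on minor-allele dosage plus
#' the covariates declared in the model specification, on complete cases.
#' The per-test chi-square is the squared Wald t of the genotype
#' coefficient (the 1-df Wald chi-square).
#'
#' @param phenotypes data frame, subject ID in column 1, ROI columns named
#'   `<trait>.<roi>`.
#' @param genotypes a [genotype_matrix()].
#' @param covariates data frame, subject ID in column 1.
#' @param spec an [assoc_model_spec()].
#' @param snp,roi identifiers.
#' @return one-row data frame: `snp`, `roi`, `trait`, `n_used`, `beta`,
#'   `se`, `t_stat`, `df_resid`, `chi2`, `p_nominal`.
#' @export
fit_snp_roi <- function(phenotypes, genotypes, covariates, spec, snp, roi) {
  al <- .align_subjects(phenotypes, genotypes, covariates)
  col <- paste0(spec$trait, ".", roi)
  if (!col %in% names(al$phenotypes)) {
    stop(sprintf("phenotype column '%s' not found", col))
  }
  if (!snp %in% colnames(al$dosages)) {
    stop(sprintf("SNP '%s' not present in genotype matrix", snp))
  }
  y <- al$phenotypes[[col]]
  if (stats::var(y, na.rm = TRUE) == 0) {
    # constant phenotype: the genotype explains nothing by definition
    X <- .nuisance_design(al$phenotypes, al$covariates, spec)
    n <- sum(stats::complete.cases(y, al$dosages[, snp], X))
    return(data.frame(snp = snp, roi = roi, trait = spec$trait, n_used = n,
                      beta = 0, se = 0, t_stat = 0,
                      df_resid = n - ncol(X) - 1, chi2 = 0, p_nominal = 1,
                      stringsAsFactors = FALSE))
  }
  X <- .nuisance_design(al$phenotypes, al$covariates, spec)
  f <- .ols_geno(y, al$dosages[, snp], X)
  data.frame(snp = snp, roi = roi, trait = spec$trait, n_used = f$n_used,
             beta = f$beta, se = f$se, t_stat = f$t, df_resid = f$df_resid,
             chi2 = f$chi2, p_nominal = f$p, stringsAsFactors = FALSE)
}

#' Aggregate chi-square across ROIs for one SNP
#'
#' The observed aggregate statistic is the sum of the per-ROI 1-df
#' chi-squares for a single SNP across the model's ROI set.
#'
#' @param results data frame of [fit_snp_roi()] rows for one SNP.
#' @param roi_set the ROI set that must be covered (default: the ROIs
#'   present in `results`).
#' @return the aggregate chi-square (numeric scalar).
#' @export
aggregate_x2 <- function(results, roi_set = unique(results$roi)) {
  if (length(unique(results$snp)) != 1) {
    stop("aggregate_x2 expects results for exactly one SNP")
  }
  missing_rois <- setdiff(roi_set, results$roi)
  if (length(missing_rois)) {
    stop("missing ROI results: ", paste(missing_rois, collapse = ", "))
  }
  sum(results$chi2[match(roi_set, results$roi)])
}

# All permutations of 1..n (n small), as an n! x n matrix.
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Residualize the columns of M against the orthonormal basis Q.
.resid_q <- function(M, Q) M - Q %*% crossprod(Q, M)

# chi2 for each column of Gstar against ystar (both already residualized
# against the p-column nuisance design), n observations.
.chi2_fwl <- function(Gstar, ystar, n, p) {
  gg <- colSums(Gstar^2)
  cross <- as.vector(crossprod(Gstar, ystar))
  ssy <- sum(ystar^2)
  df <- n - p - 1
  expl <- cross^2 / gg
  chi2 <- expl * df / (ssy - expl)
  chi2[gg == 0] <- 0
  pmax(chi2, 0)
}

#' Aggregate permutation test for SNP-ROI association
#'
#' For each SNP the observed statistic is the sum over the model's ROI set
#' of the 1-df Wald chi-squares of the genotype coefficient. Significance
#' is assessed by permuting the genotype rows across subjects — one shared
#' subject shuffle per replicate, so the phenotype-covariate structure and
#' the LD among SNPs are both preserved — and refitting every model.
#' Missing genotypes travel with the shuffled genotype vector.
#'
#' Three correction modes are available:
#' \describe{
#'   \item{per_snp}{each SNP's aggregate statistic is compared with its own
#'     permutation distribution;}
#'   \item{max_t_snps}{family-wise over SNPs: compared with the permutation
#'     distribution of the maximum aggregate statistic across SNPs;}
#'   \item{max_t_snp_roi}{family-wise over all SNP-ROI pairs: each pair's
#'     chi-square is compared with the permutation distribution of the
#'     maximum single-pair chi-square.}
#' }
#' Monte-Carlo p-values use the add-one rule
#' `p = (1 + #permuted >= observed) / (1 + n_perm)` and are therefore never
#' exactly zero. With `exhaustive = TRUE` all `n!` subject permutations are
#' enumerated instead (n <= 8) and `p = #(>= observed) / n!`.
#'
#' @param phenotypes,genotypes,covariates as in [fit_snp_roi()].
#' @param spec an [assoc_model_spec()].
#' @param snps SNP identifiers to test (default: all in `genotypes`).
#' @param n_perm number of permutation replicates (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param correction_mode `"per_snp"`, `"max_t_snps"` or `"max_t_snp_roi"`.
#' @param scheme `"genotype"` permutes genotype rows (default);
#'   `"freedman_lane"` permutes residuals from the covariate-only fit.
#' @param exhaustive enumerate all subject permutations (requires n <= 8).
#' @return data frame with one row per SNP (aggregate modes) carrying
#'   `x2_obs` and `p_perm`, or one row per SNP-ROI pair
#'   (`max_t_snp_roi`) carrying `chi2_obs` and `p_perm`; attributes
#'   `n_perm`, `seed`, `correction_mode`, `perm_stats`.
#' @export
permutation_test <- function(phenotypes, genotypes, covariates, spec,
                             snps = genotypes$snp_ids,
                             n_perm = 10000, seed = 1L,
                             correction_mode = c("per_snp", "max_t_snps",
                                                 "max_t_snp_roi"),
                             scheme = c("genotype", "freedman_lane"),
                             exhaustive = FALSE) {
  correction_mode <- match.arg(correction_mode)
  scheme <- match.arg(scheme)
  if (!exhaustive && n_perm < 100) stop("n_perm must be >= 100")
  al <- .align_subjects(phenotypes, genotypes, covariates)
  n <- length(al$ids)
  cols <- paste0(spec$trait, ".", spec$roi_set)
  miss <- setdiff(cols, names(al$phenotypes))
  if (length(miss)) stop("phenotype columns missing: ",
                         paste(miss, collapse = ", "))
  G <- al$dosages[, snps, drop = FALSE]
  storage.mode(G) <- "double"
  Y <- as.matrix(al$phenotypes[, cols, drop = FALSE])
  X <- .nuisance_design(al$phenotypes, al$covariates, spec)
  if (anyNA(Y) || anyNA(X)) {
    keep <- stats::complete.cases(Y, X)
    Y <- Y[keep, , drop = FALSE]; X <- X[keep, , drop = FALSE]
    G <- G[keep, , drop = FALSE]; n <- nrow(Y)
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient covariate design")
  Q <- qr.Q(qrX)
  Ystar <- .resid_q(Y, Q)
  has_na_g <- anyNA(G)

  if (has_na_g && scheme == "freedman_lane") {
    stop("freedman_lane scheme requires complete genotype data")
  }

  chi2_for_G <- function(Gmat, Ys = Ystar) {
    # SNP x ROI chi2 matrix for one genotype configuration
    if (!anyNA(Gmat)) {
      Gstar <- .resid_q(Gmat, Q)
      out <- sapply(seq_len(ncol(Ys)), function(j)
        .chi2_fwl(Gstar, Ys[, j], n, p))
      matrix(out, nrow = ncol(Gmat))
    } else {
      # complete-case refit per SNP x ROI (missing calls travel with g)
      out <- matrix(0, ncol(Gmat), ncol(Y))
      for (s in seq_len(ncol(Gmat))) {
        g <- Gmat[, s]
        ok <- !is.na(g)
        for (j in seq_len(ncol(Y))) {
          f <- .ols_geno(Y[ok, j], g[ok], X[ok, , drop = FALSE])
          out[s, j] <- f$chi2
        }
      }
      out
    }
  }

  obs <- chi2_for_G(G)
  x2_obs <- rowSums(obs)

  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration supported only for n <= 8")
    perms <- .all_permutations(n)
  } else {
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(n)))
  }
  R <- nrow(perms)

  if (scheme == "freedman_lane") {
    fitted0 <- Y - Ystar  # covariate-only fitted values
  }

  single_snp <- ncol(G) == 1 && scheme == "genotype" && !has_na_g
  if (single_snp) {
    # batch all replicates: n x R matrix of permuted genotype columns
    Gp <- matrix(G[perms], nrow = R)  # R x n; each row a permuted g
    Gp <- t(Gp)
    Gpstar <- .resid_q(Gp, Q)
    chi2_rep <- sapply(seq_len(ncol(Ystar)), function(j)
      .chi2_fwl(Gpstar, Ystar[, j], n, p))          # R x ROI
    chi2_rep <- matrix(chi2_rep, nrow = R)
    agg_rep <- matrix(rowSums(chi2_rep), ncol = 1)   # R x 1 SNP
    max_pair_rep <- apply(chi2_rep, 1, max)
  } else {
    agg_rep <- matrix(0, R, ncol(G))
    max_pair_rep <- numeric(R)
    for (r in seq_len(R)) {
      if (scheme == "genotype") {
        ch <- chi2_for_G(G[perms[r, ], , drop = FALSE])
      } else {
        Yp <- fitted0 + Ystar[perms[r, ], , drop = FALSE]
        ch <- chi2_for_G(G, .resid_q(Yp, Q))
      }
      agg_rep[r, ] <- rowSums(ch)
      max_pair_rep[r] <- max(ch)
    }
  }

  p_from_counts <- function(count, R) {
    if (exhaustive) count / R else (1 + count) / (1 + R)
  }

  if (correction_mode == "max_t_snp_roi") {
    rows <- expand.grid(roi = spec$roi_set, snp = snps,
                        stringsAsFactors = FALSE)[, c("snp", "roi")]
    rows$trait <- spec$trait
    rows$chi2_obs <- as.vector(t(obs))
    rows$p_perm <- vapply(rows$chi2_obs, function(c0)
      p_from_counts(sum(max_pair_rep >= c0 - 1e-12), R), numeric(1))
    out <- rows
  } else {
    ref <- if (correction_mode == "per_snp") agg_rep else
      matrix(apply(agg_rep, 1, max), R, ncol(G))
    p_perm <- vapply(seq_along(snps), function(s)
      p_from_counts(sum(ref[, s] >= x2_obs[s] - 1e-12), R), numeric(1))
    out <- data.frame(snp = snps, trait = spec$trait, x2_obs = x2_obs,
                      n_perm = R, p_perm = p_perm,
                      stringsAsFactors = FALSE)
  }
  attr(out, "n_perm") <- R
  attr(out, "seed") <- if (exhaustive) NA_integer_ else seed
  attr(out, "correction_mode") <- correction_mode
  attr(out, "perm_stats") <- if (correction_mode == "max_t_snp_roi")
    max_pair_rep else agg_rep
  out
}

#' Nominal scan of every SNP-ROI pair
#'
#' Fits [fit_snp_roi()] for every pair in scope. No multiplicity
#' correction is applied here; family-wise control over pairs is provided
#' by [permutation_test()] in `max_t_snp_roi` mode. Pairs whose fit fails
#' (for example a zero-variance phenotype column passed with
#' `na_on_error = TRUE`) are recorded as `NA` with the failure reason.
#'
#' @inheritParams fit_snp_roi
#' @param snp_list SNPs to scan (default: all).
#' @param na_on_error record failed fits as NA rows instead of stopping.
#' @return data frame, one row per SNP-ROI pair, with a `reason` column
#'   (`NA` for clean fits).
#' @export
pairwise_scan <- function(phenotypes, genotypes, covariates, spec,
                          snp_list = genotypes$snp_ids,
                          na_on_error = TRUE) {
  grid <- expand.grid(roi = spec$roi_set, snp = snp_list,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- tryCatch({
      col <- paste0(spec$trait, ".", grid$roi[i])
      if (col %in% names(phenotypes) &&
          stats::var(phenotypes[[col]], na.rm = TRUE) == 0) {
        stop("zero-variance phenotype column")
      }
      fit_snp_roi(phenotypes, genotypes, covariates, spec,
                  grid$snp[i], grid$roi[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!na_on_error) stop(res)
      return(data.frame(snp = grid$snp[i], roi = grid$roi[i],
                        trait = spec$trait, n_used = NA_integer_,
                        beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                        df_resid = NA_integer_, chi2 = NA_real_,
                        p_nominal = NA_real_,
                        reason = conditionMessage(res),
                        stringsAsFactors = FALSE))
    }
    res$reason <- NA_character_
    res
  })
  do.call(rbind, rows)
}

#' Covariate-adjusted phenotype means by genotype class
#'
#' Fits the model with genotype as a three-level factor and reports the
#' covariate-adjusted (marginal) mean of the phenotype in each dosage
#' class, for allele-dosage trend displays. Classes absent from the data
#' are reported with `NA`.
#'
#' @inheritParams fit_snp_roi
#' @return data frame: `dosage` (0/1/2), `adj_mean`, `se`, `n`.
#' @export
genotype_trend_summary <- function(phenotypes, genotypes, covariates, spec,
                                   snp, roi) {
  al <- .align_subjects(phenotypes, genotypes, covariates)
  col <- paste0(spec$trait, ".", roi)
  if (!col %in% names(al$phenotypes)) {
    stop(sprintf("phenotype column '%s' not found", col))
  }
  df <- data.frame(y = al$phenotypes[[col]],
                   g = factor(al$dosages[, snp], levels = 0:2))
  X <- .nuisance_design(al$phenotypes, al$covariates, spec)
  Xdf <- as.data.frame(X[, -1, drop = FALSE])  # drop explicit intercept
  names(Xdf) <- make.names(colnames(X)[-1])
  df <- cbind(df, Xdf)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$g <- droplevels(df$g)
  fml <- stats::as.formula(paste("y ~ g +",
                                 paste(names(Xdf), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  emm <- as.data.frame(emmeans::emmeans(fit, "g"))
  out <- data.frame(dosage = 0:2, adj_mean = NA_real_, se = NA_real_,
                    n = as.integer(table(factor(df$g, levels = 0:2))))
  idx <- match(as.character(emm$g), as.character(out$dosage))
  out$adj_mean[idx] <- emm$emmean
  out$se[idx] <- emm$SE
  out
}

#' Bonferroni correction over a fixed number of endpoints
#'
#' @param p p-value(s).
#' @param n_endpoints number of endpoints tested (the three anatomical
#'   traits give `n_endpoints = 3`).
#' @return `pmin(1, p * n_endpoints)`.
#' @export
bonferroni_correct <- function(p, n_endpoints = 3) {
  stopifnot(n_endpoints >= 1)
  pmin(1, p * n_endpoints)
}
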