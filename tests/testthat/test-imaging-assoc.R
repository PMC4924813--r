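test_that("fit_snp_roi recovers a planted effect in the deterministic limit", {
  b <- make_assoc_bundle(n = 100, beta = 5, noise_sd = 1e-7, seed = 2)
  spec <- assoc_model_spec("volume")
  fit <- fit_snp_roi(b$phenotypes, b$genotypes, b$covariates, spec,
                     "snp01", "lh.SMG")
  expect_equal(fit$beta, 5, tolerance = 0.01)
  expect_lt(fit$p_nominal, 1e-10)
})

test_that("a constant phenotype yields beta = t = chi2 = 0", {
  b <- make_assoc_bundle(n = 30, seed = 3)
  b$phenotypes$volume.lh.SMG <- 7.5
  spec <- assoc_model_spec("volume")
  fit <- fit_snp_roi(b$phenotypes, b$genotypes, b$covariates, spec,
                     "snp01", "lh.SMG")
  expect_equal(fit$beta, 0)
  expect_equal(fit$t_stat, 0)
  expect_equal(fit$chi2, 0)
})

test_that("fit_snp_roi matches an explicit normal-equations solve", {
  b <- make_assoc_bundle(n = 30, beta = 1, seed = 4)
  spec <- assoc_model_spec("volume")
  fit <- fit_snp_roi(b$phenotypes, b$genotypes, b$covariates, spec,
                     "snp01", "lh.SMG")
  # independent design build: dummy coding against first lexicographic level
  cv <- b$covariates
  X <- cbind(1, cv$age, as.numeric(cv$sex == "M"),
             as.numeric(cv$ethnicity == "pop2"),
             as.numeric(cv$ethnicity == "pop3"),
             as.numeric(cv$handedness == "R"),
             b$phenotypes$volume.global,
             g = b$genotypes$dosages[, "snp01"])
  orc <- oracle_ols(b$phenotypes$volume.lh.SMG, X, ncol(X))
  expect_equal(fit$beta, orc$beta, tolerance = 1e-8)
  expect_equal(fit$se, orc$se, tolerance = 1e-8)
  expect_equal(fit$t_stat, unname(orc$t), tolerance = 1e-8)
  expect_equal(fit$chi2, unname(orc$chi2), tolerance = 1e-8)
})

test_that("chi2 equals t-squared for every fitted pair", {
  b <- make_assoc_bundle(n = 60, beta = 0.5, seed = 5)
  spec <- assoc_model_spec("volume")
  scan <- pairwise_scan(b$phenotypes, b$genotypes, b$covariates, spec)
  expect_true(all(abs(scan$chi2 - scan$t_stat^2) <=
                    1e-10 * pmax(scan$chi2, 1)))
})

test_that("rank-deficient designs error naming the collinear columns", {
  b <- make_assoc_bundle(n = 30, seed = 6)
  b$covariates$dup <- b$covariates$age
  spec <- assoc_model_spec("volume",
                           covariates = c(age = "continuous",
                                          dup = "continuous"))
  expect_error(fit_snp_roi(b$phenotypes, b$genotypes, b$covariates, spec,
                           "snp01", "lh.SMG"), "collinear")
})

test_that("aggregate_x2 sums per-ROI chi-squares and checks coverage", {
  res <- data.frame(snp = "s", roi = c("a", "b", "c"),
                    chi2 = c(1.0, 2.5, 0.5))
  expect_equal(aggregate_x2(res), 4.0)
  expect_equal(aggregate_x2(res[1, ]), 1.0)
  expect_error(aggregate_x2(res, roi_set = c("a", "b", "c", "d")), "d")

  # under the null the aggregate over 5 ROIs has mean ~ 5 (sum of five
  # 1-df chi-squares)
  x2s <- vapply(1:200, function(i) {
    cfg <- sim_config(n_subjects = 40, n_snps = 1, seed = 80000 + i)
    g <- simulate_genotypes(cfg)
    tab <- simulate_roi_phenotypes(g, cfg, traits = "volume")
    spec <- assoc_model_spec("volume")
    scan <- pairwise_scan(tab$phenotypes, g, tab$covariates, spec)
    aggregate_x2(scan)
  }, numeric(1))
  se <- sd(x2s) / sqrt(length(x2s))
  expect_lt(abs(mean(x2s) - 5), 3 * se)
})

test_that("an observed statistic above every replicate gets the add-one minimum", {
  b <- make_assoc_bundle(n = 80, beta = 8, noise_sd = 0.5, seed = 7)
  spec <- assoc_model_spec("volume", roi_set = "lh.SMG")
  pt <- permutation_test(b$phenotypes, b$genotypes, b$covariates, spec,
                         snps = "snp01", n_perm = 400, seed = 1)
  expect_equal(pt$p_perm, 1 / 401)
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration at n = 6", {
  # n = 6 subjects, a minimal intercept-only nuisance design
  for (i in 1:5) {
    set.seed(300 + i)
    d <- matrix(c(0, 1, 2, sample(0:2, 3, replace = TRUE)), ncol = 1)
    g <- genotype_matrix(d, subject_ids = paste0("S", 1:6))
    ph <- data.frame(subject = paste0("S", 1:6),
                     volume.roi1 = rnorm(6), volume.global = rnorm(6))
    cv <- data.frame(subject = paste0("S", 1:6))
    spec <- assoc_model_spec("volume", roi_set = "roi1",
                             covariates = character(0))
    ex <- permutation_test(ph, g, cv, spec, snps = "snp1",
                           exhaustive = TRUE)
    mc <- permutation_test(ph, g, cv, spec, snps = "snp1",
                           n_perm = 4000, seed = 500 + i)
    se_mc <- sqrt(ex$p_perm * (1 - ex$p_perm) / 4000)
    expect_lt(abs(mc$p_perm - ex$p_perm), 2 * se_mc + 1 / 4001)
  }
})

test_that("permutation p is invariant to the subject ordering of the inputs", {
  b <- make_assoc_bundle(n = 40, beta = 1, seed = 8)
  spec <- assoc_model_spec("volume")
  p1 <- permutation_test(b$phenotypes, b$genotypes, b$covariates, spec,
                         snps = "snp01", n_perm = 200, seed = 11)$p_perm
  ord <- sample(nrow(b$phenotypes))
  p2 <- permutation_test(b$phenotypes[ord, ], b$genotypes,
                         b$covariates[rev(seq_len(nrow(b$covariates))), ],
                         spec, snps = "snp01", n_perm = 200, seed = 11)$p_perm
  expect_identical(p1, p2)
})

test_that("max-T family-wise p is never below the per-SNP p", {
  b <- make_assoc_bundle(n = 50, beta = 1, seed = 9)
  spec <- assoc_model_spec("volume")
  per <- permutation_test(b$phenotypes, b$genotypes, b$covariates, spec,
                          n_perm = 300, seed = 2, correction_mode = "per_snp")
  maxt <- permutation_test(b$phenotypes, b$genotypes, b$covariates, spec,
                           n_perm = 300, seed = 2,
                           correction_mode = "max_t_snps")
  expect_true(all(maxt$p_perm >= per$p_perm - 1e-12))

  # pair-level max-T never anti-conservative relative to nominal
  pairs <- pairwise_scan(b$phenotypes, b$genotypes, b$covariates, spec)
  mt <- permutation_test(b$phenotypes, b$genotypes, b$covariates, spec,
                         n_perm = 300, seed = 2,
                         correction_mode = "max_t_snp_roi")
  key <- paste(pairs$snp, pairs$roi)
  mkey <- paste(mt$snp, mt$roi)
  expect_true(all(mt$p_perm >= pairs$p_nominal[match(mkey, key)] - 1e-12))
})

test_that("permutation test rejects invalid arguments", {
  b <- make_assoc_bundle(n = 20, seed = 10)
  spec <- assoc_model_spec("volume")
  expect_error(permutation_test(b$phenotypes, b$genotypes, b$covariates,
                                spec, n_perm = 50), "n_perm")
  expect_error(permutation_test(b$phenotypes, b$genotypes, b$covariates,
                                spec, n_perm = 200,
                                correction_mode = "bogus"))
})

test_that("missing genotypes travel with the permuted vector", {
  b <- make_assoc_bundle(n = 40, beta = 2, seed = 12)
  b$genotypes$dosages[c(3, 17), "snp01"] <- NA
  spec <- assoc_model_spec("volume", roi_set = "lh.SMG")
  pt <- permutation_test(b$phenotypes, b$genotypes, b$covariates, spec,
                         snps = "snp01", n_perm = 100, seed = 3)
  expect_true(is.finite(pt$p_perm))
  fit <- fit_snp_roi(b$phenotypes, b$genotypes, b$covariates, spec,
                     "snp01", "lh.SMG")
  expect_equal(fit$n_used, 38)
})

test_that("pairwise_scan covers the grid and isolates degenerate columns", {
  b <- make_assoc_bundle(n = 50, beta = 3, noise_sd = 0.3, seed = 13)
  spec <- assoc_model_spec("volume")
  scan <- pairwise_scan(b$phenotypes, b$genotypes, b$covariates, spec)
  expect_equal(nrow(scan), length(spec$roi_set) * 2)

  # planted effect on lh.SMG attains the minimum nominal p for its SNP
  top <- scan[which.min(scan$p_nominal), ]
  expect_equal(top$roi, "lh.SMG")
  expect_equal(top$snp, "snp01")

  # zero-variance ROI handled as NA with reason, other pairs unaffected
  b$phenotypes$volume.CC <- 1.0
  scan2 <- pairwise_scan(b$phenotypes, b$genotypes, b$covariates, spec)
  cc <- scan2[scan2$roi == "CC", ]
  expect_equal(nrow(scan2), nrow(scan))
  expect_true(all(is.na(cc$p_nominal)))
  expect_match(cc$reason, "zero-variance")
  expect_true(all(is.finite(scan2$p_nominal[scan2$roi != "CC"])))
})

test_that("adjusted genotype-class means are linear in dosage when the model is", {
  b <- make_assoc_bundle(n = 120, beta = 3, noise_sd = 1e-9, seed = 14)
  spec <- assoc_model_spec("volume")
  tr <- genotype_trend_summary(b$phenotypes, b$genotypes, b$covariates,
                               spec, "snp01", "lh.SMG")
  expect_equal(diff(tr$adj_mean), c(3, 3), tolerance = 1e-4)

  # under beta = 0 the class means agree within 2 SE
  b0 <- make_assoc_bundle(n = 120, beta = 0, seed = 15)
  tr0 <- genotype_trend_summary(b0$phenotypes, b0$genotypes,
                                b0$covariates, spec, "snp01", "lh.SMG")
  gaps <- abs(diff(tr0$adj_mean))
  ses <- sqrt(tr0$se[-3]^2 + tr0$se[-1]^2)
  expect_true(all(gaps < 2.5 * ses))

  # an absent dosage class is reported as NA
  bmiss <- make_assoc_bundle(n = 60, seed = 16)
  bmiss$genotypes$dosages[bmiss$genotypes$dosages[, "snp01"] == 2,
                          "snp01"] <- 1
  trm <- genotype_trend_summary(bmiss$phenotypes, bmiss$genotypes,
                                bmiss$covariates, spec, "snp01", "lh.SMG")
  expect_true(is.na(trm$adj_mean[3]))
  expect_equal(sum(!is.na(trm$adj_mean)), 2)
})

test_that("the validation-cohort model variant is purely a spec change", {
  b <- make_assoc_bundle(n = 60, beta = 1, seed = 17)
  vspec <- assoc_model_spec(
    "volume",
    covariates = c(age = "continuous", sex = "categorical",
                   ethnicity = "categorical", scanner = "categorical"))
  fit <- fit_snp_roi(b$phenotypes, b$genotypes, b$covariates, vspec,
                     "snp01", "lh.SMG")
  expect_true(is.finite(fit$p_nominal))
  # handedness no longer in the design: removing the column is harmless
  cv <- b$covariates; cv$handedness <- NULL
  fit2 <- fit_snp_roi(b$phenotypes, b$genotypes, cv, vspec,
                      "snp01", "lh.SMG")
  expect_equal(fit$beta, fit2$beta)
})

test_that("surface-area and thickness specs exclude volume-only ROIs", {
  expect_error(assoc_model_spec("surface_area", roi_set = c("CC", "lh.SMG")),
               "volume-only")
  expect_setequal(assoc_model_spec("surface_area")$roi_set,
                  c("lh.insula", "rh.ACC", "lh.SMG"))
})

test_that("Bonferroni over endpoints multiplies and caps", {
  expect_equal(bonferroni_correct(0.01, 3), 0.03)
  expect_equal(bonferroni_correct(0.5, 3), 1)
  expect_equal(bonferroni_correct(c(0.2, 1e-4), 3), c(0.6, 3e-4))
})

test_that("freedman-lane residual permutation gives a comparable p", {
  b <- make_assoc_bundle(n = 50, beta = 2, noise_sd = 1, seed = 18)
  spec <- assoc_model_spec("volume", roi_set = "lh.SMG")
  p_g <- permutation_test(b$phenotypes, b$genotypes, b$covariates, spec,
                          snps = "snp01", n_perm = 300, seed = 4)$p_perm
  p_fl <- permutation_test(b$phenotypes, b$genotypes, b$covariates, spec,
                           snps = "snp01", n_perm = 300, seed = 4,
                           scheme = "freedman_lane")$p_perm
  expect_lt(abs(p_g - p_fl), 0.1)
})
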