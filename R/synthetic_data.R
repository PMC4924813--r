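#' Simulation configuration for genotypes, covariates and ROI phenotypes
#'
#' Describes a synthetic cohort: sample size, SNP panel with LD block
#' structure, planted per-allele effects on named ROIs, covariate slopes,
#' and residual noise. The defaults emulate a discovery-style cohort of
#' 100 unrelated subjects typed at a panel of common tag-SNPs.
#'
#' LD is induced by a Gaussian copula: within a block, haplotype latent
#' variables share pairwise correlation `within_block_r` and are
#' thresholded at the allele-frequency quantile; across blocks haplotypes
#' are independent. Haplotypes are paired at random, so Hardy-Weinberg
#' proportions hold in expectation.
#'
#' @param n_subjects number of subjects (>= 10).
#' @param n_snps number of SNPs; must equal `sum(ld_block_sizes)`.
#' @param maf_range length-2 numeric, minor allele frequency bounds in
#'   (0, 0.5\]; per-SNP MAFs are drawn uniformly from this interval.
#' @param ld_block_sizes integer vector of block sizes summing to `n_snps`.
#' @param within_block_r target latent haplotype correlation in \[0, 1\].
#' @param effect_map data frame with columns `snp` (index or id), `roi`,
#'   `trait`, `beta` — planted additive per-allele effects in trait units.
#' @param covariate_effects named numeric vector of slopes for the
#'   generated covariates (`age`, `sex`, `ethnicity`, `handedness`,
#'   `global`); unnamed covariates default to 0.
#' @param noise_sd residual standard deviation in trait units (> 0).
#' @param missing_rate fraction of genotype calls set missing in a
#'   post-step (default 0, so QC tests control missingness exactly).
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 100,
                       n_snps = 10,
                       maf_range = c(0.15, 0.5),
                       ld_block_sizes = NULL,
                       within_block_r = 0.8,
                       effect_map = NULL,
                       covariate_effects = c(age = 0, sex = 0,
                                             ethnicity = 0, handedness = 0,
                                             global = 0),
                       noise_sd = 1,
                       missing_rate = 0,
                       seed = 1L) {
  if (is.null(ld_block_sizes)) ld_block_sizes <- rep(1L, n_snps)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range),
              ld_block_sizes = as.integer(ld_block_sizes),
              within_block_r = within_block_r,
              effect_map = effect_map,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 10) stop("invalid n_subjects: must be >= 10")
  if (length(cfg$maf_range) != 2 ||
      any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("invalid maf_range: must be within (0, 0.5]")
  }
  if (sum(cfg$ld_block_sizes) != cfg$n_snps) {
    stop("invalid ld_block_sizes: must sum to n_snps")
  }
  if (cfg$within_block_r < 0 || cfg$within_block_r > 1) {
    stop("invalid within_block_r: must be in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop("invalid noise_sd: must be > 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("invalid missing_rate: must be in [0, 1)")
  }
  invisible(cfg)
}

# Draw n haplotypes for one LD block via a Gaussian copula with
# exchangeable correlation r, thresholded at the MAF quantile.
.block_haplotypes <- function(n_hap, mafs, r) {
  b <- length(mafs)
  z_shared <- stats::rnorm(n_hap)
  z_own <- matrix(stats::rnorm(n_hap * b), n_hap, b)
  lat <- sqrt(r) * z_shared + sqrt(1 - r) * z_own
  # allele = 1 (minor) when the latent falls below the MAF quantile
  sweep(lat, 2, stats::qnorm(mafs), "<") + 0L
}

#' Simulate a genotype matrix with block LD structure
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with attribute `mafs` giving the
#'   configured per-SNP minor allele frequencies.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  mafs <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  blocks <- rep(seq_along(config$ld_block_sizes), config$ld_block_sizes)
  hap1 <- matrix(0L, n, config$n_snps)
  hap2 <- matrix(0L, n, config$n_snps)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    hap1[, idx] <- .block_haplotypes(n, mafs[idx], config$within_block_r)
    hap2[, idx] <- .block_haplotypes(n, mafs[idx], config$within_block_r)
  }
  dos <- hap1 + hap2
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(dos)) < config$missing_rate,
                   nrow(dos), ncol(dos))
    dos[miss] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  pair <- t(replicate(config$n_snps, sample(bases, 2)))
  gm <- genotype_matrix(
    dos,
    subject_ids = sprintf("S%03d", seq_len(n)),
    snp_ids = sprintf("snp%02d", seq_len(config$n_snps)),
    allele_labels = data.frame(snp = sprintf("snp%02d", seq_len(config$n_snps)),
                               major = pair[, 1], minor = pair[, 2],
                               stringsAsFactors = FALSE))
  attr(gm, "mafs") <- mafs
  gm
}

.default_roi_sets <- list(
  volume = c("lh.insula", "rh.ACC", "CC", "lh.tempWM", "lh.SMG"),
  surface_area = c("lh.insula", "rh.ACC", "lh.SMG"),
  thickness = c("lh.insula", "rh.ACC", "lh.SMG")
)

#' Default ROI set for a trait
#'
#' Volume includes the corpus callosum and left temporal white matter;
#' surface area and thickness are cortical-only, so those two ROIs are
#' excluded for them.
#'
#' @param trait one of `"volume"`, `"surface_area"`, `"thickness"`.
#' @return character vector of ROI names.
#' @export
default_roi_set <- function(trait = c("volume", "surface_area", "thickness")) {
  trait <- match.arg(trait)
  .default_roi_sets[[trait]]
}

#' Simulate covariates and ROI phenotypes given genotypes
#'
#' Each ROI trait is built as intercept + planted beta x dosage +
#' covariate slopes x covariates + Gaussian noise. Covariates are age
#' (continuous), sex / ethnicity / handedness (categorical, sampled
#' uniformly over 2-3 levels), scanner field strength (2 levels, for
#' validation-style model specifications) and a trait-matched global
#' measure (total brain volume, total surface area, or mean thickness).
#'
#' @param genotypes a [genotype_matrix()] with `config$n_subjects` rows.
#' @param config the [sim_config()] used for the genotypes; its
#'   `effect_map`, `covariate_effects`, `noise_sd` and `seed` fields drive
#'   this step. The phenotype stream is seeded at `seed + 1` so genotype
#'   and phenotype draws are reproducible separately.
#' @param traits traits to generate.
#' @return list with `phenotypes` (data frame, subject ID column 1, then
#'   `<trait>.<roi>` columns and `<trait>.global` columns) and
#'   `covariates` (data frame: subject, age, sex, ethnicity, handedness,
#'   scanner).
#' @export
simulate_roi_phenotypes <- function(genotypes, config,
                                    traits = c("volume", "surface_area",
                                               "thickness")) {
  validate_sim_config(config)
  n <- length(genotypes$subject_ids)
  if (n != config$n_subjects) {
    stop("genotype subject count does not match config$n_subjects")
  }
  em <- config$effect_map
  if (!is.null(em)) {
    stopifnot(all(c("snp", "roi", "trait", "beta") %in% names(em)))
    if (is.numeric(em$snp)) em$snp <- genotypes$snp_ids[em$snp]
    bad <- setdiff(em$snp, genotypes$snp_ids)
    if (length(bad)) stop("effect_map references unknown SNP: ",
                          paste(bad, collapse = ", "))
    all_rois <- unique(unlist(.default_roi_sets))
    bad_roi <- setdiff(em$roi, all_rois)
    if (length(bad_roi)) stop("effect_map references unknown ROI: ",
                              paste(bad_roi, collapse = ", "))
  }
  set.seed(config$seed + 1L)
  covs <- data.frame(
    subject = genotypes$subject_ids,
    age = round(stats::runif(n, 18, 65), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    ethnicity = sample(c("pop1", "pop2", "pop3"), n, replace = TRUE),
    handedness = sample(c("L", "R"), n, replace = TRUE, prob = c(0.1, 0.9)),
    scanner = sample(c("1.5T", "3T"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  ce <- config$covariate_effects
  slope <- function(nm) if (!is.null(ce) && nm %in% names(ce)) ce[[nm]] else 0
  phen <- data.frame(subject = genotypes$subject_ids,
                     stringsAsFactors = FALSE)
  for (trait in traits) {
    global <- stats::rnorm(n, mean = 100, sd = 10)
    phen[[paste0(trait, ".global")]] <- global
    base <- slope("age") * covs$age +
      slope("sex") * (covs$sex == "M") +
      slope("ethnicity") * (match(covs$ethnicity, c("pop1", "pop2", "pop3")) - 1) +
      slope("handedness") * (covs$handedness == "R") +
      slope("global") * global
    for (roi in .default_roi_sets[[trait]]) {
      y <- 50 + base + stats::rnorm(n, 0, config$noise_sd)
      if (!is.null(em)) {
        rows <- em[em$roi == roi & em$trait == trait, , drop = FALSE]
        for (k in seq_len(nrow(rows))) {
          dos <- genotypes$dosages[, rows$snp[k]]
          dos[is.na(dos)] <- 0  # planted effect only through observed calls
          y <- y + rows$beta[k] * dos
        }
      }
      phen[[paste0(trait, ".", roi)]] <- y
    }
  }
  list(phenotypes = phen, covariates = covs)
}

#' Configuration for the brain expression simulator
#'
#' Emulates a multi-region brain expression resource: each individual
#' contributes several regional samples of a target transcript whose
#' per-individual level carries a planted linear eQTL effect and a linear
#' dependence on a transcription factor's expression.
#'
#' @param n_individuals number of genotyped individuals (>= 10).
#' @param regions_per_individual samples (brain regions) per individual
#'   (>= 1).
#' @param eqtl_beta planted slope, expression units per minor allele.
#' @param tf_target_r target population Pearson correlation between TF and
#'   target expression, in \[-1, 1\].
#' @param noise_sd individual-level residual SD (> 0).
#' @param region_noise_sd SD of the region-level noise added around each
#'   individual's value (>= 0).
#' @param n_null_tfs additional independent TF probes with no relation to
#'   the target (for screening exercises).
#' @param seed integer seed.
#' @return an `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_individuals = 134,
                            regions_per_individual = 9,
                            eqtl_beta = 0.5,
                            tf_target_r = 0.6,
                            noise_sd = 1,
                            region_noise_sd = 0.5,
                            n_null_tfs = 0,
                            seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              regions_per_individual = as.integer(regions_per_individual),
              eqtl_beta = eqtl_beta,
              tf_target_r = tf_target_r,
              noise_sd = noise_sd,
              region_noise_sd = region_noise_sd,
              n_null_tfs = as.integer(n_null_tfs),
              seed = as.integer(seed))
  class(cfg) <- "expr_sim_config"
  if (cfg$n_individuals < 10) stop("invalid n_individuals: must be >= 10")
  if (cfg$regions_per_individual < 1) {
    stop("invalid regions_per_individual: must be >= 1")
  }
  if (abs(cfg$tf_target_r) > 1) stop("invalid tf_target_r: |r| must be <= 1")
  if (cfg$noise_sd <= 0) stop("invalid noise_sd: must be > 0")
  if (cfg$region_noise_sd < 0) stop("invalid region_noise_sd: must be >= 0")
  cfg
}

#' Simulate a multi-region brain expression matrix
#'
#' Per individual i with dosage d_i: TF_i ~ N(0, 1) and
#' target_i = 10 + eqtl_beta * d_i + lambda * TF_i + e_i, where lambda is
#' chosen so the population correlation between target and TF equals
#' `tf_target_r` given the dosage variance and `noise_sd`. Each regional
#' sample adds independent N(0, region_noise_sd^2) noise to the
#' individual's value.
#'
#' @param genotypes a [genotype_matrix()] with one row per individual; the
#'   first SNP column is the eQTL variant.
#' @param config an [expr_sim_config()].
#' @param snp SNP identifier for the planted eQTL (default: first SNP).
#' @return an [expression_matrix()] with probes `target`, `TF1`, and
#'   `nullTF*` if requested; attribute `lambda` records the TF slope used.
#' @export
simulate_expression <- function(genotypes, config,
                                snp = genotypes$snp_ids[1]) {
  n <- config$n_individuals
  if (length(genotypes$subject_ids) != n) {
    stop("genotype matrix must have one row per individual")
  }
  set.seed(config$seed + 2L)
  dos <- genotypes$dosages[, snp]
  dos_c <- dos; dos_c[is.na(dos_c)] <- mean(dos, na.rm = TRUE)
  var_d <- stats::var(dos_c)
  r <- config$tf_target_r
  v0 <- config$eqtl_beta^2 * var_d + config$noise_sd^2
  lambda <- if (abs(r) >= 1) {
    stop("tf_target_r must be strictly inside (-1, 1) for a finite TF slope")
  } else if (r == 0) 0 else sign(r) * sqrt(r^2 * v0 / (1 - r^2))
  tf <- stats::rnorm(n)
  target_ind <- 10 + config$eqtl_beta * dos_c + lambda * tf +
    stats::rnorm(n, 0, config$noise_sd)
  k <- config$regions_per_individual
  regions <- sprintf("region%02d", seq_len(k))
  sample_map <- data.frame(
    sample_id = as.vector(outer(regions, genotypes$subject_ids,
                                function(r, i) paste(i, r, sep = "_"))),
    individual_id = rep(genotypes$subject_ids, each = k),
    region = rep(regions, times = n),
    stringsAsFactors = FALSE
  )
  expand <- function(ind_values) {
    rep(ind_values, each = k) +
      stats::rnorm(n * k, 0, config$region_noise_sd)
  }
  vals <- cbind(target = expand(target_ind), TF1 = expand(tf))
  if (config$n_null_tfs > 0) {
    for (j in seq_len(config$n_null_tfs)) {
      vals <- cbind(vals, expand(stats::rnorm(n)))
      colnames(vals)[ncol(vals)] <- sprintf("nullTF%02d", j)
    }
  }
  rownames(vals) <- sample_map$sample_id
  em <- expression_matrix(vals, sample_map)
  attr(em, "lambda") <- lambda
  attr(em, "eqtl_snp") <- snp
  em
}

#' Simulate a PWM with controlled information content plus allele flanks
#'
#' Builds a motif of the requested length whose designated column has
#' information content within 0.05 bits of `target_ic`; the other columns
#' are high-information (near-consensus). Also returns a pair of 101-base
#' flank sequences (50 bases each side of the variant) in which the
#' motif's consensus is embedded across the variant position for one
#' allele (the consensus base at the designated column) while the other
#' allele carries a different base there.
#'
#' For a single-base column IC is 2 bits; a uniform column has 0 bits; a
#' 50/50 two-base column has 1 bit. Intermediate targets are met by a
#' two-base column (p, 1-p) solved numerically, so any target in \[0, 2\]
#' is reachable.
#'
#' @param length motif length (>= 4).
#' @param target_ic information content in bits for the variable-base
#'   column, in \[0, 2\].
#' @param seed integer seed.
#' @param variable_column which motif column sits over the variant
#'   (default: middle).
#' @return list with `pwm` (a [pwm()] with pseudocount 0), `context` (a
#'   [variant_context()]), and `variable_column`.
#' @export
simulate_pwm_and_flanks <- function(length = 8, target_ic = 1.0, seed = 1L,
                                    variable_column = ceiling(length / 2)) {
  if (length < 4) stop("length must be >= 4")
  if (target_ic < 0 || target_ic > 2) stop("target_ic must be in [0, 2]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, length, dimnames = list(bases, NULL))
  total <- 1000L
  for (j in seq_len(length)) {
    if (j == variable_column) next
    consensus <- sample(4, 1)
    col <- rep(0L, 4); col[consensus] <- total
    counts[, j] <- col
  }
  # variable column. Two families cover the full IC range [0, 2]:
  # a two-base (p, 1-p) column spans [1, 2] bits (p in [0.5, 1], with
  # IC = 2 + p log2 p + (1-p) log2(1-p)); a consensus/uniform mixture
  # p = (q + (1-q)/4, (1-q)/4, ...) spans [0, 2] and is used below 1 bit.
  vb <- sample(4, 2)  # vb[1]: preferred (consensus) base, vb[2]: alternate
  ent2 <- function(p) ifelse(p > 0, p * log2(p), 0)
  col <- rep(0, 4)
  if (target_ic >= 2 - 1e-9) {
    col[vb[1]] <- total
  } else if (target_ic <= 1e-9) {
    col <- rep(total / 4, 4)
  } else if (target_ic >= 1) {
    g <- function(p) 2 + ent2(p) + ent2(1 - p) - target_ic
    p <- if (abs(target_ic - 1) < 1e-9) 0.5 else
      stats::uniroot(g, c(0.5, 1 - 1e-9))$root
    col[vb[1]] <- round(total * p)
    col[vb[2]] <- total - round(total * p)
  } else {
    g <- function(q) {
      pc <- q + (1 - q) / 4; po <- (1 - q) / 4
      2 + ent2(pc) + 3 * ent2(po) - target_ic
    }
    q <- stats::uniroot(g, c(1e-9, 1 - 1e-9))$root
    pc <- q + (1 - q) / 4
    col[vb[1]] <- round(total * pc)
    col[-vb[1]] <- round(total * (1 - q) / 4)
  }
  counts[, variable_column] <- col
  motif <- pwm(name = sprintf("SIM%03d", seed), counts = counts,
               pseudocount = 0)
  consensus_seq <- apply(counts, 2, function(cl) bases[which.max(cl)])
  allele_hi <- bases[vb[1]]
  allele_lo <- bases[if (target_ic <= 1e-9) setdiff(1:4, vb[1])[1] else vb[2]]
  flank5 <- paste(sample(bases, 50, replace = TRUE), collapse = "")
  flank3 <- paste(sample(bases, 50, replace = TRUE), collapse = "")
  # embed consensus so that its variable column lands on the variant base
  left_in_motif <- variable_column - 1
  right_in_motif <- length - variable_column
  substr(flank5, 51 - left_in_motif, 50) <-
    paste(consensus_seq[seq_len(left_in_motif)], collapse = "")
  if (right_in_motif > 0) {
    substr(flank3, 1, right_in_motif) <-
      paste(consensus_seq[variable_column + seq_len(right_in_motif)],
            collapse = "")
  }
  ctx <- variant_context(variant_id = sprintf("var%03d", seed),
                         alleles = c(allele_hi, allele_lo),
                         flank_5p = flank5, flank_3p = flank3)
  list(pwm = motif, context = ctx, variable_column = variable_column)
}
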