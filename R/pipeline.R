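#' Pipeline configuration
#'
#' Bundles stage toggles, simulation settings and the analysis thresholds
#' used across the pipeline: the MAF floor for common-variant panels
#' (0.15), the tag-SNP r2 threshold (0.8), the motif relative-score match
#' threshold (0.8), the minimum information content at the variable base
#' (1 bit), and the significance level (0.05).
#'
#' @param stages character vector of stages to run, in order, from
#'   `simulate`, `qc`, `tag`, `assoc`, `assoc_validation`, `eqtl`,
#'   `tfscreen`, `tfscan`, `prioritize`.
#' @param seed integer seed (mandatory; every stochastic stage derives
#'   its stream from it).
#' @param n_perm permutation replicates for the association stage.
#' @param trait anatomical trait analysed in the association stages.
#' @param maf_min,r2_tag,match_threshold,ic_min,alpha,n_tests thresholds
#'   (see description; `n_tests` is the Bonferroni multiplier for the TF
#'   screen, default 127 for a motif-annotated human TF panel).
#' @param sim named list overriding [sim_config()] arguments.
#' @param expr_sim named list overriding [expr_sim_config()] arguments.
#' @param n_validation validation-cohort size (simulated separately with
#'   a scanner covariate in the model and handedness omitted).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(stages = c("simulate", "qc", "tag", "assoc",
                                       "assoc_validation", "eqtl",
                                       "tfscreen", "tfscan", "prioritize"),
                            seed = 1L,
                            n_perm = 1000L,
                            trait = "surface_area",
                            maf_min = 0.15, r2_tag = 0.8,
                            match_threshold = 0.8, ic_min = 1.0,
                            alpha = 0.05, n_tests = 127L,
                            sim = list(), expr_sim = list(),
                            n_validation = 400L) {
  known <- c("simulate", "qc", "tag", "assoc", "assoc_validation", "eqtl",
             "tfscreen", "tfscan", "prioritize")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- list(stages = stages, seed = as.integer(seed),
              n_perm = as.integer(n_perm), trait = trait,
              maf_min = maf_min, r2_tag = r2_tag,
              match_threshold = match_threshold, ic_min = ic_min,
              alpha = alpha, n_tests = as.integer(n_tests),
              sim = sim, expr_sim = expr_sim,
              n_validation = as.integer(n_validation))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  chk01 <- function(x, nm, lo = 0, hi = 1) {
    if (x <= lo || x > hi) stop(sprintf("%s must be in (%g, %g]", nm, lo, hi))
  }
  chk01(cfg$r2_tag, "r2_tag"); chk01(cfg$match_threshold, "match_threshold")
  chk01(cfg$alpha, "alpha")
  if (cfg$maf_min < 0 || cfg$maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (cfg$ic_min < 0 || cfg$ic_min > 2) stop("ic_min must be in [0, 2]")
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop("seed is mandatory when stochastic stages are enabled")
  }
  deps <- list(qc = "simulate", tag = "qc", assoc = "qc",
               assoc_validation = "assoc", eqtl = "simulate",
               tfscreen = "simulate", tfscan = "simulate",
               prioritize = c("eqtl", "tfscreen", "tfscan"))
  for (st in cfg$stages) {
    need <- deps[[st]]
    missing <- setdiff(need, cfg$stages)
    if (length(missing)) {
      stop(sprintf("stage '%s' requires stage(s): %s",
                   st, paste(missing, collapse = ", ")))
    }
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips byte-identically: writing a configuration read from disk
#' reproduces the file.
#'
#' @param path YAML file.
#' @return for `read_pipeline_config`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in order — simulate, genotype QC, tag-SNP
#' selection, discovery association with the aggregate permutation test,
#' a validation-style refit of the top pairs (scanner covariate in,
#' handedness out), eQTL regression on averaged expression, TF-target
#' correlation screening, allele-specific motif scanning, and
#' logical-consistency prioritization. Each stage reads only prior-stage
#' outputs; a failure halts with an error naming the stage. Rerunning
#' with the same configuration and seed reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); every stage
#'   writes its TSV outputs there.
#' @return invisibly, a manifest list: configuration echo, package
#'   version, per-stage outputs, row counts and timings, and the master
#'   seed. Also written to `manifest.yaml` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("neuroqtl_run_")) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   version = as.character(utils::packageVersion("neuroqtl")),
                   seed = config$seed, stages = list())
  env <- new.env()
  note <- function(stage, files, n) {
    manifest$stages[[stage]] <<- list(outputs = basename(files), n = n,
                                      elapsed_s = round(as.numeric(
                                        proc.time()["elapsed"] - env$t0), 3))
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    env$t0 <- proc.time()["elapsed"]
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
    env$scfg <- do.call(sim_config, sim_args)
    env$genotypes <- simulate_genotypes(env$scfg)
    tab <- simulate_roi_phenotypes(env$genotypes, env$scfg)
    env$phenotypes <- tab$phenotypes
    env$covariates <- tab$covariates
    e_args <- utils::modifyList(list(seed = config$seed), config$expr_sim)
    env$ecfg <- do.call(expr_sim_config, e_args)
    egeno_cfg <- sim_config(n_subjects = env$ecfg$n_individuals, n_snps = 1,
                            maf_range = env$scfg$maf_range,
                            seed = config$seed + 7L)
    env$expr_genotypes <- simulate_genotypes(egeno_cfg)
    env$expr <- simulate_expression(env$expr_genotypes, env$ecfg)
    pf <- simulate_pwm_and_flanks(length = 8, target_ic = 2,
                                  seed = config$seed + 11L)
    # align the motif's preferred allele with the increased-expression
    # allele of the eQTL variant so the planted candidate is retainable
    env$motif <- pf$pwm
    env$context <- pf$context
    files <- file.path(out_dir, c("genotypes.tsv", "genotypes.vcf",
                                  "phenotypes.tsv", "covariates.tsv",
                                  "expression.tsv", "sample_map.tsv",
                                  "motif.pfm", "flanks.fasta"))
    write_dosage_tsv(env$genotypes, files[1])
    write_genotypes_vcf(env$genotypes, files[2])
    write_tsv_table(env$phenotypes, files[3])
    write_tsv_table(env$covariates, files[4])
    write_expression_tsv(env$expr, files[5], files[6])
    write_jaspar_pfm(env$motif, files[7])
    write_flanks_fasta(env$context, files[8])
    note("simulate", files, nrow(env$phenotypes))
  })

  run_stage("qc", function() {
    env$qc <- qc_report(env$genotypes, maf_min = config$maf_min)
    f <- file.path(out_dir, "qc_report.tsv")
    write_tsv_table(env$qc, f)
    env$pass_snps <- env$qc$snp[env$qc$pass]
    if (!length(env$pass_snps)) stop("no SNPs pass QC")
    note("qc", f, nrow(env$qc))
  })

  run_stage("tag", function() {
    gm_pass <- genotype_matrix(
      env$genotypes$dosages[, env$pass_snps, drop = FALSE],
      subject_ids = env$genotypes$subject_ids,
      snp_ids = env$pass_snps,
      allele_labels = env$genotypes$allele_labels[
        env$genotypes$allele_labels$snp %in% env$pass_snps, ])
    env$ld <- ld_matrix(gm_pass)
    env$tagging <- greedy_tag_selection(env$ld, threshold = config$r2_tag)
    f <- file.path(out_dir, "tags.tsv")
    write_tsv_table(env$tagging$coverage, f)
    note("tag", f, length(env$tagging$tags))
  })

  run_stage("assoc", function() {
    env$spec <- assoc_model_spec(trait = config$trait)
    snps <- if (!is.null(env$tagging)) env$tagging$tags else env$pass_snps
    env$assoc <- permutation_test(env$phenotypes, env$genotypes,
                                  env$covariates, env$spec,
                                  snps = snps, n_perm = config$n_perm,
                                  seed = config$seed,
                                  correction_mode = "per_snp")
    env$pairs <- pairwise_scan(env$phenotypes, env$genotypes,
                               env$covariates, env$spec, snp_list = snps)
    f <- file.path(out_dir, c("assoc_aggregate.tsv", "assoc_pairwise.tsv"))
    write_tsv_table(env$assoc, f[1])
    write_tsv_table(env$pairs, f[2])
    env$top_snp <- env$assoc$snp[which.max(env$assoc$x2_obs)]
    note("assoc", f, nrow(env$assoc))
  })

  run_stage("assoc_validation", function() {
    vcfg <- do.call(sim_config, utils::modifyList(
      utils::modifyList(list(seed = config$seed + 1000L), config$sim),
      list(n_subjects = config$n_validation)))
    vgeno <- simulate_genotypes(vcfg)
    vtab <- simulate_roi_phenotypes(vgeno, vcfg)
    vspec <- assoc_model_spec(
      trait = config$trait,
      covariates = c(age = "continuous", sex = "categorical",
                     ethnicity = "categorical", scanner = "categorical"))
    env$validation <- pairwise_scan(vtab$phenotypes, vgeno,
                                    vtab$covariates, vspec,
                                    snp_list = env$top_snp)
    f <- file.path(out_dir, "assoc_validation.tsv")
    write_tsv_table(env$validation, f)
    note("assoc_validation", f, nrow(env$validation))
  })

  run_stage("eqtl", function() {
    avg <- average_by_individual(env$expr, "target")
    env$eqtl <- fit_eqtl(avg, env$expr_genotypes,
                         snp = env$expr_genotypes$snp_ids[1],
                         probe = "target")
    f <- file.path(out_dir, "eqtl.tsv")
    write_tsv_table(env$eqtl, f)
    note("eqtl", f, nrow(env$eqtl))
  })

  run_stage("tfscreen", function() {
    tf_probes <- setdiff(env$expr$probe_ids, "target")
    env$screen <- tf_correlation_screen(env$expr, tf_probes, "target",
                                        n_tests = config$n_tests)
    f <- file.path(out_dir, "tfscreen.tsv")
    write_tsv_table(env$screen, f)
    note("tfscreen", f, nrow(env$screen))
  })

  run_stage("tfscan", function() {
    env$db <- differential_binding(env$motif, env$context,
                                   threshold = config$match_threshold,
                                   ic_min = config$ic_min)
    f <- file.path(out_dir, "tfscan.tsv")
    write_tsv_table(env$db$calls, f)
    note("tfscan", f, nrow(env$db$calls))
  })

  run_stage("prioritize", function() {
    scr <- env$screen[env$screen$tf == "TF1", ]
    sign <- if (!nrow(scr) || is.na(scr$r)) "+" else
      if (scr$r >= 0) "+" else "-"
    # increased-expression allele of the scanned variant: the motif's
    # consensus allele when the eQTL slope is positive for the minor
    # allele is a modelling convention of the synthetic bundle; here the
    # scanned variant's allele labelled first plays that role
    inc <- env$context$alleles[if (env$eqtl$slope >= 0) 1 else 2]
    env$priority <- prioritize_tf(
      tf_name = "TF1", correlation_sign = sign,
      increased_expression_allele = inc,
      higher_affinity_allele = env$db$higher_affinity_allele,
      fold_affinity = env$db$fold_affinity,
      differential = env$db$differential)
    f <- file.path(out_dir, "prioritized_tfs.tsv")
    write_tsv_table(env$priority, f)
    note("prioritize", f, nrow(env$priority))
  })

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest$out_dir <- out_dir
  invisible(manifest)
}

#' Validate an input file bundle
#'
#' Report-only checks: file existence, header presence, dosage values in
#' 0/1/2, and subject-ID set comparisons across the genotype, covariate
#' and phenotype tables. Never throws; every finding is a report row.
#'
#' @param paths named list/vector with any of `genotypes` (dosage TSV),
#'   `covariates`, `phenotypes` (TSVs with subject ID in column 1).
#' @return data frame: `file`, `check`, `status` (`pass`/`warn`/`fail`),
#'   `detail`.
#' @export
validate_inputs <- function(paths) {
  rows <- list()
  add <- function(file, check, status, detail = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      file = file, check = check, status = status, detail = detail,
      stringsAsFactors = FALSE)
  }
  tabs <- list()
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!file.exists(p)) { add(nm, "exists", "fail", p); next }
    add(nm, "exists", "pass")
    df <- tryCatch(utils::read.table(p, header = TRUE, sep = "\t",
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) { add(nm, "readable", "fail", "cannot parse TSV"); next }
    add(nm, "readable", "pass",
        sprintf("%d rows x %d cols", nrow(df), ncol(df)))
    if (any(!nzchar(names(df)))) {
      add(nm, "header", "fail", "unnamed column")
    } else add(nm, "header", "pass")
    tabs[[nm]] <- df
    if (nm == "genotypes") {
      m <- as.matrix(df[, -1, drop = FALSE])
      bad <- which(!(is.na(m) | m %in% 0:2), arr.ind = TRUE)
      if (nrow(bad)) {
        add(nm, "dosage_values", "fail",
            sprintf("invalid dosage at row %d, column '%s'",
                    bad[1, 1], colnames(m)[bad[1, 2]]))
      } else add(nm, "dosage_values", "pass")
    }
  }
  nms <- names(tabs)
  if (length(nms) > 1) {
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq(i + 1, length(nms))) {
        a <- tabs[[nms[i]]][[1]]; b <- tabs[[nms[j]]][[1]]
        only_a <- setdiff(a, b); only_b <- setdiff(b, a)
        if (length(only_a) || length(only_b)) {
          add(paste(nms[i], nms[j], sep = "~"), "subject_ids", "warn",
              sprintf("only in %s: %s%s", nms[i],
                      paste(utils::head(only_a, 5), collapse = ","),
                      if (length(only_b))
                        sprintf("; only in %s: %s", nms[j],
                                paste(utils::head(only_b, 5), collapse = ","))
                      else ""))
        } else add(paste(nms[i], nms[j], sep = "~"), "subject_ids", "pass")
      }
    }
  }
  do.call(rbind, rows)
}
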