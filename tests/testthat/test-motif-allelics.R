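toy_counts <- function() {
  m <- matrix(c(8, 2, 0, 0,
                0, 10, 0, 0,
                5, 5, 0, 0), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}

test_that("JASPAR PFM parsing is exact and order-normalizing", {
  txt <- c(">MA0001.1 TOY",
           "A [ 8 0 5 ]",
           "C [ 2 10 5 ]",
           "G [ 0 0 0 ]",
           "T [ 0 0 0 ]")
  p <- parse_jaspar_pfm(txt, pseudocount = 0)
  expect_equal(unname(p$counts), unname(toy_counts()))
  expect_equal(p$name, "MA0001.1")

  # rows in T,G,C,A order parse to the same matrix
  txt2 <- c(">MA0001.1 TOY", "T [ 0 0 0 ]", "G [ 0 0 0 ]",
            "C [ 2 10 5 ]", "A [ 8 0 5 ]")
  expect_equal(parse_jaspar_pfm(txt2, pseudocount = 0)$counts, p$counts)

  # bracket-free rows are accepted
  txt3 <- c(">M1", "A 1 2", "C 3 4", "G 5 6", "T 7 8")
  expect_equal(parse_jaspar_pfm(txt3)$counts[, 2], c(A = 2, C = 4, G = 6, T = 8))

  # round trip write -> parse
  rt <- parse_jaspar_pfm(write_jaspar_pfm(p), pseudocount = 0)
  expect_equal(rt$counts, p$counts)
  expect_equal(rt$name, p$name)

  # errors carry diagnostics
  expect_error(parse_jaspar_pfm(c(">M", "A 1 2", "C 3 4", "G 5 6")),
               "missing base row")
  expect_error(parse_jaspar_pfm(c(">M", "A 1 2", "C 3", "G 5 6", "T 1 1")),
               "ragged")
  expect_error(parse_jaspar_pfm(c(">M", "A 1 -2", "C 3 4", "G 5 6", "T 1 1")),
               "negative")
  expect_error(parse_jaspar_pfm(c("A 1 2")), "header")
})

test_that("relative score is min-max normalized log-odds", {
  p <- pwm("toy", toy_counts(), pseudocount = 0)
  # consensus attains exactly 1, anti-consensus exactly 0
  expect_equal(relative_score(p, "ACA"), 1.0)
  expect_equal(relative_score(p, "CCC"), 0.0)
  # hand-computed: lo col1 = log2(3.2), log2(0.8); col2 C = 2; col3 = 1,1
  # S("ACA") = log2(3.2)+2+1; Smin = log2(0.8)+2+1; Smax = log2(3.2)+2+1
  s <- log2(3.2) + 2 + 1; smin <- log2(0.8) + 2 + 1; smax <- s
  expect_equal(relative_score(p, "ACA"), (s - smin) / (smax - smin))
  # a window with a zero-probability base scores 0
  expect_equal(relative_score(p, "AGA"), 0)
  expect_error(relative_score(p, "ANA"), "non-ACGT")
  expect_error(relative_score(p, "AC"), "length")
})

test_that("column information content hits the canonical values", {
  uni <- pwm("u", matrix(25, 4, 1, dimnames = list(c("A","C","G","T"), NULL)),
             pseudocount = 0)
  expect_equal(column_ic(uni, 1), 0)
  single <- pwm("s", matrix(c(100, 0, 0, 0), 4, 1,
                            dimnames = list(c("A","C","G","T"), NULL)),
                pseudocount = 0)
  expect_equal(column_ic(single, 1), 2)
  half <- pwm("h", matrix(c(50, 50, 0, 0), 4, 1,
                          dimnames = list(c("A","C","G","T"), NULL)),
              pseudocount = 0)
  expect_equal(column_ic(half, 1), 1)
  expect_error(column_ic(half, 2), "out of range")
})

test_that("increasing the pseudocount never raises IC of a non-uniform column", {
  set.seed(31)
  for (i in 1:20) {
    cnt <- matrix(rpois(4, 20) + c(30, 0, 0, 0), 4, 1,
                  dimnames = list(c("A","C","G","T"), NULL))
    ics <- vapply(c(0, 0.5, 1, 2, 5, 20), function(pc)
      column_ic(pwm("x", cnt, pseudocount = pc), 1), numeric(1))
    expect_true(all(diff(ics) <= 1e-12))
  }
})

test_that("reverse-strand score equals forward score of the reverse complement", {
  pf <- simulate_pwm_and_flanks(length = 7, target_ic = 1.5, seed = 44)
  ctx <- pf$context
  al <- ctx$alleles[1]
  got <- scan_allele(pf$pwm, ctx, al, strands = "-")
  # independent check: score every variant-overlapping window's reverse
  # complement on the forward strand and take the maximum
  seqc <- allele_sequence(ctx, al)
  L <- pwm_length(pf$pwm)
  starts <- (50 - L + 1):50
  scores <- vapply(starts, function(s) {
    w <- substr(seqc, s + 1, s + L)
    relative_score(pf$pwm, oracle_revcomp(w))
  }, numeric(1))
  expect_equal(got$best_relative_score, max(scores), tolerance = 1e-12)
  expect_equal(got$best_offset, starts[which.max(scores)])
})

test_that("scan_allele matches exhaustive enumeration over windows and strands", {
  set.seed(23)
  for (i in 1:15) {
    pf <- simulate_pwm_and_flanks(length = sample(5:9, 1),
                                  target_ic = runif(1, 0.5, 2),
                                  seed = 4000 + i)
    ctx <- pf$context
    for (al in ctx$alleles) {
      got <- scan_allele(pf$pwm, ctx, al)
      seqc <- allele_sequence(ctx, al)
      orc <- oracle_best_window(pf$pwm$counts, pf$pwm$pseudocount,
                                pf$pwm$background, seqc, 50, 50)
      expect_equal(got$best_relative_score, orc$score, tolerance = 1e-12)
      expect_equal(got$best_offset, orc$offset)
      expect_equal(got$strand, orc$strand)
    }
  }
})

test_that("match threshold semantics are respected", {
  pf <- simulate_pwm_and_flanks(length = 8, target_ic = 2, seed = 12)
  hi <- scan_allele(pf$pwm, pf$context, pf$context$alleles[1],
                    threshold = 0.8)
  expect_true(hi$is_match)
  none <- scan_allele(pf$pwm, pf$context, pf$context$alleles[1],
                      threshold = 1.01)
  expect_false(none$is_match)
})

test_that("differential binding needs both a match and an informative column", {
  # high-IC column at the variant + matching consensus allele: flagged
  pf <- simulate_pwm_and_flanks(length = 8, target_ic = 2, seed = 21)
  db <- differential_binding(pf$pwm, pf$context)
  expect_true(db$differential)

  # same construction but a 0-bit (uniform) column at the variant
  pf0 <- simulate_pwm_and_flanks(length = 8, target_ic = 0, seed = 21)
  db0 <- differential_binding(pf0$pwm, pf0$context)
  expect_false(db0$differential)

  # no allele reaches the threshold: not differential regardless of IC
  pf2 <- simulate_pwm_and_flanks(length = 8, target_ic = 2, seed = 22)
  db2 <- differential_binding(pf2$pwm, pf2$context, threshold = 1.01)
  expect_false(db2$differential)
})

test_that("fold affinity is the pseudocounted column-probability ratio", {
  # column with T = 0.6, C = 0.05 at pseudocount 0 (counts 60 and 5 of 100)
  cnt1 <- matrix(c(30, 5, 5, 60), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm("f", cnt1, pseudocount = 0)
  expect_equal(fold_affinity(p, 1, "T", "C"), 12.0)
  expect_equal(fold_affinity(p, 1, "C", "T") * fold_affinity(p, 1, "T", "C"),
               1.0)
  # equal frequencies give 1
  cnt2 <- matrix(c(10, 10, 10, 10), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(fold_affinity(pwm("e", cnt2), 1, "A", "G"), 1.0)
  # zero probability with zero pseudocount: infinity sentinel + warning
  cnt3 <- matrix(c(10, 0, 10, 10), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_warning(f <- fold_affinity(pwm("z", cnt3, pseudocount = 0),
                                    1, "A", "C"), "infinite")
  expect_equal(f, Inf)
})

test_that("TF prioritization implements the consistency truth table", {
  # positive correlation, higher-affinity allele = increased-expression
  # allele: retained
  expect_equal(prioritize_tf("TFa", "+", "T", "T", 11.8, TRUE)$verdict,
               "retained")
  # negative correlation but binding the increased-expression allele:
  # inconsistent
  expect_equal(prioritize_tf("TFb", "-", "T", "T", 3, TRUE)$verdict,
               "inconsistent")
  # not differential: never genotype sensitive, regardless of signs
  for (sgn in c("+", "-")) for (hi in c("T", "C")) {
    expect_equal(prioritize_tf("TFc", sgn, "T", hi, 2, FALSE)$verdict,
                 "not_genotype_sensitive")
  }
  # full truth table for the differential cases
  for (sgn in c("+", "-")) for (inc in c("T", "C")) for (hi in c("T", "C")) {
    v <- prioritize_tf("TFd", sgn, inc, hi, 2, TRUE)$verdict
    same <- inc == hi
    expected <- if ((sgn == "+" && same) || (sgn == "-" && !same))
      "retained" else "inconsistent"
    expect_equal(v, expected)
  }
  expect_error(prioritize_tf("TFe", "x", "T", "C", 1, TRUE), "correlation_sign")
  expect_error(prioritize_tf("TFf", "+", NA, "C", 1, TRUE), "direction")
})

test_that("flank FASTA round-trips through Biostrings", {
  pf <- simulate_pwm_and_flanks(length = 6, target_ic = 2, seed = 33)
  f <- tempfile(fileext = ".fasta")
  write_flanks_fasta(pf$context, f)
  ctx2 <- read_flanks_fasta(f)
  expect_equal(ctx2$alleles, pf$context$alleles)
  expect_equal(ctx2$flank_5p, pf$context$flank_5p)
  expect_equal(ctx2$flank_3p, pf$context$flank_3p)
})

test_that("pwm constructor validates its inputs", {
  expect_error(pwm("x", matrix(1, 3, 2)), "4 rows")
  expect_error(pwm("x", matrix(-1, 4, 2)), "non-negative")
  expect_error(pwm("x", matrix(1, 4, 2), pseudocount = -1), "pseudocount")
  expect_error(pwm("x", matrix(1, 4, 2), background = c(1, 1, 1, 1)),
               "background")
})
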