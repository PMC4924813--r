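BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Counts are stored as a 4 x L matrix with rows A, C, G, T. Column
#' probabilities are computed with a background-distributed pseudocount,
#' the convention used by the JASPAR ecosystem:
#' `p = (count + pseudocount * bg) / (colsum + pseudocount)`.
#'
#' @param name motif identifier.
#' @param counts 4 x L non-negative matrix; row names A, C, G, T in any
#'   order (reordered internally).
#' @param pseudocount non-negative scalar (default 0.8).
#' @param background length-4 probability vector over A, C, G, T
#'   (default uniform).
#' @return an object of class `pwm`.
#' @export
pwm <- function(name, counts, pseudocount = 0.8,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), BASES)) {
      stop("count row names must be A, C, G, T")
    }
    counts <- counts[BASES, , drop = FALSE]
  } else {
    rownames(counts) <- BASES
  }
  if (ncol(counts) < 1) stop("motif length must be >= 1")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("every column needs a positive count")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  background <- as.numeric(background)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 strictly positive probabilities summing to 1")
  }
  names(background) <- BASES
  structure(list(name = name, counts = counts,
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, pseudocount %g\n",
              x$name, ncol(x$counts), x$pseudocount))
  invisible(x)
}

#' Motif length
#' @param x a [pwm()].
#' @return integer number of columns.
#' @export
pwm_length <- function(x) ncol(x$counts)

#' Pseudocounted column probabilities of a PWM
#'
#' @param x a [pwm()].
#' @return 4 x L matrix of probabilities (columns sum to 1).
#' @export
pwm_probabilities <- function(x) {
  cs <- colSums(x$counts)
  sweep(x$counts + x$pseudocount * x$background, 2, cs + x$pseudocount, "/")
}

# per-position log2-odds score matrix against the background
.pwm_logodds <- function(x) {
  log2(pwm_probabilities(x) / x$background)
}

#' Parse JASPAR PFM text
#'
#' Accepts the JASPAR 2016 dialect: a `>` header line (matrix ID and
#' optional TF name) followed by four base rows, with or without
#' brackets, e.g. `A [ 3 12 0 ]` or `A 3 12 0`. Rows may appear in any
#' order; the returned counts matrix is normalized to A, C, G, T.
#'
#' @param text character scalar (whole file) or vector of lines, or a
#'   file path to read.
#' @param pseudocount,background passed to [pwm()].
#' @return a [pwm()] (or list of them if the text holds several records).
#' @export
parse_jaspar_pfm <- function(text, pseudocount = 0.8,
                             background = rep(0.25, 4)) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else if (length(text) == 1) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- text
  }
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("parse error at line 1: no '>' header found")
  ends <- c(starts[-1] - 1, length(lines))
  out <- lapply(seq_along(starts), function(k) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    name <- strsplit(trimws(hdr), "\\s+")[[1]][1]
    body <- lines[seq(starts[k] + 1, ends[k])]
    rows <- list()
    for (i in seq_along(body)) {
      ln <- trimws(body[i])
      m <- regmatches(ln, regexec("^([ACGTacgt])\\s*[\\[|:]?\\s*([-0-9. \t]+)\\]?\\s*$", ln))[[1]]
      if (length(m) != 3) {
        stop(sprintf("parse error at line %d: cannot read base row '%s'",
                     starts[k] + i, ln))
      }
      base <- toupper(m[2])
      vals <- as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]])
      if (anyNA(vals)) {
        stop(sprintf("parse error at line %d: non-numeric count", starts[k] + i))
      }
      if (any(vals < 0)) {
        stop(sprintf("parse error at line %d: negative count", starts[k] + i))
      }
      rows[[base]] <- vals
    }
    missing <- setdiff(BASES, names(rows))
    if (length(missing)) {
      stop(sprintf("parse error: missing base row(s) %s in record '%s'",
                   paste(missing, collapse = ", "), name))
    }
    lens <- lengths(rows[BASES])
    if (length(unique(lens)) != 1) {
      stop(sprintf("parse error: ragged columns in record '%s'", name))
    }
    counts <- do.call(rbind, rows[BASES])
    pwm(name = name, counts = counts, pseudocount = pseudocount,
        background = background)
  })
  if (length(out) == 1) out[[1]] else out
}

#' Write a PWM as JASPAR PFM text
#'
#' @param x a [pwm()] or list of them.
#' @param path file path, or `NULL` to return the lines.
#' @return invisibly, the text lines.
#' @export
write_jaspar_pfm <- function(x, path = NULL) {
  pwms <- if (inherits(x, "pwm")) list(x) else x
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$name),
      vapply(BASES, function(b)
        sprintf("%s  [ %s ]", b,
                paste(format(p$counts[b, ], trim = TRUE), collapse = " ")),
        character(1)))
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Min-max normalized log-odds score of a window
#'
#' The raw score is the summed per-column log2 odds of the window bases
#' against the background; the relative score rescales it by the minimal
#' and maximal attainable sums, so the consensus scores exactly 1 and the
#' anti-consensus exactly 0. With a zero pseudocount a zero-probability
#' base has log-odds of minus infinity; the per-column minimum is then
#' taken over the positive-probability bases, and any window containing a
#' zero-probability base scores exactly 0 (it is below every attainable
#' in-model score).
#'
#' @param x a [pwm()].
#' @param window base string of length equal to the motif length.
#' @return relative score in \[0, 1\].
#' @export
relative_score <- function(x, window) {
  L <- pwm_length(x)
  b <- strsplit(toupper(window), "")[[1]]
  if (length(b) != L) stop("window length must equal motif length")
  if (!all(b %in% BASES)) {
    stop("window contains a non-ACGT base (mask windows containing N)")
  }
  lo <- .pwm_logodds(x)
  s <- sum(lo[cbind(match(b, BASES), seq_len(L))])
  if (!is.finite(s)) return(0)
  smin <- sum(apply(lo, 2, function(col) min(col[is.finite(col)])))
  smax <- sum(apply(lo, 2, max))
  if (smax == smin) return(1)
  min(1, max(0, (s - smin) / (smax - smin)))
}

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

#' Construct a variant flanking-sequence context
#'
#' @param variant_id identifier.
#' @param alleles character vector of two distinct allele strings.
#' @param flank_5p,flank_3p 50-base flanking sequences.
#' @return an object of class `variant_context`; the per-allele sequence
#'   is `flank_5p + allele + flank_3p`, and `variable_offset` (0-based)
#'   marks where the allele starts.
#' @export
variant_context <- function(variant_id, alleles, flank_5p, flank_3p) {
  alleles <- toupper(alleles)
  flank_5p <- toupper(flank_5p); flank_3p <- toupper(flank_3p)
  if (length(alleles) != 2 || alleles[1] == alleles[2]) {
    stop("need two distinct alleles")
  }
  if (nchar(flank_5p) != 50 || nchar(flank_3p) != 50) {
    stop("flanks must be exactly 50 bases each")
  }
  structure(list(variant_id = variant_id, alleles = alleles,
                 flank_5p = flank_5p, flank_3p = flank_3p,
                 variable_offset = 50L),
            class = "variant_context")
}

#' Assembled sequence for one allele of a variant context
#' @param context a [variant_context()].
#' @param allele one of `context$alleles`.
#' @return character scalar.
#' @export
allele_sequence <- function(context, allele) {
  allele <- toupper(allele)
  if (!allele %in% context$alleles) {
    stop(sprintf("allele '%s' is not one of the context's alleles", allele))
  }
  paste0(context$flank_5p, allele, context$flank_3p)
}

#' Scan one allele's sequence for the best motif match over the variant
#'
#' Assembles the allele's sequence and evaluates every motif window that
#' overlaps the variant position, on the requested strands (reverse
#' strand windows are scored on the reverse complement). Returns the
#' best-scoring call, together with the motif column aligned over the
#' variable base at that window (reverse-strand alignments map columns
#' accordingly) and that column's information content. Windows containing
#' non-ACGT bases are skipped. Ties prefer the forward strand, then the
#' lower offset.
#'
#' @param x a [pwm()].
#' @param context a [variant_context()].
#' @param allele one of the context's alleles.
#' @param threshold relative-score match threshold (default 0.8).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @return one-row data frame: `motif`, `variant`, `allele`,
#'   `best_relative_score`, `best_offset` (0-based window start),
#'   `strand`, `is_match`, `aligned_column`, `column_ic`.
#' @export
scan_allele <- function(x, context, allele, threshold = 0.8,
                        strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  seqc <- allele_sequence(context, allele)
  L <- pwm_length(x)
  if (L > nchar(seqc)) stop("motif longer than assembled sequence")
  v0 <- context$variable_offset               # 0-based allele start
  v1 <- v0 + nchar(allele) - 1L               # 0-based allele end
  # 0-based window starts overlapping [v0, v1]
  starts <- max(0L, v0 - L + 1L):min(nchar(seqc) - L, v1)
  best <- NULL
  for (st in if (strands == "both") c("+", "-") else strands) {
    for (s in starts) {
      w <- substr(seqc, s + 1, s + L)
      if (grepl("[^ACGT]", w)) next
      sc <- relative_score(x, if (st == "+") w else .revcomp(w))
      if (is.null(best) || sc > best$score + 1e-12) {
        best <- list(score = sc, offset = s, strand = st)
      }
    }
  }
  if (is.null(best)) stop("no scorable window overlaps the variant")
  # motif column over the first variable base at the best window
  col <- if (best$strand == "+") v0 - best$offset + 1L
  else L - (v0 - best$offset)
  col_ok <- col >= 1 && col <= L
  data.frame(motif = x$name, variant = context$variant_id, allele = allele,
             best_relative_score = best$score, best_offset = best$offset,
             strand = best$strand,
             is_match = best$score >= threshold,
             aligned_column = if (col_ok) col else NA_integer_,
             column_ic = if (col_ok) column_ic(x, col) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Information content of a PWM column
#'
#' `IC = 2 + sum(p * log2(p))` bits, using the pseudocounted column
#' probabilities, with `0 * log2(0)` taken as 0. A uniform column has 0
#' bits, a single-base column (pseudocount 0) has 2 bits, and a 50/50
#' two-base column has 1 bit.
#'
#' @param x a [pwm()].
#' @param column column index.
#' @return bits in \[0, 2\].
#' @export
column_ic <- function(x, column) {
  if (column < 1 || column > pwm_length(x)) stop("column index out of range")
  p <- pwm_probabilities(x)[, column]
  h <- ifelse(p > 0, p * log2(p), 0)
  2 + sum(h)
}

#' Allele-specific differential binding call
#'
#' Scans both alleles and flags the site as differential when (a) at
#' least one allele's best variant-overlapping window reaches the match
#' threshold, and (b) the motif column aligned over the variable base at
#' that best window has information content of at least `ic_min` bits.
#' Both alleles' calls are always reported. For single-base substitutions
#' the per-allele fold affinity at the aligned column is attached; for
#' alleles of unequal length (indels) the column alignment differs per
#' allele and the fold is reported `NA`.
#'
#' @param x a [pwm()].
#' @param context a [variant_context()].
#' @param threshold relative-score match threshold (default 0.8).
#' @param ic_min minimum information content in bits at the variable base
#'   (default 1.0).
#' @return list: `calls` (two-row data frame), `differential` (logical),
#'   `fold_affinity` (ratio toward the higher-affinity allele, or `NA`),
#'   `higher_affinity_allele`.
#' @export
differential_binding <- function(x, context, threshold = 0.8, ic_min = 1.0) {
  calls <- rbind(scan_allele(x, context, context$alleles[1], threshold),
                 scan_allele(x, context, context$alleles[2], threshold))
  any_match <- any(calls$is_match)
  best_idx <- which.max(calls$best_relative_score)
  ic_ok <- !is.na(calls$column_ic[best_idx]) &&
    calls$column_ic[best_idx] >= ic_min
  differential <- any_match && ic_ok
  snv <- all(nchar(context$alleles) == 1)
  fold <- NA_real_; hi <- NA_character_
  if (snv && !is.na(calls$aligned_column[best_idx])) {
    colx <- calls$aligned_column[best_idx]
    a1 <- context$alleles[1]; a2 <- context$alleles[2]
    # on the reverse strand the motif reads the complementary bases
    if (calls$strand[best_idx] == "-") {
      a1 <- chartr("ACGT", "TGCA", a1); a2 <- chartr("ACGT", "TGCA", a2)
    }
    f12 <- suppressWarnings(fold_affinity(x, colx, a1, a2))
    if (!is.finite(f12)) {
      fold <- Inf; hi <- context$alleles[1]
    } else if (f12 == 0) {
      fold <- Inf; hi <- context$alleles[2]
    } else if (f12 >= 1) {
      fold <- f12; hi <- context$alleles[1]
    } else {
      fold <- 1 / f12; hi <- context$alleles[2]
    }
  }
  list(calls = calls, differential = differential,
       fold_affinity = fold, higher_affinity_allele = hi)
}

#' Fold affinity between two alleles at a motif column
#'
#' Ratio of the pseudocounted column probabilities of the two bases,
#' `p(allele_a) / p(allele_b)`. With pseudocount 0 a zero denominator
#' yields an infinity sentinel with a warning.
#'
#' @param x a [pwm()].
#' @param aligned_column column index over the variable base.
#' @param allele_a,allele_b single bases.
#' @return positive ratio (possibly `Inf`).
#' @export
fold_affinity <- function(x, aligned_column, allele_a, allele_b) {
  if (nchar(allele_a) != 1 || nchar(allele_b) != 1) {
    stop("fold affinity is defined only for single-base alleles")
  }
  p <- pwm_probabilities(x)[, aligned_column]
  pa <- p[toupper(allele_a)]; pb <- p[toupper(allele_b)]
  if (pb == 0) {
    warning("zero probability with zero pseudocount: fold affinity infinite")
    return(Inf)
  }
  unname(pa / pb)
}

#' Logical-consistency prioritization of a candidate TF
#'
#' A TF whose binding is not predicted to differ between alleles is
#' `not_genotype_sensitive`. Otherwise the direction of the TF-target
#' expression correlation must agree with the allele predicted to bind
#' more strongly: a positively correlated TF must bind the
#' increased-expression allele more strongly (an activator bound more at
#' the high-expression allele), and a negatively correlated TF must bind
#' the *other* allele more strongly; violations are `inconsistent`,
#' agreements `retained`.
#'
#' @param tf_name TF identifier.
#' @param correlation_sign `"+"` or `"-"` (sign of the TF-target
#'   expression correlation).
#' @param increased_expression_allele allele associated with higher
#'   target expression (from the eQTL direction).
#' @param higher_affinity_allele allele with the stronger predicted
#'   binding.
#' @param fold_affinity ratio toward the higher-affinity allele.
#' @param differential logical flag from [differential_binding()].
#' @return one-row data frame: `tf`, `correlation_sign`,
#'   `increased_expression_allele`, `higher_affinity_allele`,
#'   `fold_affinity`, `verdict`.
#' @export
prioritize_tf <- function(tf_name, correlation_sign,
                          increased_expression_allele,
                          higher_affinity_allele,
                          fold_affinity = NA_real_,
                          differential = TRUE) {
  if (!correlation_sign %in% c("+", "-")) {
    stop("correlation_sign must be '+' or '-'")
  }
  verdict <- if (!isTRUE(differential)) {
    "not_genotype_sensitive"
  } else {
    if (is.na(increased_expression_allele) || is.na(higher_affinity_allele)) {
      stop("missing direction information for a differential candidate")
    }
    same <- identical(toupper(increased_expression_allele),
                      toupper(higher_affinity_allele))
    if ((correlation_sign == "+" && !same) ||
        (correlation_sign == "-" && same)) "inconsistent" else "retained"
  }
  data.frame(tf = tf_name, correlation_sign = correlation_sign,
             increased_expression_allele = increased_expression_allele,
             higher_affinity_allele = higher_affinity_allele,
             fold_affinity = fold_affinity, verdict = verdict,
             stringsAsFactors = FALSE)
}
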