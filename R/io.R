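#' Write genotypes as a TSV dosage matrix
#'
#' Subject ID in column 1, one column per SNP, values 0/1/2 or empty for
#' missing.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(subject = genotypes$subject_ids,
                   genotypes$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read genotypes from a TSV dosage matrix
#'
#' @param path file written by [write_dosage_tsv()] (subject IDs in
#'   column 1).
#' @param allele_labels optional allele label table (see
#'   [genotype_matrix()]).
#' @return a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path, allele_labels = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  genotype_matrix(m, subject_ids = as.character(df[[1]]),
                  snp_ids = colnames(df)[-1],
                  allele_labels = allele_labels)
}

#' Write genotypes as a minimal VCF
#'
#' GT-only VCF with one sample column per subject. The minor allele is
#' written as ALT, so the ALT dosage in the VCF equals the stored
#' minor-allele dosage.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file (plain text).
#' @param chrom,pos_start chromosome label and starting position used for
#'   the synthetic records.
#' @export
write_genotypes_vcf <- function(genotypes, path, chrom = "15",
                                pos_start = 22783636L) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$subject_ids),
                    collapse = "\t"))
  rows <- vapply(seq_along(genotypes$snp_ids), function(j) {
    d <- genotypes$dosages[, j]
    calls <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    lab <- genotypes$allele_labels[j, ]
    paste(c(chrom, pos_start + (j - 1L) * 1000L, genotypes$snp_ids[j],
            lab$major, lab$minor, ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
}

#' Read genotypes from a VCF
#'
#' Reads GT fields (phased or unphased) with `vcfR` and converts ALT
#' allele counts to dosages, treating ALT as the minor allele label.
#'
#' @param path VCF file.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a)
             sum(a == "1"), integer(1)))
  }
  # samples in rows, variants in columns
  dos <- vapply(seq_len(nrow(gt)), function(i) count_alt(gt[i, ]),
                integer(ncol(gt)))
  dos <- matrix(dos, nrow = ncol(gt))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snp_ids <- fix$ID
  snp_ids[is.na(snp_ids) | snp_ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(snp_ids) | snp_ids == "."]
  colnames(dos) <- snp_ids
  genotype_matrix(dos,
                  subject_ids = colnames(gt),
                  snp_ids = snp_ids,
                  allele_labels = data.frame(snp = snp_ids,
                                             major = fix$REF,
                                             minor = fix$ALT,
                                             stringsAsFactors = FALSE))
}

#' Write an expression matrix plus sample map as TSV
#'
#' @param expr an [expression_matrix()].
#' @param expr_path,map_path output files.
#' @export
write_expression_tsv <- function(expr, expr_path, map_path) {
  df <- data.frame(sample_id = expr$sample_ids, expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$sample_map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read an expression matrix plus sample map from TSV
#'
#' @param expr_path,map_path files written by [write_expression_tsv()].
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(expr_path, map_path) {
  df <- utils::read.table(expr_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, map)
}

#' Write per-allele flank sequences as FASTA
#'
#' One record per allele, named `<variant>_<allele>`.
#'
#' @param context a [variant_context()].
#' @param path output FASTA file.
#' @export
write_flanks_fasta <- function(context, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(context$alleles, function(a) allele_sequence(context, a),
           character(1)))
  names(seqs) <- paste(context$variant_id, context$alleles, sep = "_")
  Biostrings::writeXStringSet(seqs, path)
}

#' Read per-allele flank FASTA back into a variant context
#'
#' Expects exactly two records named `<variant>_<allele>` whose sequences
#' share 50-base flanks around the allele.
#'
#' @param path FASTA file.
#' @return a [variant_context()].
#' @export
read_flanks_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2) stop("expected exactly two allele records")
  ids <- names(seqs)
  variant <- sub("_[^_]+$", "", ids[1])
  alleles <- sub("^.*_", "", ids)
  s1 <- as.character(seqs[[1]])
  flank5 <- substr(s1, 1, 50)
  flank3 <- substr(s1, 51 + nchar(alleles[1]), nchar(s1))
  variant_context(variant_id = variant, alleles = alleles,
                  flank_5p = flank5, flank_3p = flank3)
}

#' Write a table as TSV (header, no row names)
#' @param df data frame.
#' @param path output file.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
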