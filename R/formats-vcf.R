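#' Read a VCF into a genotype dosage matrix
#'
#' Parses a (plain or gzipped) VCF via the vcfR package and converts it to a
#' [geno_matrix]. Only biallelic SNP records are retained; multi-allelic
#' records and indels are dropped and counted. Genotypes are converted to
#' alternate-allele dosage; half-calls and `./.` become missing. QUAL is
#' retained per site (`NA` when "." in the file).
#'
#' @param path path to a VCF file with GT fields.
#' @param verbose if TRUE, report the number of records dropped.
#' @return a [geno_matrix]; the number of dropped records is available in
#'   `attr(, "dropped")` (named vector: `multiallelic`, `indel`).
#' @export
read_vcf <- function(path, verbose = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  keep <- !multi & !indel
  dropped <- c(multiallelic = sum(multi), indel = sum(indel))
  if (verbose && sum(dropped) > 0)
    message("read_vcf: dropped ", dropped[["multiallelic"]],
            " multi-allelic and ", dropped[["indel"]], " indel record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dos <- .gt_to_dosage(gt)            # sites x samples
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      qual = qual, stringsAsFactors = FALSE)
  g <- geno_matrix(t(dos), sites, colnames(gt))
  attr(g, "dropped") <- dropped
  g
}

# GT strings ("0/1", "1|1", "./.", ".") -> integer dosage matrix; anything
# containing a "." is missing.
.gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  clean <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d[clean] <- (a1[clean] == "1") + (a2[clean] == "1")
  d
}

#' Write a genotype matrix as a plain-text VCF 4.2
#'
#' Emits unphased diploid GT records (one biallelic SNP per row) with QUAL
#' populated from the site table. Round-trips with [read_vcf()].
#'
#' @param g a [geno_matrix].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pinekit",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  if (ncol(g$dosage) > 0) {
    gt_code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = ncol(g$dosage), ncol = nrow(g$dosage))
    dos <- t(g$dosage)                 # sites x samples
    ok <- !is.na(dos)
    gt[ok] <- gt_code[dos[ok] + 1L]
    qual <- ifelse(is.na(g$sites$qual), ".", format(g$sites$qual, trim = TRUE))
    lines <- paste(g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt,
                   qual, "PASS", ".", "GT", sep = "\t")
    lines <- paste(lines, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
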