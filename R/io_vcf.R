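#' Read biallelic SNPs from a VCF file
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}), keeps only biallelic SNP records
#' with quality at or above \code{min_qual} (inclusive), and converts diploid
#' GT fields to alternate-allele counts.  Positions become 0-based.
#' Half-called genotypes (e.g. \code{"./1"}) are treated as missing;
#' phased and unphased separators are equivalent.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param min_qual minimum QUAL retained (inclusive).  Defaults to 100, the
#'   usual threshold for SAMtools-called SNPs in low-coverage resequencing
#'   panels.  Records with missing QUAL are dropped.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, min_qual = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path)

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    !is.na(qual) & qual >= min_qual
  if (!any(keep)) stop("no biallelic SNPs pass min_qual=", min_qual)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  geno <- matrix(gt_to_code(gt), nrow = nrow(gt), ncol = ncol(gt))

  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"]) - 1L
  key <- paste(chrom, pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) in VCF: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  o <- order(chrom, pos)
  variant_table(chrom[o], pos[o], ref[keep][o], alt[keep][o],
                qual[keep][o], geno[o, , drop = FALSE], colnames(gt))
}

# light structural scan so malformed lines are reported with their number
check_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#")
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf < 8L]
  if (length(bad))
    stop("malformed VCF line ", bad[1], " in ", path,
         " (expected >= 8 tab-separated fields)")
  pos <- vapply(strsplit(lines[body], "\t", fixed = TRUE), `[`, "", 2L)
  badp <- which(body)[is.na(suppressWarnings(as.integer(pos)))]
  if (length(badp))
    stop("malformed VCF line ", badp[1], " in ", path, " (POS not an integer)")
  invisible(TRUE)
}

# "0/1", "0|1", "./." ... -> 0/1/2/NA
gt_to_code <- function(gt) {
  a <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  b <- sub("^[^/|]*[/|]([^/|:]*).*$", "\\1", gt)
  # haploid or malformed entries have no separator
  nosep <- !grepl("[/|]", gt)
  code <- ifelse(a %in% c("0", "1") & b %in% c("0", "1"),
                 as.integer(a == "1") + as.integer(b == "1"),
                 NA_integer_)
  code[nosep | is.na(gt)] <- NA_integer_
  as.integer(code)
}

#' Write a VariantTable as VCF
#'
#' Emits a minimal VCF 4.2 file with a GT-only FORMAT.  Positions are
#' converted back to 1-based.  \code{read_vcf(write_vcf(x))} reproduces
#' \code{x} on all retained fields.
#'
#' @param table a [variant_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(table, path) {
  gt <- matrix(c("0/0", "0/1", "1/1")[table$geno + 1L],
               nrow = n_sites(table))
  gt[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=apisweep",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$sample_ids), collapse = "\t"))
  body <- paste(table$chrom, table$pos + 1L, ".", table$ref, table$alt,
                format(table$qual, trim = TRUE, scientific = FALSE), ".", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
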