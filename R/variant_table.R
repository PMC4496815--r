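#' Construct a VariantTable
#'
#' A \code{VariantTable} holds ordered biallelic SNP sites with one diploid
#' genotype code per sample.  Positions are 0-based internally; conversion to
#' and from 1-based coordinates happens only at format boundaries (VCF,
#' outgroup TSV).  Genotype codes count copies of the alternate allele:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' \code{NA} = missing.  Phasing is ignored.
#'
#' @param chrom character vector of sequence names.
#' @param pos integer vector of 0-based positions.
#' @param ref,alt single-nucleotide reference and alternate alleles.
#' @param qual numeric variant quality scores.
#' @param geno integer matrix, sites in rows, samples in columns, entries in
#'   \{0, 1, 2, NA\}.
#' @param sample_ids ordered sample labels (column names of \code{geno}).
#' @return An object of class \code{VariantTable}.
#' @export
variant_table <- function(chrom, pos, ref, alt, qual, geno, sample_ids) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  colnames(geno) <- sample_ids
  x <- structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         qual = as.numeric(qual), geno = geno,
         sample_ids = as.character(sample_ids)),
    class = "VariantTable")
  validate_variant_table(x)
}

validate_variant_table <- function(x) {
  n <- length(x$chrom)
  stopifnot(length(x$pos) == n, length(x$ref) == n, length(x$alt) == n,
            length(x$qual) == n, nrow(x$geno) == n,
            ncol(x$geno) == length(x$sample_ids))
  if (n > 0) {
    if (any(x$ref == x$alt))
      stop("ref and alt allele identical at ",
           sum(x$ref == x$alt), " site(s)")
    if (!all(nchar(x$ref) == 1L & nchar(x$alt) == 1L))
      stop("alleles must be single nucleotides")
    o <- order(x$chrom, x$pos)
    if (!identical(o, seq_len(n))) stop("sites must be sorted by (chrom, pos)")
    key <- paste(x$chrom, x$pos)
    if (anyDuplicated(key))
      stop("duplicate site(s): ", paste(unique(key[duplicated(key)]),
                                        collapse = ", "))
    bad <- x$geno[!is.na(x$geno)]
    if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
      stop("genotype codes must be 0, 1, 2 or NA")
  }
  x
}

#' @export
print.VariantTable <- function(x, ...) {
  cat("VariantTable:", n_sites(x), "sites x", length(x$sample_ids),
      "samples on", length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of sites in a VariantTable
#' @param x a \code{VariantTable}.
#' @return integer site count.
#' @export
n_sites <- function(x) length(x$chrom)

#' Subset a VariantTable by site index
#' @param x a \code{VariantTable}.
#' @param i logical or integer site index.
#' @param ... unused.
#' @return a \code{VariantTable} with the selected sites.
#' @export
`[.VariantTable` <- function(x, i, ...) {
  structure(
    list(chrom = x$chrom[i], pos = x$pos[i], ref = x$ref[i], alt = x$alt[i],
         qual = x$qual[i], geno = x$geno[i, , drop = FALSE],
         sample_ids = x$sample_ids),
    class = "VariantTable")
}

# resolve a sample selection (NULL = all) to column indices, with checks
sample_index <- function(table, samples) {
  if (is.null(samples)) return(seq_along(table$sample_ids))
  idx <- match(samples, table$sample_ids)
  if (anyNA(idx))
    stop("sample(s) not in VariantTable: ",
         paste(samples[is.na(idx)], collapse = ", "))
  idx
}

#' Construct a PopulationSpec
#'
#' Maps group labels to disjoint sets of sample ids.
#'
#' @param groups named list of character vectors of sample ids.
#' @return An object of class \code{PopulationSpec}.
#' @export
population_spec <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)), all(nzchar(names(groups))))
  ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("groups must be disjoint; duplicated sample(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(lapply(groups, as.character), class = "PopulationSpec")
}

#' @export
print.PopulationSpec <- function(x, ...) {
  cat("PopulationSpec:", length(x), "group(s)\n")
  for (g in names(x))
    cat("  ", g, ": ", length(x[[g]]), " sample(s)\n", sep = "")
  invisible(x)
}

# group label -> sample ids, validated against a VariantTable
group_samples <- function(pops, group, table = NULL) {
  if (!group %in% names(pops)) stop("group not in PopulationSpec: ", group)
  ids <- pops[[group]]
  if (length(ids) == 0L) stop("group '", group, "' is empty")
  if (!is.null(table)) sample_index(table, ids)  # errors on unknown ids
  ids
}
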