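#' Read a population assignment file
#'
#' Tab-separated \code{sample<TAB>group} with \code{#} comment lines.
#' Samples absent from the file are simply unassigned.
#'
#' @param path path to the TSV file.
#' @param table optional [variant_table()]; if given, every sample named in
#'   the file must exist in it (error names the offending sample).
#' @return a [population_spec()].
#' @export
read_populations <- function(path, table = NULL) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("sample", "group"),
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty population file: ", path)
  if (!is.null(table)) {
    missing <- setdiff(df$sample, table$sample_ids)
    if (length(missing))
      stop("sample(s) in population file absent from VCF: ",
           paste(missing, collapse = ", "))
  }
  population_spec(split(df$sample, df$group))
}

#' Write a population assignment file
#' @param pops a [population_spec()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_populations <- function(pops, path) {
  df <- data.frame(sample = unlist(pops, use.names = FALSE),
                   group = rep(names(pops), lengths(pops)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-site outgroup alleles
#'
#' Tab-separated \code{chrom<TAB>pos(1-based)<TAB>allele}.  Returns a
#' character vector aligned 1:1 with the sites of \code{table}; sites without
#' an entry, or with allele \code{"."}, \code{"-"} or \code{"N"}, are
#' \code{NA} (missing).  Used to polarize the site frequency spectrum and to
#' count interspecies divergences in the McDonald-Kreitman test.
#'
#' @param path path to the TSV file.
#' @param table the [variant_table()] whose sites the alleles annotate.
#' @return character vector of outgroup alleles (or \code{NA}), one per site.
#' @export
read_outgroup <- function(path, table) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("chrom", "pos", "allele"),
                          colClasses = c("character", "integer", "character"))
  key <- paste(df$chrom, df$pos - 1L)
  out <- df$allele[match(paste(table$chrom, table$pos), key)]
  out[!out %in% c("A", "C", "G", "T")] <- NA_character_
  out
}

#' Write outgroup alleles
#' @param table the [variant_table()] the alleles annotate.
#' @param alleles character vector of outgroup alleles (\code{NA} = missing).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_outgroup <- function(table, alleles, path) {
  a <- ifelse(is.na(alleles), ".", alleles)
  writeLines(paste(table$chrom, table$pos + 1L, a, sep = "\t"), path)
  invisible(path)
}

#' Write scored intervals as BED
#'
#' BED3+2: \code{chrom start end score empirical_p}, 0-based half-open.
#'
#' @param intervals data frame of scan results (see [maximal_segments()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  p <- if ("empirical_p" %in% names(intervals)) intervals$empirical_p else NA
  writeLines(paste(intervals$chrom, intervals$start, intervals$end,
                   format(intervals$score, trim = TRUE, digits = 15),
                   ifelse(is.na(p), ".", format(p, trim = TRUE, digits = 15)),
                   sep = "\t"), path)
  invisible(path)
}

#' Read scored intervals from BED
#' @param path BED3+2 file written by [write_intervals()].
#' @return data frame with columns chrom, start, end, score, empirical_p.
#' @export
read_intervals <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "score",
                                        "empirical_p"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric", "character"))
  df$empirical_p <- suppressWarnings(as.numeric(df$empirical_p))
  df
}

#' Write a per-gene counts table as TSV
#' @param counts data frame keyed by gene id (see [pnps_table()],
#'   [fixed_diff_table()], [mk_table()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
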