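#' Construct a GeneModel
#'
#' A stranded chain of CDS intervals for one gene.  Intervals use 0-based
#' half-open coordinates and are stored in transcription order (decreasing
#' genomic start on the minus strand).  If the spliced CDS length is not a
#' multiple of 3, the trailing partial codon (3'-most bases in transcription
#' order) is dropped and the number of trimmed bases recorded.
#'
#' @param gene_id gene identifier.
#' @param chrom sequence name.
#' @param strand "+" or "-".
#' @param starts,ends parallel vectors of 0-based half-open CDS intervals
#'   (any order; they are sorted into transcription order).
#' @param phase optional phase per interval (kept as annotation).
#' @return An object of class \code{GeneModel}.
#' @export
gene_model <- function(gene_id, chrom, strand, starts, ends, phase = NULL) {
  stopifnot(strand %in% c("+", "-"), length(starts) == length(ends),
            all(ends > starts))
  o <- order(starts)
  if (any(starts[o][-1] < ends[o][-length(o)]))
    stop("CDS intervals overlap for gene ", gene_id)
  if (strand == "-") o <- rev(o)
  iv <- data.frame(start = as.integer(starts[o]), end = as.integer(ends[o]),
                   phase = if (is.null(phase)) NA_integer_
                           else as.integer(phase[o]))
  len <- sum(iv$end - iv$start)
  trimmed <- len %% 3L
  if (trimmed) {
    # remove the trailing bases in transcription order
    drop <- trimmed
    i <- nrow(iv)
    while (drop > 0L && i >= 1L) {
      w <- iv$end[i] - iv$start[i]
      take <- min(w, drop)
      if (strand == "+") iv$end[i] <- iv$end[i] - take
      else iv$start[i] <- iv$start[i] + take
      drop <- drop - take
      if (iv$end[i] == iv$start[i]) iv <- iv[-i, , drop = FALSE]
      i <- i - 1L
    }
  }
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, intervals = iv,
                 cds_length = len - trimmed, trimmed_bp = trimmed),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel ", x$gene_id, " (", x$chrom, x$strand, "): ",
      nrow(x$intervals), " CDS interval(s), spliced length ", x$cds_length,
      if (x$trimmed_bp) paste0(" (", x$trimmed_bp, " bp trimmed)"), "\n",
      sep = "")
  invisible(x)
}

# genomic span of the CDS chain, 0-based half-open
gene_span <- function(gene) {
  c(start = min(gene$intervals$start), end = max(gene$intervals$end))
}

#' Read gene models (CDS chains) from a GFF3 file
#'
#' Extracts CDS features (via \pkg{rtracklayer}) and assembles one
#' [gene_model()] per gene.  The gene identifier is taken from the first
#' available of the \code{gene_id}, \code{gene}, \code{Parent} and \code{ID}
#' attributes.  CDS features without a strand or without any gene attribute
#' are skipped with a warning.
#'
#' @param path path to a GFF3 file.
#' @return named list of [gene_model()] objects.
#' @export
read_gff_cds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- rtracklayer::readGFF(path)
  g <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(g) == 0L) stop("no CDS features in ", path)

  pick <- function(col) {
    if (!col %in% names(g)) return(rep(NA_character_, nrow(g)))
    v <- g[[col]]
    if (is.list(v)) vapply(v, function(x)
      if (length(x)) as.character(x[[1]]) else NA_character_, "")
    else as.character(v)
  }
  id <- pick("gene_id")
  for (col in c("gene", "Parent", "ID")) {
    alt <- pick(col)
    id[is.na(id) | !nzchar(id)] <- alt[is.na(id) | !nzchar(id)]
  }
  strand <- as.character(g$strand)
  ok <- !is.na(id) & nzchar(id) & strand %in% c("+", "-")
  if (any(!ok))
    warning(sum(!ok), " CDS feature(s) without strand or gene id skipped")
  g <- g[ok, , drop = FALSE]; id <- id[ok]; strand <- strand[ok]
  if (nrow(g) == 0L) stop("no usable CDS features in ", path)

  genes <- lapply(split(seq_len(nrow(g)), id), function(i) {
    gm <- gene_model(id[i[1]], as.character(g$seqid[i[1]]), strand[i[1]],
                     starts = g$start[i] - 1L, ends = g$end[i],
                     phase = suppressWarnings(as.integer(g$phase[i])))
    if (gm$trimmed_bp)
      warning("gene ", gm$gene_id, ": spliced CDS length not divisible by 3; ",
              gm$trimmed_bp, " trailing bp dropped")
    gm
  })
  genes
}

#' Write gene models as GFF3
#'
#' One \code{gene} feature plus its \code{CDS} chain per gene; used by the
#' synthetic fixture generators.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff_cds <- function(genes, path) {
  lines <- "##gff-version 3"
  for (gm in genes) {
    span <- gene_span(gm)
    lines <- c(lines,
      paste(gm$chrom, "apisweep", "gene", span["start"] + 1L, span["end"],
            ".", gm$strand, ".", paste0("ID=", gm$gene_id), sep = "\t"))
    iv <- gm$intervals
    # genomic order in the file regardless of strand
    iv <- iv[order(iv$start), , drop = FALSE]
    off <- if (gm$strand == "+") {
      cumsum(c(0L, head(iv$end - iv$start, -1L)))
    } else {
      rev(cumsum(c(0L, rev(iv$end - iv$start)[-nrow(iv)])))
    }
    phase <- (3L - off %% 3L) %% 3L
    for (k in seq_len(nrow(iv)))
      lines <- c(lines,
        paste(gm$chrom, "apisweep", "CDS", iv$start[k] + 1L, iv$end[k], ".",
              gm$strand, phase[k],
              paste0("ID=cds-", gm$gene_id, ";Parent=", gm$gene_id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
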