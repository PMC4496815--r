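BASES <- c("A", "C", "G", "T")

# standard genetic code as a named character vector, "*" = stop
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

revcomp <- function(s) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", s), ""), function(x)
    paste(rev(x), collapse = ""), "")
}

# per-codon fraction of the 9 single-base mutants that are synonymous,
# divided by 3 per position: s in [0, 3].  Mutants that hit a stop codon are
# nonsynonymous by this accounting, so n = 3 - s exactly for every codon.
codon_syn_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- genetic_code()
    s <- stats::setNames(numeric(length(gc)), names(gc))
    for (codon in names(gc)) {
      aa <- gc[[codon]]
      if (aa == "*") { s[[codon]] <- NA_real_; next }
      syn <- 0L
      for (p in 1:3) for (b in BASES) {
        if (b == substr(codon, p, p)) next
        mut <- codon
        substr(mut, p, p) <- b
        if (gc[[mut]] == aa) syn <- syn + 1L
      }
      s[[codon]] <- syn / 3
    }
    cache <<- s
    s
  }
})

#' Effective synonymous and nonsynonymous site counts for a CDS
#'
#' Nei-Gojobori style site counting: for each codon, the synonymous site
#' count is the fraction of its nine single-base mutants that preserve the
#' encoded amino acid (divided by 3 per position); mutations that create a
#' stop count as nonsynonymous, so every counted codon contributes exactly
#' 3 sites in total.  Stop codons and codons containing non-ACGT letters
#' (assembly gaps) are skipped and tallied.
#'
#' @param cds_sequence spliced CDS nucleotide sequence (character string or
#'   \code{DNAString}); length must be divisible by 3.
#' @return list with \code{N}, \code{S}, \code{codons_counted},
#'   \code{codons_skipped}.
#' @export
effective_sites <- function(cds_sequence) {
  seq <- toupper(as.character(cds_sequence))
  if (nchar(seq) %% 3L != 0L)
    stop("CDS length ", nchar(seq), " not divisible by 3; pre-trim required")
  codons <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
  stab <- codon_syn_sites()
  s <- stab[codons]                      # NA for stops and unknown codons
  skipped <- sum(is.na(s))
  counted <- length(codons) - skipped
  S <- sum(s, na.rm = TRUE)
  list(N = 3 * counted - S, S = S,
       codons_counted = counted, codons_skipped = skipped)
}

# reference sequences: accept DNAStringSet or named character vector and
# return a named character vector of chromosome sequences
ref_as_character <- function(ref_genome) {
  if (is.character(ref_genome)) return(toupper(ref_genome))
  stats::setNames(toupper(as.character(ref_genome)), names(ref_genome))
}

# spliced CDS in transcription orientation (reverse-complemented for "-")
spliced_cds <- function(gene, ref_genome) {
  refs <- ref_as_character(ref_genome)
  if (!gene$chrom %in% names(refs))
    stop("chromosome ", gene$chrom, " not in reference genome")
  chromseq <- refs[[gene$chrom]]
  iv <- gene$intervals[order(gene$intervals$start), , drop = FALSE]
  seq <- paste(substring(chromseq, iv$start + 1L, iv$end), collapse = "")
  if (gene$strand == "-") revcomp(seq) else seq
}

# 0-based offsets into the spliced CDS for genomic positions; NA outside CDS
cds_offsets <- function(gene, pos) {
  iv <- gene$intervals                   # transcription order
  w <- iv$end - iv$start
  before <- cumsum(c(0L, w))[seq_len(nrow(iv))]
  off <- rep(NA_integer_, length(pos))
  for (k in seq_len(nrow(iv))) {
    inside <- pos >= iv$start[k] & pos < iv$end[k]
    off[inside] <- before[k] + if (gene$strand == "+")
      pos[inside] - iv$start[k] else iv$end[k] - 1L - pos[inside]
  }
  off
}

#' Classify the coding effect of a SNP
#'
#' Builds the reference codon from the reference genome in transcription
#' orientation (reverse-complemented on the minus strand), substitutes the
#' alternate allele at the in-codon position and translates both codons under
#' the standard genetic code.
#'
#' @param gene a [gene_model()].
#' @param pos 0-based genomic position of the SNP (must lie in the CDS).
#' @param ref,alt reference and alternate alleles on the genome strand.
#' @param ref_genome reference sequences (named \code{DNAStringSet} or
#'   character vector).
#' @return data frame with one row: \code{gene_id}, \code{pos},
#'   \code{codon_index} and \code{codon_pos} (both 0-based, transcription
#'   frame), \code{ref_codon}, \code{alt_codon} and \code{effect} in
#'   \code{SYNONYMOUS}, \code{NONSYNONYMOUS}, \code{STOP_AFFECTED},
#'   \code{SKIPPED}.
#' @export
classify_snp <- function(gene, pos, ref, alt, ref_genome) {
  eff <- snp_effects(gene,
                     data.frame(pos = pos, ref = ref, alt = alt),
                     ref_genome)
  if (nrow(eff) == 0L) stop("position ", pos, " outside CDS of ", gene$gene_id)
  eff
}

# classify every supplied site that falls in the gene's CDS.
# sites: data.frame(pos, ref, alt) with 0-based pos, genome-strand alleles.
snp_effects <- function(gene, sites, ref_genome) {
  off <- cds_offsets(gene, sites$pos)
  keep <- which(!is.na(off))
  if (!length(keep))
    return(data.frame(gene_id = character(), pos = integer(),
                      codon_index = integer(), codon_pos = integer(),
                      ref_codon = character(), alt_codon = character(),
                      effect = character(), stringsAsFactors = FALSE))
  cds <- spliced_cds(gene, ref_genome)
  off <- off[keep]
  pos <- sites$pos[keep]
  ref <- toupper(sites$ref[keep]); alt <- toupper(sites$alt[keep])

  oriented_ref <- if (gene$strand == "+") ref else chartr("ACGT", "TGCA", ref)
  oriented_alt <- if (gene$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  cds_base <- substring(cds, off + 1L, off + 1L)
  mism <- cds_base != oriented_ref & cds_base %in% BASES
  if (any(mism))
    stop("ref allele disagrees with reference genome at ", gene$chrom, ":",
         pos[which(mism)[1]] + 1L, " (gene ", gene$gene_id, ")")

  codon_index <- off %/% 3L
  codon_pos <- off %% 3L
  ref_codon <- substring(cds, codon_index * 3L + 1L, codon_index * 3L + 3L)
  alt_codon <- mapply(function(c0, p, b) {
    substr(c0, p, p) <- b; c0
  }, ref_codon, codon_pos + 1L, oriented_alt, USE.NAMES = FALSE)

  gc <- genetic_code()
  known <- function(x) !is.na(match(x, names(gc)))
  effect <- character(length(off))
  for (i in seq_along(off)) {
    if (!known(ref_codon[i]) || !known(alt_codon[i])) {
      effect[i] <- "SKIPPED"
    } else {
      a <- gc[[ref_codon[i]]]; b <- gc[[alt_codon[i]]]
      effect[i] <- if (a == "*" || b == "*") "STOP_AFFECTED"
        else if (a == b) "SYNONYMOUS" else "NONSYNONYMOUS"
    }
  }
  data.frame(gene_id = gene$gene_id, pos = pos, codon_index = codon_index,
             codon_pos = codon_pos, ref_codon = ref_codon,
             alt_codon = alt_codon, effect = effect,
             stringsAsFactors = FALSE)
}

# --- per-gene tallies ------------------------------------------------------

# site status among a sample subset:
#   "poly"  >= 2 distinct alleles observed among called genotypes
#   "fixed_alt" all called genotypes hom-alt (>= 1 called)
#   "fixed_ref" all called genotypes hom-ref (>= 1 called)
#   "uncalled" no called genotype
site_status <- function(table, samples = NULL) {
  g <- table$geno[, sample_index(table, samples), drop = FALSE]
  called <- rowSums(!is.na(g))
  any_het <- rowSums(g == 1L, na.rm = TRUE) > 0L
  any_ref <- rowSums(g == 0L, na.rm = TRUE) > 0L
  any_alt <- rowSums(g == 2L, na.rm = TRUE) > 0L
  status <- rep("uncalled", n_sites(table))
  poly <- any_het | (any_ref & any_alt)
  status[called > 0L & poly] <- "poly"
  status[called > 0L & !poly & any_alt] <- "fixed_alt"
  status[called > 0L & !poly & any_ref] <- "fixed_ref"
  status
}

# shared scaffolding: per gene, classify its CDS SNPs and hand the effect
# table plus site status to `tally`, which fills gene-specific columns
gene_tables <- function(table, genes, ref_genome, samples, tally) {
  status <- site_status(table, samples)
  rows <- lapply(genes, function(gene) {
    es <- effective_sites(spliced_cds(gene, ref_genome))
    if (es$codons_counted == 0L) {
      warning("gene ", gene$gene_id, " has no countable codons; omitted")
      return(NULL)
    }
    on_chrom <- which(table$chrom == gene$chrom)
    eff <- snp_effects(gene,
                       data.frame(pos = table$pos[on_chrom],
                                  ref = table$ref[on_chrom],
                                  alt = table$alt[on_chrom]),
                       ref_genome)
    eff$site <- on_chrom[match(eff$pos, table$pos[on_chrom])]
    base <- data.frame(gene = gene$gene_id, chrom = gene$chrom,
                       N = es$N, S = es$S,
                       codons_counted = es$codons_counted,
                       codons_skipped = es$codons_skipped,
                       stringsAsFactors = FALSE)
    cbind(base, tally(eff, status[eff$site]))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) stop("no gene with countable codons")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

count_effects <- function(eff, which_sites) {
  e <- eff$effect[which_sites]
  # stop-affected changes count as nonsynonymous; SKIPPED excluded
  c(n = sum(e %in% c("NONSYNONYMOUS", "STOP_AFFECTED")),
    s = sum(e == "SYNONYMOUS"))
}

#' Per-gene pN/pS from within-sample polymorphism
#'
#' Counts nonsynonymous (\code{P_N}) and synonymous (\code{P_S}) polymorphic
#' CDS SNPs per gene among the selected samples and reports
#' \code{pnps = (P_N / N) / (P_S / S)}, site-normalized by the
#' [effective_sites()] counts of the reference CDS.  Genes with
#' \code{P_S = 0} have \code{pnps = NA} (flagged): the ratio is only defined
#' for genes with at least one synonymous polymorphism.
#'
#' @param table a [variant_table()].
#' @param genes list of [gene_model()] objects.
#' @param ref_genome reference sequences.
#' @param samples sample ids to use (default all).
#' @return data frame, one row per gene: gene, chrom, N, S, codon tallies,
#'   P_N, P_S, pnps, flags.
#' @export
pnps_table <- function(table, genes, ref_genome, samples = NULL) {
  out <- gene_tables(table, genes, ref_genome, samples,
                     function(eff, status) {
    p <- count_effects(eff, status == "poly")
    data.frame(P_N = p[["n"]], P_S = p[["s"]],
               flags = if (p[["s"]] == 0L) "pnps_undefined:P_S=0" else "",
               stringsAsFactors = FALSE)
  })
  out$pnps <- ifelse(out$P_S >= 1L,
                     (out$P_N / out$N) / (out$P_S / out$S), NA_real_)
  out
}

#' Per-gene fixed differences from the reference genome
#'
#' A site is a fixed difference when every called genotype among the selected
#' samples is homozygous alternate.  Reports \code{E_N}, \code{E_S} (fixed
#' nonsynonymous/synonymous differences) together with the within-sample
#' polymorphism counts, and ranks genes by
#' \code{e_ratio = E_N / (P_N + 1)} (descending); the +1 keeps genes with no
#' amino-acid polymorphism in the ranking.
#'
#' @inheritParams pnps_table
#' @return data frame sorted by \code{e_ratio} descending.
#' @export
fixed_diff_table <- function(table, genes, ref_genome, samples = NULL) {
  out <- gene_tables(table, genes, ref_genome, samples,
                     function(eff, status) {
    p <- count_effects(eff, status == "poly")
    e <- count_effects(eff, status == "fixed_alt")
    data.frame(P_N = p[["n"]], P_S = p[["s"]],
               E_N = e[["n"]], E_S = e[["s"]],
               stringsAsFactors = FALSE)
  })
  out$e_ratio <- out$E_N / (out$P_N + 1)
  out[order(-out$e_ratio), , drop = FALSE]
}

#' Per-gene McDonald-Kreitman tables and Fixation Index
#'
#' For every CDS SNP with a usable outgroup allele: if the in-group is
#' polymorphic the site increments \code{P_N} or \code{P_S}; if the in-group
#' is fixed (all called genotypes identical) and its allele differs from the
#' outgroup allele it increments \code{D_N} or \code{D_S}.  Sites whose
#' outgroup allele matches neither the reference nor the alternate allele are
#' excluded and tallied in \code{sites_skipped}.  The Fixation Index is
#' \code{fi = (D_N / D_S) / (P_N / P_S)}, \code{NA} (with a flag naming the
#' zero cell) whenever \code{D_S}, \code{P_N} or \code{P_S} is zero.
#'
#' @inheritParams pnps_table
#' @param outgroup per-site outgroup alleles from [read_outgroup()] (aligned
#'   with \code{table}; \code{NA} = missing).
#' @param pseudocount optional value added to all four cells before computing
#'   \code{fi} (exploratory ranking only; default 0 reports \code{NA} for
#'   degenerate tables).
#' @return data frame, one row per gene: gene, chrom, N, S, codon tallies,
#'   P_N, P_S, D_N, D_S, sites_skipped, fi, flags.
#' @export
mk_table <- function(table, genes, ref_genome, outgroup, samples = NULL,
                     pseudocount = 0) {
  stopifnot(length(outgroup) == n_sites(table))
  out <- gene_tables(table, genes, ref_genome, samples,
                     function(eff, status) {
    og <- outgroup[eff$site]
    usable <- !is.na(og) & (og == table$ref[eff$site] |
                            og == table$alt[eff$site])
    skipped <- sum(!is.na(og) & !usable)
    # a site polymorphic in-group contributes to P even when the outgroup
    # allele differs (polymorphism takes precedence over divergence)
    p <- count_effects(eff, usable & status == "poly")
    div <- usable &
      ((status == "fixed_ref" & og == table$alt[eff$site]) |
       (status == "fixed_alt" & og == table$ref[eff$site]))
    d <- count_effects(eff, div)
    data.frame(P_N = p[["n"]], P_S = p[["s"]],
               D_N = d[["n"]], D_S = d[["s"]], sites_skipped = skipped,
               stringsAsFactors = FALSE)
  })
  dn <- out$D_N + pseudocount; ds <- out$D_S + pseudocount
  pn <- out$P_N + pseudocount; ps <- out$P_S + pseudocount
  ok <- ds > 0 & pn > 0 & ps > 0
  out$fi <- ifelse(ok, (dn / ds) / (pn / ps), NA_real_)
  out$flags <- ifelse(ok, "", paste0("fi_undefined:", ifelse(ds == 0, "D_S=0",
                              ifelse(ps == 0, "P_S=0", "P_N=0"))))
  out
}
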