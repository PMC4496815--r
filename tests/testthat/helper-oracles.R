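# Independent oracles used to cross-check the package implementations.
# These deliberately use different code paths (quadratic enumeration,
# pair-by-pair counting, a second translation engine) from the functions
# they verify.

# All maximal-scoring segments by quadratic enumeration: find the
# maximum-sum interval (shortest, then leftmost, among ties), remove it,
# recurse on both flanks.
brute_segments <- function(x) {
  out <- list()
  rec <- function(lo, hi) {
    if (lo > hi) return(invisible())
    best <- 0; bi <- NA_integer_; bj <- NA_integer_
    for (i in lo:hi) {
      s <- 0
      for (j in i:hi) {
        s <- s + x[j]
        better <- s > best ||
          (s == best && !is.na(bi) && (j - i) < (bj - bi))
        if (better) { best <- s; bi <- i; bj <- j }
      }
    }
    if (is.na(bi) || best <= 0) return(invisible())
    out[[length(out) + 1L]] <<- c(first = bi, last = bj, score = best)
    rec(lo, bi - 1L)
    rec(bj + 1L, hi)
  }
  rec(1L, length(x))
  if (!length(out))
    return(data.frame(first = integer(), last = integer(), score = numeric()))
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(df$first), , drop = FALSE]
  df$first <- as.integer(df$first)
  df$last <- as.integer(df$last)
  rownames(df) <- NULL
  df
}

# Nei-style synonymous site count for one codon via seqinr's translator:
# fraction of the 9 single-base mutants preserving the amino acid (stops
# count as nonsynonymous), divided by 3 per position.
oracle_syn_sites <- function(codon) {
  tr <- function(s) seqinr::translate(strsplit(s, "")[[1]])
  aa <- tr(codon)
  if (aa == "*") return(NA_real_)
  syn <- 0L
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, p, p)) next
    mut <- codon
    substr(mut, p, p) <- b
    if (tr(mut) == aa) syn <- syn + 1L
  }
  syn / 3
}

# mean pairwise difference via explicit enumeration of chromosome pairs
brute_pi <- function(geno) {
  hap <- do.call(rbind, lapply(seq_len(nrow(geno)), function(s) {
    unlist(lapply(geno[s, ], function(g) {
      if (is.na(g)) stop("brute_pi requires complete genotypes")
      switch(as.character(g), "0" = c(0L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L))
    }))
  }))
  n <- ncol(hap)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(hap[, i] != hap[, j])
  tot / choose(n, 2)
}

# build a small VariantTable from a genotype matrix (sites x samples)
make_table <- function(geno, chrom = "chr1", pos = NULL,
                       ref = "A", alt = "G", qual = 999) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  variant_table(rep(chrom, length.out = n),
                if (is.null(pos)) seq_len(n) * 10L else pos,
                rep(ref, length.out = n), rep(alt, length.out = n),
                rep(qual, length.out = n), geno,
                paste0("s", seq_len(ncol(geno))))
}

# every reported segment must be locally optimal: strictly positive score,
# pairwise disjoint per chromosome, and adding either flanking site never
# increases the score
expect_locally_optimal <- function(segments, track, cutoff) {
  expect_true(all(segments$score > 0))
  for (chrom in unique(segments$chrom)) {
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    seg <- seg[order(seg$first_site), , drop = FALSE]
    if (nrow(seg) > 1)
      expect_true(all(seg$first_site[-1] > seg$last_site[-nrow(seg)]))
    x <- track$score[track$chrom == chrom] - cutoff
    for (r in seq_len(nrow(seg))) {
      if (seg$first_site[r] > 1)
        expect_lte(x[seg$first_site[r] - 1L], 0)
      if (seg$last_site[r] < length(x))
        expect_lte(x[seg$last_site[r] + 1L], 0)
    }
  }
}
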