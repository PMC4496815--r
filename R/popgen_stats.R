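#' Per-site allele frequencies within a sample group
#'
#' @param table a [variant_table()].
#' @param samples sample ids forming the group (default all).
#' @return data frame with one row per site: chrom, pos, \code{n} (called
#'   chromosomes, 2 per called genotype), \code{a} (alternate allele count),
#'   \code{p_alt}, \code{p_ref}.  Sites with \code{n = 0} have \code{NA}
#'   frequencies and should be excluded downstream.
#' @export
allele_freqs <- function(table, samples = NULL) {
  idx <- sample_index(table, samples)
  if (!length(idx)) stop("empty sample group")
  g <- table$geno[, idx, drop = FALSE]
  n <- 2L * rowSums(!is.na(g))
  a <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n > 0L, a / n, NA_real_)
  data.frame(chrom = table$chrom, pos = table$pos, n = n, a = a,
             p_alt = p, p_ref = 1 - p, stringsAsFactors = FALSE)
}

#' Construct a ScoreTrack
#'
#' An ordered per-chromosome (position, score) series, the input of the
#' maximal-segment scanner.  Sites with non-finite scores are dropped.
#'
#' @param chrom,pos,score parallel vectors (pos 0-based).
#' @param provenance tag recording how the scores were produced
#'   ("homozygosity", "fst", "custom").
#' @return data frame of class \code{ScoreTrack}.
#' @export
score_track <- function(chrom, pos, score, provenance = "custom") {
  keep <- is.finite(score)
  df <- data.frame(chrom = as.character(chrom)[keep],
                   pos = as.integer(pos)[keep],
                   score = as.numeric(score)[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(paste(df$chrom, df$pos)))
    stop("duplicate positions in score track")
  rownames(df) <- NULL
  structure(df, class = c("ScoreTrack", "data.frame"),
            provenance = provenance)
}

#' Homozygosity score track
#'
#' Score per site: the squared difference of the alternate and reference
#' allele frequencies, \code{(p_alt - p_ref)^2}.  A site monomorphic within
#' the group scores exactly 1; a site at frequency 1/2 scores 0.  Runs of
#' high-scoring sites are runs of homozygosity (ROH), the footprint of a
#' recent selective sweep.
#'
#' @param freqs output of [allele_freqs()].
#' @return a [score_track()] with provenance "homozygosity"; \code{n = 0}
#'   sites are dropped.
#' @export
homozygosity_scores <- function(freqs) {
  ok <- freqs$n > 0L
  score_track(freqs$chrom[ok], freqs$pos[ok],
              (freqs$p_alt[ok] - freqs$p_ref[ok])^2, "homozygosity")
}

# --- Reich-Patterson FST ---------------------------------------------------

# numerator/denominator of the Reich et al. (2009) estimator from alt counts
# a1, a2 and chromosome counts n1, n2 (vectorized over sites)
reich_terms <- function(a1, n1, a2, n2) {
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  num <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  list(num = num, den = num + h1 + h2)
}

#' Per-SNP Reich-Patterson FST between two groups
#'
#' Unbiased small-sample estimator: with alternate allele count \eqn{a_k}
#' out of \eqn{n_k} called chromosomes in group \eqn{k} and
#' \eqn{h_k = a_k (n_k - a_k) / (n_k (n_k - 1))},
#' \deqn{N = (a_1/n_1 - a_2/n_2)^2 - h_1/n_1 - h_2/n_2, \quad D = N + h_1 + h_2}
#' and per-site FST \eqn{= N / D}.  Negative values arise when variation
#' within groups exceeds variation between them.  Sites where either group
#' has fewer than 2 called chromosomes are skipped; sites with \eqn{D = 0}
#' (both groups monomorphic for the same allele) are \code{NA}.
#'
#' @param table a [variant_table()].
#' @param samples_a,samples_b sample ids of the two groups.
#' @return data frame per site: chrom, pos, num, den, fst.
#' @export
fst_per_snp <- function(table, samples_a, samples_b) {
  fa <- allele_freqs(table, samples_a)
  fb <- allele_freqs(table, samples_b)
  usable <- fa$n >= 2L & fb$n >= 2L
  rt <- reich_terms(fa$a, fa$n, fb$a, fb$n)
  fst <- ifelse(usable & rt$den != 0, rt$num / rt$den, NA_real_)
  data.frame(chrom = table$chrom, pos = table$pos,
             num = ifelse(usable, rt$num, NA_real_),
             den = ifelse(usable, rt$den, NA_real_),
             fst = fst, stringsAsFactors = FALSE)
}

#' Per-SNP FST as a ScoreTrack
#' @inheritParams fst_per_snp
#' @return a [score_track()] of defined per-site FST values.
#' @export
fst_scores <- function(table, samples_a, samples_b) {
  f <- fst_per_snp(table, samples_a, samples_b)
  score_track(f$chrom, f$pos, f$fst, "fst")
}

#' Overall Reich-Patterson FST between two groups
#'
#' Ratio of sums \eqn{\sum N / \sum D} over all usable sites (not the mean of
#' per-site ratios), the standard genome-wide form of the Reich estimator.
#'
#' @inheritParams fst_per_snp
#' @return a single FST estimate.
#' @export
fst_overall <- function(table, samples_a, samples_b) {
  f <- fst_per_snp(table, samples_a, samples_b)
  ok <- !is.na(f$den)
  if (!any(ok)) stop("no site with defined FST numerator/denominator")
  den <- sum(f$den[ok])
  if (den == 0) stop("sum of FST denominators is zero")
  sum(f$num[ok]) / den
}

#' Randomization test for overall FST
#'
#' Compares the observed overall FST between two groups against a null of
#' random disjoint groupings of the same sizes drawn from all samples.
#'
#' @param table a [variant_table()].
#' @param samples_a,samples_b the observed groups.
#' @param reps number of randomized groupings (default 1000).
#' @param seed RNG seed for reproducibility.
#' @return list with \code{observed}, \code{empirical_p} computed with the
#'   +1 rule \eqn{(1 + \#\{F_{rep} \ge F_{obs}\}) / (1 + reps)}, and the
#'   vector \code{null} of replicate FST values.
#' @export
fst_group_randomization <- function(table, samples_a, samples_b,
                                    reps = 1000, seed = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- fst_overall(table, samples_a, samples_b)
  size_a <- length(samples_a); size_b <- length(samples_b)
  if (size_a + size_b > length(table$sample_ids))
    stop("group sizes exceed number of samples")
  null <- vapply(seq_len(reps), function(i) {
    pick <- sample(table$sample_ids, size_a + size_b)
    fst_overall(table, pick[seq_len(size_a)], pick[-seq_len(size_a)])
  }, 0)
  list(observed = observed,
       empirical_p = (1 + sum(null >= observed)) / (1 + reps),
       null = null)
}

# --- Tajima's D and Fay-Wu's H machinery -----------------------------------

#' Variance constants for Tajima's D and the normalized Fay-Wu H
#'
#' Deterministic functions of the number of sampled chromosomes \code{n}:
#' \code{a1 = sum(1/i)}, \code{a2 = sum(1/i^2)} for \code{i < n}, the
#' Tajima (1989) constants \code{b1, b2, c1, c2, e1, e2}, and
#' \code{b_np1 = sum(1/i^2)} for \code{i <= n} used by the Zeng et al.
#' (2006) variance of \eqn{\pi - \theta_L}.
#'
#' @param n number of chromosomes (>= 2).
#' @return named list of constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2),
       b_np1 = a2 + 1 / n^2)
}

# Tajima's D from segregating-site count S and pairwise diversity pi
tajima_d_core <- function(n, S, pi) {
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# pi (mean pairwise differences) from per-site minor/alt counts a out of n
theta_pi <- function(a, n) sum(2 * a * (n - a) / (n * (n - 1)))

# normalized Fay-Wu H (Zeng et al. 2006) from per-site derived counts
faywu_h_core <- function(n, derived) {
  derived <- derived[derived >= 1 & derived <= n - 1]
  S <- length(derived)
  if (S == 0) return(NA_real_)
  k <- tajima_constants(n)
  pi <- theta_pi(derived, n)
  theta_l <- sum(derived) / (n - 1)
  theta_w <- S / k$a1
  theta2 <- S * (S - 1) / (k$a1^2 + k$a2)
  v <- (n - 2) / (6 * (n - 1)) * theta_w +
    (18 * n^2 * (3 * n + 2) * k$b_np1 -
       (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2) * theta2
  (pi - theta_l) / sqrt(v)
}

# window index per site for fixed-width tiling of [0, chrom_length)
window_of <- function(pos, window_bp) pos %/% as.integer(window_bp)

# complete-genotype alt counts for a sample subset; sites with any missing
# genotype are NA unless allow_missing
subset_counts <- function(table, samples, allow_missing = FALSE) {
  idx <- sample_index(table, samples)
  g <- table$geno[, idx, drop = FALSE]
  n_run <- 2L * length(idx)
  a <- rowSums(g, na.rm = TRUE)
  complete <- rowSums(is.na(g)) == 0L
  if (!allow_missing) a[!complete] <- NA_real_
  list(a = a, n = n_run, complete = complete)
}

#' Windowed diversity statistics and Tajima's D
#'
#' Tiles each chromosome with non-overlapping windows of \code{window_bp}
#' (default 5 kb) and reports, per window, the number of segregating sites
#' \code{S}, pairwise diversity \code{pi} (unbiased per-site estimator
#' \eqn{2 a (n - a) / (n (n - 1))}), Watterson's \code{theta_w = S / a1} and
#' Tajima's \code{D} per the original 1989 definition.  \code{D} is \code{NA}
#' when \code{S = 0}.  The chromosome count \code{n} is fixed per run at
#' twice the group size; by default only sites with complete genotypes in
#' the group are used (see \code{allow_missing}).
#'
#' @param table a [variant_table()].
#' @param samples sample ids of the analysis group (default all).
#' @param window_bp window width in bp.
#' @param chrom_lengths optional named vector of chromosome lengths; default
#'   extends to the last SNP.
#' @param allow_missing if \code{TRUE}, sites with missing genotypes keep
#'   their observed allele count while the run-level \code{n} still sets the
#'   variance constants.
#' @return data frame per window: chrom, start, end, n, S, pi, theta_w,
#'   tajima_d.
#' @export
window_stats <- function(table, samples = NULL, window_bp = 5000,
                         chrom_lengths = NULL, allow_missing = FALSE) {
  stopifnot(window_bp > 0)
  sc <- subset_counts(table, samples, allow_missing)
  n <- sc$n
  out <- list()
  for (chrom in unique(table$chrom)) {
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
      chrom_lengths[[chrom]] else max(table$pos[table$chrom == chrom]) + 1L
    nwin <- ceiling(len / window_bp)
    on_chrom <- table$chrom == chrom & !is.na(sc$a)
    w <- window_of(table$pos[on_chrom], window_bp)
    a <- sc$a[on_chrom]
    seg <- a >= 1 & a <= n - 1
    S <- tabulate(w[seg] + 1L, nbins = nwin)
    pi_site <- 2 * a * (n - a) / (n * (n - 1))
    pi <- rowsum_by_window(pi_site[seg], w[seg], nwin)
    k <- tajima_constants(n)
    d <- ifelse(S > 0,
                (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1)),
                NA_real_)
    out[[chrom]] <- data.frame(
      chrom = chrom, start = (seq_len(nwin) - 1L) * window_bp,
      end = pmin(seq_len(nwin) * window_bp, len), n = n, S = S,
      pi = pi, theta_w = S / k$a1, tajima_d = d, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

rowsum_by_window <- function(x, w, nwin) {
  out <- numeric(nwin)
  if (length(x)) {
    agg <- rowsum(x, w)
    out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  out
}

#' Tajima's D over an arbitrary site set
#'
#' Pools the selected sites (e.g. all noncoding, synonymous or nonsynonymous
#' SNPs genome-wide) and applies the same formula as [window_stats()].
#'
#' @param table a [variant_table()].
#' @param samples sample ids of the analysis group (default all).
#' @param site_mask logical or integer index selecting sites of \code{table}.
#' @param allow_missing as in [window_stats()].
#' @return list with \code{n}, \code{S}, \code{pi}, \code{theta_w},
#'   \code{tajima_d}.
#' @export
tajima_d_for_sites <- function(table, samples = NULL, site_mask,
                               allow_missing = FALSE) {
  sub <- table[site_mask]
  if (n_sites(sub) == 0L) stop("site_mask selects no sites")
  sc <- subset_counts(sub, samples, allow_missing)
  a <- sc$a[!is.na(sc$a)]
  n <- sc$n
  seg <- a >= 1 & a <= n - 1
  S <- sum(seg)
  pi <- theta_pi(a[seg], n)
  list(n = n, S = S, pi = pi,
       theta_w = S / tajima_constants(n)$a1,
       tajima_d = tajima_d_core(n, S, pi))
}

#' Windowed normalized Fay-Wu H
#'
#' Polarizes each segregating site with the outgroup allele (outgroup = ref
#' means the alternate allele is derived; outgroup = alt means the reference
#' allele is derived, count \code{n - a}); sites with a missing or
#' third-allele outgroup are excluded.  Reports, per window, \code{theta_l}
#' (the high-frequency-weighted estimator \eqn{\sum i S_i / (n-1)}) and
#' \code{faywu_h_norm}, the Zeng et al. (2006) normalization of
#' \eqn{\pi - \theta_L}; \code{NA} when a window has no polarizable
#' segregating site.
#'
#' @inheritParams window_stats
#' @param outgroup per-site outgroup alleles aligned with \code{table}.
#' @return data frame per window: chrom, start, end, n, S, pi, theta_l,
#'   faywu_h_norm.
#' @export
fay_wu_h_norm <- function(table, samples = NULL, outgroup,
                          window_bp = 5000, chrom_lengths = NULL,
                          allow_missing = FALSE) {
  stopifnot(length(outgroup) == n_sites(table))
  sc <- subset_counts(table, samples, allow_missing)
  n <- sc$n
  derived <- ifelse(outgroup == table$ref, sc$a,
                    ifelse(outgroup == table$alt, n - sc$a, NA_real_))
  out <- list()
  for (chrom in unique(table$chrom)) {
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
      chrom_lengths[[chrom]] else max(table$pos[table$chrom == chrom]) + 1L
    nwin <- ceiling(len / window_bp)
    on_chrom <- table$chrom == chrom & !is.na(derived)
    w <- window_of(table$pos[on_chrom], window_bp)
    d <- derived[on_chrom]
    seg <- d >= 1 & d <= n - 1
    rows <- lapply(seq_len(nwin) - 1L, function(wi) {
      dw <- d[seg & w == wi]
      data.frame(chrom = chrom, start = wi * window_bp,
                 end = min((wi + 1L) * window_bp, len), n = n,
                 S = length(dw), pi = theta_pi(dw, n),
                 theta_l = if (length(dw)) sum(dw) / (n - 1) else 0,
                 faywu_h_norm = faywu_h_core(n, dw),
                 stringsAsFactors = FALSE)
    })
    out[[chrom]] <- do.call(rbind, rows)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
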