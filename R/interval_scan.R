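#' Locally optimal maximal-scoring segments of a score track
#'
#' Subtracts \code{cutoff} from every score and reports all maximal-scoring
#' segments in the Ruzzo-Tompa sense: each reported segment has strictly
#' positive total, no extension or trimming at either end increases its
#' total, and the segments are disjoint and exhaustive.  Zero-sum
#' extensions are not absorbed (a segment stops at its last strictly
#' positive prefix/suffix).  The scan runs in linear time per chromosome.
#'
#' Segment genomic spans run from the first to the last member SNP (+1,
#' half-open); optimality is computed over member scores only, so SNP-free
#' gaps carry no penalty.
#'
#' @param track a [score_track()].
#' @param cutoff value subtracted from every score before scanning.
#' @return data frame per segment: chrom, start, end, first_site, last_site
#'   (indices into the per-chromosome track), n_sites, score.
#' @export
maximal_segments <- function(track, cutoff) {
  out <- lapply(unique(track$chrom), function(chrom) {
    sel <- track$chrom == chrom
    seg <- ruzzo_tompa(track$score[sel] - cutoff)
    if (nrow(seg) == 0L) return(NULL)
    pos <- track$pos[sel]
    data.frame(chrom = chrom, start = pos[seg$first], end = pos[seg$last] + 1L,
               first_site = seg$first, last_site = seg$last,
               n_sites = seg$last - seg$first + 1L, score = seg$score,
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), first_site = integer(),
                      last_site = integer(), n_sites = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Ruzzo-Tompa linear-time all-maximal-scoring-subsequences algorithm.
# x: transformed scores.  Returns data.frame(first, last, score), 1-based.
# Cumulative bounds come from cumsum() so segment scores share the same
# floating-point accumulation as the permutation-null maxima.
ruzzo_tompa <- function(x) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  # stack of candidate subsequences: L/R cumulative bounds, first/last index
  Ls <- Rs <- numeric(n); firsts <- lasts <- integer(n)
  top <- 0L
  for (k in seq_len(n)) {
    if (x[k] <= 0) next
    L <- cs[k]; R <- cs[k + 1L]; f <- k; l <- k
    repeat {
      # rightmost stacked candidate with L_j < L
      j <- top
      while (j >= 1L && Ls[j] >= L) j <- j - 1L
      if (j == 0L || Rs[j] >= R) {
        top <- top + 1L
        Ls[top] <- L; Rs[top] <- R; firsts[top] <- f; lasts[top] <- l
        break
      }
      # merge: extend left over candidates j..top
      L <- Ls[j]; f <- firsts[j]
      top <- j - 1L
    }
  }
  if (top == 0L)
    return(data.frame(first = integer(), last = integer(), score = numeric()))
  idx <- seq_len(top)
  data.frame(first = firsts[idx], last = lasts[idx],
             score = Rs[idx] - Ls[idx])
}

#' Nearest-rank percentile cutoff for a score track
#'
#' The empirical \code{1 - top_fraction} quantile of the defined scores,
#' computed genome-wide across chromosomes by the nearest-rank rule
#' (\code{sorted[ceiling((1 - top_fraction) * n)]}).  With
#' \code{top_fraction = 0.10} the returned cutoff puts the top-scoring 10\%
#' of sites above it.  If all scores are identical the cutoff equals that
#' value and the scanner returns no segments.
#'
#' @param track a [score_track()] (or numeric vector of scores).
#' @param top_fraction fraction of scores to leave above the cutoff,
#'   in (0, 1).
#' @return the cutoff value.
#' @export
percentile_cutoff <- function(track, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  scores <- if (is.numeric(track)) track else track$score
  scores <- scores[is.finite(scores)]
  if (!length(scores)) stop("no defined scores")
  sort(scores)[max(1L, ceiling((1 - top_fraction) * length(scores)))]
}

# maximum contiguous-subarray sum (0 when all values are <= 0), vectorized
max_segment_score <- function(x) {
  if (!length(x)) return(0)
  cs <- cumsum(x)
  max(0, max(cs - cummin(c(0, cs[-length(cs)]))))
}

#' Empirical p-values for maximal segments by score permutation
#'
#' Runs [maximal_segments()] on the observed track, then builds a null by
#' permuting the score-to-position assignment (within each chromosome by
#' default, preserving per-chromosome score distribution and site density)
#' and recording each replicate's maximum segment score across the whole
#' scan.  Each observed segment gets
#' \code{empirical_p = (1 + #\{replicate maxima >= score\}) / (1 + reps)},
#' a family-wise p-value; only segments with \code{empirical_p < p_max}
#' are reported.  With the defaults (\code{reps = 1000},
#' \code{p_max = 0.001}) a segment is reported only when its score exceeds
#' every replicate maximum, giving \code{p = 1/1001}.
#'
#' @param track a [score_track()].
#' @param cutoff value subtracted from scores (see [percentile_cutoff()]).
#' @param reps number of permutation replicates.
#' @param seed RNG seed.
#' @param p_max report segments with empirical p strictly below this.
#' @param within_chrom permute within chromosomes (default) or genome-wide.
#' @return data frame as [maximal_segments()] plus \code{empirical_p},
#'   sorted by score descending.
#' @export
empirical_pvalues <- function(track, cutoff, reps = 1000, seed = NULL,
                              p_max = 0.001, within_chrom = TRUE) {
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- maximal_segments(track, cutoff)
  if (nrow(obs) == 0L) {
    obs$empirical_p <- numeric()
    return(obs)
  }
  x <- track$score - cutoff
  by_chrom <- if (within_chrom) split(x, track$chrom) else list(x)
  null_max <- vapply(seq_len(reps), function(i) {
    max(vapply(by_chrom, function(xs) max_segment_score(sample(xs)), 0))
  }, 0)
  obs$empirical_p <- vapply(obs$score, function(s)
    (1 + sum(null_max >= s)) / (1 + reps), 0)
  obs <- obs[obs$empirical_p < p_max, , drop = FALSE]
  obs <- obs[order(-obs$score), , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

#' Intersect scored intervals with gene models
#'
#' Emits a (gene, interval) pair whenever the gene's genomic span (first to
#' last CDS base) and the interval overlap by at least 1 bp; both sides use
#' 0-based half-open coordinates, so abutting features do not overlap.
#'
#' @param intervals data frame with chrom, start, end (e.g. from
#'   [empirical_pvalues()]).
#' @param genes list of [gene_model()] objects.
#' @return data frame of pairs: gene, chrom, gene_start, gene_end, start,
#'   end, score, empirical_p (when present).
#' @export
intersect_genes <- function(intervals, genes) {
  empty <- data.frame(gene = character(), chrom = character(),
                      gene_start = integer(), gene_end = integer(),
                      start = integer(), end = integer(),
                      score = numeric(), empirical_p = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(genes) || nrow(intervals) == 0L) return(empty)
  spans <- t(vapply(genes, gene_span, c(start = 0L, end = 0L)))
  gr_genes <- GenomicRanges::GRanges(
    vapply(genes, `[[`, "", "chrom"),
    IRanges::IRanges(start = spans[, "start"] + 1L, end = spans[, "end"]))
  gr_iv <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_iv)
  if (!length(hits)) return(empty)
  gi <- S4Vectors::queryHits(hits); ii <- S4Vectors::subjectHits(hits)
  data.frame(
    gene = vapply(genes, `[[`, "", "gene_id")[gi],
    chrom = intervals$chrom[ii],
    gene_start = spans[gi, "start"], gene_end = spans[gi, "end"],
    start = intervals$start[ii], end = intervals$end[ii],
    score = intervals$score[ii],
    empirical_p = if ("empirical_p" %in% names(intervals))
      intervals$empirical_p[ii] else NA_real_,
    stringsAsFactors = FALSE)
}
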