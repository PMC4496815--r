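#' Simulate one neutral coalescent window
#'
#' Standard neutral coalescent without recombination under the
#' infinite-sites model: coalescence times are exponential with rate
#' \eqn{k (k - 1) / 2} while \eqn{k} lineages remain (coalescent time
#' units); the number of mutations is Poisson with mean
#' \eqn{\theta T_{total} / 2} and each mutation falls on a branch with
#' probability proportional to its length, deriving all samples below it.
#' Site positions are uniform on \code{[0, 1)} so windowed code paths can be
#' exercised.  Expected values: \eqn{E[S] = \theta a_1(n)} and
#' \eqn{E[\pi] = \theta}.
#'
#' @param n number of sampled chromosomes (>= 2).
#' @param theta population-scaled mutation rate \eqn{4 N_e \mu} per window.
#' @param seed RNG seed (optional).
#' @return list of class \code{HaplotypeSample}: \code{haplotypes}
#'   (\code{n x S} 0/1 matrix, 1 = derived), \code{derived} (per-site
#'   derived-allele counts), \code{positions} (uniform in [0, 1), sorted),
#'   \code{n}, \code{theta}, \code{seed}.
#' @export
coalescent_window <- function(n, theta, seed = NULL) {
  stopifnot(n >= 2, theta > 0)
  if (!is.null(seed)) set.seed(seed)
  # active lineages: list of leaf index vectors + pending branch lengths
  leaves <- as.list(seq_len(n))
  pend <- numeric(n)
  branch_leaves <- vector("list", 2L * (n - 1L))
  branch_len <- numeric(2L * (n - 1L))
  nb <- 0L
  k <- n
  while (k > 1L) {
    pend <- pend + stats::rexp(1L, k * (k - 1L) / 2)
    pair <- sample.int(k, 2L)
    i <- min(pair); j <- max(pair)
    for (b in c(i, j)) {
      nb <- nb + 1L
      branch_leaves[[nb]] <- leaves[[b]]
      branch_len[nb] <- pend[b]
    }
    leaves[[i]] <- c(leaves[[i]], leaves[[j]])
    pend[i] <- 0
    leaves[[j]] <- NULL
    pend <- pend[-j]
    k <- k - 1L
  }
  total <- sum(branch_len)
  m <- stats::rpois(1L, theta * total / 2)
  if (m > 0L) {
    hit <- sample.int(nb, m, replace = TRUE, prob = branch_len)
    posn <- sort(stats::runif(m))
    hap <- matrix(0L, nrow = n, ncol = m)
    for (s in seq_len(m)) hap[branch_leaves[[hit[s]]], s] <- 1L
  } else {
    posn <- numeric(0)
    hap <- matrix(0L, nrow = n, ncol = 0L)
  }
  structure(list(haplotypes = hap, derived = colSums(hap), positions = posn,
                 n = n, theta = theta, seed = seed),
            class = "HaplotypeSample")
}

#' @export
print.HaplotypeSample <- function(x, ...) {
  cat("HaplotypeSample: n =", x$n, ", S =", length(x$derived),
      ", theta =", x$theta, "\n")
  invisible(x)
}

# D and normalized H for one simulated window (ancestral state known)
sim_window_stats <- function(hs) {
  d <- hs$derived
  S <- length(d)
  pi <- theta_pi(d, hs$n)
  list(S = S, pi = pi,
       tajima_d = tajima_d_core(hs$n, S, pi),
       faywu_h_norm = faywu_h_core(hs$n, d))
}

#' Calibrate significance cutoffs from neutral coalescent simulations
#'
#' Simulates \code{reps} independent neutral windows at the data-estimated
#' \eqn{\hat\theta} (mean segregating sites per window divided by
#' \eqn{a_1(n)}), computes Tajima's D and the normalized Fay-Wu H on each
#' (ancestral states are known to the simulator), and returns the empirical
#' lower-tail \code{alpha} quantiles as significance cutoffs.  With
#' \code{experiment_wide = TRUE} the null statistic is instead the minimum
#' over \code{n_windows} windows per replicate, giving an experiment-wide
#' (multiple-testing corrected) cutoff in the spirit of Nielsen et al.
#' (2005).
#'
#' @param n number of chromosomes.
#' @param theta_hat estimated theta per window (from the observed mean
#'   segregating-site count: \code{theta_hat = S_bar / a1}).
#' @param alpha lower-tail probability of the cutoff (default 0.05).
#' @param reps number of simulated windows (or replicates when
#'   \code{experiment_wide}); at least 100.
#' @param n_windows windows per replicate in experiment-wide mode.
#' @param seed RNG seed.
#' @param experiment_wide take per-replicate minima over \code{n_windows}
#'   windows.
#' @return list of class \code{CalibrationResult}: \code{cutoff_d},
#'   \code{cutoff_h}, \code{null_d}, \code{null_h}, plus the call
#'   parameters.
#' @export
calibrate_cutoffs <- function(n, theta_hat, alpha = 0.05, reps = 1000,
                              n_windows = 1, seed = NULL,
                              experiment_wide = FALSE) {
  stopifnot(theta_hat > 0, reps >= 100, alpha > 0, alpha < 1)
  if (!is.null(seed)) set.seed(seed)
  one_rep <- function() {
    if (!experiment_wide) {
      sim_window_stats(coalescent_window(n, theta_hat))
    } else {
      ws <- lapply(seq_len(n_windows), function(i)
        sim_window_stats(coalescent_window(n, theta_hat)))
      list(tajima_d = suppressWarnings(
             min(unlist(lapply(ws, `[[`, "tajima_d")), na.rm = TRUE)),
           faywu_h_norm = suppressWarnings(
             min(unlist(lapply(ws, `[[`, "faywu_h_norm")), na.rm = TRUE)))
    }
  }
  stats_list <- lapply(seq_len(reps), function(i) one_rep())
  null_d <- vapply(stats_list, function(s)
    if (is.finite(s$tajima_d %||% NA)) s$tajima_d else NA_real_, 0)
  null_h <- vapply(stats_list, function(s)
    if (is.finite(s$faywu_h_norm %||% NA)) s$faywu_h_norm else NA_real_, 0)
  if (all(is.na(null_d)))
    stop("all simulated windows monomorphic; increase theta_hat or reps")
  structure(list(
    n = n, theta_hat = theta_hat, alpha = alpha, reps = reps,
    n_windows = n_windows, experiment_wide = experiment_wide,
    cutoff_d = stats::quantile(null_d, alpha, na.rm = TRUE, names = FALSE,
                               type = 1),
    cutoff_h = stats::quantile(null_h, alpha, na.rm = TRUE, names = FALSE,
                               type = 1),
    null_d = null_d, null_h = null_h), class = "CalibrationResult")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.CalibrationResult <- function(x, ...) {
  cat("CalibrationResult: n =", x$n, ", theta_hat =", x$theta_hat,
      ", alpha =", x$alpha,
      if (x$experiment_wide) "(experiment-wide)\n" else "(per-window)\n")
  cat("  cutoff_d =", x$cutoff_d, "; cutoff_h =", x$cutoff_h, "\n")
  invisible(x)
}

# --- synthetic fixtures ----------------------------------------------------

#' Two-deme island-model genotype fixture (Balding-Nichols)
#'
#' Per SNP, an ancestral frequency \eqn{p \sim U(0.05, 0.95)} is drawn and
#' each deme's frequency from \eqn{Beta(p (1 - F) / F, (1 - p)(1 - F)/F)}
#' with \eqn{F} the target FST; diploid genotypes are binomial samples from
#' the deme frequency.  \code{target_fst = 0} collapses both demes onto the
#' ancestral frequency (one panmictic pool).  The Reich-Patterson overall
#' estimator recovers \code{target_fst} on this fixture.
#'
#' @param n_per_deme diploid sample sizes, length-2 vector (or scalar used
#'   for both demes).
#' @param n_snps number of SNP sites.
#' @param target_fst Balding-Nichols F, in [0, 1).
#' @param seed RNG seed.
#' @param chrom chromosome name for the simulated sites.
#' @return list with \code{table} (a [variant_table()]) and \code{pops}
#'   (a [population_spec()] with groups "demeA" and "demeB").
#' @export
island_fixture <- function(n_per_deme = c(3, 5), n_snps = 1000,
                           target_fst = 0, seed = NULL, chrom = "sim1") {
  stopifnot(target_fst >= 0, target_fst < 1)
  if (!is.null(seed)) set.seed(seed)
  if (length(n_per_deme) == 1L) n_per_deme <- rep(n_per_deme, 2L)
  p <- stats::runif(n_snps, 0.05, 0.95)
  f <- target_fst
  deme_freq <- function() {
    if (f == 0) p
    else stats::rbeta(n_snps, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  pa <- deme_freq(); pb <- deme_freq()
  geno <- cbind(
    matrix(stats::rbinom(n_snps * n_per_deme[1], 2L, pa), nrow = n_snps),
    matrix(stats::rbinom(n_snps * n_per_deme[2], 2L, pb), nrow = n_snps))
  ids <- c(paste0("A", seq_len(n_per_deme[1])),
           paste0("B", seq_len(n_per_deme[2])))
  tab <- variant_table(rep(chrom, n_snps), seq_len(n_snps) * 100L,
                       rep("A", n_snps), rep("G", n_snps),
                       rep(999, n_snps), geno, ids)
  list(table = tab,
       pops = population_spec(list(demeA = ids[seq_len(n_per_deme[1])],
                                   demeB = ids[-seq_len(n_per_deme[1])])))
}

#' Selective-sweep (run-of-homozygosity) genotype fixture
#'
#' Two groups of diploids; background sites are guaranteed polymorphic in
#' both groups, while a contiguous tract of \code{tract_len} sites is
#' monomorphic (all homozygous reference) in group A only, so its
#' homozygosity score is exactly 1.0 across the tract.  Exercises the ROH
#' scan end to end: with the usual 0.9 cutoff the tract is the only segment
#' and survives permutation testing.
#'
#' @param n_samples total diploids, split evenly between groups A and B.
#' @param length_snps number of background SNP sites.
#' @param tract_len sites in the monomorphic tract (0 = no sweep), inserted
#'   mid-chromosome.
#' @param seed RNG seed.
#' @param spacing_bp distance between adjacent SNPs.
#' @return list with \code{table}, \code{pops} (groups "groupA", "groupB"),
#'   and \code{tract} (0-based half-open tract span, NULL when
#'   \code{tract_len = 0}).
#' @export
sweep_fixture <- function(n_samples = 8, length_snps = 1000, tract_len = 50,
                          seed = NULL, spacing_bp = 50L) {
  stopifnot(tract_len < length_snps, n_samples >= 4)
  if (!is.null(seed)) set.seed(seed)
  na <- ceiling(n_samples / 2); nb <- n_samples - na
  n_total <- length_snps + tract_len
  # background: redraw until polymorphic within both groups
  draw_poly <- function(n_sites, n_dip) {
    g <- matrix(0L, n_sites, n_dip)
    todo <- seq_len(n_sites)
    while (length(todo)) {
      p <- stats::runif(length(todo), 0.25, 0.75)
      g[todo, ] <- stats::rbinom(length(todo) * n_dip, 2L, rep(p, n_dip))
      ac <- rowSums(g[todo, , drop = FALSE])
      todo <- todo[ac == 0L | ac == 2L * n_dip]
    }
    g
  }
  ga <- draw_poly(n_total, na)
  gb <- draw_poly(n_total, nb)
  tract <- NULL
  if (tract_len > 0L) {
    at <- floor(length_snps / 2) + seq_len(tract_len)
    ga[at, ] <- 0L                      # monomorphic hom-ref in group A only
    tract <- c(start = (min(at) - 1L) * spacing_bp,
               end = (max(at) - 1L) * spacing_bp + 1L)
  }
  ids <- c(paste0("A", seq_len(na)), paste0("B", seq_len(nb)))
  tab <- variant_table(rep("sweep1", n_total),
                       (seq_len(n_total) - 1L) * spacing_bp,
                       rep("C", n_total), rep("T", n_total),
                       rep(999, n_total), cbind(ga, gb), ids)
  list(table = tab,
       pops = population_spec(list(groupA = ids[seq_len(na)],
                                   groupB = ids[-seq_len(na)])),
       tract = tract)
}

#' Toy coding-gene fixture with a known SNP plan
#'
#' Builds a mini reference chromosome containing one gene, an annotation for
#' it and a variant table realizing a list of planned SNPs with known coding
#' effects, optionally with per-site outgroup alleles.  Each plan entry is a
#' list/row with fields:
#' \describe{
#'   \item{codon}{1-based codon index within the CDS.}
#'   \item{codon_pos}{0-based position within the codon (transcription
#'     frame).}
#'   \item{ref_codon}{optional codon to place at that position in the CDS;
#'     when omitted the randomly drawn codon is kept.}
#'   \item{alt}{alternate base in transcription orientation.}
#'   \item{class}{intended effect ("SYNONYMOUS", "NONSYNONYMOUS",
#'     "STOP_AFFECTED"); verified against [classify_snp()], error on
#'     conflict.}
#'   \item{kind}{"poly" (one heterozygote), "fixed" (all samples hom-alt) or
#'     "divergence" (all hom-ref, outgroup = alt).}
#' }
#'
#' @param n_codons CDS length in codons (stop codon appended after them).
#' @param snp_plan data frame or list of plan entries (may be empty).
#' @param base_codon if non-NULL, every codon is initialized to this codon
#'   (e.g. "GGG" for a gene of known effective site counts) before plan
#'   entries override individual codons; default draws random sense codons.
#' @param seed RNG seed for the random codons and flanks.
#' @param strand place the gene on "+" or "-".
#' @param n_samples diploid samples in the variant table.
#' @param dir if non-NULL, also write \code{ref.fa}, \code{genes.gff3},
#'   \code{variants.vcf} and \code{outgroup.tsv} into this directory.
#' @return list with \code{ref} (named character), \code{gene}
#'   (a [gene_model()]), \code{table}, \code{outgroup}, \code{effects}
#'   (verified [classify_snp()] rows) and \code{paths} (when written).
#' @export
coding_gene_fixture <- function(n_codons, snp_plan = NULL,
                                base_codon = NULL, seed = NULL,
                                strand = "+", n_samples = 4, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  plan <- normalize_plan(snp_plan)
  gc <- genetic_code()
  sense <- names(gc)[gc != "*" ]
  codons <- if (is.null(base_codon)) sample(sense, n_codons, replace = TRUE)
            else rep(toupper(base_codon), n_codons)
  for (i in seq_len(nrow(plan))) {
    if (!is.na(plan$ref_codon[i])) codons[plan$codon[i]] <- plan$ref_codon[i]
  }
  cds <- paste(c(codons, "TAA"), collapse = "")   # includes the stop codon
  flank <- 30L
  rand_bases <- function(k) paste(sample(BASES, k, TRUE), collapse = "")
  chromseq_fwd <- paste0(rand_bases(flank), cds, rand_bases(flank))
  gene_start <- flank
  gene_end <- flank + nchar(cds)
  if (strand == "+") {
    chromseq <- chromseq_fwd
  } else {
    chromseq <- revcomp(chromseq_fwd)
    tot <- nchar(chromseq)
    new_start <- tot - gene_end
    gene_end <- tot - gene_start
    gene_start <- new_start
  }
  ref <- stats::setNames(chromseq, "toy1")
  gene <- gene_model("toygene1", "toy1", strand, gene_start, gene_end)

  n_snps <- nrow(plan)
  if (n_snps > 0L) {
    off <- (plan$codon - 1L) * 3L + plan$codon_pos      # CDS offset, 0-based
    pos <- if (strand == "+") gene_start + off else gene_end - 1L - off
    ref_base <- substring(chromseq, pos + 1L, pos + 1L)
    alt_base <- if (strand == "+") toupper(plan$alt)
                else chartr("ACGT", "TGCA", toupper(plan$alt))
    if (any(ref_base == alt_base))
      stop("snp_plan conflicts with generated sequence: alt equals ref at ",
           "codon ", plan$codon[which(ref_base == alt_base)[1]])
    o <- order(pos)
    plan <- plan[o, , drop = FALSE]
    pos <- pos[o]; ref_base <- ref_base[o]; alt_base <- alt_base[o]
    geno <- matrix(0L, n_snps, n_samples)
    geno[plan$kind == "poly", 1L] <- 1L
    geno[plan$kind == "fixed", ] <- 2L
    outgroup <- ifelse(plan$kind == "divergence", alt_base, ref_base)
    tab <- variant_table(rep("toy1", n_snps), pos, ref_base, alt_base,
                         rep(999, n_snps), geno,
                         paste0("s", seq_len(n_samples)))
    effects <- snp_effects(gene, data.frame(pos = pos, ref = ref_base,
                                            alt = alt_base), ref)
    bad <- which(effects$effect != plan$class)
    if (length(bad))
      stop("snp_plan conflicts with generated sequence: codon ",
           plan$codon[bad[1]], " gives ", effects$effect[bad[1]],
           " not ", plan$class[bad[1]])
  } else {
    tab <- variant_table(character(), integer(), character(), character(),
                         numeric(), matrix(integer(), 0L, n_samples),
                         paste0("s", seq_len(n_samples)))
    outgroup <- character(0)
    effects <- NULL
  }

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "ref.fa"),
                  gff = file.path(dir, "genes.gff3"),
                  vcf = file.path(dir, "variants.vcf"),
                  outgroup = file.path(dir, "outgroup.tsv"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), paths$fasta)
    write_gff_cds(list(gene), paths$gff)
    write_vcf(tab, paths$vcf)
    write_outgroup(tab, outgroup, paths$outgroup)
  }
  list(ref = ref, gene = gene, table = tab, outgroup = outgroup,
       effects = effects, plan = plan, paths = paths)
}

normalize_plan <- function(snp_plan) {
  if (is.null(snp_plan) ||
      (is.data.frame(snp_plan) && nrow(snp_plan) == 0L) ||
      (is.list(snp_plan) && !is.data.frame(snp_plan) &&
         length(snp_plan) == 0L))
    return(data.frame(codon = integer(), codon_pos = integer(),
                      ref_codon = character(), alt = character(),
                      class = character(), kind = character(),
                      stringsAsFactors = FALSE))
  df <- if (is.data.frame(snp_plan)) snp_plan
        else do.call(rbind, lapply(snp_plan, as.data.frame))
  if (is.null(df$ref_codon)) df$ref_codon <- NA_character_
  if (is.null(df$kind)) df$kind <- "poly"
  stopifnot(all(df$kind %in% c("poly", "fixed", "divergence")),
            all(df$codon_pos %in% 0:2))
  if (anyDuplicated(paste(df$codon, df$codon_pos)))
    stop("snp_plan places two SNPs at the same codon position")
  df
}
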