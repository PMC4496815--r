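test_that("coalescent windows match closed-form expectations for S and pi", {
  set.seed(61)
  reps <- 10000
  # n = 2: E[S] = theta * a1(2) = theta
  S2 <- replicate(reps, length(coalescent_window(2, 2)$derived))
  se2 <- sd(S2) / sqrt(reps)
  expect_lt(abs(mean(S2) - 2), 3 * se2)

  # n = 10, theta = 5: E[S] = 5 * a1(10) = 14.1448...
  sims <- replicate(reps, {
    hs <- coalescent_window(10, 5)
    c(S = length(hs$derived), pi = apisweep:::theta_pi(hs$derived, 10))
  })
  expect_lt(abs(mean(sims["S", ]) - 5 * tajima_constants(10)$a1),
            3 * sd(sims["S", ]) / sqrt(reps))
  # E[pi] = theta
  expect_lt(abs(mean(sims["pi", ]) - 5), 3 * sd(sims["pi", ]) / sqrt(reps))
})

test_that("simulated derived counts are proper polymorphisms and seeds reproduce", {
  hs <- coalescent_window(8, 10, seed = 62)
  expect_true(all(hs$derived >= 1 & hs$derived <= 7))
  expect_equal(hs$derived, colSums(hs$haplotypes))
  expect_equal(ncol(hs$haplotypes), length(hs$positions))
  expect_false(is.unsorted(hs$positions))

  hs2 <- coalescent_window(8, 10, seed = 62)
  expect_identical(hs$haplotypes, hs2$haplotypes)
  expect_identical(hs$positions, hs2$positions)
})

test_that("calibrated cutoffs are the stated empirical quantiles and are MC-stable", {
  cal1 <- calibrate_cutoffs(22, 5, alpha = 0.05, reps = 4000, seed = 63)
  expect_equal(cal1$cutoff_d,
               stats::quantile(cal1$null_d, 0.05, na.rm = TRUE,
                               names = FALSE, type = 1))
  cal2 <- calibrate_cutoffs(22, 5, alpha = 0.05, reps = 4000, seed = 64)
  expect_lt(abs(cal1$cutoff_d - cal2$cutoff_d), 0.1)
  expect_lt(abs(cal1$cutoff_h - cal2$cutoff_h), 0.15)

  # alpha = 0.5 puts the cutoff near the centre of the null distribution
  cal_med <- calibrate_cutoffs(22, 5, alpha = 0.5, reps = 4000, seed = 65)
  expect_lt(abs(cal_med$cutoff_d - mean(cal_med$null_d, na.rm = TRUE)), 0.1)

  expect_error(calibrate_cutoffs(22, 5, reps = 10), "reps")
})

test_that("experiment-wide calibration uses per-replicate minima", {
  per_window <- calibrate_cutoffs(10, 5, alpha = 0.05, reps = 400, seed = 66)
  expwide <- calibrate_cutoffs(10, 5, alpha = 0.05, reps = 400,
                               n_windows = 10, seed = 66,
                               experiment_wide = TRUE)
  # the minimum over 10 windows is stochastically smaller
  expect_lt(expwide$cutoff_d, per_window$cutoff_d)
})

test_that("island fixtures recover the target FST and reproduce under a seed", {
  fx <- island_fixture(c(3, 5), 20000, 0.05, seed = 67)
  est <- fst_overall(fx$table, fx$pops$demeA, fx$pops$demeB)
  expect_lt(abs(est - 0.05), 0.015)

  fx2 <- island_fixture(c(3, 5), 200, 0.05, seed = 68)
  fx3 <- island_fixture(c(3, 5), 200, 0.05, seed = 68)
  expect_identical(fx2$table$geno, fx3$table$geno)
})

test_that("sweep fixtures plant a tract monomorphic in group A only", {
  sw <- sweep_fixture(8, 500, 30, seed = 69)
  in_tract <- sw$table$pos >= sw$tract["start"] & sw$table$pos < sw$tract["end"]
  expect_equal(sum(in_tract), 30L)
  fa <- allele_freqs(sw$table, sw$pops$groupA)
  fb <- allele_freqs(sw$table, sw$pops$groupB)
  expect_true(all(fa$p_alt[in_tract] == 0))
  # background polymorphic within both groups
  expect_true(all(fa$a[!in_tract] > 0 & fa$a[!in_tract] < fa$n[!in_tract]))
  expect_true(all(fb$a > 0 & fb$a < fb$n))

  sw0 <- sweep_fixture(8, 500, 0, seed = 70)
  expect_null(sw0$tract)
  expect_equal(n_sites(sw0$table), 500L)
})

test_that("coding-gene fixtures realize their SNP plan and write valid files", {
  plan <- data.frame(codon = c(2L, 5L), codon_pos = c(0L, 2L),
                     ref_codon = "GGG", alt = "A",
                     class = c("NONSYNONYMOUS", "SYNONYMOUS"),
                     kind = "poly")
  dir <- withr::local_tempdir()
  fx <- coding_gene_fixture(10, plan, seed = 71, dir = dir)
  expect_equal(sort(fx$effects$effect), c("NONSYNONYMOUS", "SYNONYMOUS"))

  # files round-trip through the standard readers into the same analysis
  ref <- Biostrings::readDNAStringSet(fx$paths$fasta)
  genes <- read_gff_cds(fx$paths$gff)
  tab <- read_vcf(fx$paths$vcf, min_qual = 0)
  expect_equal(genes[[1]]$intervals$start, fx$gene$intervals$start)
  expect_equal(genes[[1]]$intervals$end, fx$gene$intervals$end)
  counts <- pnps_table(tab, genes, ref)
  expect_equal(counts$P_N, 1L)
  expect_equal(counts$P_S, 1L)

  # outgroup file aligns with the table
  og <- read_outgroup(fx$paths$outgroup, tab)
  expect_equal(og, fx$outgroup)

  # an impossible plan is a conflict, not a silent reinterpretation
  bad <- data.frame(codon = 2L, codon_pos = 0L, ref_codon = "GGG",
                    alt = "A", class = "SYNONYMOUS", kind = "poly")
  expect_error(coding_gene_fixture(10, bad, seed = 71), "conflict")

  # empty plan -> empty table, zero counts
  fx0 <- coding_gene_fixture(5, NULL, seed = 72)
  expect_equal(n_sites(fx0$table), 0L)
})

test_that("the command-line interface drives an ROH scan end to end", {
  dir <- withr::local_tempdir()
  sw <- sweep_fixture(8, 300, 20, seed = 73)
  vcf <- file.path(dir, "v.vcf"); pops <- file.path(dir, "p.tsv")
  out <- file.path(dir, "roh.bed")
  write_vcf(sw$table, vcf)
  write_populations(sw$pops, pops)
  expect_message(
    apisweep_main(c("roh", "--vcf", vcf, "--pops", pops, "--group", "groupA",
                    "--cutoff", "0.9", "--reps", "200", "--seed", "7",
                    "--p-max", "0.01", "--min-qual", "0", "--out", out)),
    "interval")
  iv <- read_intervals(out)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, unname(sw$tract["start"]))

  expect_output(apisweep_main(character()), "usage")
})
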