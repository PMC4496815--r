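test_that("effective site counts match hand-derived codon values", {
  tt <- effective_sites("TTT")
  expect_equal(tt$S, 1 / 3)
  expect_equal(tt$N, 8 / 3)
  atg <- effective_sites("ATG")   # Met has no synonymous mutant
  expect_equal(atg$S, 0)
  expect_equal(atg$N, 3)
  ggg <- effective_sites(strrep("GGG", 10))  # 4-fold degenerate third position
  expect_equal(ggg$S, 10)
  expect_equal(ggg$N, 20)
  expect_equal(ggg$codons_counted, 10L)
})

test_that("effective sites agree with exhaustive single-mutant enumeration for all sense codons", {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  expect_length(sense, 61L)
  for (codon in sense) {
    got <- effective_sites(codon)
    expect_equal(got$S, oracle_syn_sites(codon), info = codon)
    expect_equal(got$N + got$S, 3, info = codon)   # n = 3 - s per codon
  }
  # summed over the 61 sense codons the total is exactly 183
  tot <- effective_sites(paste(sense, collapse = ""))
  expect_equal(tot$N + tot$S, 183)
  expect_equal(tot$codons_counted, 61L)
})

test_that("stop codons and ambiguous codons are skipped and tallied", {
  x <- effective_sites("GGGTAANGGGGG")   # stop + codon containing N
  expect_equal(x$codons_counted, 2L)
  expect_equal(x$codons_skipped, 2L)
  expect_equal(x$S, 2)
  expect_error(effective_sites("GGGA"), "divisible by 3")
})

test_that("classify_snp translates substitutions in the correct frame", {
  ref <- c(chr = paste0(strrep("T", 6), "AAAAAA", strrep("T", 6)))
  gene <- gene_model("g", "chr", "+", 6L, 12L)   # CDS = AAAAAA, 2 codons
  syn <- classify_snp(gene, pos = 8L, ref = "A", alt = "G", ref_genome = ref)
  expect_equal(syn$effect, "SYNONYMOUS")         # AAA -> AAG, Lys -> Lys
  expect_equal(syn$codon_pos, 2L)
  non <- classify_snp(gene, pos = 6L, ref = "A", alt = "G", ref_genome = ref)
  expect_equal(non$effect, "NONSYNONYMOUS")      # AAA -> GAA, Lys -> Glu
  expect_equal(non$codon_pos, 0L)
  expect_error(classify_snp(gene, pos = 2L, ref = "T", alt = "G", ref),
               "outside CDS")
  expect_error(classify_snp(gene, pos = 7L, ref = "C", alt = "G", ref),
               "disagrees")
})

test_that("minus-strand classification works through the reverse complement", {
  # genomic TTC on the minus strand is transcribed as GAA (Glu); the genomic
  # C pairs with codon position 0, and C->T makes the codon AAA (Lys)
  ref <- c(chr = paste0(strrep("G", 5), "TTC", strrep("G", 5)))
  gene <- gene_model("g", "chr", "-", 5L, 8L)
  hit <- classify_snp(gene, pos = 7L, ref = "C", alt = "T", ref_genome = ref)
  expect_equal(hit$ref_codon, "GAA")
  expect_equal(hit$alt_codon, "AAA")
  expect_equal(hit$codon_pos, 0L)
  expect_equal(hit$effect, "NONSYNONYMOUS")
})

test_that("strand symmetry: the same codon plan classifies identically on both strands", {
  plan <- data.frame(codon = c(2L, 5L, 8L), codon_pos = c(0L, 2L, 1L),
                     ref_codon = c("GGG", "GGG", "TGG"),
                     alt = c("A", "A", "A"),
                     class = c("NONSYNONYMOUS", "SYNONYMOUS", "STOP_AFFECTED"),
                     kind = "poly")
  plus <- coding_gene_fixture(10, plan, seed = 5, strand = "+")
  minus <- coding_gene_fixture(10, plan, seed = 5, strand = "-")
  for (fx in list(plus, minus)) {
    eff <- fx$effects[order(fx$effects$codon_index), ]
    expect_equal(eff$effect,
                 c("NONSYNONYMOUS", "SYNONYMOUS", "STOP_AFFECTED"))
  }
})

test_that("every CDS SNP lands in exactly one effect class", {
  set.seed(31)
  fx <- coding_gene_fixture(40, seed = 31)
  # place unplanned random SNPs across the CDS and classify them all
  span <- c(fx$gene$intervals$start[1], fx$gene$intervals$end[1])
  pos <- seq(span[1], span[2] - 1L, by = 2L)
  base_at <- substring(fx$ref, pos + 1L, pos + 1L)
  alt <- vapply(base_at, function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  eff <- apisweep:::snp_effects(
    fx$gene, data.frame(pos = pos, ref = base_at, alt = alt), fx$ref)
  expect_equal(nrow(eff), length(pos))
  tallies <- table(factor(eff$effect,
    c("SYNONYMOUS", "NONSYNONYMOUS", "STOP_AFFECTED", "SKIPPED")))
  expect_equal(sum(tallies), length(pos))   # conservation across classes
})

test_that("pnps is the site-normalized polymorphism ratio, undefined without synonymous SNPs", {
  # 10 x GGG gene: N = 20, S = 10; 2 nonsynonymous + 1 synonymous SNPs
  plan <- data.frame(codon = c(2L, 4L, 6L), codon_pos = c(0L, 0L, 2L),
                     ref_codon = "GGG", alt = "A",
                     class = c("NONSYNONYMOUS", "NONSYNONYMOUS", "SYNONYMOUS"),
                     kind = "poly")
  fx <- coding_gene_fixture(10, plan, base_codon = "GGG", seed = 6)
  tab <- pnps_table(fx$table, list(fx$gene), fx$ref)
  expect_equal(tab$N, 20)
  expect_equal(tab$S, 10)
  expect_equal(tab$P_N, 2L)
  expect_equal(tab$P_S, 1L)
  expect_equal(tab$pnps, 1.0)   # (2/20) / (1/10)

  # no synonymous polymorphism -> undefined, flagged
  plan2 <- plan[1:2, ]
  fx2 <- coding_gene_fixture(10, plan2, base_codon = "GGG", seed = 6)
  tab2 <- pnps_table(fx2$table, list(fx2$gene), fx2$ref)
  expect_true(is.na(tab2$pnps))
  expect_match(tab2$flags, "P_S=0")
})

test_that("fixed differences require every called genotype to be hom-alt", {
  plan <- data.frame(codon = 2:9, codon_pos = c(0L, 0L, 0L, 0L, 0L, 2L, 2L, 0L),
                     ref_codon = "GGG", alt = "A",
                     class = c(rep("NONSYNONYMOUS", 5), "SYNONYMOUS",
                               "SYNONYMOUS", "NONSYNONYMOUS"),
                     kind = c(rep("fixed", 5), "fixed", "poly", "poly"))
  fx <- coding_gene_fixture(12, plan, seed = 7)
  tab <- fixed_diff_table(fx$table, list(fx$gene), fx$ref)
  expect_equal(tab$E_N, 5L)
  expect_equal(tab$E_S, 1L)
  expect_equal(tab$P_N, 1L)
  expect_equal(tab$P_S, 1L)
  expect_equal(tab$e_ratio, 5 / (1 + 1))

  # {2,2,NA} is fixed; {2,1} is a polymorphism
  g <- fx$table$geno
  fixed_row <- which(fx$table$pos == fx$table$pos[1])
  tab3 <- fx$table
  tab3$geno[1, ] <- c(2L, 2L, NA, NA)
  tab3$geno[2, ] <- c(2L, 1L, 0L, 0L)
  status <- apisweep:::site_status(tab3)
  expect_equal(status[1], "fixed_alt")
  expect_equal(status[2], "poly")
})

test_that("genes with no amino-acid fixed difference get e_ratio 0 and sort last", {
  plan <- data.frame(codon = c(2L, 3L), codon_pos = c(2L, 0L),
                     ref_codon = "GGG", alt = "A",
                     class = c("SYNONYMOUS", "NONSYNONYMOUS"),
                     kind = c("fixed", "poly"))
  fx <- coding_gene_fixture(6, plan, seed = 8)
  tab <- fixed_diff_table(fx$table, list(fx$gene), fx$ref)
  expect_equal(tab$E_N, 0L)
  expect_equal(tab$e_ratio, 0)
})

test_that("the McDonald-Kreitman fixation index follows the 2x2 table rules", {
  fi_of <- function(dn, ds, pn, ps, pseudocount = 0) {
    n_codons <- 4L + dn + ds + pn + ps
    plan <- data.frame(
      codon = seq_len(dn + ds + pn + ps) + 1L,
      codon_pos = c(rep(0L, dn), rep(2L, ds), rep(0L, pn), rep(2L, ps)),
      ref_codon = "GGG", alt = "A",
      class = c(rep("NONSYNONYMOUS", dn), rep("SYNONYMOUS", ds),
                rep("NONSYNONYMOUS", pn), rep("SYNONYMOUS", ps)),
      kind = c(rep("divergence", dn + ds), rep("poly", pn + ps)))
    fx <- coding_gene_fixture(n_codons, plan, seed = 9)
    mk_table(fx$table, list(fx$gene), fx$ref, fx$outgroup,
             pseudocount = pseudocount)
  }
  sym <- fi_of(2, 2, 3, 3)
  expect_equal(sym$D_N, 2L); expect_equal(sym$P_S, 3L)
  expect_equal(sym$fi, 1.0)

  zero <- fi_of(0, 3, 2, 2)
  expect_equal(zero$fi, 0)

  undef <- fi_of(5, 0, 2, 2)
  expect_true(is.na(undef$fi))
  expect_match(undef$flags, "D_S=0")

  # pseudocount rescues degenerate tables for exploratory ranking
  resc <- fi_of(5, 0, 2, 2, pseudocount = 1)
  expect_equal(resc$fi, (6 / 1) / (3 / 3))
})

test_that("outgroup alleles matching neither allele are excluded and tallied", {
  plan <- data.frame(codon = c(2L, 3L), codon_pos = 0L,
                     ref_codon = c("GGG", "GGG"), alt = "A",
                     class = "NONSYNONYMOUS", kind = "divergence")
  fx <- coding_gene_fixture(6, plan, seed = 10)
  og <- fx$outgroup
  og[1] <- setdiff(c("A", "C", "G", "T"),
                   c(fx$table$ref[1], fx$table$alt[1]))[1]
  tab <- mk_table(fx$table, list(fx$gene), fx$ref, og)
  expect_equal(tab$D_N, 1L)
  expect_equal(tab$sites_skipped, 1L)
})
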