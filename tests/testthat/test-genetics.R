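# small hand-built catalog used across blocks
toy_catalog <- function() {
  snp_catalog(rbind(
    snp_row("rs1", 9, 22000000, "Coronary artery disease", "A", "G"),
    snp_row("rs1", 9, 22000000, "Breast cancer", "G", "A"),
    snp_row("rs2", 12, 111000000, "Type 2 diabetes", "C", "T"),
    snp_row("rs3", 12, 111040000, "Lung cancer", "T", "A"),
    snp_row("rs4", 1, 5000000, "Height", "A", "C"),
    snp_row("rs5", 2, 9000000, "Alzheimer's disease", "G", "T")))
}

test_that("keyword matching partitions traits, multi-matches join all sets", {
  cat6 <- toy_catalog()
  sets <- build_trait_snp_sets(cat6)
  expect_equal(sort(sets$cancer$rsid), c("rs1", "rs3"))
  expect_equal(sets$CVD$rsid, "rs1")
  expect_equal(sets$T2D$rsid, "rs2")
  expect_equal(sets$NDD$rsid, "rs5")
  expect_equal(sets$non_ageing$rsid, "rs4")  # no-match default pool
  # a trait matching two categories lands in both
  multi <- snp_catalog(snp_row("rs9", 3, 1000, "Stroke and heart disease",
                               "A", "T"))
  s2 <- suppressWarnings(build_trait_snp_sets(multi, list(
    CVD = c("stroke"), NDD = c("heart"))))
  expect_equal(s2$CVD$rsid, "rs9")
  expect_equal(s2$NDD$rsid, "rs9")
})

test_that("sharing finds identical rsIDs and LD partners above threshold", {
  cat6 <- toy_catalog()
  sets <- build_trait_snp_sets(cat6)
  ld <- ld_table(data.frame(rsid_a = c("rs2", "rs4"),
                            rsid_b = c("rs3", "rs5"),
                            r2 = c(0.9, 0.5),
                            phase = c("C=T,T=A", "A=G,C=T")))
  sh_cvd <- find_shared_risk_snps(sets$cancer, sets$CVD, ld)
  expect_equal(nrow(sh_cvd), 1)
  expect_equal(sh_cvd$mode, "identical")
  sh_t2d <- find_shared_risk_snps(sets$cancer, sets$T2D, ld)
  expect_equal(nrow(sh_t2d), 1)
  expect_equal(sh_t2d$mode, "LD")
  # r2 = 0.5 below the default threshold: no sharing
  sh_ndd <- find_shared_risk_snps(sets$non_ageing, sets$NDD, ld)
  expect_equal(nrow(sh_ndd), 0)
  # brute-force pair count on a toy cross product
  set1 <- snp_catalog(rbind(snp_row("a1", 1, 100, "t", "A", "G"),
                            snp_row("a2", 1, 200, "t", "C", "T"),
                            snp_row("a3", 1, 300, "t", "G", "A")))
  set2 <- snp_catalog(rbind(snp_row("b1", 1, 150, "u", "A", "G"),
                            snp_row("b2", 1, 250, "u", "T", "C"),
                            snp_row("a3", 1, 300, "u", "G", "A"),
                            snp_row("b4", 2, 999, "u", "A", "C")))
  ld2 <- ld_table(data.frame(rsid_a = c("a1", "b2"),
                             rsid_b = c("b1", "a2"),
                             r2 = c(0.95, 0.85),
                             phase = c("A=A,G=G", "T=C,C=T")))
  sh <- find_shared_risk_snps(set1, set2, ld2)
  # oracle: full scan of the 3 x 4 cross product
  expected <- 0
  for (i in 1:3) for (j in 1:4) {
    if (set1$rsid[i] == set2$rsid[j]) expected <- expected + 1
    else {
      hit <- ld_lookup(ld2, set1$rsid[i], set2$rsid[j])
      if (!is.null(hit) && hit$r2 >= 0.8) expected <- expected + 1
    }
  }
  expect_equal(nrow(sh), expected)
  expect_equal(expected, 3)
})

test_that("classification follows the same/alternative allele rule", {
  cat6 <- toy_catalog()
  sets <- build_trait_snp_sets(cat6)
  # rs1: CVD risk A, cancer risk G (the alternative): antagonistic,
  # mirroring the SH2B3-type case of opposite alleles at one position
  sh <- classify_shared_snps(
    find_shared_risk_snps(sets$CVD, sets$cancer))
  expect_equal(sh$label, "antagonistic")
  # same risk allele: synergistic
  s1 <- snp_catalog(snp_row("rs7", 1, 10, "Breast cancer", "A", "G"))
  s2 <- snp_catalog(snp_row("rs7", 1, 10, "Stroke", "A", "G"))
  sh2 <- classify_shared_snps(find_shared_risk_snps(s1, s2))
  expect_equal(sh2$label, "synergistic")
})

test_that("LD-mode classification maps risk alleles through the phase", {
  # rs2 risk C; rs3 risk T; phase C=T: same haplotype => synergistic
  s1 <- snp_catalog(snp_row("rs2", 12, 1000, "Type 2 diabetes", "C", "T"))
  s2 <- snp_catalog(snp_row("rs3", 12, 2000, "Lung cancer", "T", "A"))
  ld <- ld_table(data.frame(rsid_a = "rs2", rsid_b = "rs3", r2 = 0.9,
                            phase = "C=T,T=A"))
  sh <- classify_shared_snps(find_shared_risk_snps(s1, s2, ld), ld)
  expect_equal(sh$label, "synergistic")
  # opposite haplotype: antagonistic
  s2b <- snp_catalog(snp_row("rs3", 12, 2000, "Lung cancer", "A", "T"))
  shb <- classify_shared_snps(find_shared_risk_snps(s1, s2b, ld), ld)
  expect_equal(shb$label, "antagonistic")
  # no phase available: unclassified
  ld0 <- ld_table(data.frame(rsid_a = "rs2", rsid_b = "rs3", r2 = 0.9,
                             phase = "C=T,T=A"))
  sh0 <- find_shared_risk_snps(s1, s2, ld0)
  expect_equal(classify_shared_snp(sh0[1, ], ld = NULL), "unclassified")
})

test_that("classification is symmetric in the pair order", {
  set.seed(51)
  for (i in 1:20) {
    al <- sample(VALID_ALLELES <- c("A", "C", "G", "T"), 2)
    al2 <- sample(c("A", "C", "G", "T"), 2)
    s1 <- snp_catalog(snp_row("rsA", 1, 1000, "Breast cancer",
                              al[1], al[2]))
    risk2 <- sample(al2, 1)
    s2 <- snp_catalog(snp_row("rsB", 1, 2000, "Stroke", risk2,
                              setdiff(al2, risk2)))
    ld <- ld_table(data.frame(rsid_a = "rsA", rsid_b = "rsB", r2 = 0.92,
                              phase = sprintf("%s=%s,%s=%s", al[1],
                                              al2[1], al[2], al2[2])))
    l12 <- classify_shared_snps(find_shared_risk_snps(s1, s2, ld), ld)$label
    l21 <- classify_shared_snps(find_shared_risk_snps(s2, s1, ld), ld)$label
    expect_equal(l12, l21)
  }
})

test_that("locus counting via connected components", {
  # 3 SNPs mutually in LD + 2 distant singletons -> 3 loci
  sh <- data.frame(
    rsid_1 = c("x1", "x2", "y1", "z1"), trait_1 = "a",
    risk_1 = "A", alt_1 = "G",
    rsid_2 = c("x2", "x3", "y1", "z1"), trait_2 = "b",
    risk_2 = "A", alt_2 = "G",
    chrom = c("1", "1", "5", "7"), pos = c(1e6, 1.2e6, 5e6, 9e6),
    chrom_2 = c("1", "1", "5", "7"),
    pos_2 = c(1.2e6, 30e6, 5e6, 9e6),
    mode = "LD", r2 = 0.9)
  ld <- ld_table(data.frame(rsid_a = c("x1", "x2"),
                            rsid_b = c("x2", "x3"),
                            r2 = c(0.9, 0.8),
                            phase = c("A=A,G=G", "A=A,G=G")))
  out <- count_independent_loci(sh, ld)
  expect_equal(out$n_loci, 3)
  expect_equal(length(unique(out$loci$locus[out$loci$rsid %in%
                                              c("x1", "x2", "x3")])), 1)
  # all on different chromosomes without LD: one locus per SNP
  sh2 <- sh
  sh2$chrom <- sh2$chrom_2 <- as.character(1:4)
  sh2$rsid_2 <- sh2$rsid_1
  sh2$pos_2 <- sh2$pos
  out2 <- count_independent_loci(sh2, ld = NULL)
  expect_equal(out2$n_loci, 4)
  # single SNP is a single locus
  out3 <- count_independent_loci(sh[3, ], ld = NULL)
  expect_equal(out3$n_loci, 1)
})

test_that("binomial bias test reproduces exact tail sums", {
  expect_equal(antagonism_bias_binomial(10, 10, 0.5)$p, 1 / 1024)
  expect_equal(antagonism_bias_binomial(9, 10, 0.5)$p, 11 / 1024)
  expect_equal(antagonism_bias_binomial(0, 10, 0.5)$p, 1)
  expect_error(antagonism_bias_binomial(11, 10, 0.5), "exceed")
  # p0 derived from a classified background set
  bg <- data.frame(label = c("antagonistic", "synergistic",
                             "synergistic", "antagonistic"))
  out <- antagonism_bias_binomial(3, 4, background = bg)
  expect_equal(out$p0, 0.5)
  expect_equal(out$p, sum(dbinom(3:4, 4, 0.5)))
  expect_error(antagonism_bias_binomial(1, 2, background = NULL),
               "background")
})

test_that("randomization null matches exhaustive enumeration on a small pool", {
  focal <- snp_catalog(rbind(
    snp_row("f1", 1, 1000, "Breast cancer", "A", "G"),
    snp_row("f2", 2, 2000, "Lung cancer", "C", "T")))
  # pool of 8, two of which share rsIDs with the focal set
  pool <- snp_catalog(rbind(
    snp_row("f1", 1, 1000, "Height", "A", "G"),
    snp_row("f2", 2, 2000, "Height", "T", "C"),
    snp_row("p3", 3, 3000, "Height", "A", "C"),
    snp_row("p4", 4, 4000, "Height", "G", "T"),
    snp_row("p5", 5, 5000, "Height", "A", "T"),
    snp_row("p6", 6, 6000, "Height", "C", "G"),
    snp_row("p7", 7, 7000, "Height", "G", "A"),
    snp_row("p8", 8, 8000, "Height", "T", "C")))
  replaced <- pool[1:3, ]  # draw size 3
  class(replaced) <- c("snp_catalog", "data.frame")
  out <- randomization_null_snps(focal, replaced, pool, n_reps = 3000,
                                 seed = 8)
  # exhaustive oracle over all C(8,3) = 56 subsets
  idx <- combn(8, 3)
  totals <- apply(idx, 2, function(ii) {
    sub <- pool[ii, ]
    class(sub) <- c("snp_catalog", "data.frame")
    nrow(find_shared_risk_snps(focal, sub))
  })
  exact_mean <- mean(totals)
  se <- sd(totals) / sqrt(3000)
  expect_lt(abs(mean(out$null[, "total"]) - exact_mean), 2 * se + 1e-9)
  # determinism and the degenerate empirical p
  out2 <- randomization_null_snps(focal, replaced, pool, n_reps = 50,
                                  seed = 8)
  out3 <- randomization_null_snps(focal, replaced, pool, n_reps = 50,
                                  seed = 8)
  expect_identical(out2$null, out3$null)
  expect_error(randomization_null_snps(focal, pool, pool[1:2, ]),
               "pool smaller")
})
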