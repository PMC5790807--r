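test_that("generators are pure functions of parameters and seed", {
  a <- generate_expression_study(n_species = 2, n_tissues = 2,
                                 n_per_cell = 2, n_genes = 60,
                                 n_processes = 6, n_regulated = 2,
                                 genes_per_set = 12, seed = 61)
  b <- generate_expression_study(n_species = 2, n_tissues = 2,
                                 n_per_cell = 2, n_genes = 60,
                                 n_processes = 6, n_regulated = 2,
                                 genes_per_set = 12, seed = 61)
  expect_identical(a$study$values, b$study$values)
  expect_identical(a$sets$sets, b$sets$sets)
  expect_identical(a$truth, b$truth)
  c <- generate_expression_study(n_species = 2, n_tissues = 2,
                                 n_per_cell = 2, n_genes = 60,
                                 n_processes = 6, n_regulated = 2,
                                 genes_per_set = 12, seed = 62)
  expect_false(identical(a$study$values, c$study$values))
  s1 <- generate_snp_catalog(n_loci = 8, n_shared_loci = 4,
                             pool_size = 30, seed = 63)
  s2 <- generate_snp_catalog(n_loci = 8, n_shared_loci = 4,
                             pool_size = 30, seed = 63)
  expect_identical(as.data.frame(s1$catalog), as.data.frame(s2$catalog))
  expect_identical(as.data.frame(s1$ld), as.data.frame(s2$ld))
  d1 <- generate_disease_signature(a$truth, seed = 64)
  d2 <- generate_disease_signature(a$truth, seed = 64)
  expect_identical(d1$foldchange, d2$foldchange)
})

test_that("planted truth matches the emitted study structure", {
  sim <- generate_expression_study(n_species = 4, n_tissues = 2,
                                   n_per_cell = 3, n_genes = 200,
                                   n_processes = 20, n_regulated = 4,
                                   genes_per_set = 15, seed = 65)
  tr <- sim$truth
  expect_equal(nrow(tr$regulated), 4)
  expect_setequal(unique(tr$regulated$direction), c(1, -1))
  # regulated processes' core genes carry the process direction
  for (i in seq_len(nrow(tr$regulated))) {
    p <- tr$regulated$process[i]
    core <- sim$sets$sets[[p]][1:10]
    expect_true(all(tr$gene_direction[core] == tr$regulated$direction[i]))
  }
  # null processes contain no directional genes
  null_procs <- setdiff(names(sim$sets$sets), tr$regulated$process)
  for (p in null_procs) {
    expect_true(all(tr$gene_direction[sim$sets$sets[[p]]] == 0))
  }
  expect_setequal(c(tr$fish, tr$mammals), unique(sim$study$meta$species))
  # planted rank-scale shift materializes near the target
  st <- filter_unexpressed_genes(sim$study)
  pa <- normalize_activities(compute_process_activity(
    st, filter_gene_sets_min_genes(sim$sets, st)))
  old <- pa$meta$age_group %in% c("old_1", "old_2")
  young <- pa$meta$age_group == "young"
  fc <- rowMeans(pa$activity[, old]) - rowMeans(pa$activity[, young])
  planted_fc <- fc[tr$regulated$process] * tr$regulated$direction
  expect_gt(mean(planted_fc), 0.15)   # strong, correctly signed
  expect_lt(median(abs(fc[null_procs])), 0.1)
})

test_that("a zero effect produces no planted foldchange", {
  sim <- generate_expression_study(n_species = 2, n_tissues = 2,
                                   n_per_cell = 4, n_genes = 200,
                                   n_processes = 20, n_regulated = 4,
                                   effect = 0, genes_per_set = 15,
                                   seed = 66)
  expect_true(all(sim$truth$regulated$beta == 0))
  expect_true(all(sim$truth$gene_direction[
    unlist(sim$sets$sets[sim$truth$regulated$process])] %in% c(-1, 0, 1)))
  st <- filter_unexpressed_genes(sim$study)
  pa <- normalize_activities(compute_process_activity(
    st, filter_gene_sets_min_genes(sim$sets, st)))
  sig <- ageing_signature(pa, fish = sim$truth$fish,
                          mammals = sim$truth$mammals)
  expect_equal(sum(sig$processes$significant), 0)
})

test_that("disease generator flips sign with c and washes out with noise", {
  sim <- generate_expression_study(n_species = 2, n_tissues = 2,
                                   n_per_cell = 2, n_genes = 300,
                                   n_processes = 30, n_regulated = 6,
                                   genes_per_set = 15, seed = 67)
  gd <- sim$truth$gene_direction
  U <- names(gd)[gd > 0]; R <- names(gd)[gd < 0]
  noiseless_pos <- normalize_disease_foldchanges(
    generate_disease_signature(sim$truth, c_align = 1, noise_sd = 0,
                               seed = 68))
  noiseless_neg <- normalize_disease_foldchanges(
    generate_disease_signature(sim$truth, c_align = -1, noise_sd = 0,
                               seed = 68))
  s_pos <- amda_score(U, R, noiseless_pos)
  s_neg <- amda_score(U, R, noiseless_neg)
  expect_equal(s_neg, -s_pos)
  # noiseless AMDA equals the analytic maximum given rank normalization:
  # U genes occupy the top |U| ranks, R genes the bottom |R|
  N <- length(gd)
  rank_to_norm <- function(r) 2 * (r - 1) / (N - 1) - 1
  max_amda <- mean(rank_to_norm(seq(N - length(U) + 1, N))) -
    mean(rank_to_norm(seq_len(length(R))))
  expect_equal(s_pos, max_amda)
  # heavy noise drives the score toward zero
  noisy <- normalize_disease_foldchanges(
    generate_disease_signature(sim$truth, c_align = 1, noise_sd = 25,
                               seed = 69))
  expect_lt(abs(amda_score(U, R, noisy)), abs(s_pos) / 3)
})

test_that("SNP generator plants exact labels, loci and within-locus LD", {
  gen <- generate_snp_catalog(seed = 70)  # defaults: 30 loci, 12 shared
  sets <- build_trait_snp_sets(gen$catalog)
  degen <- unique(rbind(sets$CVD, sets$NDD, sets$T2D))
  class(degen) <- c("snp_catalog", "data.frame")
  shared <- classify_shared_snps(
    find_shared_risk_snps(sets$cancer, degen, gen$ld), gen$ld)
  expect_equal(nrow(shared), gen$truth$n_shared)
  # exact recovery of the planted antagonistic fraction
  expect_equal(mean(shared$label == "antagonistic"),
               gen$truth$antagonistic_fraction)
  expect_equal(sort(table(shared$label), decreasing = TRUE),
               sort(table(gen$truth$planted$label), decreasing = TRUE))
  # planted 12 shared loci recovered at generator-matched thresholds
  loci <- count_independent_loci(shared, gen$ld)
  expect_equal(loci$n_loci, 12)
  # extreme plant: fraction 1 -> all antagonistic
  gen1 <- generate_snp_catalog(n_loci = 10, n_shared_loci = 5,
                               antagonistic_fraction = 1,
                               pool_size = 40, seed = 71)
  sets1 <- build_trait_snp_sets(gen1$catalog)
  degen1 <- unique(rbind(sets1$CVD, sets1$NDD, sets1$T2D))
  class(degen1) <- c("snp_catalog", "data.frame")
  sh1 <- classify_shared_snps(
    find_shared_risk_snps(sets1$cancer, degen1, gen1$ld), gen1$ld)
  expect_true(all(sh1$label == "antagonistic"))
  # within-locus r2 >= 0.9 everywhere
  expect_true(all(gen$ld$r2 >= 0.9))
})

test_that("AMDA sign tracks the planted alignment coefficient across replicates", {
  sim <- generate_expression_study(n_species = 2, n_tissues = 2,
                                   n_per_cell = 2, n_genes = 300,
                                   n_processes = 30, n_regulated = 6,
                                   genes_per_set = 15, seed = 72)
  gd <- sim$truth$gene_direction
  U <- names(gd)[gd > 0]; R <- names(gd)[gd < 0]
  hits <- vapply(1:50, function(s) {
    c_align <- if (s %% 2 == 0) 1 else -1
    sig <- normalize_disease_foldchanges(generate_disease_signature(
      sim$truth, c_align = c_align, noise_sd = 0.3, seed = 100 + s))
    sign(amda_score(U, R, sig)) == c_align
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
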