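#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs used by the downstream
# analyses -- a cross-species ageing expression study (4 species x 4
# tissues x 3 age groups, 20 of 200 processes age-regulated), a panel of
# disease signatures (aligned, reverted and null), and a risk-SNP
# catalog with LD blocks and a planted antagonistic bias. All inputs
# are written as the plain TSV/GMT dialects the package readers accept,
# alongside their ground-truth tables.

library(agealign)

seed <- 42
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("simulating expression study (seed ", seed, ") ...")
sim <- generate_expression_study(seed = seed)
write_expression_study(sim$study,
                       file.path(out, "expression.tsv"),
                       file.path(out, "samples.tsv"),
                       file.path(out, "gene_lengths.tsv"))
write_gene_sets(sim$sets, file.path(out, "processes.gmt"))
write_simulation_truth(sim$truth, file.path(out, "expression_truth.tsv"))
message("  ", nrow(sim$study$values), " genes x ",
        ncol(sim$study$values), " samples; ",
        nrow(sim$truth$regulated), " regulated processes planted")

message("simulating disease signatures ...")
panel <- list(
  cvd_aligned   = list(cat = "CVD",    c = +1, seed = seed + 1),
  ndd_aligned   = list(cat = "NDD",    c = +1, seed = seed + 2),
  t2d_aligned   = list(cat = "T2D",    c = +1, seed = seed + 3),
  cancer_revert = list(cat = "cancer", c = -1, seed = seed + 4),
  cancer_null   = list(cat = "cancer", c =  0, seed = seed + 5))
for (nm in names(panel)) {
  p <- panel[[nm]]
  sig <- generate_disease_signature(sim$truth, p$cat, c_align = p$c,
                                    noise_sd = 0.3, id = nm,
                                    seed = p$seed)
  write_disease_signature(sig, file.path(out, paste0("disease_", nm,
                                                     ".tsv")))
}
writeLines(vapply(names(panel), function(nm)
  paste(nm, panel[[nm]]$cat, panel[[nm]]$c, sep = "\t"), character(1)),
  file.path(out, "disease_panel.tsv"))

message("simulating SNP catalog ...")
snp <- generate_snp_catalog(seed = seed)
write_snp_catalog(snp$catalog, file.path(out, "snp_catalog.tsv"))
write_ld_table(snp$ld, file.path(out, "ld_table.tsv"))
write_simulation_truth(snp$truth, file.path(out, "snp_truth.tsv"))
message("  ", nrow(snp$catalog), " catalog records, ",
        snp$truth$n_shared, " shared pairs planted (",
        round(100 * snp$truth$antagonistic_fraction), "% antagonistic)")
message("done; inputs under ", out)
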