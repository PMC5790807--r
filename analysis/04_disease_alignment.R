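#!/usr/bin/env Rscript
# Step 4: align the ageing signature with disease signatures. Derives
# ageing-induced/repressed gene sets from the expression study, scores
# every disease with the AMDA statistic (Wilcoxon significance, BH
# across pairs), runs the induced/repressed swap randomization, computes
# per-process DAC scores by disease category, and embeds all condition
# foldchange profiles with classical MDS.

library(agealign)

data_dir <- "results/data"
out <- "results"

study <- filter_unexpressed_genes(
  read_expression_study(file.path(data_dir, "expression.tsv"),
                        file.path(data_dir, "samples.tsv")))

message("deriving ageing-induced / repressed gene sets ...")
dg <- differential_genes(study)
message("  |U| = ", length(dg$U), ", |R| = ", length(dg$R))
ageing <- list(synthetic_ageing = list(U = dg$U, R = dg$R))

panel <- read.delim(file.path(data_dir, "disease_panel.tsv"),
                    header = FALSE,
                    col.names = c("id", "category", "c_align"))
diseases <- lapply(seq_len(nrow(panel)), function(i) {
  normalize_disease_foldchanges(read_disease_signature(
    file.path(data_dir, paste0("disease_", panel$id[i], ".tsv")),
    id = panel$id[i], category = panel$category[i]))
})
names(diseases) <- panel$id

amda <- amda_significance(ageing, diseases)
write_alignment_table(amda, file.path(out, "amda_scores.tsv"))
message("AMDA scores:")
for (i in seq_len(nrow(amda))) {
  message(sprintf("  %-14s %-7s score %+0.3f  fdr %.2g %s",
                  amda$disease[i], amda$category[i], amda$score[i],
                  amda$fdr[i],
                  if (amda$significant[i]) "(significant)" else ""))
}

message("induced/repressed swap randomization (100 replicates) ...")
swap <- amda_randomization(ageing, diseases, n_reps = 100, seed = 11)
message("  observed significant pairs: ", swap$observed,
        "; swap replicates with any: ", sum(swap$counts > 0), "/100")

message("DAC scores ...")
sets <- filter_gene_sets_min_genes(
  parse_gene_sets(file.path(data_dir, "processes.gmt"),
                  name = "synthetic_ontology"), study)
dac <- dac_scores(sets, ageing, diseases)
write_alignment_table(dac$normalized, file.path(out, "dac_scores.tsv"))
top <- order(-apply(abs(dac$normalized), 1, max))[1:5]
message("  top|DAC| processes: ",
        paste(rownames(dac$normalized)[top], collapse = ", "))

message("MDS embedding of condition foldchange profiles ...")
genes <- rownames(study$values)
old <- study$meta$age_group %in% c("old_1", "old_2")
young <- study$meta$age_group == "young"
ageing_fc <- log2(apply(study$values[, old], 1, median) /
                    apply(study$values[, young], 1, median))
profiles <- rbind(ageing = ageing_fc[genes])
for (nm in names(diseases)) {
  profiles <- rbind(profiles, diseases[[nm]]$normalized[genes])
}
rownames(profiles) <- c("ageing", names(diseases))
emb <- mds_embedding(profiles, k = 2)
coords <- data.frame(condition = rownames(emb$points), emb$points)
write.table(coords, file.path(out, "mds_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  variance explained: ",
        paste(sprintf("%.1f%%", 100 * emb$variance_explained),
              collapse = ", "))
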