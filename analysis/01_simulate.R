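#!/usr/bin/env Rscript
# 01 — Generate the synthetic bone-marrow ASC dataset.
#
# Desk-scale stand-in for a five-subject BM ASC study: 1,000 cells x 800
# genes in 8 clusters, with a 200-lineage heavy-chain repertoire mutated at
# a 6.89% per-base SHM rate. Everything downstream (02-06) reads the files
# written here; ground truth goes to JSON so each stage can be audited.

suppressPackageStartupMessages(library(bmpc))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20230L)   # defaults are the study conditions
thr <- qc_thresholds(genes_min_exclusive = 100L, umi_min_exclusive = 200L,
                     genes_max_inclusive = 600L, umi_max_inclusive = 20000L)
ex <- simulate_expression(cfg, qc_design = list(thresholds = thr,
                                                n_per_rule = 5L))
rp <- simulate_repertoire(cfg, ex$truth$labels, ex$truth$subjects)

write_count_matrix(ex$counts, out)
write_airr(rp$records, file.path(out, "rearrangements.tsv"))
write_ground_truth(list(labels = as.list(ex$truth$labels),
                        subjects = as.list(ex$truth$subjects),
                        contaminants = ex$truth$contaminants,
                        qc_design = ex$truth$qc_design,
                        lineage = as.list(rp$truth$lineage)),
                   file.path(out, "truth.json"))
utils::write.table(
  data.frame(cell_id = names(ex$truth$labels),
             cluster = ex$truth$labels,
             subject = ex$truth$subjects[names(ex$truth$labels)]),
  file.path(out, "labels.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

cat(sprintf("cells: %d  genes: %d  VDJ records: %d  lineages seeded: %d\n",
            nrow(ex$counts), ncol(ex$counts), nrow(rp$records),
            length(unique(rp$truth$lineage))))
cat(sprintf("contaminant cells: %d  designed QC violations: %d\n",
            length(ex$truth$contaminants),
            length(unlist(ex$truth$qc_design))))
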