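#!/usr/bin/env Rscript
# 02 — Cell-level quality control.
#
# Applies the six numeric filters (mitochondrial fraction, detected-gene and
# UMI floors/ceilings, immunoglobulin-fraction floor) at thresholds scaled
# to the synthetic library size, plus the diagnostic-marker contaminant
# screen. Writes the keep list and per-rule removal counts.

suppressPackageStartupMessages(library(bmpc))

counts <- read_count_matrix("results/data")
thr <- qc_thresholds(genes_min_exclusive = 100L, umi_min_exclusive = 200L,
                     genes_max_inclusive = 600L, umi_max_inclusive = 20000L)

metrics <- compute_cell_qc(counts)
filt <- apply_qc_filters(metrics, thr)
contam <- flag_contaminants(counts, thr$contaminant_markers,
                            thr$contaminant_min_umi)
keep <- filt$keep & !contam

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
utils::write.table(metrics, "results/qc/cell_metrics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(cell_id = metrics$cell_id[keep]),
                   "results/qc/keep.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
jsonlite::write_json(c(as.list(filt$rule_counts),
                       list(contaminant = sum(contam),
                            kept = sum(keep), input = nrow(counts))),
                     "results/qc/rule_counts.json", auto_unbox = TRUE)

cat("per-rule removals (a cell may violate several):\n")
print(filt$rule_counts)
cat(sprintf("contaminants flagged: %d\nkept %d of %d cells\n",
            sum(contam), sum(keep), nrow(counts)))
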