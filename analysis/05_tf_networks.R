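#!/usr/bin/env Rscript
# 05 — Transcription-factor cluster assignment and interaction filtering.
#
# A sampled TF universe (candidates gated by marker/DEG membership and the
# 10% expressing-fraction rule) is assigned to the cluster with the highest
# mean expression; cluster-distinct TFs need >= 0.25 avgLogFC over the
# runner-up. Synthetic STRING-like edges are filtered to same-cluster pairs
# with combined score > 500.

suppressPackageStartupMessages(library(bmpc))

counts <- read_count_matrix("results/data")
keep <- utils::read.delim("results/qc/keep.tsv")$cell_id
lab_tab <- utils::read.delim("results/data/labels.tsv")
labels <- stats::setNames(as.character(lab_tab$cluster), lab_tab$cell_id)
norm <- lognormalize(counts[keep, ])
labels <- labels[rownames(norm)]
markers <- utils::read.delim("results/signatures/markers.tsv")

set.seed(20236L)
# TF universe: the cluster markers double as the "regulators" of the
# synthetic design, padded with random background genes
mk <- unique(markers$gene)
universe <- unique(c(sample(mk, min(30, length(mk))),
                     sample(exclude_ig_genes(colnames(norm)), 30)))
flags <- stats::setNames(universe %in% markers$gene, universe)

tfs <- select_tfs(norm, labels, universe, flags)
asg <- assign_tf_clusters(norm, labels, tfs)

pool <- utils::combn(sort(universe), 2)
pick <- sample.int(ncol(pool), 300)
edges <- data.frame(protein_a = pool[1, pick], protein_b = pool[2, pick],
                    combined_score = sample.int(1000L, 300, replace = TRUE))
kept <- filter_interactions(edges, asg)

dir.create("results/tf", showWarnings = FALSE, recursive = TRUE)
utils::write.table(asg, "results/tf/assignments.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(kept, "results/tf/edges.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("TFs past gates: %d of %d  cluster-distinct: %d\n",
            length(tfs), length(universe), sum(asg$distinct, na.rm = TRUE)))
cat(sprintf("edges kept: %d of %d (same cluster, score > 500)\n",
            nrow(kept), nrow(edges)))
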