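#!/usr/bin/env Rscript
# 04 — Markers, preranked enrichment and pathway U-scores.
#
# Differential expression between adjacent maturation stages (built-in
# rank-sum engine), marker thresholding (avgLogFC > 0.25, Bonferroni
# p < 0.05), the NLP x sign preranked list with weighted-KS enrichment and
# permutation significance over synthetic hallmark-like gene sets, and the
# cluster x pathway U-score panel (row-z scaled).

suppressPackageStartupMessages(library(bmpc))

counts <- read_count_matrix("results/data")
keep <- utils::read.delim("results/qc/keep.tsv")$cell_id
lab_tab <- utils::read.delim("results/data/labels.tsv")
labels <- stats::setNames(as.character(lab_tab$cluster), lab_tab$cell_id)
norm <- lognormalize(counts[keep, ])
labels <- labels[rownames(norm)]

cl <- sort(unique(labels))
adj <- list()
for (i in seq_len(length(cl) - 1)) {
  nm <- paste0(cl[i], "_vs_", cl[i + 1])
  adj[[nm]] <- de_rank_sum(norm, labels, cl[i], cl[i + 1])
}
half <- length(cl) %/% 2
stage <- stats::setNames(ifelse(labels %in% cl[seq_len(half)],
                                "early", "late"), names(labels))
early_late <- de_rank_sum(norm, stage, "early", "late")

markers <- do.call(rbind, lapply(adj, filter_markers))
maturation <- maturation_deg_union(adj, early_late)
ranked <- prerank_statistic(early_late)

set.seed(20234L)
universe <- exclude_ig_genes(colnames(norm))
gene_sets <- stats::setNames(
  lapply(1:10, function(i) sample(universe, 40)),
  sprintf("SET_%02d", 1:10))

es_tab <- do.call(rbind, lapply(names(gene_sets), function(nm) {
  sig <- preranked_significance(ranked, gene_sets[[nm]], n_perm = 200,
                                seed = 20235L)
  data.frame(gene_set = nm, es = sig$es, perm_p = sig$p)
}))
es_tab$fdr <- stats::p.adjust(es_tab$perm_p, method = "BH")

scores <- do.call(cbind, lapply(gene_sets, function(gs) {
  s <- ustat_pathway_score(norm, gs, maturation)
  if (is.null(s)) rep(NA_real_, nrow(norm)) else s
}))
colnames(scores) <- names(gene_sets)
rownames(scores) <- rownames(norm)
ok <- colSums(is.na(scores)) == 0
panel <- summarize_scores(scores[, ok, drop = FALSE], labels, "rowz")

dir.create("results/signatures", showWarnings = FALSE, recursive = TRUE)
utils::write.table(markers, "results/signatures/markers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(ranked, "results/signatures/ranked_list.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(es_tab, "results/signatures/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(gene_set = rownames(panel), panel,
                              check.names = FALSE),
                   "results/signatures/es_panel.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("markers: %d  maturation DEGs: %d  scored pathways: %d\n",
            nrow(markers), length(maturation), sum(ok)))
cat(sprintf("top |ES|: %s (ES %.2f, permutation p %.3f)\n",
            es_tab$gene_set[which.max(abs(es_tab$es))],
            es_tab$es[which.max(abs(es_tab$es))],
            es_tab$perm_p[which.max(abs(es_tab$es))]))
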