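#!/usr/bin/env Rscript
# 06 — BCR repertoire: lineages, somatic hypermutation, R/S, connectivity.
#
# Clonal lineages at 85% CDR3 homology (clones at 98%), per-region SHM
# frequencies, aggregate R/S ratios with the silent floor and the 2.9
# antigen-selection flag, Morisita-Horn connectivity between clusters
# (per-subject, averaged, with and without singletons) and the ANOVA/Tukey
# permutation test for mutation-frequency differences between clusters.

suppressPackageStartupMessages(library(bmpc))

records <- read_airr("results/data/rearrangements.tsv")
lab_tab <- utils::read.delim("results/data/labels.tsv")
labels <- stats::setNames(as.character(lab_tab$cluster), lab_tab$cell_id)
keep <- utils::read.delim("results/qc/keep.tsv")$cell_id
labels <- labels[names(labels) %in% keep]

jn <- join_vdj_expression(keep, records)
cat(sprintf("VDJ match rate: %.2f  Ig-dominant cells: %.2f\n",
            jn$match_rate, mean(jn$matched$ig_dominant)))

lin <- cluster_lineages(records)
clones <- track_clones(records)
prof <- mutation_profiles(records)
glob <- prof[prof$region == "global", ]

cat(sprintf("lineages: %d  clones: %d  mean global SHM: %.2f%%\n",
            length(unique(lin)), length(unique(clones)),
            100 * mean(glob$frequency)))

rs_tab <- do.call(rbind, lapply(
  c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR", "FR", "global"),
  function(rg) {
    rows <- prof[prof$region == rg, ]
    rs <- rs_ratio(data.frame(region = rg,
                              n_replacement = sum(rows$n_replacement),
                              n_silent = sum(rows$n_silent)), rg)
    data.frame(region = rg, r = rs$r_count, s = rs$s_count,
               ratio = round(rs$ratio, 2), selected = rs$selected)
  }))
print(rs_tab, row.names = FALSE)

ab <- lineage_cluster_table(lin, labels, records$cell_id)
ab_ns <- lineage_cluster_table(lin, labels, records$cell_id,
                               remove_singletons = TRUE)
subj <- records$subject_id
per_subject <- Filter(Negate(is.null),
  lapply(split(seq_len(nrow(records)), subj), function(i) {
    a <- lineage_cluster_table(lin[i], labels, records$cell_id[i])
    if (nrow(a) == 0) NULL else morisita_matrix(a)
  }))
mor <- morisita_average(per_subject)

freqs <- stats::setNames(glob$frequency,
                         records$cell_id[match(glob$sequence_id,
                                               records$sequence_id)])
common <- intersect(names(freqs), names(labels))
perm <- mutation_permutation_test(freqs[common], labels[common],
                                  n_perm = 100, seed = 20237L)
cat(sprintf("ANOVA p: %.4g  pairs with permutation p < 0.05: %d of %d\n",
            perm$anova_p, sum(perm$pairs$perm_p < 0.05), nrow(perm$pairs)))

dir.create("results/repertoire", showWarnings = FALSE, recursive = TRUE)
w <- function(x, f) utils::write.table(x, file.path("results/repertoire", f),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)
w(data.frame(sequence_id = names(lin), lineage = as.character(lin),
             clone = as.character(clones)), "lineages.tsv")
w(prof, "mutation_profiles.tsv")
w(rs_tab, "rs_table.tsv")
w(data.frame(cluster = rownames(mor), mor, check.names = FALSE),
  "morisita_mean.tsv")
w(perm$pairs, "permutation_test.tsv")
w(lineage_links(ab_ns), "lineage_links_nosingletons.tsv")
w(lineage_links(ab), "lineage_links.tsv")
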