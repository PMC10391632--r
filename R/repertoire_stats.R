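# Repertoire connectivity (lineage x cluster abundances, Morisita-Horn
# overlap) and the ANOVA/Tukey permutation test for mutation-frequency
# differences between clusters.

#' Lineage x cluster abundance table
#'
#' Entry (l, c) counts the cells of lineage l carrying cluster label c.
#' Records without a cell label are dropped (and counted). Singleton removal
#' drops lineages totalling one cell, which enriches for larger clones.
#'
#' @param lineage_ids named lineage id per record (names = sequence ids).
#' @param cell_labels named cluster label per cell id.
#' @param cell_ids cell id per record (same order as `lineage_ids`).
#' @param remove_singletons drop one-cell lineages.
#' @return integer matrix lineages x clusters; attribute `n_unlabeled`
#'   counts dropped records.
#' @export
lineage_cluster_table <- function(lineage_ids, cell_labels, cell_ids,
                                  remove_singletons = FALSE) {
  labels <- cell_labels[cell_ids]
  keep <- !is.na(labels) & !is.na(lineage_ids)
  n_unlabeled <- sum(!keep)
  tab <- table(lineage = lineage_ids[keep], cluster = as.character(labels[keep]))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  if (remove_singletons) {
    m <- m[rowSums(m) > 1, , drop = FALSE]
    if (nrow(m) == 0) warning("all lineages are singletons; empty table")
  }
  attr(m, "n_unlabeled") <- n_unlabeled
  m
}

#' Morisita-Horn overlap index between two abundance profiles
#'
#' `C(x, y) = 2 * sum(x_i y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`
#' with X, Y the profile totals. C is 1 for identical repertoires (at any
#' finite counts) and 0 for disjoint supports.
#'
#' @param x,y non-negative abundance vectors over the same lineages.
#' @return overlap in `[0, 1]`; NA when either profile is empty.
#' @export
morisita_index <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0) return(NA_real_)
  # algebraically (sum(x^2)/X^2 + sum(y^2)/Y^2) * X * Y, arranged so that
  # identical profiles yield exactly 1 in floating point
  denom <- sum(x^2) * (Y / X) + sum(y^2) * (X / Y)
  2 * sum(x * y) / denom
}

#' Pairwise Morisita-Horn overlap between cell clusters
#'
#' @param abundance lineages x clusters matrix from
#'   [lineage_cluster_table()]. Clusters with zero cells are excluded and
#'   reported via the `excluded_clusters` attribute.
#' @return symmetric cluster x cluster matrix with unit diagonal.
#' @export
morisita_matrix <- function(abundance) {
  if (nrow(abundance) == 0) stop("input error: no lineages")
  totals <- colSums(abundance)
  empty <- names(totals)[totals == 0]
  if (length(empty) > 0) {
    message("clusters with zero cells excluded: ",
            paste(empty, collapse = ", "))
  }
  ab <- abundance[, totals > 0, drop = FALSE]
  k <- ncol(ab)
  m <- matrix(NA_real_, k, k, dimnames = list(colnames(ab), colnames(ab)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      m[i, j] <- m[j, i] <- morisita_index(ab[, i], ab[, j])
    }
  }
  attr(m, "excluded_clusters") <- empty
  m
}

#' Average Morisita matrix over subjects
#'
#' Arithmetic mean of per-subject matrices over the subjects in which both
#' clusters are non-empty.
#'
#' @param matrices list of per-subject Morisita matrices.
#' @return averaged matrix over the union of cluster names.
#' @export
morisita_average <- function(matrices) {
  clusters <- sort(unique(unlist(lapply(matrices, colnames))))
  acc <- matrix(0, length(clusters), length(clusters),
                dimnames = list(clusters, clusters))
  cnt <- acc
  for (m in matrices) {
    cl <- colnames(m)
    ok <- !is.na(m)
    acc[cl, cl] <- acc[cl, cl] + ifelse(ok, m, 0)
    cnt[cl, cl] <- cnt[cl, cl] + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Circos-ready lineage link table
#'
#' One row per lineage per unordered cluster pair it spans:
#' (cluster_from, cluster_to, lineage, count = cells involved).
#'
#' @param abundance lineages x clusters matrix.
#' @return data frame of links.
#' @export
lineage_links <- function(abundance) {
  rows <- list()
  cl <- colnames(abundance)
  for (l in seq_len(nrow(abundance))) {
    present <- which(abundance[l, ] > 0)
    if (length(present) < 2) next
    pairs <- utils::combn(present, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_from = cl[i], cluster_to = cl[j],
        lineage = rownames(abundance)[l],
        count = abundance[l, i] + abundance[l, j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cluster_from = character(0), cluster_to = character(0),
                      lineage = character(0), count = integer(0)))
  }
  do.call(rbind, rows)
}

# --- fast one-way ANOVA + Tukey HSD ---------------------------------------
# Vectorized equivalents of stats::aov / stats::TukeyHSD for a single
# grouping factor (verified against them in the test suite); needed because
# the permutation protocol evaluates them tens of thousands of times.

anova_tukey <- function(y, group_idx, group_sizes, pairs) {
  k <- length(group_sizes)
  n <- length(y)
  sums <- rowsum(y, group_idx, reorder = TRUE)
  means <- sums / group_sizes
  grand <- sum(y) / n
  ssb <- sum(group_sizes * (means - grand)^2)
  sst <- sum(y^2) - n * grand^2
  sse <- sst - ssb
  df1 <- k - 1
  df2 <- n - k
  if (sse <= max(1e-12 * max(sst, 1), 0)) {
    # zero residual variance: identical values within groups
    if (ssb <= 1e-12 * max(sst, 1)) {
      return(list(anova_p = 1,
                  tukey_p = rep(1, ncol(pairs))))
    }
    return(list(anova_p = 0,
                tukey_p = ifelse(means[pairs[1, ]] == means[pairs[2, ]],
                                 1, 0)))
  }
  f <- (ssb / df1) / (sse / df2)
  anova_p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  mse <- sse / df2
  i <- pairs[1, ]; j <- pairs[2, ]
  se <- sqrt(mse / 2 * (1 / group_sizes[i] + 1 / group_sizes[j]))
  q <- abs(means[i] - means[j]) / se
  tukey_p <- stats::ptukey(q, k, df2, lower.tail = FALSE)
  list(anova_p = anova_p, tukey_p = tukey_p)
}

#' Permutation test for mutation-frequency differences between clusters
#'
#' Observed statistics: one-way ANOVA F-test over clusters followed by
#' Tukey's HSD for every cluster pair. For each permutation the mutation
#' frequencies are shuffled across all cells (labels fixed) and the same
#' statistics recomputed. The permutation p-value of a pair is
#' `#\{permutations with Tukey p* < observed Tukey p\} / n_perm`
#' (strict inequality, as printed; generalizing the published n_perm = 100).
#' `compare = "anova"` applies the same formula to the ANOVA p-value
#' instead.
#'
#' @param freqs named per-cell global mutation frequencies (cells lacking a
#'   value are dropped listwise).
#' @param labels named cluster labels.
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @param compare "tukey" (per-pair, default) or "anova".
#' @return list: `anova_p`, `pairs` (data frame with observed Tukey p and
#'   permutation p per cluster pair), `anova_perm_p`, `n_perm`,
#'   `excluded_clusters`.
#' @export
mutation_permutation_test <- function(freqs, labels, n_perm = 100L,
                                      seed = 1L,
                                      compare = c("tukey", "anova")) {
  compare <- match.arg(compare)
  common <- intersect(names(freqs)[!is.na(freqs)], names(labels))
  y <- as.numeric(freqs[common])
  g <- as.character(labels[common])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("clusters with < 2 cells excluded: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    y <- y[keep]; g <- g[keep]
  }
  cl <- sort(unique(g))
  if (length(cl) < 2) stop("input error: need >= 2 clusters with >= 2 cells")
  gi <- match(g, cl)
  sizes <- as.integer(table(factor(g, levels = cl)))
  pairs <- utils::combn(seq_along(cl), 2)
  obs <- anova_tukey(y, gi, sizes, pairs)
  set.seed(seed)
  exceed <- integer(ncol(pairs))
  exceed_anova <- 0L
  for (b in seq_len(n_perm)) {
    yb <- y[sample.int(length(y))]
    perm <- anova_tukey(yb, gi, sizes, pairs)
    exceed <- exceed + (perm$tukey_p < obs$tukey_p)
    exceed_anova <- exceed_anova + (perm$anova_p < obs$anova_p)
  }
  pair_tab <- data.frame(
    cluster_a = cl[pairs[1, ]], cluster_b = cl[pairs[2, ]],
    tukey_p = obs$tukey_p,
    perm_p = if (compare == "tukey") exceed / n_perm
             else rep(exceed_anova / n_perm, ncol(pairs)),
    stringsAsFactors = FALSE)
  list(anova_p = obs$anova_p, pairs = pair_tab,
       anova_perm_p = exceed_anova / n_perm, n_perm = n_perm,
       excluded_clusters = small)
}

#' Join expression barcodes with VDJ records
#'
#' Inner join on cell barcode; duplicate barcodes in the rearrangement table
#' keep the record with the highest `duplicate_count`. The dominance flag
#' marks cells whose consensus-isotype transcript count exceeds
#' `dominance_min` (default 100).
#'
#' @param barcodes cell barcodes of the expression matrix.
#' @param records AIRR-style data frame.
#' @param dominance_min transcript-count threshold for Ig dominance.
#' @return list: `matched` (records restricted to shared barcodes, plus
#'   `ig_dominant` flag), `match_rate` = matched / expression cells.
#' @export
join_vdj_expression <- function(barcodes, records, dominance_min = 100L) {
  dup <- records[order(records$cell_id, -records$duplicate_count), ,
                 drop = FALSE]
  dupes <- duplicated(dup$cell_id)
  if (any(dupes)) {
    message(sum(dupes), " duplicate barcode record(s) dropped ",
            "(kept highest duplicate_count)")
  }
  dup <- dup[!dupes, , drop = FALSE]
  matched <- dup[dup$cell_id %in% barcodes, , drop = FALSE]
  matched$ig_dominant <- matched$duplicate_count > dominance_min
  rownames(matched) <- NULL
  list(matched = matched,
       match_rate = nrow(matched) / length(barcodes))
}
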