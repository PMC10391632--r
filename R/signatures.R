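# Marker thresholding, the NLP x sign prerank statistic, preranked
# weighted-KS enrichment with permutation significance, and the pathway
# U-score (mean normalized expression of maturation-associated pathway
# genes) with cluster-level summaries.

#' Marker rule
#'
#' Published thresholds: a marker gene is significantly up-regulated with
#' average natural-log fold change > 0.25 and Bonferroni-adjusted p < 0.05.
#'
#' @param lfc_min natural-log fold-change threshold.
#' @param alpha adjusted-p cutoff.
#' @return a `bmpc_marker_rule` list.
#' @export
marker_rule <- function(lfc_min = 0.25, alpha = 0.05) {
  if (lfc_min < 0 || alpha <= 0 || alpha >= 1) {
    stop("invalid marker rule: need lfc_min >= 0 and alpha in (0, 1)")
  }
  structure(list(lfc_min = lfc_min, alpha = alpha),
            class = "bmpc_marker_rule")
}

#' Two-group rank-sum differential expression (built-in fallback)
#'
#' A simple engine so the pipeline runs end-to-end on synthetic data:
#' Wilcoxon rank-sum p-value per gene plus the natural-log fold change of
#' group means. Externally computed DE tables (e.g. from a hurdle model)
#' can be supplied anywhere this output is accepted.
#'
#' @param norm_expr cells x genes normalized expression matrix.
#' @param labels named cluster labels for the rows of `norm_expr`.
#' @param group1,group2 cluster ids to compare (group1 vs group2).
#' @return data frame: `gene`, `avgLogFC`, `p_raw`, `p_adj` (Bonferroni),
#'   `pct_expr_1`, `pct_expr_2`, `comparison`.
#' @export
de_rank_sum <- function(norm_expr, labels, group1, group2) {
  labels <- labels[rownames(norm_expr)]
  i1 <- which(labels == group1)
  i2 <- which(labels == group2)
  if (length(i1) < 2 || length(i2) < 2) {
    stop("input error: both groups need at least 2 cells")
  }
  x1 <- norm_expr[i1, , drop = FALSE]
  x2 <- norm_expr[i2, , drop = FALSE]
  p <- vapply(seq_len(ncol(norm_expr)), function(j) {
    if (all(x1[, j] == x1[1, j]) && all(x2[, j] == x2[1, j]) &&
        x1[1, j] == x2[1, j]) return(1)
    stats::wilcox.test(x1[, j], x2[, j], exact = FALSE)$p.value
  }, numeric(1))
  lfc <- log_fc(colMeans(x1), colMeans(x2))
  data.frame(gene = colnames(norm_expr),
             avgLogFC = as.numeric(lfc),
             p_raw = p,
             p_adj = pmin(1, p * ncol(norm_expr)),
             pct_expr_1 = as.numeric(colMeans(x1 > 0)),
             pct_expr_2 = as.numeric(colMeans(x2 > 0)),
             comparison = paste0(group1, "_vs_", group2),
             stringsAsFactors = FALSE)
}

#' Filter a DE table to marker genes (or top DEGs)
#'
#' Bonferroni adjustment over `n_tests`: `p_adj = min(1, p_raw * n_tests)`.
#' A marker satisfies `avgLogFC > lfc_min` and `p_adj < alpha`. In top-DEG
#' mode, significantly down-regulated genes (`avgLogFC < -lfc_min`) are also
#' returned, flagged by `direction`.
#'
#' @param de DE table with columns `gene`, `avgLogFC`, `p_raw`.
#' @param rule a [marker_rule()].
#' @param n_tests number of tests for the Bonferroni correction; defaults to
#'   the row count (a smaller value triggers a warning).
#' @param include_down `TRUE` for top-DEG mode.
#' @return the retained rows with `p_adj` and `direction` columns.
#' @export
filter_markers <- function(de, rule = marker_rule(), n_tests = nrow(de),
                           include_down = FALSE) {
  if (n_tests < nrow(de)) {
    warning("n_tests smaller than the number of rows; using row count")
    n_tests <- nrow(de)
  }
  de$p_adj <- pmin(1, de$p_raw * n_tests)
  up <- de$avgLogFC > rule$lfc_min & de$p_adj < rule$alpha
  down <- de$avgLogFC < -rule$lfc_min & de$p_adj < rule$alpha
  keep <- if (include_down) up | down else up
  out <- de[keep, , drop = FALSE]
  out$direction <- ifelse(out$avgLogFC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Build the preranked gene list (NLP x sign of fold change)
#'
#' Score = -log10(max(p_raw, p_floor)) * sign(avgLogFC), ordered descending;
#' ties broken by |avgLogFC| descending, then gene symbol ascending.
#'
#' @param de DE table with `gene`, `avgLogFC`, `p_raw`.
#' @param p_floor floor applied before the log so p = 0 stays finite.
#' @return data frame `gene`, `score`, ordered.
#' @export
prerank_statistic <- function(de, p_floor = 1e-300) {
  score <- -log10(pmax(de$p_raw, p_floor)) * sign(de$avgLogFC)
  ord <- order(-score, -abs(de$avgLogFC), de$gene)
  data.frame(gene = de$gene[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' Preranked weighted Kolmogorov-Smirnov enrichment score
#'
#' The running sum increments by `|score|^exponent / sum over hits` at set
#' members and decrements by `1 / (N - N_set)` elsewhere. The enrichment
#' score is the signed running-sum value of maximal absolute deviation (on
#' an exact tie between the positive and negative extreme, the positive one
#' is taken). `exponent = 0` reduces to the classic unweighted KS statistic.
#'
#' @param ranked data frame from [prerank_statistic()].
#' @param gene_set character vector of gene symbols.
#' @param exponent weighting exponent (default 1).
#' @return list `es`, `leading_edge`, `running` (the full running sum);
#'   `NULL` if the set does not overlap the ranked list.
#' @export
preranked_es <- function(ranked, gene_set, exponent = 1) {
  hit <- ranked$gene %in% gene_set
  n <- nrow(ranked)
  n_hit <- sum(hit)
  if (n_hit == 0) {
    message("gene set has no overlap with the ranked list")
    return(NULL)
  }
  w <- abs(ranked$score)^exponent
  w[!hit] <- 0
  total_w <- sum(w)
  inc <- if (total_w > 0) w / total_w else ifelse(hit, 1 / n_hit, 0)
  dec <- if (n > n_hit) 1 / (n - n_hit) else 0
  steps <- ifelse(hit, inc, -dec)
  running <- cumsum(steps)
  max_pos <- max(running)
  min_neg <- min(running)
  # on a (numerical) tie between the positive and negative extreme the
  # positive deviation is taken; the tolerance absorbs accumulator rounding
  es <- if (max_pos >= abs(min_neg) - 1e-10) max_pos else min_neg
  if (es > 0) {
    peak <- which.max(running)
    le <- ranked$gene[seq_len(peak)][hit[seq_len(peak)]]
  } else if (es < 0) {
    peak <- which.min(running)
    le <- ranked$gene[peak:n][hit[peak:n]]
  } else {
    le <- character(0)
  }
  list(es = es, leading_edge = le, running = running)
}

#' Permutation significance of a preranked enrichment score
#'
#' Random gene sets of the same size are drawn from the ranked list;
#' `p = (1 + #\{|ES*| >= |ES|\}) / (n_perm + 1)`, seed-deterministic.
#'
#' @param ranked ranked list.
#' @param gene_set gene set (must not exceed the ranked list).
#' @param n_perm number of random sets (>= 1).
#' @param seed RNG seed.
#' @param exponent weighting exponent passed to [preranked_es()].
#' @return list `es`, `p`, `n_perm`.
#' @export
preranked_significance <- function(ranked, gene_set, n_perm = 1000L,
                                   seed = 1L, exponent = 1) {
  if (n_perm < 1) stop("input error: n_perm must be >= 1")
  members <- intersect(gene_set, ranked$gene)
  if (length(members) > nrow(ranked)) {
    stop("input error: gene set larger than the ranked list")
  }
  obs <- preranked_es(ranked, members, exponent)
  if (is.null(obs)) return(NULL)
  set.seed(seed)
  m <- length(members)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    rnd <- sample(ranked$gene, m)
    es_b <- preranked_es(ranked, rnd, exponent)$es
    if (abs(es_b) >= abs(obs$es)) exceed <- exceed + 1L
  }
  list(es = obs$es, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Union of top DEGs across maturation comparisons
#'
#' Maturation-associated DEGs: genes passing the top-DEG rule (up- or
#' down-regulated) in any adjacent-stage comparison or in the early-vs-late
#' comparison.
#'
#' @param adjacent_pair_de list of DE tables for adjacent cluster pairs.
#' @param early_vs_late_de DE table for the early-vs-late comparison (may be
#'   NULL).
#' @param rule a [marker_rule()].
#' @return character vector of gene symbols (each gene once).
#' @export
maturation_deg_union <- function(adjacent_pair_de, early_vs_late_de = NULL,
                                 rule = marker_rule()) {
  tables <- c(adjacent_pair_de,
              if (!is.null(early_vs_late_de)) list(early_vs_late_de))
  if (length(tables) == 0) {
    warning("no DE tables supplied; empty maturation set")
    return(character(0))
  }
  genes <- unlist(lapply(tables, function(de) {
    filter_markers(de, rule, include_down = TRUE)$gene
  }))
  unique(genes)
}

#' Per-cell pathway U-score
#'
#' The pathway score of a cell is the mean normalized expression over the
#' genes in `pathway` that are also maturation-associated DEGs. Not
#' applicable (NULL) when the intersection is empty.
#'
#' @param norm_expr cells x genes normalized expression.
#' @param pathway_genes pathway member symbols.
#' @param maturation_set maturation-associated DEG symbols.
#' @return named numeric vector of per-cell scores, or NULL.
#' @export
ustat_pathway_score <- function(norm_expr, pathway_genes, maturation_set) {
  genes <- intersect(intersect(pathway_genes, maturation_set),
                     colnames(norm_expr))
  if (length(genes) == 0) {
    message("pathway has no maturation-associated genes; score not applicable")
    return(NULL)
  }
  rowMeans(norm_expr[, genes, drop = FALSE])
}

#' Summarize per-cell pathway scores into a cluster x pathway panel
#'
#' Cluster value = mean of member-cell scores. Row scaling operates across
#' clusters within each pathway: `"rowz"` standardizes to mean 0 / sd 1
#' (skipped with a flag when the sd is 0), `"minmax"` maps to `[0, 1]`.
#'
#' @param scores cells x pathways matrix of per-cell scores.
#' @param labels named cluster labels covering every cell.
#' @param scaling one of "none", "rowz", "minmax".
#' @return matrix pathways x clusters with attribute `scaling_skipped`
#'   naming pathways whose scaling was skipped (zero spread).
#' @export
summarize_scores <- function(scores, labels, scaling = c("none", "rowz",
                                                         "minmax")) {
  scaling <- match.arg(scaling)
  labels <- labels[rownames(scores)]
  if (anyNA(labels)) stop("input error: every cell must be labeled")
  labels <- as.character(labels)
  cl <- sort(unique(labels))
  means <- vapply(cl, function(k) {
    colMeans(scores[labels == k, , drop = FALSE])
  }, numeric(ncol(scores)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = ncol(scores), ncol = length(cl))
  }
  dimnames(means) <- list(colnames(scores), cl)
  skipped <- character(0)
  if (scaling != "none" && ncol(means) > 1) {
    for (i in seq_len(nrow(means))) {
      row <- means[i, ]
      if (max(row) - min(row) == 0) {
        skipped <- c(skipped, rownames(means)[i])
        next
      }
      means[i, ] <- if (scaling == "rowz") {
        (row - mean(row)) / stats::sd(row)
      } else {
        (row - min(row)) / (max(row) - min(row))
      }
    }
  } else if (scaling != "none") {
    skipped <- rownames(means)
    message("single cluster: scaling skipped, raw means returned")
  }
  attr(means, "scaling_skipped") <- skipped
  means
}
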