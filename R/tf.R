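# Transcription-factor selection, cluster assignment, distinctness labeling
# and interaction-network filtering.

#' TF analysis parameters
#'
#' Published rules: a TF must be expressed in at least 10% of cells of some
#' cluster; visualization additionally requires expression in at least 20%
#' of the assigned cluster and a natural-log fold change >= 0.25 between the
#' highest- and lowest-expressing clusters; a TF is "cluster distinct" when
#' the fold change between the top and second cluster is >= 0.25; STRING
#' edges are kept only above combined score 500.
#'
#' @param min_frac_any_cluster expressing-fraction gate for selection.
#' @param min_frac_assigned expressing-fraction gate for visualization.
#' @param distinct_lfc natural-log fold-change threshold.
#' @param min_combined_score STRING combined-score threshold (exclusive).
#' @return a `bmpc_tf_params` list.
#' @export
tf_params <- function(min_frac_any_cluster = 0.10,
                      min_frac_assigned = 0.20,
                      distinct_lfc = 0.25,
                      min_combined_score = 500L) {
  p <- list(min_frac_any_cluster = min_frac_any_cluster,
            min_frac_assigned = min_frac_assigned,
            distinct_lfc = distinct_lfc,
            min_combined_score = as.integer(min_combined_score))
  if (any(c(p$min_frac_any_cluster, p$min_frac_assigned) < 0) ||
      any(c(p$min_frac_any_cluster, p$min_frac_assigned) > 1) ||
      p$distinct_lfc < 0) {
    stop("invalid TF parameters")
  }
  structure(p, class = "bmpc_tf_params")
}

# expressing fraction (normalized value > 0) per gene per cluster;
# returns genes x clusters
expr_fraction_by_cluster <- function(norm_expr, labels, genes) {
  labels <- as.character(labels[rownames(norm_expr)])
  cl <- sort(unique(labels))
  out <- vapply(cl, function(k) {
    colMeans(norm_expr[labels == k, genes, drop = FALSE] > 0)
  }, numeric(length(genes)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(genes))
  dimnames(out) <- list(genes, cl)
  out
}

mean_expr_by_cluster <- function(norm_expr, labels, genes) {
  labels <- as.character(labels[rownames(norm_expr)])
  cl <- sort(unique(labels))
  out <- vapply(cl, function(k) {
    colMeans(norm_expr[labels == k, genes, drop = FALSE])
  }, numeric(length(genes)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(genes))
  dimnames(out) <- list(genes, cl)
  out
}

#' Select candidate TFs
#'
#' Retains TFs that are flagged candidates (highly variable feature, marker,
#' or DEG in a maturation comparison — computed upstream or supplied) AND
#' expressed (normalized value > 0) in at least `min_frac_any_cluster` of
#' the cells of at least one cluster.
#'
#' @param norm_expr cells x genes normalized expression.
#' @param labels named cluster labels.
#' @param tf_universe TF gene symbols.
#' @param candidate_flags named logical vector over `tf_universe` (HVF /
#'   marker / DEG membership).
#' @param params a [tf_params()].
#' @return character vector of retained TFs.
#' @export
select_tfs <- function(norm_expr, labels, tf_universe, candidate_flags,
                       params = tf_params()) {
  if (length(tf_universe) == 0) {
    warning("empty TF universe")
    return(character(0))
  }
  tfs <- intersect(tf_universe, colnames(norm_expr))
  tfs <- tfs[candidate_flags[tfs] %in% TRUE]
  if (length(tfs) == 0) return(character(0))
  frac <- expr_fraction_by_cluster(norm_expr, labels, tfs)
  tfs[apply(frac, 1, max) >= params$min_frac_any_cluster]
}

#' Assign each TF to the cluster with the highest mean expression
#'
#' Ties are broken toward the smaller cluster id (and logged). The distinct
#' flag marks TFs whose natural-log fold change between the assigned and the
#' second-highest cluster is >= `distinct_lfc` (not applicable with a single
#' cluster). The visualization gate additionally requires an expressing
#' fraction >= `min_frac_assigned` in the assigned cluster and a
#' top-vs-bottom fold change >= `distinct_lfc`.
#'
#' @param norm_expr cells x genes normalized expression.
#' @param labels named cluster labels.
#' @param tfs TF subset from [select_tfs()].
#' @param params a [tf_params()].
#' @param stage_map optional named map cluster -> stage; adds a stage-level
#'   assignment computed the same way over stage means.
#' @return data frame: `tf`, `cluster` (assigned), `expressed_fraction`,
#'   `distinct`, `viz_pass`, and `stage` if a stage map was given.
#' @export
assign_tf_clusters <- function(norm_expr, labels, tfs,
                               params = tf_params(), stage_map = NULL) {
  if (length(tfs) == 0) {
    return(data.frame(tf = character(0), cluster = character(0),
                      expressed_fraction = numeric(0), distinct = logical(0),
                      viz_pass = logical(0), stringsAsFactors = FALSE))
  }
  means <- mean_expr_by_cluster(norm_expr, labels, tfs)
  frac <- expr_fraction_by_cluster(norm_expr, labels, tfs)
  cl <- colnames(means)
  single <- length(cl) == 1
  out <- do.call(rbind, lapply(seq_along(tfs), function(i) {
    m <- means[i, ]
    top <- which(m == max(m))
    if (length(top) > 1) {
      message("TF ", tfs[i], ": tie for highest expression; assigned to ",
              "cluster ", cl[top[1]])
    }
    top <- top[1]
    distinct <- NA
    if (!single) {
      second <- max(m[-top])
      distinct <- log_fc(m[top], second) >= params$distinct_lfc
    }
    viz <- frac[i, top] >= params$min_frac_assigned &&
      (single || log_fc(m[top], min(m)) >= params$distinct_lfc)
    data.frame(tf = tfs[i], cluster = cl[top],
               expressed_fraction = frac[i, top],
               distinct = distinct, viz_pass = viz,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(stage_map)) {
    stages <- stage_map[as.character(labels[rownames(norm_expr)])]
    stage_means <- mean_expr_by_cluster(
      norm_expr, stats::setNames(stages, rownames(norm_expr)), tfs)
    out$stage <- colnames(stage_means)[apply(stage_means, 1, which.max)]
  }
  rownames(out) <- NULL
  out
}

#' Filter protein-interaction edges to within-cluster, high-confidence pairs
#'
#' An edge is retained iff its combined score exceeds
#' `min_combined_score` and both endpoints are assigned to the same cluster
#' (`mode = "both"`, the default, matching the within-cluster networks;
#' `mode = "either"` requires only one endpoint's cluster to match the
#' other's assignment, i.e. retains any same-score pair with at least the
#' two endpoints present). Edges with endpoints missing from the assignment
#' table are dropped and counted.
#'
#' @param edges edge table from [read_interaction_edges()].
#' @param assignments assignment table from [assign_tf_clusters()].
#' @param params a [tf_params()].
#' @param mode "both" or "either".
#' @return retained edges with a `cluster` column; attribute
#'   `n_dropped_missing` counts edges with unassigned endpoints.
#' @export
filter_interactions <- function(edges, assignments, params = tf_params(),
                                mode = c("both", "either")) {
  mode <- match.arg(mode)
  assigned <- stats::setNames(assignments$cluster, assignments$tf)
  known <- edges$protein_a %in% names(assigned) &
    edges$protein_b %in% names(assigned)
  n_missing <- sum(!known)
  edges <- edges[known, , drop = FALSE]
  ca <- assigned[edges$protein_a]
  cb <- assigned[edges$protein_b]
  same <- ca == cb
  keep <- edges$combined_score > params$min_combined_score &
    (if (mode == "both") same else TRUE)
  out <- edges[keep, , drop = FALSE]
  out$cluster <- ifelse(same[keep], ca[keep], NA_character_)
  rownames(out) <- NULL
  attr(out, "n_dropped_missing") <- n_missing
  out
}
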