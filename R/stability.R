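# Rand-Index computation and the clustering-parameter-grid stability
# protocol. Clustering itself is a pluggable contract: any function mapping
# (grid point, data handle) -> integer labels can be scanned.

#' Rand Index between two labelings
#'
#' The plain (unadjusted) Rand Index: the proportion of cell pairs on which
#' two partitions agree (co-clustered in both or separated in both), from 0
#' (low) to 1 (high). Symmetric and invariant to relabeling either argument.
#'
#' @param a,b label vectors over the same cells (same length and, if named,
#'   the same names).
#' @return RI in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("input error: labelings must cover the same cells")
  }
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("input error: labelings must cover the same cells")
    }
    b <- b[names(a)]
  }
  n <- length(a)
  if (n < 2) stop("input error: need at least 2 cells")
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  1 - (sum_a + sum_b - 2 * sum_ij) / choose(n, 2)
}

#' Stability grid of clustering parameters
#'
#' Defaults are the published sweep: dimensions 50/60/70, principal
#' components 30/50/70, resolutions 0.2/0.5/1.0/1.5 (36 grid points).
#'
#' @param dims integer set of integration-dimension values.
#' @param pcs integer set of principal-component counts.
#' @param resolutions real set of clustering resolutions.
#' @return a `bmpc_stability_grid` data frame of grid points.
#' @export
stability_grid <- function(dims = c(50L, 60L, 70L),
                           pcs = c(30L, 50L, 70L),
                           resolutions = c(0.2, 0.5, 1.0, 1.5)) {
  if (length(dims) == 0 || length(pcs) == 0 || length(resolutions) == 0 ||
      any(c(dims, pcs, resolutions) <= 0)) {
    stop("invalid grid: all parameter sets must be non-empty and positive")
  }
  grid <- expand.grid(dims = dims, pcs = pcs, resolution = resolutions,
                      KEEP.OUT.ATTRS = FALSE)
  class(grid) <- c("bmpc_stability_grid", "data.frame")
  grid
}

#' Run the Rand-Index stability protocol over a parameter grid
#'
#' Calls `labeler(grid_point, data)` for every grid point and computes the
#' Rand Index for every unordered pair of the resulting labelings. The
#' summary statistic is the arithmetic mean over all pairs. Labeler failures
#' at single grid points are recorded and the affected pairs skipped.
#'
#' @param labeler function(point, data) -> label vector; must be
#'   deterministic given a grid point.
#' @param grid a [stability_grid()].
#' @param data data handle passed through to the labeler (for the built-in
#'   labeler: a cells x genes normalized matrix).
#' @return list with `ri` (symmetric matrix, unit diagonal), `mean_ri`
#'   (NA if fewer than two labelings succeeded), `labelings` and `failures`.
#' @export
run_stability_grid <- function(labeler, grid, data) {
  pts <- seq_len(nrow(grid))
  point_name <- sprintf("d%g_p%g_r%g", grid$dims, grid$pcs, grid$resolution)
  labelings <- vector("list", length(pts))
  failures <- character(0)
  for (i in pts) {
    res <- tryCatch(labeler(grid[i, , drop = FALSE], data),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, stats::setNames(conditionMessage(res),
                                              point_name[i]))
    } else {
      labelings[[i]] <- res
    }
  }
  ok <- which(!vapply(labelings, is.null, logical(1)))
  ri <- matrix(NA_real_, length(pts), length(pts),
               dimnames = list(point_name, point_name))
  diag(ri)[ok] <- 1
  if (length(ok) >= 2) {
    pairs <- utils::combn(ok, 2)
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      v <- rand_index(labelings[[i1]], labelings[[i2]])
      ri[i1, i2] <- v
      ri[i2, i1] <- v
    }
    mean_ri <- mean(ri[upper.tri(ri)][!is.na(ri[upper.tri(ri)])])
  } else {
    mean_ri <- NA_real_
    message("stability grid: fewer than two labelings available; ",
            "mean RI not applicable")
  }
  list(ri = ri, mean_ri = mean_ri, labelings = labelings,
       failures = failures)
}

#' Built-in graph-based labeler for synthetic demonstrations
#'
#' A deliberately simple clustering contract implementation: select the top
#' `10 * dims` most variable genes, project onto `pcs` principal components,
#' build a k-nearest-neighbor graph and cut the fast-greedy modularity
#' dendrogram at `max(2, round(5 * resolution))` communities. PCA and the
#' graph are cached per (dims, pcs) so a full grid scan stays cheap.
#'
#' @param k_neighbors neighbors per cell in the kNN graph.
#' @param seed seed applied before each labeling (determinism contract).
#' @return function(point, data) -> integer labels named by cell.
#' @export
pca_graph_labeler <- function(k_neighbors = 20L, seed = 1L) {
  cache <- new.env(parent = emptyenv())
  function(point, data) {
    set.seed(seed)
    key <- sprintf("d%g_p%g", point$dims, point$pcs)
    if (is.null(cache[[key]])) {
      vars <- apply(data, 2, stats::var)
      n_feat <- min(ncol(data), 10L * point$dims)
      feats <- order(vars, decreasing = TRUE)[seq_len(n_feat)]
      n_pc <- min(point$pcs, n_feat - 1L, nrow(data) - 1L)
      pca <- stats::prcomp(data[, feats, drop = FALSE], rank. = n_pc)
      emb <- pca$x
      d <- as.matrix(stats::dist(emb))
      diag(d) <- Inf
      k <- min(k_neighbors, nrow(d) - 1L)
      nn <- t(apply(d, 1, function(x) order(x)[seq_len(k)]))
      edges <- cbind(rep(seq_len(nrow(d)), each = k), as.vector(t(nn)))
      g <- igraph::graph_from_edgelist(edges, directed = FALSE)
      g <- igraph::simplify(g)
      cache[[key]] <- list(graph = g)
    }
    g <- cache[[key]]$graph
    comm <- igraph::cluster_fast_greedy(g)
    k_target <- max(2L, round(5 * point$resolution))
    k_target <- min(k_target, length(igraph::V(g)))
    # cut_at warns (and returns the finest cut) when the dendrogram has
    # fewer communities than requested
    labels <- tryCatch(suppressWarnings(igraph::cut_at(comm, no = k_target)),
                       error = function(e) igraph::membership(comm))
    stats::setNames(as.integer(labels), rownames(data))
  }
}

#' Labeler reading precomputed label files
#'
#' For workflows where clustering ran elsewhere: expects one TSV per grid
#' point named `labels_d<dims>_p<pcs>_r<resolution>.tsv` with columns
#' `cell_id` and `cluster`.
#'
#' @param dir directory of label files.
#' @return function(point, data) -> integer labels named by cell.
#' @export
precomputed_labeler <- function(dir) {
  function(point, data) {
    f <- file.path(dir, sprintf("labels_d%g_p%g_r%g.tsv",
                                point$dims, point$pcs, point$resolution))
    if (!file.exists(f)) stop("no label file for grid point: ", f)
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    stats::setNames(as.integer(tab$cluster), tab$cell_id)
  }
}
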