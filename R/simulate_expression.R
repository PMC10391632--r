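# Synthetic expression generator: negative-binomial UMI counts with cluster
# structure, per-cell mitochondrial / immunoglobulin UMI fractions, optional
# contaminant spikes and optional cells constructed to violate exactly one QC
# rule each. All output is a pure function of (config, seed).

MITO_GENES <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "CO3", "ATP6",
                              "ATP8", "CYB", "ND3", "ND4", "ND4L", "ND5",
                              "ND6"))

IG_GENES <- c("IGHM", "IGHD", "IGHG3", "IGHG1", "IGHA1", "IGHG2", "IGHG4",
              "IGHE", "IGHA2", "IGKC", "IGLC1", "IGLC2", "IGLC3",
              "IGHV1-2", "IGHV1-69", "IGHV3-23", "IGHV3-30", "IGHV4-34",
              "IGHV4-59", "IGHV5-51", "IGKV1-39", "IGKV3-20", "IGLV1-44",
              "IGLV2-14", "IGLV3-25")

#' Default contaminant marker panel
#'
#' Diagnostic markers of non-ASC cell types: CD3E (T cells), FCGR3A/CD16 and
#' CD14 (monocytes), NKG7 and GNLY (NK cells), HBB (erythrocytes), MS4A1/CD20,
#' PAX5 and IRF8 (B cells).
#' @export
CONTAMINANT_MARKERS <- c("CD3E", "FCGR3A", "CD14", "NKG7", "GNLY", "HBB",
                         "MS4A1", "PAX5", "IRF8")

# gene universe layout for a simulation: designated mito / Ig / contaminant
# genes first, then background genes, the first blocks of which serve as
# cluster markers
build_gene_universe <- function(cfg) {
  n_special <- length(MITO_GENES) + length(IG_GENES) + length(CONTAMINANT_MARKERS)
  n_markers <- cfg$n_clusters * cfg$marker_genes_per_cluster
  n_bg <- cfg$n_genes - n_special
  if (n_bg < n_markers + 10L) {
    stop("configuration error: n_genes too small for the designated ",
         "mito/Ig/contaminant genes plus ", n_markers, " cluster markers")
  }
  bg <- sprintf("GENE%05d", seq_len(n_bg))
  symbols <- c(MITO_GENES, IG_GENES, CONTAMINANT_MARKERS, bg)
  marker_idx <- split(n_special + seq_len(n_markers),
                      rep(seq_len(cfg$n_clusters),
                          each = cfg$marker_genes_per_cluster))
  list(symbols = symbols,
       mito = seq_along(MITO_GENES),
       ig = length(MITO_GENES) + seq_along(IG_GENES),
       contam = length(MITO_GENES) + length(IG_GENES) +
         seq_along(CONTAMINANT_MARKERS),
       background = n_special + seq_len(n_bg),
       markers = marker_idx)
}

#' Simulate a cell x gene UMI count matrix with ground truth
#'
#' Counts are drawn from a negative binomial with gene-level baseline means;
#' each cluster's marker genes are spiked by `marker_fold_change` in member
#' cells. Designated mitochondrial (`MT-`) and immunoglobulin (`IGH/IGK/IGL`)
#' genes receive per-cell target UMI fractions drawn uniformly from the
#' configured ranges. A configured fraction of cells is spiked with one
#' diagnostic contaminant marker. Optionally, cells violating exactly one QC
#' rule each are appended (deterministic integer construction, so per-rule
#' violation counts are exact).
#'
#' @param config a [sim_config()].
#' @param qc_design optional list with `thresholds` (a [qc_thresholds()]) and
#'   `n_per_rule`; appends `6 * n_per_rule` cells, each violating exactly one
#'   of the six numeric QC rules.
#' @return list with `counts` (sparse cells x genes dgCMatrix, barcodes as
#'   rownames, gene symbols as colnames) and `truth` (labels, subjects,
#'   contaminants, marker gene map, qc_design cell map).
#' @export
simulate_expression <- function(config, qc_design = NULL) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  genes <- build_gene_universe(cfg)
  n_genes <- cfg$n_genes

  # gene-level baseline means (gamma-distributed for between-gene variability)
  base_mean <- cfg$nb_mean_base * stats::rgamma(n_genes, shape = 2, rate = 2)
  base_mean[genes$contam] <- 0   # contaminant markers silent in true ASCs

  labels <- sample.int(cfg$n_clusters, cfg$n_cells, replace = TRUE,
                       prob = cfg$cluster_proportions)
  subjects <- sprintf("S%d", sample.int(cfg$n_subjects, cfg$n_cells,
                                        replace = TRUE))

  mu <- matrix(rep(base_mean, each = cfg$n_cells), nrow = cfg$n_cells)
  for (k in seq_len(cfg$n_clusters)) {
    in_k <- labels == k
    mu[in_k, genes$markers[[k]]] <- mu[in_k, genes$markers[[k]]] *
      cfg$marker_fold_change
  }

  # per-cell target mito / Ig fractions: scale the designated genes so the
  # expected fraction of the cell's UMIs equals the target
  f_mito <- stats::runif(cfg$n_cells, cfg$mito_fraction_range[1],
                         cfg$mito_fraction_range[2])
  f_ig <- stats::runif(cfg$n_cells, cfg$ig_fraction_range[1],
                       cfg$ig_fraction_range[2])
  other <- setdiff(seq_len(n_genes), c(genes$mito, genes$ig))
  bg_total <- rowSums(mu[, other, drop = FALSE])
  w_mito <- base_mean[genes$mito] / sum(base_mean[genes$mito])
  w_ig <- base_mean[genes$ig] / sum(base_mean[genes$ig])
  scale_tot <- bg_total / (1 - f_mito - f_ig)
  mu[, genes$mito] <- outer(scale_tot * f_mito, w_mito)
  mu[, genes$ig] <- outer(scale_tot * f_ig, w_ig)

  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = cfg$nb_dispersion),
                   nrow = cfg$n_cells)

  # contaminant cells: one diagnostic marker spiked to a nonzero count
  n_cont <- round(cfg$contaminant_fraction * cfg$n_cells)
  contam_cells <- integer(0)
  if (n_cont > 0) {
    contam_cells <- sample.int(cfg$n_cells, n_cont)
    marker_pick <- sample(genes$contam, n_cont, replace = TRUE)
    counts[cbind(contam_cells, marker_pick)] <-
      1L + stats::rnbinom(n_cont, mu = 4, size = 2)
  }

  qc_cells <- list()
  if (!is.null(qc_design)) {
    qd <- build_qc_violation_cells(qc_design$thresholds,
                                   qc_design$n_per_rule %||% 10L, genes)
    qd$cells <- lapply(qd$cells, function(i) i + nrow(counts))
    counts <- rbind(counts, qd$counts)
    extra_n <- nrow(qd$counts)
    labels <- c(labels, rep_len(seq_len(cfg$n_clusters), extra_n))
    subjects <- c(subjects, rep_len(sprintf("S%d", seq_len(cfg$n_subjects)),
                                    extra_n))
    qc_cells <- qd$cells
  }

  barcodes <- sprintf("BC%05d-1", seq_len(nrow(counts)))
  rownames(counts) <- barcodes
  colnames(counts) <- genes$symbols
  names(labels) <- barcodes
  names(subjects) <- barcodes
  qc_cells <- lapply(qc_cells, function(i) barcodes[i])

  truth <- list(
    labels = labels,
    subjects = subjects,
    contaminants = barcodes[sort(contam_cells)],
    marker_genes = lapply(genes$markers, function(i) genes$symbols[i]),
    qc_design = qc_cells
  )
  list(counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                        "generalMatrix"), "CsparseMatrix"),
       truth = truth)
}

# Deterministically construct count vectors for cells that each violate
# exactly one QC rule. Counts are integer-rounded allocations, so the
# realized n_genes / n_umi / fractions are exact by construction.
build_qc_violation_cells <- function(thresholds, n_per_rule, genes) {
  thr <- thresholds
  n_genes_avail <- length(genes$symbols)
  if (n_genes_avail <= ceiling(thr$genes_max_inclusive * 1.05)) {
    stop("configuration error: need more genes than genes_max_inclusive ",
         "to construct a high-gene-count violation")
  }
  if (thr$umi_min_exclusive - thr$genes_min_exclusive < 6) {
    stop("configuration error: umi_min must exceed genes_min by >= 6 to ",
         "construct a UMI-only violation")
  }
  g_mid <- round(sqrt((thr$genes_min_exclusive + 1) *
                      (thr$genes_max_inclusive - 1)))
  g_mid <- min(g_mid, n_genes_avail - 10L)
  u_mid <- max(round(sqrt((thr$umi_min_exclusive + 1) *
                          (thr$umi_max_inclusive - 1))), 2L * g_mid)
  pad <- ceiling((thr$umi_min_exclusive - thr$genes_min_exclusive) / 3)

  specs <- list(
    mito     = list(g = min(g_mid, floor(u_mid * (1 - min(0.9, thr$mito_max * 1.5) - 0.35) * 0.9)),
                    u = u_mid,
                    f_m = min(0.9, thr$mito_max * 1.5), f_i = 0.35),
    genes_low = list(g = max(1L, floor(thr$genes_min_exclusive * 0.6)),
                     u = u_mid, f_m = 0.10, f_i = 0.40),
    umi_low  = list(g = thr$genes_min_exclusive + pad,
                    u = thr$umi_min_exclusive - pad,
                    f_m = 0.02, f_i = 0.08),
    genes_high = list(g = min(ceiling(thr$genes_max_inclusive * 1.05),
                              n_genes_avail),
                      u = max(u_mid, 3L * thr$genes_max_inclusive),
                      f_m = 0.10, f_i = 0.40),
    umi_high = list(g = g_mid, u = ceiling(thr$umi_max_inclusive * 1.2),
                    f_m = 0.10, f_i = 0.40),
    ig_low   = list(g = g_mid, u = u_mid, f_m = 0.10,
                    f_i = thr$ig_fraction_min * 0.4)
  )

  rows <- list()
  cells <- stats::setNames(vector("list", length(specs)), names(specs))
  row_i <- 0L
  for (rule in names(specs)) {
    sp <- specs[[rule]]
    vec <- allocate_cell_counts(sp$g, sp$u, sp$f_m, sp$f_i, genes)
    for (j in seq_len(n_per_rule)) {
      row_i <- row_i + 1L
      rows[[row_i]] <- vec
      cells[[rule]] <- c(cells[[rule]], row_i)
    }
  }
  list(counts = do.call(rbind, rows), cells = cells)
}

# Exact integer allocation of `u` UMIs over `g` genes with mito fraction
# ~f_m and Ig fraction ~f_i (rounded to integers once, never resampled).
allocate_cell_counts <- function(g, u, f_m, f_i, genes) {
  stopifnot(g <= length(genes$symbols), g <= u)
  mito_total <- round(u * f_m)
  ig_total <- round(u * f_i)
  g_m <- if (mito_total > 0) max(1L, min(length(genes$mito),
                                         round(g * f_m))) else 0L
  g_i <- if (ig_total > 0) max(1L, min(length(genes$ig),
                                       round(g * f_i))) else 0L
  g_b <- g - g_m - g_i
  bg_total <- u - mito_total - ig_total
  stopifnot(g_b >= 1, bg_total >= g_b,
            mito_total >= g_m, ig_total >= g_i)
  vec <- integer(length(genes$symbols))
  fill <- function(idx, total) {
    n <- length(idx)
    base <- total %/% n
    extra <- total %% n
    v <- rep(base, n)
    if (extra > 0) v[seq_len(extra)] <- v[seq_len(extra)] + 1L
    v
  }
  if (g_m > 0) vec[genes$mito[seq_len(g_m)]] <- fill(seq_len(g_m), mito_total)
  if (g_i > 0) vec[genes$ig[seq_len(g_i)]] <- fill(seq_len(g_i), ig_total)
  vec[genes$background[seq_len(g_b)]] <- fill(seq_len(g_b), bg_total)
  vec
}
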