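# Cell- and gene-level quality-control filters. Boundary semantics follow
# the printed rules literally: a cell is removed iff
#   mito_fraction >= 0.30  OR  n_genes <= 800  OR  n_umi <= 1000  OR
#   n_genes >= 6000        OR  n_umi >= 60000  OR  ig_fraction <= 0.05.

#' QC thresholds
#'
#' Defaults are the published filter values for 10x bone-marrow ASC data:
#' cells are excluded with >= 30% mitochondrial UMIs, <= 800 detected genes,
#' <= 1000 UMIs, >= 6000 genes or >= 60000 UMIs (doublet control), or <= 5%
#' immunoglobulin UMIs (non-ASC control). The contaminant marker panel and
#' its minimum UMI count drive [flag_contaminants()]; the protocol states no
#' count threshold, so a single UMI suffices by default.
#'
#' @param mito_max maximal allowed mitochondrial UMI fraction (exclusive).
#' @param genes_min_exclusive cells with `n_genes <=` this are excluded.
#' @param umi_min_exclusive cells with `n_umi <=` this are excluded.
#' @param genes_max_inclusive cells with `n_genes >=` this are excluded.
#' @param umi_max_inclusive cells with `n_umi >=` this are excluded.
#' @param ig_fraction_min cells with `ig_fraction <=` this are excluded.
#' @param contaminant_markers diagnostic marker symbols.
#' @param contaminant_min_umi minimal UMI count flagging a contaminant.
#' @return a `bmpc_qc_thresholds` list.
#' @export
qc_thresholds <- function(mito_max = 0.30,
                          genes_min_exclusive = 800L,
                          umi_min_exclusive = 1000L,
                          genes_max_inclusive = 6000L,
                          umi_max_inclusive = 60000L,
                          ig_fraction_min = 0.05,
                          contaminant_markers = CONTAMINANT_MARKERS,
                          contaminant_min_umi = 1L) {
  thr <- list(mito_max = mito_max,
              genes_min_exclusive = as.integer(genes_min_exclusive),
              umi_min_exclusive = as.integer(umi_min_exclusive),
              genes_max_inclusive = as.integer(genes_max_inclusive),
              umi_max_inclusive = as.integer(umi_max_inclusive),
              ig_fraction_min = ig_fraction_min,
              contaminant_markers = contaminant_markers,
              contaminant_min_umi = as.integer(contaminant_min_umi))
  if (!(thr$genes_min_exclusive > 0 &&
        thr$genes_min_exclusive < thr$genes_max_inclusive)) {
    stop("invalid thresholds: need 0 < genes_min < genes_max")
  }
  if (!(thr$umi_min_exclusive > 0 &&
        thr$umi_min_exclusive < thr$umi_max_inclusive)) {
    stop("invalid thresholds: need 0 < umi_min < umi_max")
  }
  if (thr$mito_max < 0 || thr$mito_max > 1 ||
      thr$ig_fraction_min < 0 || thr$ig_fraction_min > 1) {
    stop("invalid thresholds: fractions must lie in [0, 1]")
  }
  class(thr) <- "bmpc_qc_thresholds"
  thr
}

#' Compute per-cell QC metrics
#'
#' @param counts cells x genes count matrix with gene-symbol colnames.
#' @return data frame with one row per cell: `cell_id`, `n_umi`, `n_genes`,
#'   `mito_fraction`, `ig_fraction`. Fractions are defined as 0 for cells
#'   with zero total UMIs (such cells fall to the UMI-minimum rule anyway).
#' @export
compute_cell_qc <- function(counts) {
  symbols <- colnames(counts)
  if (is.null(symbols)) {
    stop("input error: counts must carry gene symbols as colnames")
  }
  n_umi <- Matrix::rowSums(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  mito <- Matrix::rowSums(counts[, is_mito_gene(symbols), drop = FALSE])
  ig <- Matrix::rowSums(counts[, is_ig_gene(symbols), drop = FALSE])
  denom <- ifelse(n_umi > 0, n_umi, 1)
  data.frame(cell_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             n_umi = as.integer(n_umi),
             n_genes = as.integer(n_genes),
             mito_fraction = as.numeric(mito / denom),
             ig_fraction = as.numeric(ig / denom),
             stringsAsFactors = FALSE)
}

#' Apply the cell-level QC filters
#'
#' A cell is removed iff it violates any rule; each removal is attributed to
#' every rule it violates, so per-rule counts may overlap. Filtering is
#' idempotent: applying it to an already-filtered set removes zero cells.
#'
#' @param metrics data frame from [compute_cell_qc()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `keep` (logical mask, input order), `rule_counts`
#'   (named integer vector) and `rules` (per-cell logical matrix of
#'   violations).
#' @export
apply_qc_filters <- function(metrics, thresholds = qc_thresholds()) {
  thr <- thresholds
  rules <- cbind(
    mito       = metrics$mito_fraction >= thr$mito_max,
    genes_low  = metrics$n_genes <= thr$genes_min_exclusive,
    umi_low    = metrics$n_umi <= thr$umi_min_exclusive,
    genes_high = metrics$n_genes >= thr$genes_max_inclusive,
    umi_high   = metrics$n_umi >= thr$umi_max_inclusive,
    ig_low     = metrics$ig_fraction <= thr$ig_fraction_min
  )
  keep <- rowSums(rules) == 0
  list(keep = keep,
       rule_counts = colSums(rules),
       rules = rules)
}

#' Flag contaminant cells by diagnostic marker expression
#'
#' @param counts cells x genes count matrix.
#' @param markers diagnostic marker symbols; markers absent from the gene
#'   annotation are reported in a message and skipped.
#' @param min_umi minimal UMI count that flags a cell.
#' @return logical mask, `TRUE` for flagged cells.
#' @export
flag_contaminants <- function(counts, markers = CONTAMINANT_MARKERS,
                              min_umi = 1L) {
  if (length(markers) == 0) {
    warning("empty contaminant marker list: no cells flagged")
    return(rep(FALSE, nrow(counts)))
  }
  present <- markers %in% colnames(counts)
  if (any(!present)) {
    message("contaminant markers absent from annotation, skipped: ",
            paste(markers[!present], collapse = ", "))
  }
  markers <- markers[present]
  if (length(markers) == 0) return(rep(FALSE, nrow(counts)))
  as.vector(Matrix::rowSums(counts[, markers, drop = FALSE] >= min_umi) > 0)
}

#' Remove immunoglobulin genes from a symbol list
#'
#' Used to strip Ig genes from highly-variable-feature lists before
#' clustering so no single rearranged V gene drives a cluster. Order is
#' preserved; only true Ig locus symbols are removed (see [is_ig_gene()]).
#'
#' @param symbols character vector of gene symbols.
#' @return the retained symbols.
#' @export
exclude_ig_genes <- function(symbols) {
  symbols[!is_ig_gene(symbols)]
}
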