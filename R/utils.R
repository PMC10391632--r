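#' Identify immunoglobulin genes by symbol
#'
#' Ig locus genes are recognized by the official symbol stem: `IGH`, `IGK` or
#' `IGL` followed by one of the locus-gene letters V/D/J/G/A/M/E/C. The naive
#' three-letter prefix is deliberately not used, so e.g. `IGF`-family genes
#' (IGFBP3) are never misclassified.
#'
#' @param symbols character vector of gene symbols (case-sensitive).
#' @return logical vector.
#' @export
is_ig_gene <- function(symbols) {
  grepl("^IG[HKL][VDJGAMEC]", symbols)
}

#' Identify mitochondrial genes by symbol
#'
#' @param symbols character vector of gene symbols.
#' @return logical vector; `TRUE` for symbols with the 10x-style `MT-` prefix.
#' @export
is_mito_gene <- function(symbols) {
  startsWith(symbols, "MT-")
}

#' Log-normalize a UMI count matrix
#'
#' Standard library-size normalization: counts are scaled per cell to
#' `scale_factor` total and log1p-transformed.
#'
#' @param counts cells x genes matrix (sparse or dense) of UMI counts.
#' @param scale_factor per-cell total after scaling (default 1e4).
#' @return dense cells x genes matrix of log-normalized expression.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  totals[totals == 0] <- 1
  log1p(counts / totals * scale_factor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-stage seed from the run seed; kept within 32-bit integer range.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

# natural-log fold change between two group means with a small pseudocount
# (the ratio is undefined at zero means; the pseudocount only matters there)
log_fc <- function(mean1, mean2, pseudocount = 1e-9) {
  log((mean1 + pseudocount) / (mean2 + pseudocount))
}
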