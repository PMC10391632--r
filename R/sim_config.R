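#' Simulation configuration
#'
#' Collects every parameter of the synthetic expression + repertoire
#' generator. Defaults emulate a desk-scale version of a bone-marrow
#' antibody-secreting-cell (ASC) dataset: negative-binomial UMI counts with
#' cluster-specific marker genes, high immunoglobulin transcript load,
#' moderate mitochondrial content, a small contaminant fraction, and a
#' power-law clonal-lineage size distribution with per-base somatic
#' hypermutation of the V segment.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (must leave room for the designated
#'   mitochondrial, immunoglobulin, contaminant-marker and cluster-marker
#'   genes).
#' @param n_clusters number of cell clusters.
#' @param cluster_proportions probability vector over clusters (defaults to
#'   uniform); must sum to 1.
#' @param nb_mean_base baseline negative-binomial mean per gene.
#' @param nb_dispersion negative-binomial size (dispersion) parameter.
#' @param marker_genes_per_cluster number of marker genes spiked per cluster.
#' @param marker_fold_change fold change applied to marker genes within their
#'   cluster.
#' @param mito_fraction_range range of per-cell mitochondrial UMI fractions.
#' @param ig_fraction_range range of per-cell immunoglobulin UMI fractions;
#'   ASCs devote a large share of their transcriptome to Ig transcripts, so
#'   the default is 0.3-0.8.
#' @param contaminant_fraction fraction of cells spiked with one diagnostic
#'   non-ASC marker (e.g. CD3E).
#' @param n_subjects number of subjects cells are assigned to; clonal
#'   lineages never span subjects.
#' @param n_lineages number of clonal lineages seeded in the repertoire.
#' @param lineage_size_distribution list with elements `name` (currently
#'   `"powerlaw"`), `exponent` and `max_size`.
#' @param v_mutation_rate per-base substitution probability applied to the
#'   germline V segment (default 0.0689, a typical mean somatic-hypermutation
#'   frequency for bone-marrow ASCs).
#' @param cdr3_length_range integer range of CDR3 nucleotide lengths (>= 3).
#' @param cdr3_divergence maximum per-base divergence of a lineage member's
#'   CDR3 from the lineage founder sequence; pairwise within-lineage
#'   divergence is at most twice this value.
#' @param vdj_match_rate fraction of labeled cells eligible for a matched
#'   rearrangement (emulates the typical ~83% VDJ match rate).
#' @param seed integer RNG seed; all generator output is a pure function of
#'   (config, seed).
#' @return a `bmpc_sim_config` list.
#' @export
sim_config <- function(n_cells = 1000L,
                       n_genes = 800L,
                       n_clusters = 8L,
                       cluster_proportions = NULL,
                       nb_mean_base = 0.3,
                       nb_dispersion = 2,
                       marker_genes_per_cluster = 10L,
                       marker_fold_change = 4,
                       mito_fraction_range = c(0.02, 0.15),
                       ig_fraction_range = c(0.30, 0.80),
                       contaminant_fraction = 0.02,
                       n_subjects = 5L,
                       n_lineages = 200L,
                       lineage_size_distribution = list(name = "powerlaw",
                                                        exponent = 2.0,
                                                        max_size = 25L),
                       v_mutation_rate = 0.0689,
                       cdr3_length_range = c(30L, 60L),
                       cdr3_divergence = 0.03,
                       vdj_match_rate = 0.83,
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells),
              n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              cluster_proportions = cluster_proportions %||%
                rep(1 / n_clusters, n_clusters),
              nb_mean_base = nb_mean_base,
              nb_dispersion = nb_dispersion,
              marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
              marker_fold_change = marker_fold_change,
              mito_fraction_range = mito_fraction_range,
              ig_fraction_range = ig_fraction_range,
              contaminant_fraction = contaminant_fraction,
              n_subjects = as.integer(n_subjects),
              n_lineages = as.integer(n_lineages),
              lineage_size_distribution = lineage_size_distribution,
              v_mutation_rate = v_mutation_rate,
              cdr3_length_range = as.integer(cdr3_length_range),
              cdr3_divergence = cdr3_divergence,
              vdj_match_rate = vdj_match_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "bmpc_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(n_cells = cfg$n_cells, n_genes = cfg$n_genes,
              n_clusters = cfg$n_clusters,
              marker_genes_per_cluster = cfg$marker_genes_per_cluster,
              n_subjects = cfg$n_subjects, n_lineages = cfg$n_lineages)
  if (any(counts <= 0)) {
    stop("configuration error: all counts must be positive (",
         paste(names(counts)[counts <= 0], collapse = ", "), ")")
  }
  if (length(cfg$cluster_proportions) != cfg$n_clusters) {
    stop("configuration error: cluster_proportions must have length n_clusters")
  }
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-9) {
    stop("configuration error: cluster_proportions must sum to 1")
  }
  rates <- c(contaminant_fraction = cfg$contaminant_fraction,
             v_mutation_rate = cfg$v_mutation_rate,
             cdr3_divergence = cfg$cdr3_divergence,
             vdj_match_rate = cfg$vdj_match_rate,
             cfg$mito_fraction_range, cfg$ig_fraction_range)
  if (any(rates < 0 | rates > 1)) {
    stop("configuration error: rates and fraction ranges must lie in [0, 1]")
  }
  if (cfg$nb_mean_base <= 0 || cfg$nb_dispersion <= 0 ||
      cfg$marker_fold_change <= 0) {
    stop("configuration error: nb_mean_base, nb_dispersion and ",
         "marker_fold_change must be positive")
  }
  if (length(cfg$cdr3_length_range) != 2 ||
      max(cfg$cdr3_length_range) < 3) {
    stop("configuration error: cdr3_length_range must allow lengths >= 3 nt")
  }
  invisible(cfg)
}
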