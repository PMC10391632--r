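# End-to-end orchestration of the synthetic demonstration run: simulate ->
# qc -> labels -> signatures -> tf -> repertoire -> stability, with every
# output table written alongside a provenance manifest. Reruns with an
# identical configuration reproduce identical outputs.

#' Pipeline configuration
#'
#' A single nested list (writable as YAML) holding every stage's parameter
#' block plus stage toggles. Exactly one of a simulation config or a set of
#' real input paths drives a run; the seed is propagated to every stochastic
#' stage.
#'
#' The default QC thresholds here are scaled to the synthetic library size
#' (a few hundred UMIs per cell) while keeping the published mitochondrial
#' and immunoglobulin fraction rules; the full-scale published thresholds
#' remain the [qc_thresholds()] defaults.
#'
#' @param simulation a [sim_config()] (or NULL when `inputs` is given).
#' @param inputs list of paths (`counts_dir`, `airr`, `labels`) for a run on
#'   real data.
#' @param qc list: `enabled`, `thresholds`, `n_fail_per_rule` (designed QC
#'   violations added to the simulation; 0 disables).
#' @param labels list: `method` = "builtin" (graph labeler), "truth", or
#'   "file"; `grid_point` for the builtin method.
#' @param signatures list: `n_gene_sets`, `genes_per_set`, `n_perm` for the
#'   enrichment permutation p, `scaling` for the panel.
#' @param tf list: `n_tfs` sampled as the TF universe.
#' @param repertoire list: `lineage_params`, `remove_singletons`, `n_perm`.
#' @param stability list: `enabled`, `grid` (a [stability_grid()]),
#'   `k_neighbors`.
#' @param out_dir output directory.
#' @param seed run seed.
#' @return a `bmpc_pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            inputs = NULL,
                            qc = list(enabled = TRUE,
                                      thresholds = qc_thresholds(
                                        genes_min_exclusive = 100L,
                                        umi_min_exclusive = 200L,
                                        genes_max_inclusive = 600L,
                                        umi_max_inclusive = 20000L),
                                      n_fail_per_rule = 5L),
                            labels = list(method = "truth",
                                          grid_point = data.frame(
                                            dims = 70, pcs = 50,
                                            resolution = 1.0)),
                            signatures = list(n_gene_sets = 10L,
                                              genes_per_set = 40L,
                                              n_perm = 100L,
                                              scaling = "rowz"),
                            tf = list(n_tfs = 40L),
                            repertoire = list(lineage_params = lineage_params(),
                                              remove_singletons = FALSE,
                                              n_perm = 100L),
                            stability = list(enabled = TRUE,
                                             grid = stability_grid(),
                                             k_neighbors = 20L),
                            out_dir = tempfile("bmpc_run_"),
                            seed = 1L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("configuration error: exactly one of simulation / inputs required")
  }
  structure(list(simulation = simulation, inputs = inputs, qc = qc,
                 labels = labels, signatures = signatures, tf = tf,
                 repertoire = repertoire, stability = stability,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "bmpc_pipeline_config")
}

#' Run the full pipeline
#'
#' Stages execute in order simulate/ingest -> qc -> labels -> signatures ->
#' tf -> repertoire -> stability. Every result table is written to
#' `config$out_dir` with a JSON manifest recording parameters, seed and
#' package version. A stage failure halts the run with the stage name after
#' writing a partial manifest.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (invisibly also written to disk).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  bundle <- list()
  results <- list()
  stage <- "simulate"
  res <- tryCatch({
    # --- simulate / ingest ------------------------------------------------
    if (!is.null(cfg$simulation)) {
      sim <- cfg$simulation
      sim$seed <- stage_seed(cfg$seed, 0L)
      qc_design <- NULL
      if (isTRUE(cfg$qc$enabled) && (cfg$qc$n_fail_per_rule %||% 0L) > 0) {
        qc_design <- list(thresholds = cfg$qc$thresholds,
                          n_per_rule = cfg$qc$n_fail_per_rule)
      }
      expr <- simulate_expression(sim, qc_design = qc_design)
      counts <- expr$counts
      truth <- expr$truth
      rep_sim <- simulate_repertoire(sim, truth$labels, truth$subjects)
      records <- rep_sim$records
    } else {
      counts <- read_count_matrix(cfg$inputs$counts_dir)
      records <- read_airr(cfg$inputs$airr)
      lab_tab <- utils::read.delim(cfg$inputs$labels,
                                   stringsAsFactors = FALSE)
      truth <- list(labels = stats::setNames(lab_tab$cluster,
                                             lab_tab$cell_id),
                    subjects = NULL, contaminants = character(0))
      rep_sim <- NULL
    }
    results$n_cells_input <- nrow(counts)

    # --- qc ---------------------------------------------------------------
    stage <- "qc"
    metrics <- compute_cell_qc(counts)
    if (isTRUE(cfg$qc$enabled)) {
      filt <- apply_qc_filters(metrics, cfg$qc$thresholds)
      contam <- flag_contaminants(counts, cfg$qc$thresholds$contaminant_markers,
                                  cfg$qc$thresholds$contaminant_min_umi)
      keep <- filt$keep & !contam
      rule_counts <- c(filt$rule_counts, contaminant = sum(contam))
    } else {
      keep <- rep(TRUE, nrow(counts))
      rule_counts <- c(disabled = 0L)
    }
    counts_qc <- counts[keep, , drop = FALSE]
    bundle$qc_metrics <- metrics
    bundle$qc_keep <- data.frame(cell_id = rownames(counts_qc))
    results$qc <- list(rule_counts = as.list(rule_counts),
                       n_kept = nrow(counts_qc), enabled = cfg$qc$enabled)

    # --- labels -----------------------------------------------------------
    stage <- "labels"
    norm <- lognormalize(counts_qc)
    hv_genes <- exclude_ig_genes(colnames(norm))
    labels <- switch(cfg$labels$method,
      truth = truth$labels[rownames(counts_qc)],
      builtin = {
        labeler <- pca_graph_labeler(seed = stage_seed(cfg$seed, 2L))
        labeler(cfg$labels$grid_point, norm[, hv_genes, drop = FALSE])
      },
      file = {
        tab <- utils::read.delim(cfg$labels$path, stringsAsFactors = FALSE)
        stats::setNames(tab$cluster, tab$cell_id)[rownames(counts_qc)]
      },
      stop("unknown label method: ", cfg$labels$method))
    labels <- stats::setNames(as.character(labels), rownames(counts_qc))
    bundle$labels <- data.frame(cell_id = names(labels), cluster = labels)
    results$n_clusters <- length(unique(labels))

    # --- signatures -------------------------------------------------------
    stage <- "signatures"
    cl <- sort(unique(labels))
    adj_de <- list()
    if (length(cl) >= 2) {
      for (i in seq_len(length(cl) - 1)) {
        adj_de[[paste0(cl[i], "_vs_", cl[i + 1])]] <-
          de_rank_sum(norm, labels, cl[i], cl[i + 1])
      }
    }
    early_late <- NULL
    if (length(cl) >= 4) {
      half <- length(cl) %/% 2
      early_lab <- ifelse(labels %in% cl[seq_len(half)], "early", "late")
      names(early_lab) <- names(labels)
      early_late <- de_rank_sum(norm, early_lab, "early", "late")
    }
    markers <- do.call(rbind, lapply(adj_de, filter_markers))
    maturation <- maturation_deg_union(adj_de, early_late)
    # synthetic hallmark-like gene sets over the non-Ig gene universe
    set.seed(stage_seed(cfg$seed, 3L))
    universe <- exclude_ig_genes(colnames(norm))
    gene_sets <- lapply(seq_len(cfg$signatures$n_gene_sets), function(i) {
      sample(universe, min(cfg$signatures$genes_per_set, length(universe)))
    })
    names(gene_sets) <- sprintf("SET_%02d", seq_along(gene_sets))
    ranked <- if (length(adj_de)) prerank_statistic(adj_de[[1]]) else NULL
    es_tab <- NULL
    if (!is.null(ranked)) {
      es_tab <- do.call(rbind, lapply(names(gene_sets), function(nm) {
        sig <- preranked_significance(ranked, gene_sets[[nm]],
                                      n_perm = cfg$signatures$n_perm,
                                      seed = stage_seed(cfg$seed, 4L))
        if (is.null(sig)) return(NULL)
        data.frame(gene_set = nm, es = sig$es, perm_p = sig$p)
      }))
      if (!is.null(es_tab)) {
        es_tab$fdr <- stats::p.adjust(es_tab$perm_p, method = "BH")
      }
    }
    scores <- do.call(cbind, lapply(gene_sets, function(gs) {
      s <- ustat_pathway_score(norm, gs, maturation)
      if (is.null(s)) rep(NA_real_, nrow(norm)) else s
    }))
    colnames(scores) <- names(gene_sets)
    rownames(scores) <- rownames(norm)
    usable <- colSums(is.na(scores)) == 0
    panel <- if (any(usable)) {
      summarize_scores(scores[, usable, drop = FALSE], labels,
                       scaling = cfg$signatures$scaling)
    } else NULL
    if (!is.null(markers)) bundle$markers <- markers
    if (!is.null(ranked)) bundle$ranked_list <- ranked
    if (!is.null(es_tab)) bundle$enrichment <- es_tab
    if (!is.null(panel)) {
      bundle$es_panel <- data.frame(gene_set = rownames(panel), panel,
                                    check.names = FALSE)
    }
    results$signatures <- list(n_markers = if (is.null(markers)) 0L
                                           else nrow(markers),
                               n_maturation_degs = length(maturation))

    # --- tf ---------------------------------------------------------------
    stage <- "tf"
    set.seed(stage_seed(cfg$seed, 5L))
    tf_universe <- sample(universe, min(cfg$tf$n_tfs, length(universe)))
    cand <- stats::setNames(tf_universe %in%
                              c(maturation,
                                if (!is.null(markers)) markers$gene),
                            tf_universe)
    tfs <- select_tfs(norm, labels, tf_universe, cand)
    assignments <- assign_tf_clusters(norm, labels, tfs)
    # synthetic STRING-like edges among the TF universe
    edge_pool <- utils::combn(sort(tf_universe), 2)
    n_edges <- min(200L, ncol(edge_pool))
    pick <- sample.int(ncol(edge_pool), n_edges)
    edges <- data.frame(protein_a = edge_pool[1, pick],
                        protein_b = edge_pool[2, pick],
                        combined_score = sample.int(1000L, n_edges,
                                                    replace = TRUE),
                        stringsAsFactors = FALSE)
    kept_edges <- filter_interactions(edges, assignments)
    bundle$tf_assignments <- assignments
    bundle$tf_edges <- kept_edges
    results$tf <- list(n_selected = length(tfs),
                       n_edges_kept = nrow(kept_edges))

    # --- repertoire -------------------------------------------------------
    stage <- "repertoire"
    rp <- cfg$repertoire$lineage_params
    lin <- cluster_lineages(records, rp)
    clones <- track_clones(records, rp)
    prof <- mutation_profiles(records)
    glob <- prof[prof$region == "global", ]
    freq_by_cell <- stats::setNames(glob$frequency,
                                    records$cell_id[match(glob$sequence_id,
                                                          records$sequence_id)])
    abundance <- lineage_cluster_table(lin, labels, records$cell_id,
                                       remove_singletons =
                                         cfg$repertoire$remove_singletons)
    subj <- records$subject_id %||% rep("S1", nrow(records))
    per_subject <- lapply(split(seq_len(nrow(records)), subj), function(i) {
      ab <- lineage_cluster_table(lin[i], labels, records$cell_id[i])
      if (nrow(ab) == 0) return(NULL)
      morisita_matrix(ab)
    })
    per_subject <- Filter(Negate(is.null), per_subject)
    mor <- morisita_average(per_subject)
    qc_cells <- intersect(names(freq_by_cell), names(labels))
    perm <- mutation_permutation_test(freq_by_cell[qc_cells],
                                      labels[qc_cells],
                                      n_perm = cfg$repertoire$n_perm,
                                      seed = stage_seed(cfg$seed, 6L))
    region_rs <- do.call(rbind, lapply(c("CDR1", "CDR2", "FR", "CDR"),
      function(rg) {
        rows <- prof[prof$region == rg, ]
        agg <- data.frame(region = rg,
                          n_replacement = sum(rows$n_replacement),
                          n_silent = sum(rows$n_silent))
        rs <- rs_ratio(agg, rg)
        data.frame(region = rg, r_count = rs$r_count, s_count = rs$s_count,
                   ratio = rs$ratio, selected = rs$selected)
      }))
    bundle$lineages <- data.frame(sequence_id = names(lin),
                                  lineage = as.character(lin),
                                  clone = as.character(clones))
    bundle$mutation_profiles <- prof
    bundle$rs_table <- region_rs
    bundle$morisita <- data.frame(cluster = rownames(mor), mor,
                                  check.names = FALSE)
    bundle$permutation_test <- perm$pairs
    bundle$lineage_links <- lineage_links(abundance)
    results$repertoire <- list(
      n_records = nrow(records),
      n_lineages = length(unique(lin)),
      n_clones = length(unique(clones)),
      mean_shm = mean(glob$frequency, na.rm = TRUE),
      anova_p = perm$anova_p)

    # --- stability --------------------------------------------------------
    stage <- "stability"
    if (isTRUE(cfg$stability$enabled)) {
      labeler <- pca_graph_labeler(k_neighbors = cfg$stability$k_neighbors,
                                   seed = stage_seed(cfg$seed, 7L))
      stab <- run_stability_grid(labeler, cfg$stability$grid,
                                 norm[, hv_genes, drop = FALSE])
      bundle$stability_ri <- data.frame(point = rownames(stab$ri), stab$ri,
                                        check.names = FALSE)
      results$stability <- list(mean_ri = stab$mean_ri,
                                n_failures = length(stab$failures))
    }
    results
  }, error = function(e) {
    write_report_tables(bundle, cfg$out_dir,
                        parameters = list(failed_stage = stage,
                                          error = conditionMessage(e)),
                        seed = cfg$seed)
    stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- write_report_tables(
    bundle, cfg$out_dir,
    parameters = list(stages = res, qc_enabled = cfg$qc$enabled,
                      label_method = cfg$labels$method),
    seed = cfg$seed)
  invisible(list(results = res, manifest = manifest, out_dir = cfg$out_dir))
}

#' Load pipeline options from a YAML document
#'
#' Reads a YAML file of scalar overrides (seed, out_dir, stage toggles and
#' the numeric members of each parameter block) and merges them over the
#' [pipeline_config()] defaults. Structured members that YAML cannot carry
#' faithfully (the simulation config, threshold/parameter objects) are
#' rebuilt from their scalar fields when present.
#'
#' @param path YAML file.
#' @return a `bmpc_pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    simulation = do.call(sim_config, doc$simulation %||% list()),
    out_dir = doc$out_dir %||% tempfile("bmpc_run_"),
    seed = doc$seed %||% 1L)
  if (!is.null(doc$qc)) {
    if (!is.null(doc$qc$thresholds)) {
      cfg$qc$thresholds <- do.call(qc_thresholds, doc$qc$thresholds)
    }
    if (!is.null(doc$qc$enabled)) cfg$qc$enabled <- doc$qc$enabled
    if (!is.null(doc$qc$n_fail_per_rule)) {
      cfg$qc$n_fail_per_rule <- doc$qc$n_fail_per_rule
    }
  }
  for (block in c("labels", "signatures", "tf", "repertoire", "stability")) {
    for (nm in names(doc[[block]])) {
      cfg[[block]][[nm]] <- doc[[block]][[nm]]
    }
  }
  if (!is.null(doc$stability$grid)) {
    cfg$stability$grid <- do.call(stability_grid, doc$stability$grid)
  }
  if (!is.null(doc$repertoire$lineage_params)) {
    cfg$repertoire$lineage_params <-
      do.call(lineage_params, doc$repertoire$lineage_params)
  }
  cfg
}
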