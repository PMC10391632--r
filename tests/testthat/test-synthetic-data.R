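# Synthetic expression + repertoire generator: contracts, determinism,
# and recovery of the simulated ground truth.

test_that("expression simulation honors shape, determinism and contaminant contracts", {
  cfg <- sim_config(n_cells = 100, n_genes = 500, n_clusters = 4,
                    n_lineages = 20, seed = 42)
  ex1 <- simulate_expression(cfg)
  expect_equal(dim(ex1$counts), c(100, 500))
  expect_setequal(names(ex1$truth$labels), rownames(ex1$counts))
  expect_true(all(table(names(ex1$truth$labels)) == 1))

  ex2 <- simulate_expression(cfg)
  expect_identical(as.matrix(ex1$counts), as.matrix(ex2$counts))
  expect_identical(ex1$truth, ex2$truth)

  cfg0 <- sim_config(n_cells = 100, n_genes = 500, n_clusters = 4,
                     contaminant_fraction = 0, seed = 42)
  ex0 <- simulate_expression(cfg0)
  expect_length(ex0$truth$contaminants, 0)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_cells = 0), "positive")
  expect_error(sim_config(cluster_proportions = c(0.5, 0.4), n_clusters = 2),
               "sum to 1")
  expect_error(sim_config(cdr3_length_range = c(1, 2)), "3 nt")
  expect_error(simulate_expression(sim_config(n_genes = 50)), "too small")
})

test_that("marker genes carry the configured cluster fold change on average", {
  cfg <- sim_config(n_cells = 600, n_genes = 400, n_clusters = 3,
                    marker_fold_change = 6, seed = 5)
  ex <- simulate_expression(cfg)
  counts <- as.matrix(ex$counts)
  lab <- ex$truth$labels
  mk <- ex$truth$marker_genes[[1]]
  in1 <- names(lab)[lab == 1]
  out1 <- names(lab)[lab != 1]
  ratio <- mean(counts[in1, mk]) / mean(counts[out1, mk])
  expect_gt(ratio, 3)
})

test_that("substitution-only SHM has exact per-site truth", {
  germ <- "GGAGGAGGA"
  out0 <- mutate_v_sequence(germ, 0)
  expect_identical(out0$sequence, germ)
  expect_equal(nrow(out0$sites), 0)

  set.seed(1)
  out <- mutate_v_sequence(paste(rep("ACGT", 250), collapse = ""), 0.1)
  g <- strsplit(paste(rep("ACGT", 250), collapse = ""), "")[[1]]
  s <- strsplit(out$sequence, "")[[1]]
  expect_equal(nrow(out$sites), sum(g != s))
  expect_identical(out$sites$germline_base, g[out$sites$position])
  expect_identical(out$sites$new_base, s[out$sites$position])
  expect_true(all(out$sites$status %in% c("replacement", "silent")))

  expect_error(mutate_v_sequence("ACGN", 0.1), "A/C/G/T")
  expect_error(mutate_v_sequence("ACG", 0.1, frame_offset = 3), "frame_offset")
})

test_that("codon-level truth matches the genetic code on known substitutions", {
  # force the specific substitutions by construction
  expect_identical(oracle_classify("GGA", 3, "G"), "silent")   # Gly -> Gly
  expect_identical(oracle_classify("GGA", 1, "A"), "replacement") # Gly -> Arg
  set.seed(99)
  hit <- FALSE
  for (rep in 1:50) {
    out <- mutate_v_sequence("GGA", 0.9)
    for (k in seq_len(nrow(out$sites))) {
      st <- out$sites[k, ]
      expect_identical(st$status,
                       oracle_classify("GGA", st$position, st$new_base))
      hit <- TRUE
    }
  }
  expect_true(hit)
})

test_that("aggregate mutation frequency recovers the simulated rate", {
  mu <- 0.05
  set.seed(7)
  L <- 400L
  germ <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
  n_seq <- 40L   # 16,000 aggregated bases
  muts <- 0L
  for (i in seq_len(n_seq)) {
    out <- mutate_v_sequence(germ, mu)
    muts <- muts + nrow(out$sites)
  }
  se <- sqrt(mu * (1 - mu) / (n_seq * L))
  expect_lt(abs(muts / (n_seq * L) - mu), 3 * se)
})

test_that("repertoire generation respects lineage structure and determinism", {
  cfg <- sim_config(n_cells = 200, n_genes = 400, n_clusters = 3,
                    n_lineages = 30, v_mutation_rate = 0,
                    cdr3_divergence = 0, seed = 8)
  ex <- simulate_expression(cfg)
  rp <- simulate_repertoire(cfg, ex$truth$labels, ex$truth$subjects)
  # no SHM: every V sequence equals its germline
  expect_identical(rp$records$v_sequence_alignment,
                   rp$records$v_germline_alignment)
  # zero divergence: all CDR3s within a lineage identical
  by_lin <- split(rp$records$cdr3, rp$truth$lineage[rp$records$sequence_id])
  expect_true(all(vapply(by_lin, function(x) length(unique(x)) == 1,
                         logical(1))))
  rp2 <- simulate_repertoire(cfg, ex$truth$labels, ex$truth$subjects)
  expect_identical(rp$records, rp2$records)

  one <- sim_config(n_cells = 50, n_genes = 400, n_clusters = 2,
                    n_lineages = 1, cdr3_divergence = 0, seed = 3)
  ex1 <- simulate_expression(one)
  rp1 <- simulate_repertoire(one, ex1$truth$labels)
  expect_equal(length(unique(rp1$records$cdr3)), 1)
})

test_that("lineage clustering recovers the simulated partition exactly", {
  cfg <- sim_config(n_cells = 300, n_genes = 400, n_clusters = 4,
                    n_lineages = 50, cdr3_divergence = 0.03, seed = 21)
  ex <- simulate_expression(cfg)
  rp <- simulate_repertoire(cfg, ex$truth$labels, ex$truth$subjects)
  lin <- cluster_lineages(rp$records)
  truth <- rp$truth$lineage[names(lin)]
  expect_true(same_partition(as.integer(factor(lin)),
                             as.integer(factor(truth))))
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(lin, truth), 1)
})

test_that("per-record mutation truth totals match observed mismatches", {
  cfg <- sim_config(n_cells = 120, n_genes = 400, n_clusters = 2,
                    n_lineages = 25, v_mutation_rate = 0.06, seed = 13)
  ex <- simulate_expression(cfg)
  rp <- simulate_repertoire(cfg, ex$truth$labels, ex$truth$subjects)
  prof <- mutation_profiles(rp$records)
  glob <- prof[prof$region == "global", ]
  truth_tot <- tapply(rp$truth$mutations$n_mutations,
                      rp$truth$mutations$sequence_id, sum)
  expect_equal(as.vector(truth_tot[glob$sequence_id]), glob$n_mutations)
  # per-region R/S truth agrees with the analysis-side classification
  per_region <- merge(prof, rp$truth$mutations,
                      by = c("sequence_id", "region"))
  expect_equal(per_region$n_replacement.x, per_region$n_replacement.y)
  expect_equal(per_region$n_silent.x, per_region$n_silent.y)
})
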