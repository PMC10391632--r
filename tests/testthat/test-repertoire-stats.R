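# Connectivity (abundance tables, Morisita-Horn) and the ANOVA/Tukey
# permutation machinery, cross-checked against stats::aov / stats::TukeyHSD.

test_that("lineage x cluster abundances conserve cells and drop singletons", {
  lin <- stats::setNames(c("L1", "L1", "L1", "L2"), paste0("s", 1:4))
  cells <- paste0("bc", 1:4)
  labels <- stats::setNames(c("c1", "c1", "c2", "c2"), cells)
  ab <- lineage_cluster_table(lin, labels, cells)
  expect_equal(unname(ab["L1", c("c1", "c2")]), c(2L, 1L))
  expect_equal(unname(colSums(ab)), unname(as.integer(table(labels))))
  ab2 <- lineage_cluster_table(lin, labels, cells, remove_singletons = TRUE)
  expect_false("L2" %in% rownames(ab2))
  only_singles <- stats::setNames(c("L1", "L2"), c("s1", "s2"))
  expect_warning(
    empty <- lineage_cluster_table(only_singles,
                                   stats::setNames(c("c1", "c2"),
                                                   c("b1", "b2")),
                                   c("b1", "b2"), remove_singletons = TRUE),
    "singletons")
  expect_equal(nrow(empty), 0)
  # unlabeled records dropped and counted
  lin3 <- stats::setNames(c("L1", "L1"), c("s1", "s2"))
  ab3 <- lineage_cluster_table(lin3, stats::setNames("c1", "b1"),
                               c("b1", "zz"))
  expect_equal(attr(ab3, "n_unlabeled"), 1)
})

test_that("Morisita-Horn matches its identities and the direct formula", {
  expect_equal(morisita_index(c(3, 2, 1), c(3, 2, 1)), 1)
  expect_equal(morisita_index(c(5, 0, 2), c(0, 4, 0)), 0)
  expect_equal(morisita_index(c(2, 0), c(1, 1)), 2 / 3)
  set.seed(8)
  for (i in 1:30) {
    x <- rpois(6, 3); y <- rpois(6, 3)
    if (sum(x) == 0 || sum(y) == 0) next
    v <- morisita_index(x, y)
    expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
    expect_equal(morisita_index(x, x), 1)
    # invariance to lineage relabeling (joint permutation)
    p <- sample.int(6)
    expect_equal(morisita_index(x[p], y[p]), v)
  }
})

test_that("Morisita matrices are symmetric with unit diagonal, excluding empty clusters", {
  ab <- matrix(c(2, 1, 0,
                 0, 3, 0,
                 1, 1, 0), nrow = 3, byrow = TRUE,
               dimnames = list(paste0("L", 1:3), paste0("c", 1:3)))
  expect_message(m <- morisita_matrix(ab), "c3")
  expect_equal(dim(m), c(2, 2))
  expect_equal(unname(diag(m)), c(1, 1))
  expect_equal(m[1, 2], m[2, 1])
  avg <- morisita_average(list(m, m))
  expect_equal(avg[rownames(m), colnames(m)], m, ignore_attr = TRUE)
})

test_that("lineage link tables enumerate cluster pairs per shared lineage", {
  ab <- matrix(c(2, 1, 1,
                 0, 3, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("L1", "L2"), paste0("c", 1:3)))
  links <- lineage_links(ab)
  expect_equal(nrow(links), 3)   # L1 spans 3 clusters -> 3 pairs; L2 none
  expect_true(all(links$lineage == "L1"))
})

test_that("the vectorized ANOVA/Tukey engine equals stats::aov and stats::TukeyHSD", {
  set.seed(15)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    y <- rnorm(k * 8, mean = rep(runif(k, 0, 2), each = 8))
    g <- rep(letters[1:k], each = 8)
    names(y) <- paste0("c", seq_along(y))
    pt <- mutation_permutation_test(stats::setNames(y, names(y)),
                                    stats::setNames(g, names(y)),
                                    n_perm = 3, seed = 1)
    fit <- stats::aov(y ~ factor(g))
    expect_equal(pt$anova_p, summary(fit)[[1]][["Pr(>F)"]][1],
                 tolerance = 1e-10)
    tk <- stats::TukeyHSD(fit)[[1]]
    expect_equal(sort(pt$pairs$tukey_p), sort(unname(tk[, "p adj"])),
                 tolerance = 1e-8)
  }
})

test_that("permutation p follows the printed strict-inequality formula", {
  set.seed(30)
  y <- stats::setNames(rnorm(40), paste0("c", 1:40))
  g <- stats::setNames(rep(c("a", "b"), each = 20), names(y))
  y[g == "a"] <- y[g == "a"] + 1.2
  pt <- mutation_permutation_test(y, g, n_perm = 60, seed = 5)
  # independent recount over the same shuffle stream
  obs <- stats::TukeyHSD(stats::aov(y ~ factor(g)))[[1]][, "p adj"]
  set.seed(5)
  count <- 0L
  for (b in 1:60) {
    yb <- y[sample.int(40)]
    pb <- stats::TukeyHSD(stats::aov(yb ~ factor(g)))[[1]][, "p adj"]
    if (pb < obs) count <- count + 1L
  }
  expect_equal(pt$pairs$perm_p, count / 60)
  # determinism
  pt2 <- mutation_permutation_test(y, g, n_perm = 60, seed = 5)
  expect_identical(pt$pairs, pt2$pairs)
})

test_that("degenerate inputs: identical frequencies give Tukey p 1 and permutation p 0", {
  y <- stats::setNames(rep(0.05, 12), paste0("c", 1:12))
  g <- stats::setNames(rep(c("a", "b", "c"), each = 4), names(y))
  pt <- mutation_permutation_test(y, g, n_perm = 20, seed = 2)
  expect_true(all(pt$pairs$tukey_p == 1))
  expect_true(all(pt$pairs$perm_p == 0))   # strict <: 1 < 1 never holds
  expect_equal(pt$anova_p, 1)
})

test_that("clusters with fewer than two cells are excluded with a warning", {
  y <- stats::setNames(c(rnorm(8), 0.5), paste0("c", 1:9))
  g <- stats::setNames(c(rep(c("a", "b"), each = 4), "tiny"), names(y))
  expect_warning(pt <- mutation_permutation_test(y, g, n_perm = 5, seed = 1),
                 "tiny")
  expect_equal(pt$excluded_clusters, "tiny")
  expect_error(
    suppressWarnings(mutation_permutation_test(
      stats::setNames(c(1, 2), c("x", "y")),
      stats::setNames(c("a", "b"), c("x", "y")), n_perm = 5)),
    ">= 2 clusters")
})

test_that("VDJ-expression joins compute match rates and Ig dominance", {
  rec <- rbind(make_record("ACGT", "ACGT", regions = data.frame(
                 start = c(1, 2, 3, 3, 4), end = c(1, 2, 3, 3, 4))),
               make_record("ACGT", "ACGT", regions = data.frame(
                 start = c(1, 2, 3, 3, 4), end = c(1, 2, 3, 3, 4))))
  rec$cell_id <- c("BC1", "BC2")
  rec$duplicate_count <- c(150L, 80L)
  j <- join_vdj_expression(c("BC1", "BC2", "BC3"), rec)
  expect_equal(j$match_rate, 2 / 3)
  expect_equal(j$matched$ig_dominant, c(TRUE, FALSE))
  expect_equal(join_vdj_expression(c("Z1", "Z2"), rec)$match_rate, 0)
  expect_equal(join_vdj_expression(rec$cell_id, rec)$match_rate, 1)
  # duplicate barcodes keep the heaviest record
  rec2 <- rec
  rec2$cell_id <- "BC1"
  rec2$sequence_id <- c("seq-a", "seq-b")
  expect_message(jd <- join_vdj_expression("BC1", rec2), "duplicate")
  expect_equal(jd$matched$sequence_id, "seq-a")
})
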