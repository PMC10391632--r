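# Marker thresholding, prerank statistic, preranked weighted-KS enrichment
# and the pathway U-score summaries.

test_that("marker filtering applies the fold-change and Bonferroni rules", {
  de <- data.frame(
    gene = c("A", "B", "C", "D"),
    avgLogFC = c(0.30, 0.20, -0.40, 0.50),
    p_raw = c(1e-6, 1e-10, 5e-7, 0.5))
  mk <- filter_markers(de, n_tests = 20000)
  expect_equal(mk$gene, "A")                # 0.30 lfc, p_adj 0.02
  expect_equal(mk$p_adj, 0.02)
  # B fails fold change despite tiny p; D fails significance
  top <- filter_markers(de, n_tests = 20000, include_down = TRUE)
  expect_setequal(top$gene, c("A", "C"))    # C included as down-regulated
  expect_equal(top$direction[top$gene == "C"], "down")
  expect_warning(filter_markers(de, n_tests = 2), "row count")
})

test_that("marker sets are monotone in alpha", {
  set.seed(3)
  de <- data.frame(gene = sprintf("g%03d", 1:200),
                   avgLogFC = rnorm(200, 0, 0.5),
                   p_raw = runif(200)^3)
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  sets <- lapply(alphas, function(a) {
    filter_markers(de, marker_rule(alpha = a))$gene
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("prerank statistic is NLP x sign with deterministic tie-breaks", {
  de <- data.frame(gene = c("up", "dn", "z", "big", "small"),
                   avgLogFC = c(0.5, -0.5, 0, 1.2, 0.3),
                   p_raw = c(0.001, 0.001, 0.001, 0.01, 0.01))
  r <- prerank_statistic(de)
  expect_equal(r$score[r$gene == "up"], 3)
  expect_equal(r$score[r$gene == "dn"], -3)
  expect_equal(r$score[r$gene == "z"], 0)
  # tie at score 2: |avgLogFC| descending breaks it
  expect_lt(which(r$gene == "big"), which(r$gene == "small"))
  # p = 0 is floored
  de0 <- data.frame(gene = "x", avgLogFC = -1, p_raw = 0)
  expect_equal(prerank_statistic(de0)$score, -300)
})

test_that("preranked ES matches the derived extremes and a brute-force walk", {
  r <- data.frame(gene = c("a", "b", "c"), score = c(3, 2, 1))
  expect_equal(preranked_es(r, "a")$es, 1)
  expect_equal(preranked_es(r, "c")$es, -1)
  expect_equal(preranked_es(r, c("a", "b", "c"))$es, 1)
  expect_message(expect_null(preranked_es(r, "zzz")), "no overlap")

  set.seed(14)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    scores <- sort(round(rnorm(n, 0, 3), 2), decreasing = TRUE)
    ranked <- data.frame(gene = sprintf("g%02d", 1:n), score = scores)
    m <- sample.int(n - 1, 1)
    set <- sample(ranked$gene, m)
    es <- preranked_es(ranked, set)$es
    expect_equal(es, oracle_es(scores, ranked$gene %in% set),
                 tolerance = 1e-12)
    expect_lte(abs(es), 1)
  }
})

test_that("exponent 0 reduces to the unweighted KS statistic", {
  set.seed(5)
  n <- 40
  ranked <- data.frame(gene = sprintf("g%02d", 1:n),
                       score = sort(rnorm(n), decreasing = TRUE))
  set <- sample(ranked$gene, 12)
  hit <- ranked$gene %in% set
  # direct unweighted running sum
  run <- cumsum(ifelse(hit, 1 / sum(hit), -1 / (n - sum(hit))))
  direct <- if (max(run) >= abs(min(run))) max(run) else min(run)
  expect_equal(preranked_es(ranked, set, exponent = 0)$es, direct)
})

test_that("permutation significance follows the (1+k)/(B+1) estimator", {
  r2 <- data.frame(gene = c("a", "b"), score = c(2, -2))
  # both singleton sets reach |ES| = 1, so every draw exceeds
  sig <- preranked_significance(r2, "a", n_perm = 25, seed = 1)
  expect_equal(sig$p, 1)
  sig2 <- preranked_significance(r2, "a", n_perm = 25, seed = 1)
  expect_equal(sig$p, sig2$p)
  expect_error(preranked_significance(r2, "a", n_perm = 0), "n_perm")
})

test_that("maturation DEG union has union semantics without duplicates", {
  de1 <- data.frame(gene = c("A", "B"), avgLogFC = c(0.5, 0.1),
                    p_raw = c(1e-6, 1e-6))
  de2 <- data.frame(gene = c("A", "C"), avgLogFC = c(0.5, -0.6),
                    p_raw = c(1e-6, 1e-6))
  u <- maturation_deg_union(list(de1, de2))
  expect_setequal(u, c("A", "C"))   # B fails the rule everywhere
  expect_equal(anyDuplicated(u), 0)
  expect_warning(maturation_deg_union(list()), "no DE tables")
})

test_that("pathway U-scores are means over the pathway-maturation intersection", {
  expr <- matrix(c(2, 4, 1,
                   0, 0, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  s <- ustat_pathway_score(expr, c("g1", "g2"), c("g1", "g2", "g3"))
  expect_equal(unname(s), c(3, 0))
  s1 <- ustat_pathway_score(expr, "g1", c("g1", "g3"))
  expect_equal(unname(s1), expr[, "g1"], ignore_attr = TRUE)
  # invariance to genes outside the intersection
  s2 <- ustat_pathway_score(expr, c("g1", "g2", "g3"), c("g1", "g2"))
  expect_equal(s2, s)
  expect_message(expect_null(ustat_pathway_score(expr, "g9", "g1")),
                 "not applicable")
})

test_that("cluster score panels scale as requested", {
  scores <- matrix(c(1, 1, 3, 3,
                     2, 2, 2, 2), ncol = 2,
                   dimnames = list(paste0("c", 1:4), c("P1", "P2")))
  labels <- stats::setNames(c("k1", "k1", "k2", "k2"), paste0("c", 1:4))
  mm <- summarize_scores(scores, labels, "minmax")
  expect_equal(unname(mm["P1", ]), c(0, 1))
  expect_true("P2" %in% attr(mm, "scaling_skipped"))  # zero spread
  rz <- summarize_scores(scores, labels, "rowz")
  expect_equal(mean(rz["P1", ]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(rz["P1", ]), 1, tolerance = 1e-9)
  one <- stats::setNames(rep("k1", 4), paste0("c", 1:4))
  expect_message(raw <- summarize_scores(scores, one, "rowz"),
                 "scaling skipped")
  expect_equal(unname(raw[, 1]), c(2, 2))
})

test_that("the rank-sum fallback ranks a spiked gene first", {
  set.seed(9)
  n <- 60
  expr <- matrix(rpois(n * 20, 2), n, 20,
                 dimnames = list(sprintf("c%02d", 1:n),
                                 sprintf("g%02d", 1:20)))
  labels <- stats::setNames(rep(c("a", "b"), each = n / 2), rownames(expr))
  expr[labels == "a", "g01"] <- expr[labels == "a", "g01"] + 25
  de <- de_rank_sum(lognormalize(expr), labels, "a", "b")
  expect_equal(de$gene[which.min(de$p_raw)], "g01")
  expect_gt(de$avgLogFC[de$gene == "g01"], 0.25)
  expect_true(all(de$p_adj >= de$p_raw))
})
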