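# Lineage/clone clustering, mutation profiling on gapped alignments, and
# replacement/silent classification with the R/S selection statistic.

simple_records <- function(cdr3s, v = "IGHV1-2*01", j = "IGHJ4",
                           subject = "S1") {
  n <- length(cdr3s)
  data.frame(cell_id = sprintf("BC%02d", seq_len(n)),
             sequence_id = sprintf("seq-%02d", seq_len(n)),
             subject_id = rep_len(subject, n),
             v_call = rep_len(v, n), j_call = rep_len(j, n),
             c_call = "IGHG1", cdr3 = cdr3s, stringsAsFactors = FALSE)
}

test_that("lineage thresholds follow the homology arithmetic", {
  # identical CDR3s, same V/J -> one lineage
  r <- simple_records(c("ACACACACAC", "ACACACACAC"))
  expect_equal(length(unique(cluster_lineages(r))), 1)

  base <- strsplit(paste(rep("AC", 10), collapse = ""), "")[[1]]  # length 20
  two <- base; two[c(1, 3)] <- "G"     # 90% identity
  four <- base; four[c(1, 3, 5, 7)] <- "G"  # 80% identity
  r2 <- simple_records(vapply(list(base, two), paste, "", collapse = ""))
  expect_equal(length(unique(cluster_lineages(r2))), 1)
  r3 <- simple_records(vapply(list(base, four), paste, "", collapse = ""))
  expect_equal(length(unique(cluster_lineages(r3))), 2)

  # single linkage chains A~B~C even when A~C is below threshold
  a <- base
  b <- base; b[1:2] <- "G"             # A-B 90%
  c2 <- base; c2[c(1, 2, 3, 4)] <- "G" # B-C 90%, A-C 80%
  r4 <- simple_records(vapply(list(a, b, c2), paste, "", collapse = ""))
  lin <- cluster_lineages(r4)
  expect_equal(length(unique(lin)), 1)
  # complete linkage refuses the chain
  lin_c <- cluster_lineages(r4, lineage_params(linkage = "complete"))
  expect_gt(length(unique(lin_c)), 1)
})

test_that("records never cluster across subjects, V, J or CDR3 length", {
  r <- simple_records(rep("ACACACACAC", 4))
  r$subject_id <- c("S1", "S2", "S1", "S1")
  r$v_call[3] <- "IGHV3-23*01"
  r$j_call[4] <- "IGHJ6"
  expect_equal(length(unique(cluster_lineages(r))), 4)
  # same V gene, different allele: still one partition
  r2 <- simple_records(rep("ACACACACAC", 2))
  r2$v_call <- c("IGHV1-2*01", "IGHV1-2*02")
  expect_equal(length(unique(cluster_lineages(r2))), 1)
})

test_that("lineage ids are canonical and input-order invariant", {
  r <- simple_records(c("ACACACACAC", "ACACACACAC", "GTGTGTGTGT"))
  lin1 <- cluster_lineages(r)
  perm <- c(3, 1, 2)
  lin2 <- cluster_lineages(r[perm, ])
  expect_identical(lin1[r$sequence_id], lin2[r$sequence_id])
  expect_equal(unname(lin1["seq-01"]), "seq-01")
})

test_that("lineage clustering equals the brute-force oracle on random repertoires", {
  for (s in 1:40) {
    r <- random_repertoire(sample(5:50, 1), seed = 1000 + s)
    lin <- cluster_lineages(r)
    oracle <- oracle_lineages(r, 0.85)
    expect_true(same_partition(as.integer(factor(lin[r$sequence_id])),
                               oracle))
  }
})

test_that("clones refine lineages and follow the 98% threshold", {
  L <- 50
  base <- strsplit(paste(rep("A", L), collapse = ""), "")[[1]]
  one <- base; one[1] <- "C"          # 98% to base
  two <- base; two[2:3] <- "C"        # 96% to base, 94% to `one`
  r <- simple_records(vapply(list(base, one, two), paste, "", collapse = ""))
  clones <- track_clones(r)
  expect_equal(unname(clones["seq-01"]), unname(clones["seq-02"]))
  expect_false(clones[["seq-03"]] == clones[["seq-01"]])
  # property: clone partition refines lineage partition
  for (s in 1:20) {
    rr <- random_repertoire(sample(5:40, 1), seed = 2000 + s)
    lin <- cluster_lineages(rr)
    cl <- track_clones(rr)
    split_by_clone <- split(lin, cl)
    expect_true(all(vapply(split_by_clone,
                           function(x) length(unique(x)) == 1, logical(1))))
  }
})

test_that("records without a CDR3 are excluded and counted", {
  r <- simple_records(c("ACACACACAC", NA, ""))
  expect_message(lin <- cluster_lineages(r), "2 record")
  expect_equal(attr(lin, "n_excluded"), 2)
  expect_true(is.na(lin[["seq-02"]]))
})

test_that("mutation profiles count non-gap mismatches per region", {
  germ <- paste(rep("ACGTT", 50), collapse = "")   # 250 nt
  rec0 <- make_record(germ, germ)
  p0 <- mutation_profile(rec0)
  expect_true(all(p0$frequency == 0))
  # 5 mismatches over 250 bases -> 2%
  s <- strsplit(germ, "")[[1]]
  s[c(3, 50, 100, 150, 240)] <- c("T", "A", "G", "G", "A")
  p5 <- mutation_profile(make_record(paste(s, collapse = ""), germ))
  expect_equal(p5$frequency[p5$region == "global"], 0.02)
  expect_equal(sum(p5$n_mutations[p5$region %in%
                                    c("FR1", "CDR1", "FR2", "CDR2", "FR3")]),
               p5$n_mutations[p5$region == "global"])
  # CDR = CDR1 u CDR2 and FR = FR1 u FR2 u FR3
  expect_equal(p5$n_mutations[p5$region == "CDR"] +
                 p5$n_mutations[p5$region == "FR"],
               p5$n_mutations[p5$region == "global"])
})

test_that("gap columns are excluded from numerator and denominator", {
  # 100 columns: 10 gap columns, 2 mismatches among the 90 non-gap columns
  g <- rep("A", 100); s <- rep("A", 100)
  g[11:20] <- "."                      # germline gaps
  s[c(30, 60)] <- "G"
  rec <- make_record(paste(s, collapse = ""), paste(g, collapse = ""),
                     regions = data.frame(start = c(1, 21, 41, 61, 81),
                                          end = c(20, 40, 60, 80, 100)))
  p <- mutation_profile(rec)
  glob <- p[p$region == "global", ]
  expect_equal(glob$n_nongap_bases, 90)
  expect_equal(glob$n_mutations, 2)
  expect_equal(glob$frequency, 2 / 90)
})

test_that("region intervals outside the alignment raise input errors", {
  rec <- make_record("ACGTACGTA", "ACGTACGTA")
  rec$fwr3_end <- 50
  expect_error(mutation_profile(rec), "outside alignment")
  rec2 <- make_record("ACGT", "ACGTACGTA")
  expect_error(mutation_profile(rec2), "differ in length")
})

test_that("replacement/silent calls match codon translation", {
  # GGA -> GGG at third codon position: Gly -> Gly, silent
  rec_s <- make_record("GGG", "GGA",
                       regions = data.frame(start = c(1, 1, 1, 1, 1),
                                            end = c(3, 3, 3, 3, 3)))
  expect_equal(classify_rs(rec_s)$status, "silent")
  # GGA -> AGA at first position: Gly -> Arg, replacement
  rec_r <- make_record("AGA", "GGA",
                       regions = data.frame(start = c(1, 1, 1, 1, 1),
                                            end = c(3, 3, 3, 3, 3)))
  expect_equal(classify_rs(rec_r)$status, "replacement")
  # two mismatches in one codon, classified one at a time:
  # AAA -> AGG: A2G Lys->Arg replacement, A3G Lys->Lys silent
  rec_2 <- make_record("AGG", "AAA",
                       regions = data.frame(start = c(1, 1, 1, 1, 1),
                                            end = c(3, 3, 3, 3, 3)))
  rs2 <- classify_rs(rec_2)
  expect_equal(rs2$status[rs2$position == 2], "replacement")
  expect_equal(rs2$status[rs2$position == 3], "silent")
  # codons containing gaps are unclassifiable
  rec_g <- make_record("AGG", "A.A",
                       regions = data.frame(start = c(1, 1, 1, 1, 1),
                                            end = c(3, 3, 3, 3, 3)))
  expect_true(all(classify_rs(rec_g)$status == "unclassifiable"))
  rec_na <- rec_s
  rec_na$v_frame <- NA
  expect_error(classify_rs(rec_na), "v_frame")
})

test_that("classification agrees with an independent translation oracle", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:120) {
    codon <- sample(bases, 3, replace = TRUE)
    pos <- sample.int(3, 1)
    alt <- sample(setdiff(bases, codon[pos]), 1)
    mut <- codon; mut[pos] <- alt
    rec <- make_record(paste(mut, collapse = ""),
                       paste(codon, collapse = ""),
                       regions = data.frame(start = rep(1, 5),
                                            end = rep(3, 5)))
    got <- classify_rs(rec)
    expect_equal(got$status,
                 oracle_classify(paste(codon, collapse = ""), pos, alt))
  }
})

test_that("R/S ratio applies the silent floor and the 2.9 selection flag", {
  prof <- data.frame(region = c("CDR", "FR", "CDR2", "CDR1"),
                     n_replacement = c(6L, 3L, 0L, 29L),
                     n_silent = c(2L, 0L, 0L, 10L))
  r1 <- rs_ratio(prof, "CDR")
  expect_equal(r1$ratio, 3.0)
  expect_true(r1$selected)
  r2 <- rs_ratio(prof, "FR")       # r=3, s=0 -> floor to 1
  expect_equal(r2$s_denominator, 1L)
  expect_equal(r2$ratio, 3.0)
  r3 <- rs_ratio(prof, "CDR2")     # r=s=0 -> not applicable
  expect_true(is.na(r3$ratio))
  expect_false(r3$selected)
  r4 <- rs_ratio(prof, "CDR1")     # exactly 2.9: not selected (strict >)
  expect_equal(r4$ratio, 2.9)
  expect_false(r4$selected)
  expect_error(rs_ratio(prof, "FR2"), "region not found")
})
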