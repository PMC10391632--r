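# Independent brute-force oracles and random fixture builders used across
# the suite. Each oracle is implemented from the definition, not by calling
# the package's own code path.

# Rand index by explicit pair enumeration
oracle_rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1L
    }
  }
  agree / choose(n, 2)
}

# weighted-KS enrichment score by an explicit step-by-step walk
oracle_es <- function(scores, hit, exponent = 1) {
  n <- length(scores)
  nh <- sum(hit)
  wsum <- sum(abs(scores[hit])^exponent)
  run <- 0
  max_pos <- 0
  min_neg <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      run <- run + if (wsum > 0) abs(scores[i])^exponent / wsum else 1 / nh
    } else {
      run <- run - if (n > nh) 1 / (n - nh) else 0
    }
    if (run > max_pos) max_pos <- run
    if (run < min_neg) min_neg <- run
  }
  # same tie convention as the package: positive extreme preferred
  if (max_pos >= -min_neg - 1e-10) max_pos else min_neg
}

# single-linkage lineage partition by brute force: pairwise relatedness
# matrix + transitive closure
oracle_lineages <- function(records, threshold) {
  n <- nrow(records)
  subj <- records$subject_id
  vg <- sub("\\*.*$", "", records$v_call)
  jg <- sub("\\*.*$", "", records$j_call)
  len <- nchar(records$cdr3)
  rel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (subj[i] != subj[j] || vg[i] != vg[j] || jg[i] != jg[j] ||
          len[i] != len[j]) next
      a <- strsplit(records$cdr3[i], "")[[1]]
      b <- strsplit(records$cdr3[j], "")[[1]]
      sim <- 1 - sum(a != b) / len[i]
      rel[i, j] <- sim >= threshold
    }
  }
  # transitive closure
  repeat {
    nxt <- rel | (rel %*% rel > 0)
    if (identical(nxt, rel)) break
    rel <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(rel[i, ])] <- cid
      comp[i] <- cid
    }
  }
  comp
}

# two labelings describe the same partition?
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a), min, 1L))]),
            unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b), min, 1L))]))
}

# random repertoire with a restricted alphabet so nontrivial merges occur
random_repertoire <- function(n, seed) {
  set.seed(seed)
  lens <- c(9L, 12L)
  data.frame(
    cell_id = sprintf("BC%03d", seq_len(n)),
    sequence_id = sprintf("seq-%03d", seq_len(n)),
    subject_id = sample(c("S1", "S2"), n, replace = TRUE),
    v_call = sample(c("IGHV1-2*01", "IGHV3-23*01"), n, replace = TRUE),
    j_call = sample(c("IGHJ4", "IGHJ6"), n, replace = TRUE),
    c_call = "IGHG1",
    cdr3 = vapply(sample(lens, n, replace = TRUE), function(L) {
      paste(sample(c("A", "C"), L, replace = TRUE), collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE)
}

# replacement/silent call via seqinr translation (independent codon path)
oracle_classify <- function(germ_codon, pos_in_codon, new_base) {
  g <- strsplit(germ_codon, "")[[1]]
  m <- g
  m[pos_in_codon] <- new_base
  aa_g <- seqinr::translate(g)
  aa_m <- seqinr::translate(m)
  if (aa_g == aa_m) "silent" else "replacement"
}

# build a one-record AIRR-style data frame over a given alignment pair
make_record <- function(seq_al, germ_al, regions = NULL, frame = 0L,
                        sid = "seq-001") {
  L <- nchar(seq_al)
  if (is.null(regions)) {
    # five contiguous regions tiling the alignment
    cuts <- round(seq(0, L, length.out = 6))
    regions <- data.frame(start = cuts[1:5] + 1L, end = cuts[2:6])
  }
  data.frame(cell_id = "BC001", sequence_id = sid, subject_id = "S1",
             v_call = "IGHV1-2*01", j_call = "IGHJ4", c_call = "IGHG1",
             cdr3 = "AAATTT",
             v_sequence_alignment = seq_al, v_germline_alignment = germ_al,
             v_frame = frame,
             fwr1_start = regions$start[1], fwr1_end = regions$end[1],
             cdr1_start = regions$start[2], cdr1_end = regions$end[2],
             fwr2_start = regions$start[3], fwr2_end = regions$end[3],
             cdr2_start = regions$start[4], cdr2_end = regions$end[4],
             fwr3_start = regions$start[5], fwr3_end = regions$end[5],
             duplicate_count = 120L, stringsAsFactors = FALSE)
}
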