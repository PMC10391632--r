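# BCR repertoire core: clonal-lineage clustering by CDR3 homology, somatic
# hypermutation profiling on gapped germline alignments, replacement/silent
# classification, and the R/S selection statistic.

#' Lineage clustering parameters
#'
#' Clonal lineages share subject, V gene, J gene and CDR3 length and are
#' linked by single-linkage at 85% CDR3 homology; identical clones use 98%.
#'
#' @param lineage_homology similarity threshold for lineages.
#' @param clone_homology similarity threshold for identical clones.
#' @param linkage "single" (default) or "complete".
#' @param level "nucleotide" (default) or "aminoacid" CDR3 comparison.
#' @return a `bmpc_lineage_params` list.
#' @export
lineage_params <- function(lineage_homology = 0.85, clone_homology = 0.98,
                           linkage = c("single", "complete"),
                           level = c("nucleotide", "aminoacid")) {
  linkage <- match.arg(linkage)
  level <- match.arg(level)
  if (lineage_homology <= 0 || lineage_homology > 1 ||
      clone_homology < lineage_homology || clone_homology > 1) {
    stop("invalid homology thresholds: need 0 < lineage <= clone <= 1")
  }
  structure(list(lineage_homology = lineage_homology,
                 clone_homology = clone_homology,
                 linkage = linkage, level = level),
            class = "bmpc_lineage_params")
}

hamming <- function(a, b) {
  sum(a != b)
}

translate_cdr3 <- function(nt) {
  n <- (nchar(nt) %/% 3) * 3
  if (n == 0) return("")
  codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  paste(vapply(codons, function(cd) {
    aa <- Biostrings::GENETIC_CODE[[cd]]
    if (is.null(aa)) "X" else aa
  }, character(1)), collapse = "")
}

# cluster equal-length sequences at a similarity threshold;
# single linkage = connected components of the "similar" graph,
# complete linkage = agglomerative with the complete criterion
cluster_sequences <- function(seqs, threshold, linkage = "single") {
  n <- length(seqs)
  if (n == 1) return(1L)
  chars <- do.call(rbind, strsplit(seqs, ""))
  len <- ncol(chars)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- hamming(chars[i, ], chars[j, ])
    }
  }
  sim <- 1 - d / len
  if (linkage == "single") {
    # single linkage at a fixed threshold = connected components of the
    # "similar enough" graph; iterative label merging is plenty for the
    # partition sizes produced by the (subject, V, J, length) split
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (sim[i, j] >= threshold && comp[i] != comp[j]) {
            comp[comp == comp[j]] <- comp[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    return(match(comp, unique(comp)))
  }
  # complete linkage via hclust on Hamming distance; cut where the merge
  # similarity would drop below the threshold
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  stats::cutree(hc, h = (1 - threshold) * len + 1e-9)
}

#' Cluster rearrangements into clonal lineages
#'
#' Records are first partitioned by (subject, V gene, J gene, CDR3 length) —
#' comparisons never cross subjects — then linked within partitions by
#' single-linkage clustering of CDR3 similarity (1 - Hamming/length) at the
#' lineage homology threshold. Lineage ids are canonicalized by the smallest
#' member `sequence_id`, so they are stable under input permutation.
#'
#' @param records AIRR-style data frame (needs `sequence_id`, `v_call`,
#'   `j_call`, `cdr3`; `subject_id` defaults to one subject if absent).
#' @param params a [lineage_params()].
#' @param threshold override of the homology threshold (used by
#'   [track_clones()]).
#' @return character lineage id per record (named by `sequence_id`);
#'   attribute `n_excluded` counts records without a CDR3.
#' @export
cluster_lineages <- function(records, params = lineage_params(),
                             threshold = params$lineage_homology) {
  subject <- records$subject_id %||% rep("S1", nrow(records))
  ok <- !is.na(records$cdr3) & nzchar(records$cdr3)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(n_excluded, " record(s) without CDR3 excluded from lineage ",
            "clustering")
  }
  v_gene <- sub("\\*.*$", "", records$v_call)
  j_gene <- sub("\\*.*$", "", records$j_call)
  cdr3 <- if (params$level == "aminoacid") {
    vapply(records$cdr3, translate_cdr3, character(1), USE.NAMES = FALSE)
  } else {
    records$cdr3
  }
  key <- paste(subject, v_gene, j_gene, nchar(cdr3), sep = "|")
  out <- rep(NA_character_, nrow(records))
  idx_ok <- which(ok)
  for (grp in split(idx_ok, key[idx_ok])) {
    comp <- cluster_sequences(cdr3[grp], threshold, params$linkage)
    for (cc in unique(comp)) {
      members <- grp[comp == cc]
      out[members] <- min(records$sequence_id[members])
    }
  }
  names(out) <- records$sequence_id
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Track identical clones (98% CDR3 homology)
#'
#' Same procedure as [cluster_lineages()] at the clone homology threshold;
#' clone partitions always refine lineage partitions.
#'
#' @inheritParams cluster_lineages
#' @return character clone id per record.
#' @export
track_clones <- function(records, params = lineage_params()) {
  cluster_lineages(records, params, threshold = params$clone_homology)
}

REGION_SETS <- list(
  FR1 = "FR1", CDR1 = "CDR1", FR2 = "FR2", CDR2 = "CDR2", FR3 = "FR3",
  CDR = c("CDR1", "CDR2"), FR = c("FR1", "FR2", "FR3"), global = NA
)

region_intervals <- function(record) {
  data.frame(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
    start = as.integer(c(record$fwr1_start, record$cdr1_start,
                         record$fwr2_start, record$cdr2_start,
                         record$fwr3_start)),
    end = as.integer(c(record$fwr1_end, record$cdr1_end, record$fwr2_end,
                       record$cdr2_end, record$fwr3_end)),
    stringsAsFactors = FALSE)
}

is_gap <- function(chars) chars %in% c(".", "-")

#' Somatic-hypermutation profile of one rearrangement
#'
#' Mutation counts are non-gap mismatches between the expressed and germline
#' V alignments; positions where either sequence has a gap are excluded from
#' both numerator and denominator. Frequencies are reported per region
#' (FR1, CDR1, FR2, CDR2, FR3), for the combined CDR and FR regions, and
#' globally over the whole V alignment. Replacement/silent counts come from
#' [classify_rs()] (mismatches in gap-containing codons are counted as
#' unclassifiable).
#'
#' @param record one row of an AIRR-style data frame.
#' @return data frame with one row per region: `region`, `n_mutations`,
#'   `n_nongap_bases`, `frequency`, `n_replacement`, `n_silent`,
#'   `n_unclassifiable`.
#' @export
mutation_profile <- function(record) {
  seq_chars <- strsplit(record$v_sequence_alignment, "")[[1]]
  germ_chars <- strsplit(record$v_germline_alignment, "")[[1]]
  if (length(seq_chars) != length(germ_chars)) {
    stop("input error: alignments of record ", record$sequence_id,
         " differ in length")
  }
  L <- length(seq_chars)
  iv <- region_intervals(record)
  if (any(iv$start < 1) || any(iv$end > L)) {
    stop("input error: region interval outside alignment for record ",
         record$sequence_id)
  }
  nongap <- !is_gap(seq_chars) & !is_gap(germ_chars)
  mismatch <- nongap & seq_chars != germ_chars
  rs <- classify_rs(record)
  pos_region <- rep(NA_character_, L)
  for (i in seq_len(nrow(iv))) {
    pos_region[iv$start[i]:iv$end[i]] <- iv$region[i]
  }
  rows <- lapply(names(REGION_SETS), function(rg) {
    members <- REGION_SETS[[rg]]
    in_rg <- if (identical(rg, "global")) rep(TRUE, L)
             else pos_region %in% members
    n_mut <- sum(mismatch & in_rg)
    n_base <- sum(nongap & in_rg)
    rs_rg <- rs[rs$position %in% which(in_rg), , drop = FALSE]
    data.frame(region = rg,
               n_mutations = n_mut,
               n_nongap_bases = n_base,
               frequency = if (n_base > 0) n_mut / n_base else NA_real_,
               n_replacement = sum(rs_rg$status == "replacement"),
               n_silent = sum(rs_rg$status == "silent"),
               n_unclassifiable = sum(rs_rg$status == "unclassifiable"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mutation profiles for a whole rearrangement table
#'
#' @param records AIRR-style data frame.
#' @return long data frame of [mutation_profile()] rows with a
#'   `sequence_id` column.
#' @export
mutation_profiles <- function(records) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    cbind(sequence_id = records$sequence_id[i],
          mutation_profile(records[i, , drop = FALSE]),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify each mismatch of a record as replacement or silent
#'
#' Each non-gap mismatch is classified by translating the germline codon
#' against the germline codon with that single substitution applied
#' (standard genetic code, one substitution at a time in germline context).
#' Codons containing alignment gaps, or truncated at the alignment edges,
#' are unclassifiable.
#'
#' @param record one row of an AIRR-style data frame; requires a `v_frame`
#'   column (0-based reading-frame offset of the alignment).
#' @return data frame: `position`, `germline_base`, `observed_base`,
#'   `status`.
#' @export
classify_rs <- function(record) {
  if (is.null(record$v_frame) || is.na(record$v_frame)) {
    stop("input error: record ", record$sequence_id,
         " lacks the v_frame reading-frame offset")
  }
  frame <- as.integer(record$v_frame)
  seq_chars <- strsplit(record$v_sequence_alignment, "")[[1]]
  germ_chars <- strsplit(record$v_germline_alignment, "")[[1]]
  nongap <- !is_gap(seq_chars) & !is_gap(germ_chars)
  mis <- which(nongap & seq_chars != germ_chars)
  if (length(mis) == 0) {
    return(data.frame(position = integer(0), germline_base = character(0),
                      observed_base = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  status <- vapply(mis, function(pos) {
    codon_idx <- (pos - 1L - frame) %/% 3L
    codon_pos <- frame + codon_idx * 3L + 1:3
    if (codon_idx < 0 || any(codon_pos > length(germ_chars))) {
      return("unclassifiable")
    }
    g_codon <- germ_chars[codon_pos]
    s_at <- seq_chars[pos]
    if (any(is_gap(g_codon)) || any(is_gap(seq_chars[codon_pos])) ||
        !all(g_codon %in% DNA_BASES) || !s_at %in% DNA_BASES) {
      return("unclassifiable")
    }
    m_codon <- g_codon
    m_codon[codon_pos == pos] <- s_at
    aa_g <- Biostrings::GENETIC_CODE[[paste(g_codon, collapse = "")]]
    aa_m <- Biostrings::GENETIC_CODE[[paste(m_codon, collapse = "")]]
    if (identical(aa_g, aa_m)) "silent" else "replacement"
  }, character(1))
  data.frame(position = mis, germline_base = germ_chars[mis],
             observed_base = seq_chars[mis], status = status,
             stringsAsFactors = FALSE)
}

#' Replacement/silent ratio with the silent-count floor
#'
#' `ratio = r / max(s, 1)` when there are replacement mutations but no
#' silent ones (the silent count is set to 1); with `r = s = 0` the ratio is
#' not applicable. A ratio > 2.9 flags the region as antigen-selected.
#'
#' @param profile a [mutation_profile()] data frame (or any table with
#'   `region`, `n_replacement`, `n_silent`).
#' @param region region name to evaluate.
#' @param selection_threshold flagging threshold (default 2.9).
#' @return list: `region`, `r_count`, `s_count`, `s_denominator`, `ratio`
#'   (NA when not applicable), `selected`.
#' @export
rs_ratio <- function(profile, region, selection_threshold = 2.9) {
  row <- profile[profile$region == region, , drop = FALSE]
  if (nrow(row) != 1) stop("input error: region not found: ", region)
  r <- row$n_replacement
  s <- row$n_silent
  if (r == 0 && s == 0) {
    return(list(region = region, r_count = 0L, s_count = 0L,
                s_denominator = 0L, ratio = NA_real_, selected = FALSE))
  }
  denom <- if (r > 0) max(s, 1L) else s
  ratio <- r / denom
  list(region = region, r_count = as.integer(r), s_count = as.integer(s),
       s_denominator = as.integer(denom), ratio = ratio,
       selected = isTRUE(ratio > selection_threshold))
}
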