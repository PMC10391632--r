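# Synthetic BCR heavy-chain repertoire with known lineage membership and
# codon-level replacement/silent mutation truth.

# V-segment region layout used by the generator: five regions tiling a
# 312 nt template, codon-aligned (1-based closed intervals, frame offset 0).
V_TEMPLATE_LENGTH <- 312L
V_REGIONS <- data.frame(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
  start  = c(1L, 76L, 100L, 151L, 175L),
  end    = c(75L, 99L, 150L, 174L, 312L),
  stringsAsFactors = FALSE
)

DNA_BASES <- c("A", "C", "G", "T")

#' Apply point substitutions to a germline V sequence with codon-level truth
#'
#' Substitution-only somatic-hypermutation model (no indels): every base
#' mutates independently with probability `rate` to one of the three other
#' bases. Each substitution is classified as replacement or silent by
#' translating the affected germline codon with only that substitution
#' applied (standard genetic code, one-at-a-time in germline context).
#'
#' @param germline nucleotide string over A/C/G/T.
#' @param rate per-base substitution probability.
#' @param frame_offset 0-based reading-frame phase (0, 1 or 2).
#' @return list with `sequence` (mutated string) and `sites`, a data frame
#'   with one row per substitution: `position`, `germline_base`, `new_base`,
#'   `status` ("replacement", "silent", or "unclassifiable" for positions in
#'   incomplete codons at the sequence edges).
#' @export
mutate_v_sequence <- function(germline, rate, frame_offset = 0L) {
  chars <- strsplit(germline, "")[[1]]
  if (length(chars) == 0 || any(!chars %in% DNA_BASES)) {
    stop("input error: germline must be a non-empty string over A/C/G/T")
  }
  if (!frame_offset %in% 0:2) {
    stop("input error: frame_offset must be 0, 1 or 2")
  }
  empty <- data.frame(position = integer(0), germline_base = character(0),
                      new_base = character(0), status = character(0),
                      stringsAsFactors = FALSE)
  if (rate <= 0) {
    return(list(sequence = germline, sites = empty))
  }
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) == 0) {
    return(list(sequence = germline, sites = empty))
  }
  new_base <- vapply(chars[hit], function(b) {
    sample(setdiff(DNA_BASES, b), 1L)
  }, character(1), USE.NAMES = FALSE)
  mutated <- chars
  mutated[hit] <- new_base
  status <- vapply(seq_along(hit), function(i) {
    classify_substitution(chars, hit[i], new_base[i], frame_offset)
  }, character(1))
  list(sequence = paste(mutated, collapse = ""),
       sites = data.frame(position = hit, germline_base = chars[hit],
                          new_base = new_base, status = status,
                          stringsAsFactors = FALSE))
}

# replacement/silent call for a single substitution in germline context;
# `chars` is the germline as a character vector (no gaps)
classify_substitution <- function(chars, pos, new_base, frame_offset) {
  codon_idx <- (pos - 1L - frame_offset) %/% 3L
  codon_pos <- frame_offset + codon_idx * 3L + 1:3
  if (codon_idx < 0 || any(codon_pos > length(chars))) {
    return("unclassifiable")
  }
  germ_codon <- chars[codon_pos]
  mut_codon <- germ_codon
  mut_codon[codon_pos == pos] <- new_base
  aa_g <- Biostrings::GENETIC_CODE[[paste(germ_codon, collapse = "")]]
  aa_m <- Biostrings::GENETIC_CODE[[paste(mut_codon, collapse = "")]]
  if (identical(aa_g, aa_m)) "silent" else "replacement"
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# draw lineage sizes from a truncated power law P(k) ~ k^-exponent
sample_lineage_sizes <- function(n, dist) {
  if (!identical(dist$name, "powerlaw")) {
    stop("configuration error: unknown lineage_size_distribution '",
         dist$name, "'")
  }
  k <- seq_len(dist$max_size)
  sample(k, n, replace = TRUE, prob = k^(-dist$exponent))
}

#' Simulate an AIRR-style heavy-chain rearrangement table with ground truth
#'
#' Each clonal lineage is assigned one subject, one germline V template, one
#' J call and one CDR3 length; members' CDR3s diverge from the lineage
#' founder by at most `cdr3_divergence` per base, and V sequences are mutated
#' by [mutate_v_sequence()]. Lineage sizes follow the configured power law;
#' the total number of repertoire cells is capped at the VDJ-eligible subset
#' of labeled cells (`vdj_match_rate`).
#'
#' @param config a [sim_config()].
#' @param labels named cluster labels (names are cell barcodes); typically
#'   `truth$labels` from [simulate_expression()].
#' @param subjects optional named subject ids per barcode; lineages never
#'   span subjects. Defaults to a single subject.
#' @return list with `records` (AIRR-compliant data frame) and `truth`
#'   (lineage id per sequence_id, per-record per-region mutation and
#'   replacement/silent counts, per-site truth table).
#' @export
simulate_repertoire <- function(config, labels, subjects = NULL) {
  cfg <- validate_sim_config(config)
  if (max(cfg$cdr3_length_range) < 3) {
    stop("configuration error: cdr3_length_range shorter than 3 nt")
  }
  set.seed(stage_seed(cfg$seed, 1703L))
  cells <- names(labels)
  if (is.null(subjects)) {
    subjects <- stats::setNames(rep("S1", length(cells)), cells)
  }

  n_eligible <- round(cfg$vdj_match_rate * length(cells))
  eligible <- sample(cells, n_eligible)

  # germline V template library
  v_names <- paste0(c("IGHV1-2", "IGHV1-69", "IGHV3-23", "IGHV3-30",
                      "IGHV3-7", "IGHV4-34", "IGHV4-59", "IGHV5-51",
                      "IGHV2-5", "IGHV6-1"), "*01")
  v_templates <- vapply(v_names, function(x) random_dna(V_TEMPLATE_LENGTH),
                        character(1))
  j_names <- paste0("IGHJ", 1:6)
  isotypes <- c("IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1", "IGHA2",
                "IGHM", "IGHD", "IGHE")
  isotype_prob <- c(0.42, 0.12, 0.05, 0.02, 0.15, 0.05, 0.16, 0.02, 0.01)

  sizes <- sample_lineage_sizes(cfg$n_lineages, cfg$lineage_size_distribution)

  # assign lineages to subjects proportionally to eligible cells, then
  # draw members within subject without replacement
  subj_pool <- split(eligible, subjects[eligible])
  subj_names <- names(subj_pool)
  lineage_subject <- character(cfg$n_lineages)
  avail <- vapply(subj_pool, length, integer(1))
  members <- vector("list", cfg$n_lineages)
  for (l in seq_len(cfg$n_lineages)) {
    open <- subj_names[avail > 0]
    if (length(open) == 0) break
    s <- if (length(open) == 1) open else
      sample(open, 1L, prob = avail[open])
    take <- min(sizes[l], avail[[s]])
    picked <- subj_pool[[s]][seq_len(take)]
    subj_pool[[s]] <- subj_pool[[s]][-seq_len(take)]
    avail[[s]] <- avail[[s]] - take
    lineage_subject[l] <- s
    members[[l]] <- picked
  }

  recs <- list()
  lineage_truth <- list()
  mut_truth <- list()
  site_truth <- list()
  seq_i <- 0L
  for (l in seq_len(cfg$n_lineages)) {
    mem <- members[[l]]
    if (is.null(mem) || length(mem) == 0) next
    v_i <- sample.int(length(v_templates), 1L)
    j_call <- sample(j_names, 1L)
    iso <- sample(isotypes, 1L, prob = isotype_prob)
    len <- sample(seq(cfg$cdr3_length_range[1], cfg$cdr3_length_range[2]), 1L)
    founder <- strsplit(random_dna(len), "")[[1]]
    n_div <- floor(cfg$cdr3_divergence * len)
    for (cell in mem) {
      seq_i <- seq_i + 1L
      sid <- sprintf("seq-%05d", seq_i)
      cdr3 <- founder
      if (n_div > 0) {
        pos <- sample.int(len, n_div)
        cdr3[pos] <- vapply(cdr3[pos], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1), USE.NAMES = FALSE)
      }
      mut <- mutate_v_sequence(v_templates[[v_i]], cfg$v_mutation_rate, 0L)
      recs[[seq_i]] <- data.frame(
        cell_id = cell, sequence_id = sid,
        subject_id = subjects[[cell]],
        v_call = v_names[v_i], j_call = j_call, c_call = iso,
        cdr3 = paste(cdr3, collapse = ""),
        v_sequence_alignment = mut$sequence,
        v_germline_alignment = v_templates[[v_i]],
        v_frame = 0L,
        fwr1_start = V_REGIONS$start[1], fwr1_end = V_REGIONS$end[1],
        cdr1_start = V_REGIONS$start[2], cdr1_end = V_REGIONS$end[2],
        fwr2_start = V_REGIONS$start[3], fwr2_end = V_REGIONS$end[3],
        cdr2_start = V_REGIONS$start[4], cdr2_end = V_REGIONS$end[4],
        fwr3_start = V_REGIONS$start[5], fwr3_end = V_REGIONS$end[5],
        duplicate_count = 50L + stats::rnbinom(1L, mu = 400, size = 2),
        stringsAsFactors = FALSE)
      lineage_truth[[sid]] <- l
      mut_truth[[sid]] <- summarize_site_truth(mut$sites, sid)
      if (nrow(mut$sites) > 0) {
        site_truth[[sid]] <- cbind(sequence_id = sid, mut$sites,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  truth <- list(
    lineage = unlist(lineage_truth),
    mutations = do.call(rbind, c(mut_truth, list(make.row.names = FALSE))),
    sites = if (length(site_truth)) do.call(rbind, c(site_truth,
                                                     list(make.row.names = FALSE)))
            else NULL
  )
  list(records = records, truth = truth)
}

# aggregate per-site truth into per-region mutation / R / S counts
summarize_site_truth <- function(sites, sid) {
  region_of <- function(pos) {
    hit <- V_REGIONS$region[pos >= V_REGIONS$start & pos <= V_REGIONS$end]
    if (length(hit)) hit else NA_character_
  }
  reg <- vapply(sites$position, region_of, character(1))
  out <- data.frame(sequence_id = sid, region = V_REGIONS$region,
                    n_mutations = 0L, n_replacement = 0L, n_silent = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(sites) > 0) {
    for (r in V_REGIONS$region) {
      in_r <- reg == r
      out[out$region == r, c("n_mutations", "n_replacement", "n_silent")] <-
        c(sum(in_r), sum(in_r & sites$status == "replacement"),
          sum(in_r & sites$status == "silent"))
    }
  }
  out
}
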