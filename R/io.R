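# Readers/writers for the standard formats the pipeline touches: MatrixMarket
# count triplets (10x layout: features x cells on disk, cells x genes in
# memory), AIRR Rearrangement TSV, GMT gene sets, STRING-like edge tables,
# ground-truth JSON and the report-table bundle with its manifest.

AIRR_REQUIRED_COLUMNS <- c(
  "cell_id", "sequence_id", "v_call", "j_call", "c_call", "cdr3",
  "v_sequence_alignment", "v_germline_alignment",
  "fwr1_start", "fwr1_end", "cdr1_start", "cdr1_end",
  "fwr2_start", "fwr2_end", "cdr2_start", "cdr2_end",
  "fwr3_start", "fwr3_end", "duplicate_count")

#' Read a count matrix from a MatrixMarket triplet directory
#'
#' Expects `matrix.mtx` (features x cells, 10x convention), `barcodes.tsv`
#' and `features.tsv`. Returns a cells x genes sparse integer matrix with
#' barcodes as rownames and gene symbols as colnames.
#'
#' @param path directory containing the triplet.
#' @return dgCMatrix, cells x genes.
#' @export
read_count_matrix <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  bc <- file.path(path, "barcodes.tsv")
  ft <- file.path(path, "features.tsv")
  for (f in c(mtx, bc, ft)) {
    if (!file.exists(f)) stop("format error: missing file ", f)
  }
  m <- Matrix::readMM(mtx)
  barcodes <- readLines(bc)
  features <- readLines(ft)
  if (nrow(m) != length(features)) {
    stop("format error: matrix has ", nrow(m), " features but features.tsv ",
         "lists ", length(features))
  }
  if (ncol(m) != length(barcodes)) {
    stop("format error: matrix has ", ncol(m), " cells but barcodes.tsv ",
         "lists ", length(barcodes))
  }
  m <- methods::as(methods::as(Matrix::t(m), "generalMatrix"),
                   "CsparseMatrix")
  dimnames(m) <- list(barcodes, features)
  m
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' @param counts cells x genes matrix with barcode rownames and gene-symbol
#'   colnames.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::t(Matrix::Matrix(counts, sparse = TRUE))
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(rownames(counts), file.path(path, "barcodes.tsv"))
  writeLines(colnames(counts), file.path(path, "features.tsv"))
  invisible(path)
}

#' Read an AIRR Rearrangement TSV
#'
#' Validates the per-record invariants: equal-length gapped V alignments and
#' ordered, non-overlapping FR1 < CDR1 < FR2 < CDR2 < FR3 region intervals
#' (1-based closed, AIRR convention). Invalid records are dropped and
#' reported (row numbers) in the `"invalid"` attribute.
#'
#' @param path TSV file with a header row.
#' @return data frame of valid records; attribute `invalid` is a data frame
#'   of row numbers and reasons.
#' @export
read_airr <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  missing <- setdiff(AIRR_REQUIRED_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    attr(tab, "invalid") <- data.frame(row = integer(0),
                                       reason = character(0))
    return(tab)
  }
  reasons <- rep(NA_character_, nrow(tab))
  len_ok <- nchar(tab$v_sequence_alignment) == nchar(tab$v_germline_alignment)
  reasons[!len_ok] <- "unequal alignment lengths"
  starts <- as.matrix(tab[, c("fwr1_start", "cdr1_start", "fwr2_start",
                              "cdr2_start", "fwr3_start")])
  ends <- as.matrix(tab[, c("fwr1_end", "cdr1_end", "fwr2_end",
                            "cdr2_end", "fwr3_end")])
  ord_ok <- apply(cbind(starts, ends), 1, function(x) {
    s <- x[1:5]; e <- x[6:10]
    all(s <= e) && all(e[-5] < s[-1]) && all(s >= 1)
  })
  reasons[is.na(reasons) & !ord_ok] <- "region intervals unordered or overlapping"
  invalid <- which(!is.na(reasons))
  out <- tab[setdiff(seq_len(nrow(tab)), invalid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "invalid") <- data.frame(row = invalid,
                                     reason = reasons[invalid],
                                     stringsAsFactors = FALSE)
  out
}

#' Write an AIRR Rearrangement TSV
#' @param records data frame of rearrangements.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT lines are `name <tab> description <tab> member...`; duplicate members
#' are deduplicated. A line with fewer than three fields is a format error.
#'
#' @param path GMT file.
#' @return named list of unique gene-symbol vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("format error: GMT line ", i, " has fewer than 3 fields")
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of gene-symbol vectors.
#' @param path output file.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-like protein-interaction edge table
#'
#' Three tab-separated columns: proteinA, proteinB, combined_score (integer
#' 0-1000). Edges are undirected: (A,B) and (B,A) collapse to one edge
#' (keeping the larger score); self-loops are dropped.
#'
#' @param path TSV file (with or without a header row).
#' @return data frame with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @export
read_interaction_edges <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           header = FALSE)
  if (ncol(tab) < 3) stop("format error: expected 3 columns")
  # tolerate a header row
  if (suppressWarnings(is.na(as.numeric(tab[1, 3]))) && nrow(tab) > 0) {
    tab <- tab[-1, , drop = FALSE]
  }
  score_num <- suppressWarnings(as.numeric(tab[[3]]))
  if (any(is.na(score_num)) || any(score_num != round(score_num))) {
    stop("format error: combined_score must be an integer")
  }
  if (any(score_num < 0 | score_num > 1000)) {
    stop("format error: combined_score must lie in 0-1000")
  }
  edges <- data.frame(protein_a = as.character(tab[[1]]),
                      protein_b = as.character(tab[[2]]),
                      combined_score = as.integer(score_num),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  edges$protein_a <- a
  edges$protein_b <- b
  edges <- edges[order(a, b, -edges$combined_score), , drop = FALSE]
  edges <- edges[!duplicated(edges[, c("protein_a", "protein_b")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Write ground truth as JSON
#' @param truth ground-truth list from the generators.
#' @param path output JSON file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a bundle of result tables plus a JSON manifest
#'
#' Each named data frame in `bundle` becomes `<name>.tsv` in `out_dir`; the
#' manifest records every emitted file exactly once, along with the run
#' parameters, seed and package version. Rerunning with identical inputs
#' produces byte-identical TSVs.
#'
#' @param bundle named list of data frames (may be empty).
#' @param out_dir output directory (created if needed).
#' @param parameters list of parameters to record in the manifest.
#' @param seed seed to record.
#' @return the manifest, invisibly.
#' @export
write_report_tables <- function(bundle, out_dir, parameters = list(),
                                seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  files <- character(0)
  for (nm in names(bundle)) {
    f <- paste0(nm, ".tsv")
    utils::write.table(bundle[[nm]], file.path(out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- list(files = as.list(files),
                   parameters = parameters,
                   seed = seed,
                   version = as.character(utils::packageVersion("bmpc")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
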