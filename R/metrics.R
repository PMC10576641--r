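# Per-residue alignment-quality metrics against a reference alignment:
# precision (correct pairs / reported pairs) and sensitivity (correct pairs /
# reference pairs), plus motif coverage. Residue pairs are 1-based
# (query_index, target_index) rows of a two-column matrix.

as_pair_set <- function(pairs, what = "pair set", one_to_one = FALSE) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.null(pairs) || !length(pairs))
    return(matrix(integer(0), ncol = 2))
  stopifnot(is.matrix(pairs), ncol(pairs) == 2)
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- NULL
  pairs <- pairs[!duplicated(paste(pairs[, 1], pairs[, 2])), , drop = FALSE]
  if (one_to_one &&
      (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2])))
    stop(what, " is not a one-to-one matching: a residue index appears twice")
  pairs
}

pair_keys <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = ",")

#' Aligned residue pairs of an alignment
#'
#' One pair per matched (diagonal) step; gap steps contribute nothing.
#'
#' @param aln A `local_alignment` or `global_alignment`.
#' @return Two-column integer matrix of 1-based (query, target) indices.
#' @export
pairs_from_alignment <- function(aln) {
  if (inherits(aln, "global_alignment")) return(aln$cells)
  stopifnot(inherits(aln, "local_alignment"))
  cells <- aln$cells
  if (!nrow(cells)) return(matrix(integer(0), ncol = 2))
  diag_step <- c(TRUE, if (nrow(cells) > 1L)
    diff(cells[, 1]) == 1 & diff(cells[, 2]) == 1)
  cells[diag_step, , drop = FALSE]
}

#' Union of residue pairs over all alignments of a hit
#'
#' @param hit An `embalign_hit`, or a list of alignments.
#' @param best_only Use only the highest-scoring alignment instead of the
#'   union of all reported alignments.
#' @return Two-column integer matrix of unique pairs.
#' @export
pairs_from_hit <- function(hit, best_only = FALSE) {
  alns <- if (inherits(hit, "embalign_hit")) hit$alignments else hit
  if (!length(alns)) return(matrix(integer(0), ncol = 2))
  if (best_only) alns <- alns[1]
  as_pair_set(do.call(rbind, lapply(alns, pairs_from_alignment)))
}

#' Per-residue precision and sensitivity against a reference
#'
#' Precision is the fraction of reported pairs present in the reference;
#' sensitivity is the fraction of reference pairs recovered. An empty test
#' set gives (0, 0) by convention; an empty reference is an error.
#'
#' @param test Reported residue pairs (two-column matrix or data.frame).
#' @param reference Reference residue pairs (one-to-one matching, non-empty).
#' @return Named numeric vector `c(precision = , sensitivity = )`.
#' @export
precision_sensitivity <- function(test, reference) {
  reference <- as_pair_set(reference, "reference", one_to_one = TRUE)
  if (!nrow(reference)) stop("reference pair set must be non-empty")
  test <- as_pair_set(test, "test")
  if (!nrow(test)) return(c(precision = 0, sensitivity = 0))
  correct <- sum(pair_keys(test) %in% pair_keys(reference))
  c(precision = correct / nrow(test),
    sensitivity = correct / nrow(reference))
}

#' Coverage of a reference motif by reported pairs
#'
#' @param test Reported residue pairs.
#' @param motif Motif residue pairs (non-empty).
#' @return Fraction of motif pairs present in `test`, in \[0, 1\].
#' @export
motif_coverage <- function(test, motif) {
  motif <- as_pair_set(motif, "motif")
  if (!nrow(motif)) stop("motif pair set must be non-empty")
  test <- as_pair_set(test, "test")
  if (!nrow(test)) return(0)
  mean(pair_keys(motif) %in% pair_keys(test))
}

#' Residue pairs from a pair of gapped alignment strings
#'
#' @param gapped_query,gapped_target Equal-length gapped strings using `-`.
#' @return Two-column integer matrix of 1-based matched positions.
#' @export
pairs_from_gapped <- function(gapped_query, gapped_target) {
  qc <- strsplit(gapped_query, "")[[1]]
  tc <- strsplit(gapped_target, "")[[1]]
  if (length(qc) != length(tc))
    stop("gapped strings must have equal length")
  qi <- cumsum(qc != "-")
  ti <- cumsum(tc != "-")
  keep <- qc != "-" & tc != "-"
  cbind(qi[keep], ti[keep])
}

#' Read a reference alignment as residue pairs
#'
#' Accepts either a two-entry gapped FASTA file (the two aligned rows) or a
#' tab-separated pair list with columns `query_pos` and `target_pos`
#' (1-based; a header line is optional).
#'
#' @param path Path to the reference file.
#' @return Two-column integer matrix of residue pairs.
#' @export
read_reference_pairs <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(trimws(first), ">")) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) != 2L)
      stop("gapped FASTA reference must contain exactly two entries, found ",
           length(set))
    return(pairs_from_gapped(as.character(set[[1]]), as.character(set[[2]])))
  }
  tab <- read.table(path, sep = "\t", header = grepl("[a-zA-Z]", first),
                    stringsAsFactors = FALSE)
  cols <- if (all(c("query_pos", "target_pos") %in% names(tab)))
    tab[, c("query_pos", "target_pos")] else tab[, 1:2]
  as_pair_set(as.matrix(cols), "reference")
}
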