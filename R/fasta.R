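# Sequence records and FASTA I/O.
#
# A record collection is a plain data.frame with columns id, sequence,
# description. Sequences are uppercase over the 20 standard amino acids plus
# X; ambiguity codes B/Z/U/O are rejected explicitly rather than silently
# remapped.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Create a collection of sequence records
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of amino-acid sequences (uppercased on
#'   input; standard 20 letters plus `X`).
#' @param description Optional free-text descriptions (recycled if scalar).
#' @return A `data.frame` with columns `id`, `sequence`, `description`.
#' @export
#' @examples
#' sequence_records(c("a", "b"), c("MKV", "GG"))
sequence_records <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have the same length")
  if (any(!nzchar(id)) || anyNA(id)) stop("sequence ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  if (any(nchar(sequence) < 1L)) stop("sequences must have length >= 1")
  for (i in seq_along(sequence)) validate_sequence(sequence[i], id[i])
  data.frame(id = id, sequence = sequence,
             description = rep_len(as.character(description), length(id)),
             stringsAsFactors = FALSE)
}

validate_sequence <- function(seq, id) {
  chars <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(chars, c(AA_ALPHABET, "X"))
  if (length(bad)) {
    hint <- if (any(bad %in% c("B", "Z", "U", "O")))
      " (ambiguity/rare codes B, Z, U, O are not supported; replace or remove them)"
    else ""
    stop("sequence '", id, "' contains unsupported character(s): ",
         paste(bad, collapse = ", "), hint)
  }
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased, surrounding whitespace is stripped and duplicate
#' identifiers are rejected. The identifier is the first whitespace-delimited
#' token of the header; the remainder becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return A record `data.frame` as from [sequence_records()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) stop("empty FASTA file: ", path)
  first <- nonempty[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: sequence data before first header at line ",
         first, " of ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 trimws(sub("^\\S+\\s+", "", headers)), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    empty <- ids[!nzchar(seqs)]
    stop("FASTA entries with empty sequence: ", paste(empty, collapse = ", "))
  }
  sequence_records(ids, seqs, desc)
}

#' Write sequence records to a FASTA file
#'
#' @param records Record `data.frame` from [sequence_records()]/[read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc),
                       paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
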