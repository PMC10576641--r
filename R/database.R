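# Embedding database: an id-keyed collection of per-residue embedding
# matrices (all sharing one embedding dimension) with optional sequence
# records and free-form metadata. On disk it is a single binary archive of
# named float arrays plus a tab-separated index (id, length, description,
# dim, offset [, sequence]); metadata is kept in commented key=value lines at
# the top of the index.

DB_MAGIC <- "EMBALIGNDB1"

#' Construct an in-memory embedding database
#'
#' Entries are stored sorted by id (radix order, locale-independent) so that
#' iteration order is deterministic.
#'
#' @param embeddings Named list of embedding matrices (unique names, equal
#'   column counts).
#' @param records Optional record `data.frame` covering every embedding id;
#'   row counts must match sequence lengths.
#' @param metadata Named list of scalar metadata values (e.g. backend,
#'   prefilter window/stride used at build time).
#' @return An object of class `embedding_db`.
#' @export
embedding_db <- function(embeddings, records = NULL, metadata = list()) {
  stopifnot(is.list(embeddings))
  ids <- names(embeddings)
  if (length(embeddings)) {
    if (is.null(ids) || any(!nzchar(ids)))
      stop("embeddings must be a named list with non-empty names")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop("duplicate database id(s): ", paste(dup, collapse = ", "))
    ord <- order(ids, method = "radix")
    embeddings <- embeddings[ord]
    ids <- ids[ord]
    embeddings <- lapply(seq_along(embeddings), function(i)
      as_embedding(embeddings[[i]], ids[i]))
    names(embeddings) <- ids
    dims <- vapply(embeddings, ncol, integer(1))
    if (length(unique(dims)) != 1L)
      stop("all embeddings in a database must share one dimension; found: ",
           paste(sort(unique(dims)), collapse = ", "))
    dim <- dims[[1]]
  } else {
    dim <- NA_integer_
  }
  if (!is.null(records)) {
    stopifnot(is.data.frame(records))
    missing <- setdiff(ids, records$id)
    if (length(missing))
      stop("records missing for id(s): ", paste(missing, collapse = ", "))
    records <- records[match(ids, records$id), , drop = FALSE]
    rownames(records) <- NULL
    nres <- vapply(embeddings, nrow, integer(1))
    bad <- which(nchar(records$sequence) != nres)
    if (length(bad))
      stop("sequence length does not match embedding rows for id(s): ",
           paste(ids[bad], collapse = ", "))
  }
  structure(list(ids = ids, embeddings = embeddings, records = records,
                 dim = dim, metadata = metadata),
            class = "embedding_db")
}

#' @export
length.embedding_db <- function(x) length(x$ids)

#' @export
print.embedding_db <- function(x, ...) {
  cat(sprintf("<embedding_db> %d entr%s, dimension %s\n",
              length(x), if (length(x) == 1L) "y" else "ies",
              ifelse(is.na(x$dim), "?", x$dim)))
  if (length(x))
    cat("  ids: ", paste(head(x$ids, 5L), collapse = ", "),
        if (length(x) > 5L) ", ..." else "", "\n", sep = "")
  if (length(x$metadata))
    cat("  metadata: ",
        paste(names(x$metadata), unlist(x$metadata), sep = "=",
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Retrieve one database entry
#'
#' @param db An `embedding_db`.
#' @param id Entry identifier.
#' @return List with `embedding` and (possibly `NULL`) `record`.
#' @export
db_entry <- function(db, id) {
  stopifnot(inherits(db, "embedding_db"))
  i <- match(id, db$ids)
  if (is.na(i)) stop("no database entry with id '", id, "'")
  rec <- if (!is.null(db$records)) db$records[i, , drop = FALSE] else NULL
  list(embedding = db$embeddings[[i]], record = rec)
}

#' Save an embedding database to an indexed binary archive
#'
#' Writes `path` (magic header + concatenated row-major float arrays) and
#' `<path>.tsv` (tab-separated index with metadata in commented header
#' lines). Values are stored as 32-bit floats by default, matching the
#' half/single precision of language-model output; use
#' `precision = "double"` for a bit-exact round trip of 64-bit input.
#'
#' @param db An `embedding_db`.
#' @param path Output path for the binary archive.
#' @param precision `"single"` (default) or `"double"`.
#' @return `path`, invisibly.
#' @export
save_embedding_db <- function(db, path, precision = c("single", "double")) {
  stopifnot(inherits(db, "embedding_db"))
  precision <- match.arg(precision)
  bytes <- if (precision == "single") 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(DB_MAGIC, con, eos = NULL)
  offset <- 0
  offsets <- integer(0)
  for (E in db$embeddings) {
    writeBin(as.numeric(t(E)), con, size = bytes, endian = "little")
    offsets <- c(offsets, offset)
    offset <- offset + length(E)
  }
  n <- vapply(db$embeddings, nrow, integer(1))
  idx <- data.frame(
    id = db$ids,
    length = if (length(db$ids)) n else integer(0),
    description = if (!is.null(db$records)) db$records$description
                  else rep("", length(db$ids)),
    dim = rep(db$dim, length(db$ids)),
    offset = if (length(db$ids)) offsets else integer(0),
    sequence = if (!is.null(db$records)) db$records$sequence
               else rep("", length(db$ids)),
    stringsAsFactors = FALSE)
  if (any(grepl("[\t\n]", idx$description)))
    stop("descriptions must not contain tabs or newlines")
  icon <- file(index_path(path), "wt")
  on.exit(close(icon), add = TRUE)
  writeLines(c(sprintf("# format=%s", DB_MAGIC),
               sprintf("# precision=%s", precision),
               sprintf("# embedding_dim=%s", db$dim),
               sprintf("# meta_%s=%s", names(db$metadata),
                       vapply(db$metadata, as.character, character(1)))),
             icon)
  suppressWarnings(write.table(idx, icon, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

index_path <- function(path) paste0(path, ".tsv")

#' Load an embedding database from an archive
#'
#' Validates all container invariants on load: matching magic header, a
#' single shared embedding dimension, finite values, and sequence lengths
#' consistent with embedding row counts.
#'
#' @param path Path written by [save_embedding_db()].
#' @return An `embedding_db`.
#' @export
load_embedding_db <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  ipath <- index_path(path)
  if (!file.exists(ipath)) stop("corrupted archive: missing index ", ipath)
  lines <- readLines(ipath, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  if (is.na(vals["format"]) || vals[["format"]] != DB_MAGIC)
    stop("corrupted index: unrecognised format line in ", ipath)
  precision <- vals[["precision"]]
  bytes <- if (identical(precision, "double")) 8L else 4L
  meta_keys <- grep("^meta_", keys, value = TRUE)
  metadata <- as.list(vals[meta_keys])
  names(metadata) <- sub("^meta_", "", meta_keys)

  body <- lines[!grepl("^#", lines)]
  idx <- read.table(text = body, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "")
  for (col in intersect(c("id", "description", "sequence"), names(idx)))
    idx[[col]] <- as.character(idx[[col]])
  idx$description[is.na(idx$description)] <- ""
  idx$sequence[is.na(idx$sequence)] <- ""
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readChar(con, nchar(DB_MAGIC), useBytes = TRUE)
  if (!identical(magic, DB_MAGIC))
    stop("corrupted archive: bad magic header in ", path)
  if (nrow(idx) == 0L)
    return(embedding_db(list(), metadata = metadata))
  if (length(unique(idx$dim)) != 1L)
    stop("archive violates the shared-dimension invariant; dims found: ",
         paste(sort(unique(idx$dim)), collapse = ", "))
  m <- idx$dim[1]
  total <- sum(idx$length) * m
  vals_all <- readBin(con, "double", n = total, size = bytes,
                      endian = "little")
  if (length(vals_all) != total)
    stop("corrupted archive: expected ", total, " values, got ",
         length(vals_all))
  embeddings <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    off <- idx$offset[i]
    n <- idx$length[i]
    embeddings[[i]] <- matrix(vals_all[(off + 1):(off + n * m)],
                              nrow = n, ncol = m, byrow = TRUE)
  }
  names(embeddings) <- idx$id
  records <- NULL
  if ("sequence" %in% names(idx) && any(nzchar(idx$sequence))) {
    if (!all(nzchar(idx$sequence)))
      stop("corrupted index: sequences present for only some entries")
    records <- sequence_records(idx$id, idx$sequence, idx$description)
  }
  embedding_db(embeddings, records = records, metadata = metadata)
}
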