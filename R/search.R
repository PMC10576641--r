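# Search orchestration: prefilter -> per-pair substitution / scoring /
# traceback / extraction (local) or zero-gap global alignment -> ranking and
# tab-separated reporting. Only one substitution/scoring matrix pair is in
# memory at a time.

#' Search and alignment parameters
#'
#' @param mode `"local"` (multi-start traceback + moving-average extraction)
#'   or `"global"` (zero-gap Needleman-Wunsch).
#' @param window Moving-average window for local extraction, in cells
#'   (default 15).
#' @param sigma_factor Multiple of the substitution-matrix standard deviation
#'   used as the extraction threshold (default 2).
#' @param prefilter Whether to run the windowed-cosine prefilter before
#'   aligning database entries (default `TRUE`).
#' @param prefilter_window Prefilter window length in residues (default 30).
#' @param prefilter_stride Prefilter window stride (default 1, dense).
#' @param prefilter_percentile Per-query percentile cutoff for candidate
#'   selection (default 90).
#' @param min_score Reporting floor on the best alignment score of a hit
#'   (default 0; the sigma threshold is the real sensitivity control).
#' @return A validated list of class `search_params`.
#' @export
search_params <- function(mode = c("local", "global"), window = 15L,
                          sigma_factor = 2, prefilter = TRUE,
                          prefilter_window = 30L, prefilter_stride = 1L,
                          prefilter_percentile = 90, min_score = 0) {
  mode <- match.arg(mode)
  window <- as.integer(window)
  prefilter_window <- as.integer(prefilter_window)
  prefilter_stride <- as.integer(prefilter_stride)
  if (window < 1L || prefilter_window < 1L || prefilter_stride < 1L)
    stop("windows and strides must be >= 1")
  if (prefilter_percentile < 0 || prefilter_percentile > 100)
    stop("'prefilter_percentile' must be in [0, 100]")
  structure(list(mode = mode, window = window, sigma_factor = sigma_factor,
                 prefilter = isTRUE(prefilter),
                 prefilter_window = prefilter_window,
                 prefilter_stride = prefilter_stride,
                 prefilter_percentile = prefilter_percentile,
                 min_score = min_score),
            class = "search_params")
}

#' Align one query/target pair
#'
#' Runs the full per-pair pipeline on raw (unnormalized) embeddings: row
#' normalization, substitution matrix, then either multi-start traceback with
#' moving-average extraction (local) or the zero-gap global alignment.
#'
#' @param query,target Embedding matrices.
#' @param params A [search_params()] object.
#' @param query_seq,target_seq Optional sequences for gapped rendering.
#' @param query_id,target_id Identifiers.
#' @return An `embalign_hit`: list with `query_id`, `target_id`, `mode`,
#'   `alignments` (sorted by descending score), `best_score` and
#'   `prefilter_score` (`NA` unless set by [search_db()]).
#' @export
align_pair <- function(query, target, params = search_params(),
                       query_seq = NULL, target_seq = NULL,
                       query_id = attr(query, "id") %||% "query",
                       target_id = attr(target, "id") %||% "target") {
  stopifnot(inherits(params, "search_params"))
  S <- substitution_matrix(normalize_rows(query), normalize_rows(target),
                           query_id = query_id, target_id = target_id)
  if (params$mode == "global") {
    alns <- list(global_align(S, query_seq, target_seq))
  } else {
    H <- scoring_matrix(S)
    paths <- traceback_paths(H, S)
    alns <- list()
    for (p in paths)
      alns <- c(alns, extract_local_alignments(p, attr(S, "sigma"),
                                               params$window,
                                               params$sigma_factor))
    alns <- dedup_alignments(alns)
    if (!is.null(query_seq) && !is.null(target_seq))
      alns <- lapply(alns, function(a) {
        g <- render_alignment(a$cells, query_seq, target_seq)
        a$gapped_query <- g[1]
        a$gapped_target <- g[2]
        a
      })
    if (length(alns) > 1L)
      alns <- alns[order(-vapply(alns, `[[`, numeric(1), "score"))]
  }
  structure(list(query_id = query_id, target_id = target_id,
                 mode = params$mode, alignments = alns,
                 best_score = if (length(alns))
                   max(vapply(alns, `[[`, numeric(1), "score")) else -Inf,
                 prefilter_score = NA_real_),
            class = "embalign_hit")
}

#' Search a query against an embedding database
#'
#' With the prefilter enabled, windowed-cosine scores are computed against
#' every database entry and only candidates passing the per-query percentile
#' cutoff are aligned; hits from the prefiltered run are always a subset of
#' the unfiltered run with identical alignments. Hits are ranked by
#' descending best alignment score, ties broken by target id.
#'
#' @param query Query embedding matrix (raw, will be normalized internally).
#' @param db An [embedding_db()].
#' @param params A [search_params()] object.
#' @param query_seq Optional query sequence for gapped rendering.
#' @param query_id Query identifier.
#' @return An `embalign_hits` object (list of hits plus the parameters used).
#' @export
search_db <- function(query, db, params = search_params(), query_seq = NULL,
                      query_id = attr(query, "id") %||% "query") {
  stopifnot(inherits(db, "embedding_db"), inherits(params, "search_params"))
  query <- as_embedding(query, query_id)
  hits <- list()
  if (length(db) == 0L)
    return(structure(list(hits = hits, query_id = query_id, params = params),
                     class = "embalign_hits"))
  if (ncol(query) != db$dim)
    stop("embedding dimension mismatch: query has ", ncol(query),
         ", database has ", db$dim)
  pf_scores <- rep(NA_real_, length(db))
  names(pf_scores) <- db$ids
  candidates <- db$ids
  if (params$prefilter) {
    qn <- normalize_rows(query)
    qc <- chunk_embedding(qn, params$prefilter_window, params$prefilter_stride)
    for (id in db$ids) {
      tc <- chunk_embedding(normalize_rows(db$embeddings[[id]]),
                            params$prefilter_window, params$prefilter_stride)
      pf_scores[id] <- prefilter_score(qc, tc)
    }
    candidates <- select_candidates(
      data.frame(target_id = db$ids, score = unname(pf_scores),
                 stringsAsFactors = FALSE),
      params$prefilter_percentile)
  }
  for (id in candidates) {
    tseq <- NULL
    if (!is.null(db$records))
      tseq <- db$records$sequence[match(id, db$records$id)]
    hit <- align_pair(query, db$embeddings[[id]], params,
                      query_seq = query_seq, target_seq = tseq,
                      query_id = query_id, target_id = id)
    hit$prefilter_score <- pf_scores[[id]]
    if (length(hit$alignments) && hit$best_score >= params$min_score)
      hits[[length(hits) + 1L]] <- hit
  }
  if (length(hits)) {
    ord <- order(-vapply(hits, `[[`, numeric(1), "best_score"),
                 vapply(hits, `[[`, character(1), "target_id"),
                 method = "radix")
    hits <- hits[ord]
  }
  structure(list(hits = hits, query_id = query_id, params = params),
            class = "embalign_hits")
}

#' @export
print.embalign_hits <- function(x, ...) {
  cat(sprintf("<embalign_hits> query '%s': %d hit(s), mode %s\n",
              x$query_id, length(x$hits), x$params$mode))
  for (h in head(x$hits, 10L))
    cat(sprintf("  %-20s best_score %.3f  (%d alignment%s)\n", h$target_id,
                h$best_score, length(h$alignments),
                if (length(h$alignments) == 1L) "" else "s"))
  if (length(x$hits) > 10L) cat("  ...\n")
  invisible(x)
}

#' Flatten hits into the tabular report
#'
#' One row per alignment with 1-based inclusive coordinates.
#'
#' @param hits An `embalign_hits` object or a single `embalign_hit`.
#' @return A `data.frame` with columns `query_id`, `target_id`, `mode`,
#'   `score`, `prefilter_score`, `query_start`, `query_end`, `target_start`,
#'   `target_end`, `alignment_length`, `gapped_query`, `gapped_target`.
#' @export
hit_table <- function(hits) {
  if (inherits(hits, "embalign_hit")) hits <- list(hits = list(hits))
  rows <- list()
  for (h in hits$hits) {
    for (a in h$alignments) {
      len <- if (inherits(a, "global_alignment")) length(a$moves)
             else nrow(a$cells)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = h$query_id, target_id = h$target_id, mode = h$mode,
        score = a$score, prefilter_score = h$prefilter_score,
        query_start = a$query_start, query_end = a$query_end,
        target_start = a$target_start, target_end = a$target_end,
        alignment_length = len,
        gapped_query = a$gapped_query, gapped_target = a$gapped_target,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(query_id = character(0), target_id = character(0),
                      mode = character(0), score = numeric(0),
                      prefilter_score = numeric(0),
                      query_start = integer(0), query_end = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      alignment_length = integer(0),
                      gapped_query = character(0),
                      gapped_target = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write a hit report to a tab-separated file
#'
#' The file starts with commented header lines recording the tool version and
#' the full parameter set, so a report is reproducible from its own header.
#' Identical inputs produce byte-identical files.
#'
#' @param hits `embalign_hits` (or a prebuilt [hit_table()] `data.frame`).
#' @param path Output path.
#' @param params Parameters to record (taken from `hits` when omitted).
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, params = NULL) {
  if (inherits(hits, "embalign_hits")) {
    if (is.null(params)) params <- hits$params
    tab <- hit_table(hits)
  } else tab <- hits
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# embalign %s",
                     as.character(utils::packageVersion("embalign"))), con)
  if (!is.null(params))
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, as.character, character(1))), con)
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Read a hit report written by [write_hit_table()]
#'
#' @param path Report path.
#' @return The report `data.frame` (comment headers skipped).
#' @export
read_hit_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, quote = "",
             colClasses = c(query_id = "character", target_id = "character",
                            gapped_query = "character",
                            gapped_target = "character"))
}
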