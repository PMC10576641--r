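# Database prefilter: per-residue embeddings are treated as 2D images and one
# is convolved with the other. Each window of `window` consecutive residues
# (times the full embedding dimension) is flattened and unit-normalized; the
# prefilter score of a pair is the maximum cosine similarity over all window
# pairs, and candidates above a per-query percentile cutoff proceed to full
# alignment.

#' Slice an embedding into flattened, normalized windows
#'
#' Windows of `window` consecutive residues are slid along the sequence at
#' the given stride; each `window x m` slice is flattened row-major
#' (residue-major) and normalized to unit Euclidean norm. Sequences shorter
#' than the window yield a single window covering the whole sequence.
#'
#' @param E Embedding matrix.
#' @param window Window length in residues (default 30).
#' @param stride Step between window start positions (default 1, a dense
#'   convolution).
#' @return A `chunk_matrix`: list with `vectors` (one row per window),
#'   `window`, `stride` and `origins` (1-based window start positions).
#' @export
chunk_embedding <- function(E, window = 30L, stride = 1L) {
  E <- as_embedding(E, attr(E, "id"))
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (is.na(window) || window < 1L) stop("'window' must be a positive integer")
  if (is.na(stride) || stride < 1L) stop("'stride' must be a positive integer")
  n <- nrow(E)
  m <- ncol(E)
  if (n < window) {
    starts <- 1L
    window_eff <- n
  } else {
    starts <- seq.int(1L, n - window + 1L, by = stride)
    window_eff <- window
  }
  vectors <- matrix(0, nrow = length(starts), ncol = window_eff * m)
  for (s in seq_along(starts)) {
    v <- as.numeric(t(E[starts[s]:(starts[s] + window_eff - 1L), ,
                        drop = FALSE]))
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12)
      stop("zero-norm flattened window at position ", starts[s],
           "; embedding is degenerate")
    vectors[s, ] <- v / nv
  }
  structure(list(vectors = vectors, window = window_eff, stride = stride,
                 origins = starts),
            class = "chunk_matrix")
}

#' Prefilter score of a sequence pair
#'
#' Maximum element of the all-pairs dot-product matrix between the two chunk
#' matrices, i.e. the best cosine similarity between any query window and any
#' target window.
#'
#' @param query_chunks,target_chunks `chunk_matrix` objects built with the
#'   same embedding dimension and window settings.
#' @return A scalar in \[-1, 1\].
#' @export
prefilter_score <- function(query_chunks, target_chunks) {
  stopifnot(inherits(query_chunks, "chunk_matrix"),
            inherits(target_chunks, "chunk_matrix"))
  if (ncol(query_chunks$vectors) != ncol(target_chunks$vectors))
    stop("chunk matrices have incompatible flattened dimensions (",
         ncol(query_chunks$vectors), " vs ", ncol(target_chunks$vectors),
         "); build both with the same window and embedding dimension")
  s <- max(tcrossprod(query_chunks$vectors, target_chunks$vectors))
  min(1, max(-1, s))
}

#' Select database candidates above a percentile cutoff
#'
#' The cutoff is taken from the score distribution of the current query over
#' the whole database: with `n` scores sorted ascending, the cutoff is the
#' score at rank `min(n, floor(percentile/100 * n) + 1)` and every id scoring
#' at or above it is kept (ties included, favouring sensitivity). Percentile
#' 0 keeps everything; percentile 100 keeps the argmax (and ties).
#'
#' @param scores A `data.frame` with columns `target_id` and `score`.
#' @param percentile Cutoff percentile in \[0, 100\] (default 90).
#' @return Character vector of selected target ids.
#' @export
select_candidates <- function(scores, percentile = 90) {
  stopifnot(is.data.frame(scores),
            all(c("target_id", "score") %in% names(scores)))
  if (!nrow(scores)) stop("empty prefilter score list")
  if (percentile < 0 || percentile > 100)
    stop("'percentile' must be in [0, 100]")
  n <- nrow(scores)
  rank <- min(n, floor(percentile / 100 * n) + 1L)
  cutoff <- sort(scores$score, method = "radix")[rank]
  scores$target_id[scores$score >= cutoff]
}
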