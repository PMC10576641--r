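# Core alignment machinery: gap-free cumulative scoring, multi-start
# traceback, moving-average local-alignment extraction, and zero-gap global
# (Needleman-Wunsch) alignment. All residue coordinates are 1-based and
# inclusive.

#' Cumulative scoring matrix (gap-free local recurrence)
#'
#' Builds the `(n+1) x (k+1)` dynamic-programming matrix with zero first row
#' and column and `H[i, j] = max(H[i-1, j-1] + s[i-1, j-1], H[i-1, j],
#' H[i, j-1])`. Gap moves carry no penalty; dissimilar regions are penalised
#' through the negative cosine similarities themselves.
#'
#' @param S Substitution matrix (any finite numeric matrix).
#' @return Numeric `(n+1) x (k+1)` matrix.
#' @export
scoring_matrix <- function(S) {
  S <- unclass(S)
  stopifnot(is.matrix(S), is.numeric(S))
  if (!all(is.finite(S))) stop("substitution matrix contains non-finite values")
  .fill_scoring_cpp(S)
}

#' Candidate alignment paths by multi-start traceback
#'
#' Starts one walk from every cell of the bottom row and rightmost column of
#' the scoring matrix (the shared corner once, `n + k - 1` starts). Each walk
#' moves to the argmax predecessor (ties: diagonal, then vertical, then
#' horizontal) and stops at a non-positive cumulative score or a matrix edge.
#' Empty walks are dropped and exact duplicate paths removed.
#'
#' @param H Scoring matrix from [scoring_matrix()].
#' @param S The substitution matrix `H` was built from (per-cell scores).
#' @return List of paths; each path is a list with `cells` (L x 2 matrix of
#'   1-based query/target indices, N- to C-terminal) and `scores` (the
#'   substitution values at those cells).
#' @export
traceback_paths <- function(H, S) {
  S <- unclass(S)
  stopifnot(is.matrix(H), is.matrix(S),
            nrow(H) == nrow(S) + 1L, ncol(H) == ncol(S) + 1L)
  raw <- .traceback_cpp(H)
  if (!length(raw)) return(list())
  keys <- vapply(raw, function(cells)
    paste(cells[, 1], cells[, 2], sep = ",", collapse = ";"), character(1))
  raw <- raw[!duplicated(keys)]
  lapply(raw, function(cells) {
    list(cells = cells, scores = S[cells])
  })
}

new_local_alignment <- function(cells, scores) {
  structure(list(cells = cells, scores = scores, score = mean(scores),
                 score_total = sum(scores),
                 query_start = cells[1, 1], query_end = cells[nrow(cells), 1],
                 target_start = cells[1, 2], target_end = cells[nrow(cells), 2],
                 gapped_query = NA_character_, gapped_target = NA_character_),
            class = "local_alignment")
}

# Drop leading/trailing cells scoring below the threshold; returns NULL when
# nothing survives.
trim_subpath <- function(idx, scores, threshold) {
  above <- which(scores[idx] >= threshold)
  if (!length(above)) return(NULL)
  idx[above[1]:above[length(above)]]
}

#' Extract local alignments from one traceback path
#'
#' A moving average of the per-cell substitution scores is computed for every
#' window that fits on the path. Maximal runs of consecutive qualifying
#' windows (mean at or above `sigma_factor * sigma`) are captured as the
#' cells at the window centers of the run; a run reaching the first or last
#' window position is extended to the corresponding path end, so a uniformly
#' high-scoring path is captured in full. Finally each captured subpath is
#' trimmed of leading and trailing cells that individually score below the
#' threshold, which localises alignment boundaries to the similar region
#' itself. Paths shorter than the window yield a single whole-path candidate,
#' kept only if its (trimmed) mean reaches the threshold. The alignment score
#' is the mean per-cell substitution value of the captured subpath.
#'
#' @param path A path from [traceback_paths()].
#' @param sigma Standard deviation of the substitution matrix (attribute
#'   `sigma` of [substitution_matrix()]).
#' @param window Moving-average window length in cells (default 15).
#' @param sigma_factor Threshold multiplier (default 2); larger values make
#'   extraction stricter, smaller ones more permissive.
#' @return List of `local_alignment` objects (possibly empty).
#' @export
extract_local_alignments <- function(path, sigma, window = 15L,
                                     sigma_factor = 2) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("'window' must be a positive integer")
  if (sigma < 0) stop("'sigma' must be non-negative")
  cells <- path$cells
  scores <- path$scores
  L <- length(scores)
  threshold <- sigma_factor * sigma
  emit <- function(idx) {
    idx <- trim_subpath(idx, scores, threshold)
    if (is.null(idx) || mean(scores[idx]) < threshold) return(NULL)
    new_local_alignment(cells[idx, , drop = FALSE], scores[idx])
  }
  if (L < window) {
    a <- if (mean(scores) >= threshold) emit(seq_len(L)) else NULL
    return(if (is.null(a)) list() else list(a))
  }
  cs <- cumsum(c(0, scores))
  nwin <- L - window + 1L
  means <- (cs[(window + 1):(window + nwin)] - cs[1:nwin]) / window
  qualify <- means >= threshold
  if (!any(qualify)) return(list())
  half <- (window - 1L) %/% 2L
  r <- rle(qualify)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    from <- if (starts[k] == 1L) 1L else starts[k] + half
    to <- if (ends[k] == nwin) L else ends[k] + half
    a <- emit(from:to)
    if (!is.null(a)) out[[length(out) + 1L]] <- a
  }
  out
}

# Collapse the per-start redundancy: drop alignments with identical cell
# ranges, then among alignments sharing more than half of their cells (of the
# shorter one) keep only the highest-scoring. Candidates compete on their
# cumulative (summed) score, the quantity the scoring matrix itself
# accumulates, so a long alignment is never displaced by a short fragment of
# itself with a marginally higher mean; the reported score stays the
# length-comparable mean.
dedup_alignments <- function(alns) {
  if (length(alns) <= 1L) return(alns)
  keys <- lapply(alns, function(a) paste(a$cells[, 1], a$cells[, 2], sep = ","))
  full <- vapply(keys, paste, character(1), collapse = ";")
  keep <- !duplicated(full)
  alns <- alns[keep]
  keys <- keys[keep]
  ord <- order(-vapply(alns, `[[`, numeric(1), "score_total"),
               -lengths(keys),
               vapply(alns, `[[`, numeric(1), "query_start"),
               vapply(alns, `[[`, numeric(1), "target_start"))
  alns <- alns[ord]
  keys <- keys[ord]
  kept <- list()
  kept_keys <- list()
  for (i in seq_along(alns)) {
    overlapping <- FALSE
    for (j in seq_along(kept_keys)) {
      shared <- length(intersect(keys[[i]], kept_keys[[j]]))
      if (shared > 0.5 * min(length(keys[[i]]), length(kept_keys[[j]]))) {
        overlapping <- TRUE
        break
      }
    }
    if (!overlapping) {
      kept[[length(kept) + 1L]] <- alns[[i]]
      kept_keys[[length(kept_keys) + 1L]] <- keys[[i]]
    }
  }
  kept
}

#' Global (zero-gap Needleman-Wunsch) alignment
#'
#' The classical global alignment with the similarity matrix replaced by the
#' embedding substitution matrix and the gap penalty set to zero. The
#' traceback runs from the bottom-right corner to the origin (ties: diagonal,
#' then vertical, then horizontal), covering all residues of both sequences
#' through matches or gaps. The score is the mean substitution value over the
#' matched residue pairs of the path.
#'
#' @param S Substitution matrix.
#' @param query_seq,target_seq Optional sequences for gapped-string rendering.
#' @return A `global_alignment`: `cells` (matched residue pairs), `moves`
#'   (full step sequence: `"diag"`, `"vert"`, `"horiz"`), `score`, coordinate
#'   bounds, and gapped strings when sequences were supplied.
#' @export
global_align <- function(S, query_seq = NULL, target_seq = NULL) {
  Sm <- unclass(S)
  stopifnot(is.matrix(Sm), is.numeric(Sm))
  if (!all(is.finite(Sm))) stop("substitution matrix contains non-finite values")
  n <- nrow(Sm)
  k <- ncol(Sm)
  if (n < 1L || k < 1L) stop("substitution matrix must be non-empty")
  H <- .fill_scoring_cpp(Sm)
  # Traceback by exact recomputation of the fill: the current cell equals at
  # least one of (diag + s, vert, horiz) bitwise, since the fill evaluated
  # those same expressions. Ties: diagonal, then vertical, then horizontal.
  i <- n
  j <- k
  moves <- character(0)
  while (i > 0L && j > 0L) {
    cur <- H[i + 1L, j + 1L]
    if (H[i, j] + Sm[i, j] == cur) {
      moves <- c("diag", moves)
      i <- i - 1L
      j <- j - 1L
    } else if (H[i, j + 1L] == cur) {
      moves <- c("vert", moves)
      i <- i - 1L
    } else {
      moves <- c("horiz", moves)
      j <- j - 1L
    }
  }
  if (i > 0L) moves <- c(rep("vert", i), moves)
  if (j > 0L) moves <- c(rep("horiz", j), moves)
  qi <- 0L
  ti <- 0L
  cells <- matrix(0L, nrow = sum(moves == "diag"), ncol = 2)
  mc <- 0L
  for (mv in moves) {
    if (mv == "diag") {
      qi <- qi + 1L
      ti <- ti + 1L
      mc <- mc + 1L
      cells[mc, ] <- c(qi, ti)
    } else if (mv == "vert") qi <- qi + 1L
    else ti <- ti + 1L
  }
  score <- mean(Sm[cells])
  gq <- gt <- NA_character_
  if (!is.null(query_seq) && !is.null(target_seq)) {
    g <- render_moves(moves, query_seq, target_seq)
    gq <- g[1]
    gt <- g[2]
  }
  structure(list(cells = cells, moves = moves, scores = Sm[cells],
                 score = score,
                 query_start = 1L, query_end = n,
                 target_start = 1L, target_end = k,
                 gapped_query = gq, gapped_target = gt),
            class = "global_alignment")
}

render_moves <- function(moves, query_seq, target_seq) {
  qc <- strsplit(query_seq, "")[[1]]
  tc <- strsplit(target_seq, "")[[1]]
  qi <- 0L
  ti <- 0L
  gq <- gt <- character(length(moves))
  for (s in seq_along(moves)) {
    if (moves[s] == "diag") {
      qi <- qi + 1L
      ti <- ti + 1L
      gq[s] <- qc[qi]
      gt[s] <- tc[ti]
    } else if (moves[s] == "vert") {
      qi <- qi + 1L
      gq[s] <- qc[qi]
      gt[s] <- "-"
    } else {
      ti <- ti + 1L
      gq[s] <- "-"
      gt[s] <- tc[ti]
    }
  }
  c(paste(gq, collapse = ""), paste(gt, collapse = ""))
}

#' Render an alignment path as gapped strings
#'
#' The first cell emits a residue pair; each following step emits
#' residue/residue for a diagonal step, residue/`-` for a vertical step and
#' `-`/residue for a horizontal step.
#'
#' @param cells L x 2 matrix of 1-based (query, target) indices with strictly
#'   monotone unit steps.
#' @param query_seq,target_seq Sequences (character scalars).
#' @return Character vector `c(gapped_query, gapped_target)`.
#' @export
render_alignment <- function(cells, query_seq, target_seq) {
  stopifnot(is.matrix(cells), ncol(cells) == 2, nrow(cells) >= 1)
  if (max(cells[, 1]) > nchar(query_seq) || max(cells[, 2]) > nchar(target_seq)
      || min(cells) < 1)
    stop("alignment cells fall outside the sequence bounds")
  if (nrow(cells) > 1L) {
    d <- diff(cells)
    ok <- (d[, 1] == 1 & d[, 2] == 1) | (d[, 1] == 1 & d[, 2] == 0) |
      (d[, 1] == 0 & d[, 2] == 1)
    if (!all(ok)) stop("alignment cells are not strictly monotone unit steps")
  }
  moves <- c("diag", if (nrow(cells) > 1L)
    ifelse(diff(cells[, 1]) == 1 & diff(cells[, 2]) == 1, "diag",
           ifelse(diff(cells[, 1]) == 1, "vert", "horiz")))
  qc <- strsplit(query_seq, "")[[1]]
  tc <- strsplit(target_seq, "")[[1]]
  gq <- ifelse(moves == "horiz", "-", qc[cells[, 1]])
  gt <- ifelse(moves == "vert", "-", tc[cells[, 2]])
  c(paste(gq, collapse = ""), paste(gt, collapse = ""))
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> query %d-%d, target %d-%d, %d cells, score %.3f\n",
              x$query_start, x$query_end, x$target_start, x$target_end,
              nrow(x$cells), x$score))
  if (!is.na(x$gapped_query))
    cat(" ", x$gapped_query, "\n ", x$gapped_target, "\n")
  invisible(x)
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("<global_alignment> %d columns, %d matched pairs, score %.3f\n",
              length(x$moves), nrow(x$cells), x$score))
  if (!is.na(x$gapped_query))
    cat(" ", x$gapped_query, "\n ", x$gapped_target, "\n")
  invisible(x)
}
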