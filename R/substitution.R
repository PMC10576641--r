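# Context-dependent substitution matrix: pairwise cosine similarities of
# row-normalized per-residue embeddings. Element (i, j) is the similarity of
# query residue i and target residue j; the sigma attribute (population
# standard deviation of all elements) drives the local-alignment threshold.

#' Embedding-based substitution matrix
#'
#' Computes the dense matrix of cosine similarities between every residue of
#' the query and every residue of the target. Both inputs must already be
#' row-normalized (see [normalize_rows()]); the product is clamped into
#' \[-1, 1\] to absorb floating error before any thresholding.
#'
#' @param query,target Row-normalized embedding matrices with equal column
#'   counts.
#' @param query_id,target_id Identifiers stored on the result.
#' @return An `n_query x n_target` matrix of class `substitution_matrix` with
#'   attributes `sigma` (population standard deviation of all elements),
#'   `query_id`, `target_id`.
#' @export
substitution_matrix <- function(query, target,
                                query_id = attr(query, "id") %||% "query",
                                target_id = attr(target, "id") %||% "target") {
  query <- as_embedding(query)
  target <- as_embedding(target)
  if (ncol(query) != ncol(target))
    stop("embedding dimension mismatch: query has ", ncol(query),
         ", target has ", ncol(target))
  check_unit_rows(query, "query")
  check_unit_rows(target, "target")
  S <- tcrossprod(query, target)
  S[S > 1] <- 1
  S[S < -1] <- -1
  structure(S, sigma = pop_sd(S), query_id = as.character(query_id),
            target_id = as.character(target_id),
            class = c("substitution_matrix", class(S)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_unit_rows <- function(E, what) {
  nrm <- sqrt(rowSums(E^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop(what, " embedding rows are not unit-normalized; ",
         "call normalize_rows() first")
  invisible(TRUE)
}

pop_sd <- function(x) {
  v <- as.numeric(x)
  sqrt(mean((v - mean(v))^2))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("<substitution_matrix> %s x %s (%d x %d), sigma = %.4f\n",
              attr(x, "query_id"), attr(x, "target_id"),
              nrow(x), ncol(x), attr(x, "sigma")))
  invisible(x)
}

#' Dump a substitution matrix as a tab-separated grid
#'
#' Debug/visualisation output with query residues as rows.
#'
#' @param S A `substitution_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(S, path) {
  stopifnot(inherits(S, "substitution_matrix"))
  write.table(format(unclass(S), digits = 6, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
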