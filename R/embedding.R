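# Per-residue embedding matrices: one n x m numeric matrix per sequence,
# rows indexed by residue (N- to C-terminus), columns by embedding dimension.

#' Validate a per-residue embedding matrix
#'
#' @param values Numeric matrix, one row per residue.
#' @param id Optional sequence identifier attached as attribute `id`.
#' @return The validated matrix with attribute `id`.
#' @export
as_embedding <- function(values, id = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("an embedding must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("an embedding must have at least one row and one column")
  if (!all(is.finite(values)))
    stop("embedding contains non-finite values")
  if (!is.null(id)) attr(values, "id") <- as.character(id)
  values
}

#' Normalize embedding rows to unit Euclidean norm
#'
#' Each residue vector is divided by its Euclidean norm, the standardisation
#' applied before any cosine-similarity computation. Rows with norm below
#' `1e-12` indicate a degenerate embedding and raise an error naming the row.
#'
#' @param E Numeric embedding matrix (rows = residues).
#' @return Matrix of the same shape with unit-norm rows.
#' @export
#' @examples
#' normalize_rows(matrix(c(3, 4), 1, 2)) # -> 0.6 0.8
normalize_rows <- function(E) {
  E <- as_embedding(E, attr(E, "id"))
  nrm <- sqrt(rowSums(E^2))
  bad <- which(nrm < 1e-12)
  if (length(bad))
    stop("near-zero row norm at residue row(s) ",
         paste(head(bad, 5L), collapse = ", "),
         "; embedding is degenerate")
  out <- E / nrm
  attr(out, "id") <- attr(E, "id")
  out
}
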