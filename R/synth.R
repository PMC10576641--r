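# Deterministic synthetic-embedding generator: isotropic unit-norm random
# rows as background, plus planted homologous segments made by mixing copied
# query rows with orthogonalized noise so that the expected within-segment
# cosine equals the requested signal exactly. This is the test substrate that
# replaces a language-model download: it emulates what the alignment stages
# consume (unit-norm rows with a controllable similarity structure), not the
# anisotropy or positional smoothness of real model output.

#' Random isotropic unit-norm embedding
#'
#' Rows are independent standard Gaussian vectors normalized to unit length;
#' the result is a pure function of `(n, m, seed)`.
#'
#' @param n Number of residues (rows).
#' @param m Embedding dimension (default 64).
#' @param seed Integer seed.
#' @param scale_jitter Non-negative number; when positive, each row is
#'   multiplied by `exp(runif(-scale_jitter, scale_jitter))`, producing
#'   non-unit norms that exercise [normalize_rows()] downstream.
#' @return An `n x m` embedding matrix.
#' @export
random_embedding <- function(n, m = 64L, seed, scale_jitter = 0) {
  stopifnot(n >= 1L, m >= 1L, scale_jitter >= 0)
  with_seed(seed, {
    E <- matrix(rnorm(n * m), nrow = n, ncol = m)
    E <- E / sqrt(rowSums(E^2))
    if (scale_jitter > 0)
      E <- E * exp(runif(n, -scale_jitter, scale_jitter))
    E
  })
}

#' Random amino-acid sequence
#'
#' Uniform over the 20 standard residues; deterministic in the seed.
#'
#' @param n Sequence length.
#' @param seed Integer seed.
#' @return Character scalar.
#' @export
random_aa_sequence <- function(n, seed) {
  with_seed(seed, paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = ""))
}

#' Specification of a planted homologous segment
#'
#' @param query_region,target_region Integer `c(start, length)` pairs
#'   (1-based starts, equal lengths >= 1).
#' @param signal Expected within-segment cosine similarity, in \[0, 1\].
#' @param seed Integer seed for the generated target embedding.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(query_region, target_region, signal, seed) {
  stopifnot(length(query_region) == 2, length(target_region) == 2)
  if (query_region[2] != target_region[2])
    stop("planted regions must have equal length")
  if (query_region[2] < 1L) stop("planted region length must be >= 1")
  if (query_region[1] < 1L || target_region[1] < 1L)
    stop("planted region starts must be >= 1")
  if (signal < 0 || signal > 1) stop("'signal' must be in [0, 1]")
  structure(list(query_region = as.integer(query_region),
                 target_region = as.integer(target_region),
                 signal = signal, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Plant a homologous segment of a query into a fresh random embedding
#'
#' Generates a random target embedding of `target_len` rows and replaces its
#' target-region rows with `s * q + sqrt(1 - s^2) * z`, where `q` is the
#' corresponding (normalized) query segment row and `z` is unit noise
#' orthogonalized against `q`, so the expected pairwise cosine between
#' corresponding rows equals `s` exactly. `signal = 1` copies the rows;
#' `signal = 0` leaves the segment statistically indistinguishable from
#' background.
#'
#' @param query Query embedding matrix.
#' @param target_len Number of rows of the generated target.
#' @param spec A [plant_spec()].
#' @return Target embedding matrix with attribute `id` unset.
#' @export
plant_homology <- function(query, target_len, spec) {
  stopifnot(inherits(spec, "plant_spec"))
  query <- normalize_rows(as_embedding(query))
  len <- spec$query_region[2]
  qs <- spec$query_region[1]
  ts <- spec$target_region[1]
  if (qs + len - 1L > nrow(query))
    stop("query region [", qs, ", ", qs + len - 1L,
         "] exceeds the query length ", nrow(query))
  if (ts + len - 1L > target_len)
    stop("target region [", ts, ", ", ts + len - 1L,
         "] exceeds the target length ", target_len)
  m <- ncol(query)
  target <- random_embedding(target_len, m, spec$seed)
  s <- spec$signal
  for (k in seq_len(len) - 1L) {
    q <- query[qs + k, ]
    z <- target[ts + k, ]
    z <- z - sum(z * q) * q          # orthogonalize noise against the copy
    zn <- sqrt(sum(z^2))
    if (zn < 1e-12) z <- rep(0, m) else z <- z / zn
    v <- s * q + sqrt(1 - s^2) * z
    target[ts + k, ] <- v / sqrt(sum(v^2))
  }
  target
}

#' Synthetic benchmark database with planted homologs
#'
#' Builds a query embedding, `n_homologs` database entries that each carry a
#' planted homologous segment of the query (at entry-specific random
#' positions), and `n_decoys` pure-background decoys, together with the
#' ground-truth residue-pair set of every homolog. Random amino-acid
#' companion sequences are attached for rendering. Deterministic in `seed`.
#'
#' @param seed Integer seed.
#' @param n_decoys,n_homologs Entry counts (defaults 50 and 5).
#' @param m Embedding dimension (default 64).
#' @param query_len,entry_len Sequence lengths (default 100).
#' @param segment_len Planted segment length (default 40).
#' @param signal Within-segment cosine similarity (default 0.7).
#' @return List with `query` (embedding), `query_record`, `db`
#'   (an [embedding_db()] of decoys + homologs) and `truth` (named list per
#'   homolog id: `pairs`, `query_region`, `target_region`).
#' @export
make_benchmark_db <- function(seed, n_decoys = 50L, n_homologs = 5L,
                              m = 64L, query_len = 100L, entry_len = 100L,
                              segment_len = 40L, signal = 0.7) {
  stopifnot(n_decoys >= 0L, n_homologs >= 0L,
            segment_len <= query_len, segment_len <= entry_len)
  query <- random_embedding(query_len, m, derive_seed(seed, 1L))
  query_record <- sequence_records(
    "query", random_aa_sequence(query_len, derive_seed(seed, 2L)))
  embeddings <- list()
  ids <- character(0)
  seqs <- character(0)
  truth <- list()
  positions <- with_seed(derive_seed(seed, 3L), list(
    qs = sample.int(query_len - segment_len + 1L, max(n_homologs, 1L),
                    replace = TRUE),
    ts = sample.int(entry_len - segment_len + 1L, max(n_homologs, 1L),
                    replace = TRUE)))
  for (h in seq_len(n_homologs)) {
    id <- sprintf("homolog%02d", h)
    spec <- plant_spec(c(positions$qs[h], segment_len),
                       c(positions$ts[h], segment_len),
                       signal, derive_seed(seed, 100L + h))
    embeddings[[id]] <- plant_homology(query, entry_len, spec)
    ids <- c(ids, id)
    seqs <- c(seqs, random_aa_sequence(entry_len, derive_seed(seed, 200L + h)))
    off <- seq_len(segment_len) - 1L
    truth[[id]] <- list(
      pairs = cbind(positions$qs[h] + off, positions$ts[h] + off),
      query_region = c(positions$qs[h], segment_len),
      target_region = c(positions$ts[h], segment_len))
  }
  for (d in seq_len(n_decoys)) {
    id <- sprintf("decoy%03d", d)
    embeddings[[id]] <- random_embedding(entry_len, m,
                                         derive_seed(seed, 300L + d))
    ids <- c(ids, id)
    seqs <- c(seqs, random_aa_sequence(entry_len, derive_seed(seed, 400L + d)))
  }
  records <- if (length(ids)) sequence_records(ids, seqs) else NULL
  db <- embedding_db(embeddings, records = records,
                     metadata = list(backend = sprintf("synthetic-%d", m),
                                     seed = seed))
  list(query = as_embedding(query, "query"), query_record = query_record,
       db = db, truth = truth)
}

#' Write ground-truth residue pairs as a tab-separated list
#'
#' @param truth The `truth` element of [make_benchmark_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_pairs <- function(truth, path) {
  rows <- do.call(rbind, lapply(names(truth), function(id)
    data.frame(target_id = id, query_pos = truth[[id]]$pairs[, 1],
               target_pos = truth[[id]]$pairs[, 2],
               stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(target_id = character(0), query_pos = integer(0),
                       target_pos = integer(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
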