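# Embedding backends. A backend is a small object holding the embedding
# dimension and a function mapping (sequence, seed) to an n x m matrix. The
# synthetic backend makes the whole pipeline testable without any model
# download; an external ProtT5-class backend is isolated behind the same
# interface.

#' Construct an embedding backend
#'
#' @param fun Function `(sequence, seed)` returning an `nchar(sequence) x dim`
#'   numeric matrix.
#' @param dim Embedding dimension produced by `fun`.
#' @param name Backend name recorded in database metadata.
#' @return An object of class `embalign_backend`.
#' @export
plm_backend <- function(fun, dim, name = "custom") {
  stopifnot(is.function(fun), dim >= 1L)
  structure(list(name = name, dim = as.integer(dim), fun = fun),
            class = "embalign_backend")
}

#' Deterministic synthetic embedding backend
#'
#' Embeds a sequence of length `n` as `n` independent isotropic Gaussian
#' vectors normalized to unit length; a pure function of the sequence length,
#' the dimension and the seed. Used for testing and fixture generation.
#'
#' @param dim Embedding dimension (default 64).
#' @return An `embalign_backend`.
#' @export
synthetic_backend <- function(dim = 64L) {
  dim <- as.integer(dim)
  plm_backend(function(sequence, seed) {
    random_embedding(nchar(sequence), dim, seed)
  }, dim = dim, name = sprintf("synthetic-%d", dim))
}

#' ProtT5 protein language model backend (external, optional)
#'
#' Computes real per-residue embeddings (dimension 1024) through a local
#' Python runtime with `torch` and `transformers` installed and the
#' `Rostlab/prot_t5_xl_half_uniref50-enc` checkpoint available. The backend is
#' probed lazily; when the runtime is missing, an error instructs the user to
#' precompute embeddings and load them from an archive instead.
#'
#' @param python Python executable to use.
#' @param model Hugging Face model identifier.
#' @return An `embalign_backend` of dimension 1024.
#' @export
prott5_backend <- function(python = "python",
                           model = "Rostlab/prot_t5_xl_half_uniref50-enc") {
  fun <- function(sequence, seed) {
    ok <- suppressWarnings(system2(python, c("-c", shQuote("import torch, transformers")),
                                   stdout = FALSE, stderr = FALSE)) == 0L
    if (!ok)
      stop("the external language-model backend needs a Python runtime with ",
           "'torch' and 'transformers'; precompute embeddings there and load ",
           "them with load_embedding_db() instead")
    script <- sprintf(paste(
      "import sys, numpy as np, torch",
      "from transformers import T5Tokenizer, T5EncoderModel",
      "tok = T5Tokenizer.from_pretrained('%s', do_lower_case=False)",
      "mod = T5EncoderModel.from_pretrained('%s'); mod.eval()",
      "seq = sys.argv[1]",
      "ids = tok(' '.join(seq), return_tensors='pt')",
      "with torch.no_grad(): emb = mod(**ids).last_hidden_state[0, :len(seq)]",
      "emb.float().numpy().astype('<f8').tofile(sys.argv[2])",
      sep = "; "), model, model)
    out <- tempfile(fileext = ".f64")
    on.exit(unlink(out))
    status <- system2(python, c("-c", shQuote(script), shQuote(sequence),
                                shQuote(out)))
    if (status != 0L || !file.exists(out))
      stop("ProtT5 embedding computation failed (python exit status ", status, ")")
    vals <- readBin(out, "double", n = nchar(sequence) * 1024L, size = 8L,
                    endian = "little")
    matrix(vals, nrow = nchar(sequence), ncol = 1024L, byrow = TRUE)
  }
  plm_backend(fun, dim = 1024L, name = "prott5")
}

#' Compute per-residue embeddings for a set of sequence records
#'
#' @param records Record `data.frame` from [read_fasta()]/[sequence_records()].
#' @param backend An `embalign_backend`; see [synthetic_backend()],
#'   [prott5_backend()], [plm_backend()].
#' @param seed Base seed; record `i` uses the derived stream `seed + i - 1`,
#'   so the result is deterministic in (records, backend, seed).
#' @return Named list of embedding matrices (one per record, `n` rows each).
#' @export
compute_embeddings <- function(records, backend, seed = 1L) {
  stopifnot(is.data.frame(records), inherits(backend, "embalign_backend"))
  for (i in seq_len(nrow(records)))
    validate_sequence(records$sequence[i], records$id[i])
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    E <- backend$fun(records$sequence[i], as.integer(seed) + i - 1L)
    E <- as_embedding(E, records$id[i])
    if (nrow(E) != nchar(records$sequence[i]))
      stop("backend returned ", nrow(E), " rows for sequence '",
           records$id[i], "' of length ", nchar(records$sequence[i]))
    if (ncol(E) != backend$dim)
      stop("backend returned dimension ", ncol(E), ", expected ", backend$dim)
    out[[i]] <- E
  }
  names(out) <- records$id
  out
}
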