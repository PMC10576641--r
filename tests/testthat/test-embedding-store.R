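test_that("read_fasta parses, normalizes and validates records", {
  p <- write_tmp_fasta(c(">a", "MKV", ">b desc here", "GG"))
  rec <- read_fasta(p)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$sequence, c("MKV", "GG"))
  expect_equal(rec$description, c("", "desc here"))

  # lowercase input is uppercased
  p2 <- write_tmp_fasta(c(">a", "mkv"))
  expect_equal(read_fasta(p2)$sequence, "MKV")

  # duplicate headers are rejected naming the id
  p3 <- write_tmp_fasta(c(">a", "MK", ">a", "GG"))
  expect_error(read_fasta(p3), "a")

  # sequence data before the first header names the line
  p4 <- write_tmp_fasta(c("MKV", ">a", "GG"))
  expect_error(read_fasta(p4), "line 1")

  # empty file
  p5 <- write_tmp_fasta(character(0))
  expect_error(read_fasta(p5), "empty")
})

test_that("FASTA round trip preserves ids, sequences and descriptions", {
  rec <- sequence_records(c("s1", "s2", "s3"), c("MKVA", "GWX", "ACDEFGHIKL"),
                          c("first", "", "third"))
  p <- tempfile(fileext = ".fasta")
  write_fasta(rec, p)
  back <- read_fasta(p)
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$description, rec$description)
})

test_that("non-standard residues are rejected with the offending letters", {
  expect_error(sequence_records("x", "MKBZ"), "B")
  expect_error(sequence_records("x", "MKU"), "not supported")
  expect_silent(sequence_records("x", "MKXV")) # X passes through
})

test_that("synthetic backend obeys the shape and determinism contracts", {
  rec <- sequence_records(c("a", "b"), c("MKVAW", "GGA"))
  be <- synthetic_backend(dim = 8)
  e1 <- compute_embeddings(rec, be, seed = 5)
  e2 <- compute_embeddings(rec, be, seed = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1[["a"]]), c(5L, 8L))
  expect_equal(dim(e1[["b"]]), c(3L, 8L))
  expect_true(all(is.finite(e1[["a"]])))
  e3 <- compute_embeddings(rec, be, seed = 6)
  expect_false(identical(e1[["a"]], e3[["a"]]))
})

test_that("database round trip is lossless and validates on load", {
  rec <- sequence_records(c("a", "b", "c"), c("MKVAW", "GGA", "WYHH"))
  emb <- compute_embeddings(rec, synthetic_backend(16), seed = 1)
  db <- embedding_db(emb, records = rec,
                     metadata = list(backend = "synthetic-16",
                                     prefilter_window = 30))
  p <- tempfile(fileext = ".emb")

  # double precision: bit-identical matrices
  save_embedding_db(db, p, precision = "double")
  back <- load_embedding_db(p)
  expect_identical(back$ids, c("a", "b", "c"))
  for (id in back$ids)
    expect_identical(unname(back$embeddings[[id]]),
                     unname(db$embeddings[[id]]))
  expect_equal(back$records$sequence, rec$sequence)
  expect_equal(back$metadata$prefilter_window, "30")

  # single precision: float32 quantization, then idempotent
  save_embedding_db(db, p, precision = "single")
  once <- load_embedding_db(p)
  save_embedding_db(once, p, precision = "single")
  twice <- load_embedding_db(p)
  expect_identical(lapply(once$embeddings, unname),
                   lapply(twice$embeddings, unname))
  expect_equal(unname(once$embeddings[["a"]]), unname(db$embeddings[["a"]]),
               tolerance = 1e-6)
})

test_that("empty database saves and loads", {
  db <- embedding_db(list(), metadata = list(backend = "none"))
  p <- tempfile(fileext = ".emb")
  save_embedding_db(db, p)
  back <- load_embedding_db(p)
  expect_equal(length(back), 0L)
  expect_equal(back$metadata$backend, "none")
})

test_that("mixed embedding dimensions are rejected", {
  expect_error(embedding_db(list(a = matrix(0.1, 3, 4), b = matrix(0.1, 2, 5))),
               "dimension")
  # a corrupted archive with per-entry dims is caught on load
  rec <- sequence_records(c("a", "b"), c("MKV", "GG"))
  emb <- compute_embeddings(rec, synthetic_backend(4), seed = 1)
  db <- embedding_db(emb, records = rec)
  p <- tempfile(fileext = ".emb")
  save_embedding_db(db, p)
  idx <- readLines(paste0(p, ".tsv"))
  body <- which(!grepl("^#", idx))
  row2 <- strsplit(idx[body[3]], "\t")[[1]]
  row2[4] <- "8"
  idx[body[3]] <- paste(row2, collapse = "\t")
  writeLines(idx, paste0(p, ".tsv"))
  expect_error(load_embedding_db(p), "dimension")
})

test_that("database iteration order is deterministic (sorted by id)", {
  emb <- list(zeta = matrix(0.5, 2, 4), alpha = matrix(0.5, 3, 4),
              mid = matrix(0.5, 1, 4))
  db <- embedding_db(emb)
  expect_equal(db$ids, c("alpha", "mid", "zeta"))
})

test_that("external backend errors point to precomputed embeddings", {
  be <- prott5_backend(python = "definitely-not-a-python")
  rec <- sequence_records("a", "MKV")
  expect_error(compute_embeddings(rec, be), "precompute")
})
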