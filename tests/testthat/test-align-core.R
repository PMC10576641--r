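test_that("scoring matrix satisfies the hand-evaluated recurrence", {
  expect_equal(scoring_matrix(matrix(0, 2, 2)), matrix(0, 3, 3))
  expect_equal(scoring_matrix(matrix(1.0, 1, 1)),
               matrix(c(0, 0, 0, 1.0), 2, 2))
  S <- matrix(c(0.9, -0.5, -0.5, 0.9), 2, 2, byrow = TRUE)
  H <- scoring_matrix(S)
  expect_equal(H, bf_scoring(S), tolerance = 1e-12)
  expect_equal(H[3, 3], 1.8)
  expect_true(all(H[1, ] == 0) && all(H[, 1] == 0))
})

test_that("scoring matrix agrees with the naive fill on random inputs", {
  for (seed in 1:10) {
    n <- with_fixed_seed(derive(seed, 1), sample(1:20, 1))
    k <- with_fixed_seed(derive(seed, 2), sample(1:20, 1))
    S <- with_fixed_seed(derive(seed, 3),
                         matrix(runif(n * k, -1, 1), n, k))
    expect_lt(max(abs(scoring_matrix(S) - bf_scoring(S))), 1e-9)
  }
})

test_that("cumulative scores are non-negative and monotone under zero gaps", {
  # with single-step predecessors and free gap moves, H can never decrease
  # along a row or column, so 'no truncation at zero' keeps H >= 0
  for (seed in 1:5) {
    S <- with_fixed_seed(seed, matrix(runif(150, -1, 1), 15, 10))
    H <- scoring_matrix(S)
    expect_true(all(H >= 0))
    expect_true(all(apply(H, 1, diff) >= -1e-12))
    expect_true(all(apply(H, 2, diff) >= -1e-12))
  }
})

test_that("traceback starts once per border cell and walks the diagonal", {
  # strong diagonal: the corner start recovers the full diagonal path
  S <- matrix(-0.5, 3, 3)
  diag(S) <- 0.9
  paths <- traceback_paths(scoring_matrix(S), S)
  keys <- vapply(paths, function(p)
    paste(p$cells[, 1], p$cells[, 2], sep = ",", collapse = ";"),
    character(1))
  expect_true("1,1;2,2;3,3" %in% keys)

  # all-positive matrix: every one of the |L|+|K|-1 starts yields a distinct
  # non-empty path
  S2 <- with_fixed_seed(9, matrix(runif(24, 0.1, 1), 4, 6))
  paths2 <- traceback_paths(scoring_matrix(S2), S2)
  expect_length(paths2, 4 + 6 - 1)

  # everywhere non-positive: the stop condition fires immediately
  S3 <- matrix(-0.2, 4, 5)
  expect_length(traceback_paths(scoring_matrix(S3), S3), 0)
})

test_that("traceback paths are strictly monotone with unit steps", {
  for (seed in 1:5) {
    S <- unclass(substitution_matrix(
      random_embedding(20, 16, seed = derive(seed, 5)),
      random_embedding(25, 16, seed = derive(seed, 6))))
    paths <- traceback_paths(scoring_matrix(S), S)
    for (p in paths) {
      expect_equal(p$scores, S[p$cells])
      if (nrow(p$cells) > 1) {
        d <- diff(p$cells)
        expect_true(all(d[, 1] %in% 0:1 & d[, 2] %in% 0:1 & rowSums(d) >= 1))
      }
    }
  }
})

test_that("local extraction captures what the exhaustive window oracle finds", {
  mk_path <- function(scores)
    list(cells = cbind(seq_along(scores), seq_along(scores)), scores = scores)

  # uniform high signal spans the whole path
  a <- extract_local_alignments(mk_path(rep(0.9, 20)), sigma = 0.075,
                                window = 3, sigma_factor = 2)
  expect_length(a, 1)
  expect_equal(nrow(a[[1]]$cells), 20)
  expect_equal(a[[1]]$score, 0.9)

  # all below threshold: nothing captured
  expect_length(extract_local_alignments(mk_path(rep(0.05, 20)),
                                         sigma = 0.075, window = 3,
                                         sigma_factor = 2), 0)

  # two separated blocks against the exhaustive enumeration oracle
  scores <- c(rep(0.9, 10), rep(0, 10), rep(0.9, 10))
  got <- extract_local_alignments(mk_path(scores), sigma = 0.075, window = 5,
                                  sigma_factor = 2)
  want <- bf_extract_ranges(scores, 5, 0.15)
  expect_length(got, length(want))
  for (i in seq_along(got))
    expect_equal(range(got[[i]]$cells[, 1]), want[[i]])

  # random score vectors, several windows
  for (seed in 1:8) {
    sc <- with_fixed_seed(derive(seed, 7),
                          runif(60, -0.3, 0.9))
    for (w in c(1, 5, 15)) {
      got <- extract_local_alignments(mk_path(sc), sigma = 0.075, window = w,
                                      sigma_factor = 2)
      want <- bf_extract_ranges(sc, w, 0.15)
      expect_length(got, length(want))
      for (i in seq_along(got)) {
        expect_equal(range(got[[i]]$cells[, 1]), want[[i]])
        expect_equal(got[[i]]$score, mean(sc[want[[i]][1]:want[[i]][2]]))
      }
    }
  }

  # short path: single whole-path candidate, kept only above threshold
  short <- extract_local_alignments(mk_path(rep(0.5, 4)), sigma = 0.075,
                                    window = 15, sigma_factor = 2)
  expect_length(short, 1)
  expect_length(extract_local_alignments(mk_path(rep(0.05, 4)), sigma = 0.075,
                                         window = 15, sigma_factor = 2), 0)
  expect_error(extract_local_alignments(mk_path(rep(1, 4)), sigma = 0.075,
                                        window = 0), "positive")
})

test_that("raising sigma_factor never increases reported aligned cells", {
  for (seed in 1:5) {
    pp <- planted_pair(derive(seed, 8))
    counts <- sapply(c(1, 1.5, 2, 2.5, 3), function(sf) {
      h <- align_pair(pp$query, pp$target,
                      search_params(sigma_factor = sf))
      sum(vapply(h$alignments, function(a) nrow(a$cells), integer(1)))
    })
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("global alignment is optimal against exhaustive path enumeration", {
  g <- global_align(matrix(0.7, 1, 1))
  expect_equal(g$cells, matrix(c(1L, 1L), 1, 2))
  expect_equal(g$score, 0.7)

  # self comparison: pure diagonal with score 1
  A <- random_embedding(12, 16, seed = 31)
  SA <- substitution_matrix(A, A)
  gs <- global_align(SA)
  expect_equal(gs$cells, cbind(1:12, 1:12))
  expect_equal(gs$score, 1, tolerance = 1e-6)

  # random 3 x 4 and a spread of shapes: total matched score equals the
  # exhaustive maximum
  for (seed in 1:10) {
    n <- with_fixed_seed(derive(seed, 9), sample(1:5, 1))
    k <- with_fixed_seed(derive(seed, 10), sample(1:6, 1))
    S <- with_fixed_seed(derive(seed, 11), matrix(runif(n * k, -1, 1), n, k))
    g <- global_align(S)
    expect_equal(sum(S[g$cells]), bf_global_best(S), tolerance = 1e-9)
    # each diagonal move consumes one residue of both sequences
    expect_equal(length(g$moves), n + k - sum(g$moves == "diag"))
  }
})

test_that("global alignment covers all residues of both sequences", {
  S <- with_fixed_seed(77, matrix(runif(12, -1, 1), 3, 4))
  g <- global_align(S, "MKV", "GWAC")
  expect_equal(nchar(g$gapped_query), nchar(g$gapped_target))
  expect_equal(gsub("-", "", g$gapped_query), "MKV")
  expect_equal(gsub("-", "", g$gapped_target), "GWAC")
})

test_that("render_alignment emits residues and gaps by step direction", {
  expect_equal(render_alignment(cbind(1:2, 1:2), "MK", "MR"), c("MK", "MR"))
  expect_equal(render_alignment(cbind(c(1, 2, 3), c(1, 1, 2)), "MKV", "MR"),
               c("MKV", "M-R"))
  expect_equal(render_alignment(cbind(c(1, 1), c(1, 2)), "M", "MR"),
               c("M-", "MR"))
  expect_error(render_alignment(cbind(c(1, 3), c(1, 2)), "MKV", "MR"),
               "monotone")
  expect_error(render_alignment(cbind(5, 1), "MKV", "MR"), "bounds")
})

test_that("local self-search returns the full diagonal at score 1", {
  for (n in c(20, 47, 80)) {
    A <- random_embedding(n, 32, seed = n)
    hit <- align_pair(A, A, search_params())
    expect_gte(length(hit$alignments), 1)
    best <- hit$alignments[[1]]
    expect_equal(best$cells, cbind(seq_len(n), seq_len(n)))
    expect_equal(best$score, 1, tolerance = 1e-6)
  }
})
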