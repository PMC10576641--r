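# Independent reference implementations used as oracles. These deliberately
# use plain elementwise loops (no shared code with the package internals).

# Cosine similarity of every residue pair, one dot product at a time.
bf_substitution <- function(q, t) {
  out <- matrix(0, nrow(q), nrow(t))
  for (i in seq_len(nrow(q))) {
    for (j in seq_len(nrow(t))) {
      u <- q[i, ]
      v <- t[j, ]
      out[i, j] <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    }
  }
  out
}

# Naive cell-by-cell evaluation of the gap-free cumulative recurrence.
bf_scoring <- function(S) {
  n <- nrow(S)
  k <- ncol(S)
  H <- matrix(0, n + 1, k + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(k + 1)) {
      H[i, j] <- max(H[i - 1, j - 1] + S[i - 1, j - 1],
                     H[i - 1, j], H[i, j - 1])
    }
  }
  H
}

# Best total matched score over every monotone lattice path from the origin
# to the bottom-right corner (diagonal steps add the substitution value, gap
# steps add nothing), by exhaustive depth-first enumeration.
bf_global_best <- function(S) {
  n <- nrow(S)
  k <- ncol(S)
  best <- -Inf
  walk <- function(i, j, acc) {
    if (i == n && j == k) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i < n && j < k) walk(i + 1, j + 1, acc + S[i + 1, j + 1])
    if (i < n) walk(i + 1, j, acc)
    if (j < k) walk(i, j + 1, acc)
  }
  walk(0, 0, 0)
  best
}

# Exhaustive-window reimplementation of local extraction on one score
# vector: every window position is evaluated with an explicit loop, runs of
# qualifying windows are grown one position at a time, captures take the
# window centers (extended to the ends of the vector when a run touches the
# first/last window position) and are finally trimmed of terminal cells
# below the threshold. Returns a list of index ranges.
bf_extract_ranges <- function(scores, window, threshold) {
  L <- length(scores)
  if (L < window) {
    idx <- seq_len(L)
    keep <- which(scores >= threshold)
    if (!length(keep)) return(list())
    idx <- idx[min(keep):max(keep)]
    if (mean(scores[idx]) < threshold) return(list())
    return(list(range(idx)))
  }
  nwin <- L - window + 1
  q <- logical(nwin)
  for (t in seq_len(nwin)) {
    s <- 0
    for (u in t:(t + window - 1)) s <- s + scores[u]
    q[t] <- (s / window) >= threshold
  }
  half <- (window - 1) %/% 2
  out <- list()
  t <- 1
  while (t <= nwin) {
    if (!q[t]) {
      t <- t + 1
      next
    }
    r <- t
    while (r < nwin && q[r + 1]) r <- r + 1
    from <- if (t == 1) 1 else t + half
    to <- if (r == nwin) L else r + half
    above <- which(scores[from:to] >= threshold)
    if (length(above)) {
      idx <- (from:to)[min(above):max(above)]
      if (mean(scores[idx]) >= threshold)
        out[[length(out) + 1]] <- range(idx)
    }
    t <- r + 1
  }
  out
}

# Best cosine over all window pairs, computed pair by pair from raw slices.
bf_prefilter <- function(q, t, window) {
  slices <- function(E) {
    n <- nrow(E)
    w <- min(window, n)
    lapply(seq_len(max(n - w + 1, 1)), function(s)
      as.numeric(t(E[s:(s + w - 1), , drop = FALSE])))
  }
  best <- -Inf
  for (u in slices(q)) {
    for (v in slices(t)) {
      cs <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
      if (cs > best) best <- cs
    }
  }
  best
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# A planted-homology query/target pair with known ground truth.
planted_pair <- function(seed, n = 100L, m = 64L, seg = 40L, signal = 0.7) {
  q <- random_embedding(n, m, seed = derive(seed, 1))
  pos <- with_fixed_seed(derive(seed, 2), c(
    sample.int(n - seg + 1L, 1L), sample.int(n - seg + 1L, 1L)))
  sp <- plant_spec(c(pos[1], seg), c(pos[2], seg), signal,
                   seed = derive(seed, 3))
  list(query = q, target = plant_homology(q, n, sp),
       truth = cbind(pos[1] + seq_len(seg) - 1L, pos[2] + seq_len(seg) - 1L))
}

derive <- function(seed, i) as.integer((seed * 131 + i * 7919) %% 2147483647)

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}
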