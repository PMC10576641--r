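---
title: "Detecting remote protein homology from per-residue embeddings"
author: "embalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting remote protein homology from per-residue embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embalign)
```

## The model

Classical sequence search scores residue pairs with a fixed substitution
table (BLOSUM62 and relatives), so the score of aligning two residues is
independent of their sequence context. Protein language models (pLMs) such
as ProtT5 instead assign every residue a context-dependent vector (a
per-residue *embedding*, dimension 1024 for ProtT5). `embalign` detects
local and global similarity between two proteins by comparing these vectors
directly, with no learned alignment model on top.

For a sequence of $n$ residues the embedding is a matrix
$E \in \mathbb{R}^{n \times m}$. Each row is first normalized to unit
Euclidean norm,
$e_i^{\dagger} = e_i / \lVert e_i \rVert$,
and the **substitution matrix** of a query/target pair is the full
cosine-similarity grid
$$S = E_q^{\dagger} \, E_t^{\dagger\top}, \qquad
  s_{ij} \in [-1, 1].$$
Every entry is the similarity of query residue $i$ and target residue $j$
*in their respective contexts*; there is no invariant table anywhere in the
method.

**Cumulative scoring.** A Smith–Waterman-style matrix
$H \in \mathbb{R}^{(n+1)\times(k+1)}$ has its first row and column set to
zero and is filled with
$$h_{ij} = \max\{\, h_{i-1,j-1} + s_{ij},\; h_{i-1,j},\; h_{i,j-1} \,\}.$$
Two deliberate departures from Smith–Waterman: there is **no gap penalty**
(dissimilar regions already score near zero or negative under cosine
similarity) and the recurrence is **not truncated at zero**. We use the
single-step reading of the gap terms (predecessors one cell away) so that
the fill and the traceback inspect the same three cells. A consequence worth
recording: because gap moves copy a neighbouring value unchanged and the
borders are zero, $H$ is non-negative and monotone non-decreasing along
rows and columns under this recurrence — the "no truncation" clause can
only ever matter for multi-step gap readings, and the traceback's stop
condition $h \le 0$ fires exactly on zero plateaus.

**Multi-start traceback.** Instead of starting at the global maximum,
one walk starts from *every* cell of the bottom row and rightmost column of
$H$ ($n + k - 1$ starts; the shared corner is used once). Each walk steps to
the argmax of the three predecessor cells — ties prefer the diagonal, then
the vertical, then the horizontal move, favouring substitutions over gaps —
and stops at a non-positive cumulative score or at a matrix edge. This
yields up to $n + k - 1$ candidate paths covering different parts of the
matrix.

**Local-alignment extraction.** Each path is scanned with a moving average
(window $w = 15$ cells by default) of the substitution values along its
cells. Window means at or above
$\tau = \text{sigma\_factor} \times \sigma$ — where $\sigma$ is the
standard deviation of the substitution matrix and sigma_factor defaults to
2 — mark similar regions; maximal runs of qualifying windows become local
alignments, scored by the mean per-cell substitution value. Raising the
factor above 2 makes extraction stricter, lowering it more permissive.

**Global mode** is the textbook Needleman–Wunsch algorithm with the
similarity matrix replaced by $S$ and the gap penalty set to zero.

**Prefilter.** For database search, aligning every entry is wasteful. The
per-residue embeddings are treated as 2D images and convolved: every window
of 30 consecutive residues (times the full embedding dimension) is
flattened and unit-normalized, and the prefilter score of a pair is the
maximum cosine similarity over all window pairs. Per query, only entries at
or above the 90th percentile of the score distribution are aligned. Unlike
a single mean-pooled per-protein vector, windowed pooling retains local
similarity, so a conserved 40-residue segment inside otherwise unrelated
proteins still produces a near-maximal score.

## Design decisions in the open corners

Several details are not fixed by the description above; the choices made
here, and why:

* **What $\sigma$ is.** We use the population standard deviation over all
  $n \times k$ elements of the current pair's substitution matrix. Other
  readings (per-row deviations averaged, or an average across a whole
  database) are less local and would couple the threshold of one pair to
  unrelated pairs. On isotropic unit vectors in dimension $m$, background
  cosines have standard deviation $\approx 1/\sqrt{m}$ (0.125 at $m = 64$);
  real ProtT5 embeddings are anisotropic and sit near 0.075.

* **Window placement and capture.** The moving-average window is treated as
  *centered*: a run of qualifying windows captures the cells at the window
  centers of the run. Capturing the union of whole window footprints
  instead would extend every alignment by up to $w - k_{\min} \approx 9$
  background cells per side ($k_{\min}$ being the minimal number of
  high-scoring cells a window needs to qualify), systematically diluting
  per-residue precision on sharp similarity boundaries; centered capture
  bounds the overshoot by roughly 2 cells per side. Two refinements keep
  the rule sensible at the ends: a run touching the first or last window
  position extends its capture to the path end (so a uniformly high path —
  a self-comparison — is captured in full), and each captured subpath is
  trimmed of terminal cells individually below $\tau$, which localises the
  reported boundaries to the similar region itself. Paths shorter than the
  window are evaluated as a single whole-path candidate.

* **Redundancy across starts.** Many of the $n + k - 1$ paths funnel into
  the same high-scoring region and re-extract near-identical alignments.
  Exact duplicates are dropped; among alignments sharing more than half of
  the cells of the shorter one, only one is kept. Candidates compete on
  their *cumulative* (summed) subpath score — the quantity the scoring
  matrix itself accumulates — while the *reported* score remains the
  length-comparable mean. Competing on the mean would let a 2-cell
  fragment of a 40-cell conserved segment (mean 0.70) displace the full
  alignment (mean 0.64), which is plainly the wrong resolution of
  redundancy.

* **Prefilter stride.** The convolution is dense by default
  (`prefilter_stride = 1`). A coarser stride is exposed for very large
  databases, but note its failure mode: if query and target copies of a
  conserved segment start at offsets that differ modulo the stride, no
  window pair lines the copies up residue-for-residue, and on sharp
  (noise-like) similarity structure the prefilter score collapses to
  background. Real pLM embeddings vary smoothly along the sequence, which
  masks this on biological data; synthetic fixtures do not.

* **Percentile rule.** The cutoff is the score at ascending rank
  $\min(n, \lfloor p \cdot n / 100 \rfloor + 1)$ and selection is
  inclusive ($\ge$), keeping ties: percentile 0 keeps everything,
  percentile 100 exactly the argmax set, and 90 on 55 entries keeps the
  top 6 (plus ties).

* **Coordinates and score.** All R-level structures use 1-based inclusive
  residue indices (the R and alignment-report convention). The reported
  alignment score is the mean per-cell substitution value — dimensionless
  and comparable across alignment lengths. No E-value statistics are
  attached; the sigma threshold is the sensitivity control.

* **Tie-breaks.** Diagonal over vertical over horizontal, in both
  tracebacks; the global traceback reconstructs the fill arithmetic
  bitwise, so exactly one optimum is emitted deterministically.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `window` | 15 | path cells | moving-average window of local extraction |
| `sigma_factor` | 2 | multiples of $\sigma$ | extraction threshold $\tau$ |
| `prefilter_window` | 30 | residues | convolution window of the prefilter |
| `prefilter_stride` | 1 | residues | step between window starts |
| `prefilter_percentile` | 90 | percent | per-query candidate cutoff |
| `min_score` | 0 | mean cosine | reporting floor on hit scores |

The extraction window of 15 cells is roughly half a short paired
secondary-structure motif; the prefilter window of 30 matches the smallest
segments one would call a conserved subdomain fragment.

## The synthetic generator, and what passing tests mean

Real per-residue embeddings require a multi-gigabyte model download, so the
test substrate is synthetic: rows are independent isotropic Gaussian
vectors normalized to unit length, and homology is *planted* by replacing a
target segment with $s \cdot q + \sqrt{1 - s^2} \cdot z$, where $q$ is the
copied (normalized) query row and $z$ is unit noise orthogonalized against
it — so the expected within-segment cosine equals the signal $s$ exactly,
not approximately. Generating post-normalization embeddings is sound
because every pipeline stage consumes row-normalized input anyway; an
optional row-scale jitter produces raw-scale matrices for exercising the
normalization itself.

The default study conditions, chosen once: embedding dimension 64 (large
enough for $1/\sqrt{m}$ background statistics to be well separated from a
0.7 signal, small enough to keep hundreds of replicates cheap), sequences
of 100 residues, planted segments of 40 residues at signal 0.7 (a
conserved subdomain-sized fragment inside otherwise unrelated proteins),
and benchmark databases of 50 decoys plus 5 homologs with segment
positions uniform over the valid range.

What the synthetic substrate does *not* emulate: the anisotropy of real
pLM embedding spaces (background cosines centred well above zero), the
smooth positional correlation of neighbouring residues' embeddings, and
composition biases of real sequences. Consequently, passing the planted
recovery and ranking checks demonstrates the correctness of the machinery
— normalization, cosine algebra, recurrence, traceback, extraction,
percentile selection — under controlled signal, not the biological
sensitivity of any particular language model; the latter depends entirely
on the embeddings supplied.

Verification scales used by the automated checks: brute-force cosine
oracles on 50 random pairs up to 40 residues; naive recurrence fills on 50
matrices up to 20×20; exhaustive enumeration of all monotone lattice paths
for every shape up to 5×6 (20 trials each); 100 seeded replicates for
planted recovery (measured mean per-residue precision and sensitivity both
≈ 0.99), negative controls (signal 0: no alignments in 100/100 replicates)
and prefilter ranking (planted homologs in the top decile in 100/100
databases of 55 entries).

## Numerical choices and degenerate inputs

* Substitution values are clamped into $[-1, 1]$ after the matrix product
  to absorb floating error before thresholding.
* Embedding rows with norm below $10^{-12}$ (and zero-norm flattened
  prefilter windows) raise errors naming the offending row — a zero
  embedding row carries no information and silently normalizing it would
  inject NaNs downstream.
* Archives store values as 32-bit floats by default, matching the
  half/single precision of pLM output; alignment arithmetic is 64-bit
  throughout. A `precision = "double"` switch gives bit-exact round trips.
* Sequences are restricted to the 20 standard amino acids plus X;
  ambiguity codes B/Z/U/O are rejected with an explicit message rather than
  silently remapped.
* Empty databases search to empty results; a sequence shorter than the
  prefilter window contributes a single whole-sequence window.

## Limitations

* No E-values or match probabilities: scores are mean cosines and their
  calibration depends on the embedding model.
* Local mode reports precise but deliberately compact alignments; fully
  alignable homologs are better served by global mode.
* Database scans hold one substitution/scoring pair in memory at a time but
  are CPU-bound in R/BLAS; very large databases (millions of entries) are
  out of scope.
* The bundled ProtT5 backend shells out to a local Python runtime with
  `torch`/`transformers`; without one, embeddings must be precomputed and
  loaded from an archive.
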