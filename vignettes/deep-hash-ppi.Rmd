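---
title: "Deep-hash encoding and pigeonhole search for all-against-all PPI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-hash encoding and pigeonhole search for all-against-all PPI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhlppi)
```

## The problem

Given a database of $M$ protein sequences, deciding which of the
$M(M-1)/2$ pairs interact by scoring every pair is $O(M^2)$ and becomes
the bottleneck of all-against-all prediction. `dhlppi` sidesteps the
pairwise scan: each protein is encoded once into a 64-bit binary hash
code, and interaction candidates are retrieved by exact-match lookups in
sorted integer tables, so the whole all-against-all prediction runs in
$O(M \log M)$.

Two ideas carry the method:

1. **Learned binary codes.** A Siamese convolutional network maps a
   protein sequence to a relaxed code in $(0,1)^N$ ($N = 64$), trained so
   that interacting pairs end up within a small Manhattan distance and
   non-interacting pairs beyond a large one. Thresholding at 0.5 gives a
   binary code, and the training losses are designed to make that
   thresholding nearly lossless.
2. **Pigeonhole pre-screening.** If two $N$-bit codes are within Hamming
   distance $d$ and each is cut into $2d$ equal fragments, at least $d$
   fragments agree exactly. Indexing all $\binom{2d}{d}$ ways of choosing
   $d$ fragments (70 tables for $d = 4$) turns radius-$d$ retrieval into
   exact integer search with no false negatives; a final Hamming check
   removes false positives.

## The encoder

The trunk is shared by both inputs of a pair (a Siamese network): an
embedding layer over the 21-token alphabet (20 residues + padding 0),
then four convolution blocks. Each block applies 1-D convolutions
(stride 1, "same" zero padding), ReLU, batch normalization — in that
order, normalization after the activation — then average pooling; the
last block pools globally over positions. The full-scale profile uses
64/128/256/512 kernels of sizes 5/7/9/15 and input length $L = 5000$.

The trunk output feeds **two frozen random projections**, one producing
the *ontic* code (the database side) and one the *query* code (the probe
side). They are linear, bias-free, initialized from a symmetric uniform
distribution with distinct seeds, and never updated by training: all
discriminative capacity lives in the shared trunk, which must learn
representations whose two projections agree where they should. A sigmoid
range control squeezes each output into $(0,1)$; `binarize()` thresholds
at 0.5 (inclusive).

Residues are tokenized with a fixed table (A=1, G=2, ..., C=20) so the
encoding is deterministic and framework-independent; sequences are
zero-padded (trailing, by default) to $L$ and truncated head-anchored
beyond it. Non-standard residues (B, J, O, U, X, Z) map to the padding
token with a warning, or raise in strict mode.

### Losses

For a labeled pair with relaxed codes $o, q$ and
$\mathrm{dist} = \sum_i |o_i - q_i|$ (which tends to the Hamming distance
as bits saturate):

* **Discrimination (contrastive hinge).**
  $\mathcal{L}_d = \mathrm{label}\cdot\max(\mathrm{dist} - \mathit{in}_{dist}, 0)
  + (1-\mathrm{label})\cdot\max(\mathit{unin}_{dist} - \mathrm{dist}, 0)$
  with margins $\mathit{in}_{dist} = 2$ and $\mathit{unin}_{dist} = 12$.
  Interacting pairs are pushed inside Manhattan distance 2,
  non-interacting pairs beyond 12; the dead zone between the margins is
  what the search threshold $d = 4$ later absorbs.
* **Hash constraint (quantization).** Per code,
  $\max(q_t^2 N - \sum_i (x_i - q_t)^2,\, 0)$ with $q_t = 0.5$; zero
  exactly on binary codes, maximal ($0.25N$ per code) when every
  component sits at 0.5. Summed over the ontic and query codes.
* **Bit balance.** $(\mathrm{mean}(o) - 0.5)^2 + (\mathrm{mean}(q) - 0.5)^2$,
  nudging each code toward half zeros and half ones so the index tables
  stay uniformly loaded.

The total is $\lambda_d \mathcal{L}_d + \lambda_h \mathcal{L}_h +
\lambda_b \mathcal{L}_b$ with $\lambda_d = \lambda_h = 1$ and
$\lambda_b = 2/N$ (= 1/32 at $N = 64$). Batches are reduced by the
arithmetic mean. All margins and weights live in `loss_config()` and can
be overridden.

### Training

Every labeled pair (A, B) is used twice — once with A as ontic and B as
query, once reversed — doubling the sample count (`double_pairs()`).
Splitting happens at the level of undirected pairs *before* doubling
(`cv_split()`, 10 folds, 9:1), so a pair and its reversal never straddle
the train/test boundary. The optimizer is Adam (the only one
implemented); per-epoch means of all loss components are returned as a
trace. The frozen projections are bitwise identical before and after
training — this is asserted in the test suite.

Batch normalization during training uses the statistics of the joint
ontic + query batch (both halves pass through the same trunk in one
forward call); inference uses running averages accumulated with momentum
0.9. This is one deliberate simplification over calling the trunk twice
per pair with per-call statistics: it keeps the Siamese symmetry exact
within a step.

## Search

`build_index()` cuts each 64-bit ontic code into 8 fragments of 8 bits
and builds one sorted table per 4-subset of fragment positions — 70
tables of 32-bit integers. Subsets are enumerated in lexicographic order
(the choice of a *fixed* complete enumeration is what the pigeonhole
guarantee needs; which order is immaterial, but a fixed one keeps index
files reproducible). `bcsa()` then looks up the query's corresponding
32-bit value in every table by binary search (equal-range, so duplicated
values are all returned), unions the hits into a candidate set $S$, and
verifies each candidate with a full Hamming comparison at threshold
$d = 4$. For uniform codes the expected number of exact matches per
query is $\binom{2d}{d} M / 2^{32}$ — about $7 \times 10^{-4}$ even at
$M = 40{,}000$ — so verification cost is negligible; for adversarially
duplicated databases it degrades gracefully to the $O(M)$ scan, with no
cap imposed.

`predict_all()` runs every query code against the index (the table
lookups are vectorized across queries), drops self-matches by default
(`include_self = TRUE` re-admits homodimer-style hits), and can
symmetrize the directed relation set into unordered pairs (a pair is
reported when either direction hits). Pair-level evaluation
(`evaluate_pairs()`) uses that same union rule.

## Synthetic data: what it emulates, and what it does not

Real benchmark interactomes (e.g. the four-species HPRD-derived set) are
an optional external input; the test surface is synthetic and fully
generated in code.

* `gen_codes()` draws uniform random $N$-bit codes and plants
  near-neighbours at exact Hamming distances by flipping chosen numbers
  of bits. Together with `brute_force_search()` (a linear-scan oracle) it
  pins down the search stack: the indexed search is required to agree
  with the oracle exactly, both exhaustively at $N=8, d=2$ over all
  $256 \times 256$ code pairs and on random 64-bit databases.
* `gen_interactome()` builds paralog-style families: each family has a
  template sequence carrying a conserved 16-residue motif (a compact
  stand-in for an interaction domain) at a family-fixed position, and
  members are the template with 10% independent point substitutions
  outside the motif. Same-family pairs interact; cross-family pairs do
  not. Defaults: 200 proteins of length 200 in 4 families, uniform
  residue background.

The family model was chosen so that the interaction signal is strong and
plainly learnable by a small CNN on a CPU: within-family identity is
~90%, which is typical of recently diverged paralogs, and the conserved
motif is exact in every member. Earlier design iterations that planted
only a short motif in otherwise independent random sequences left too
much within-family sequence variance: the encoder clustered families
correctly but could not compress clusters below the $d = 4$ decision
radius at desk scale. Passing tests on this generator therefore show
that the full pipeline — tokenization, Siamese training, binarization,
indexing, radius search, evaluation — is wired correctly and can learn a
strong sequence-composition signal end to end. They do *not* show that
the desk-scale model reaches the published operating points on real
interactomes, where interaction evidence is sparser, families are not
cliques, and sequence signals are far subtler.

## Scaled-down profile and problem sizes

The full-scale encoder (L = 5000, widths 64/128/256/512) is impractical
to train repeatedly on a laptop-class CPU, so the package ships a `desk`
profile: L = 512 (200 in the benchmark, matching the generator's
sequence length), embedding dimension 32, widths 16/32/32/192. The first
three blocks are deliberately lean; the final block — whose width is the
input dimension of the two frozen projections — is kept wide. That
asymmetry matters: the trunk must find representations on which two
*different* random projections produce agreeing sign patterns, and the
abundance of such directions grows with the head dimension. With a
64-unit head the ontic/query alignment reliably stalls around 11
disagreeing bits on the synthetic task; widening the head (without
touching the earlier blocks) resolves it at a fraction of the cost of
widening the whole trunk.

`run_desk_benchmark()` fixes the whole desk-scale protocol: 400 positive
and 400 negative labeled pairs, fold-1 of the 9:1 split, Adam with batch
32 for 35 epochs at learning rate 3e-3 then 10 at 1e-3, and pair-level
evaluation at $d = 4$. Small batches are load-bearing here, not a
compute compromise: the quantization and discrimination losses balance
each other into a plateau where a few bits per pair sit near 0.5, and
the extra gradient noise of small batches resolves those bits where
large-batch training parks. Residual stalls are handled the way `kmeans`
handles bad starts: up to two random initializations, keeping the one
with the better *training*-set F1 (the held-out pairs are evaluated once,
at the end). On these conditions the held-out F1 is 1.0 for most seeds,
with occasional seeds leaving one family just outside the radius.

## Numerical choices and degenerate inputs

* Binarization threshold is inclusive: a component exactly at 0.5 maps
  to 1.
* Index values are 32-bit integers held in doubles (exact up to
  $2^{53}$); equal-range lookups use `findInterval` on sorted doubles,
  with ties broken by database ordinal so tables are reproducible.
* Batch-norm uses biased variance with eps $10^{-5}$; a zero-variance
  channel normalizes to zero rather than NaN.
* The discrimination hinge uses the sign subgradient; at exactly equal
  components the subgradient is 0.
* Empty databases index cleanly (70 empty tables); empty query sets
  return empty prediction sets; metrics with zero denominators return 0
  (including MCC).
* Training aborts with a diagnostic on non-finite loss rather than
  continuing silently.

## Known limitations

* The paper-scale profile is untrained here; only the desk profile is
  exercised end to end.
* No ROC/PR analysis: after binarization there is no continuous score —
  sweeping the Hamming threshold would give at most $N$ operating
  points.
* The search index targets exact radius-$d$ retrieval; there is no
  approximate or multi-probe mode.
* `cv_split()` folds are balanced only in pair counts, not in class
  composition per fold.
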