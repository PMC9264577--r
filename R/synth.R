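# Synthetic data: random code databases with planted near-neighbours, and
# motif-driven artificial interactomes. These generators (plus the
# brute-force scan) are the ground-truth oracles the search and training
# code is tested against.

#' Generate a random binary-code database with planted near-neighbours
#'
#' Draws `M` uniform random `N`-bit codes, then appends planted codes: for
#' each entry of `planted`, `count` codes each constructed by flipping
#' exactly `distance` distinct random bits of a randomly chosen base code
#' among the first `M`. The returned ground truth lists, for every planted
#' code, its base ordinal and exact construction distance.
#'
#' @param M Number of uniform background codes.
#' @param N Code width in bits.
#' @param planted Optional data.frame (or list convertible to one) with
#'   columns `distance` and `count`.
#' @param seed Integer RNG seed; the whole database is reproducible from it.
#' @return List with `codes` (`(M + sum(count)) x N` 0/1 integer matrix,
#'   rownames `c1..`), and `truth` — data.frame of `planted_ord`,
#'   `base_ord`, `distance` rows (zero rows when nothing is planted).
#' @export
gen_codes <- function(M, N = 64L, planted = NULL, seed = 1L) {
  stopifnot(M >= 0L, N >= 1L)
  set.seed(seed)
  codes <- matrix(rbinom(M * N, 1L, 0.5), nrow = M, ncol = N)
  truth <- data.frame(planted_ord = integer(), base_ord = integer(),
                      distance = integer())
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("distance", "count") %in% names(planted)),
              all(planted$distance >= 0L), all(planted$distance <= N),
              M >= 1L)
    for (r in seq_len(nrow(planted))) {
      k <- planted$distance[r]
      for (j in seq_len(planted$count[r])) {
        base <- sample.int(M, 1L)
        code <- codes[base, ]
        if (k > 0L) {
          flip <- sample.int(N, k)
          code[flip] <- 1L - code[flip]
        }
        codes <- rbind(codes, code)
        truth <- rbind(truth, data.frame(planted_ord = nrow(codes),
                                         base_ord = base, distance = k))
      }
    }
  }
  storage.mode(codes) <- "integer"
  rownames(codes) <- paste0("c", seq_len(nrow(codes)))
  list(codes = codes, truth = truth)
}

#' Brute-force Hamming-radius search (oracle)
#'
#' Linear scan over all codes: returns every ordinal within Hamming
#' distance `d` of the query. This is the reference the indexed BCSA search
#' is checked against.
#'
#' @param q 0/1 query code.
#' @param codes 0/1 matrix, one code per row.
#' @param d Distance threshold.
#' @return Integer vector of ordinals (row indices), ascending.
#' @export
brute_force_search <- function(q, codes, d) {
  if (ncol(codes) != length(q)) stop("code width mismatch")
  which(hamming(codes, q) <= d)
}

#' Specification of a synthetic motif-family interactome
#'
#' Emulates paralog-style interacting protein families. Each family has a
#' template sequence carrying a conserved family motif (a compact
#' interaction-domain stand-in) at a family-fixed position; members are the
#' template with independent point substitutions at rate `mut_rate` outside
#' the motif, so within-family identity is high and the motif is exact in
#' every member that carries it. Two proteins of the same family interact
#' with probability `p_interact`; cross-family pairs never interact.
#'
#' @param n_proteins Number of proteins.
#' @param seq_len Sequence length (residues).
#' @param motif_len Length of the conserved family motif; must be
#'   `< seq_len`.
#' @param n_families Number of families (0 = no signal, all labels 0).
#' @param mut_rate Per-residue substitution probability outside the motif
#'   (substitutions are drawn from the background, so a fraction
#'   resample the same residue). Default 0.10, i.e. roughly 90% pairwise
#'   within-family identity.
#' @param p_interact Probability that a within-family pair is labeled 1.
#' @param p_motif Probability that a family member actually carries its
#'   family motif (1 = always; with lower values the motif region is
#'   mutated like the rest of the sequence).
#' @param background Amino-acid background frequencies (length-20, summing
#'   to 1); default uniform.
#' @param n_pos_pairs,n_neg_pairs How many positive / negative labeled
#'   pairs to emit (sampled without replacement from the eligible pairs);
#'   `NULL` emits all of them.
#' @return List of class `"interactome_spec"`.
#' @export
interactome_spec <- function(n_proteins = 200L, seq_len = 200L,
                             motif_len = 16L, n_families = 4L,
                             mut_rate = 0.10, p_interact = 1, p_motif = 1,
                             background = NULL,
                             n_pos_pairs = NULL, n_neg_pairs = NULL) {
  if (is.null(background)) background <- rep(1 / 20, 20L)
  stopifnot(motif_len < seq_len, length(background) == 20L,
            abs(sum(background) - 1) < 1e-8, mut_rate >= 0, mut_rate < 1,
            p_interact >= 0, p_interact <= 1, p_motif >= 0, p_motif <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 seq_len = as.integer(seq_len),
                 motif_len = as.integer(motif_len),
                 n_families = as.integer(n_families),
                 mut_rate = mut_rate,
                 p_interact = p_interact, p_motif = p_motif,
                 background = background,
                 n_pos_pairs = n_pos_pairs, n_neg_pairs = n_neg_pairs),
            class = "interactome_spec")
}

#' Generate a synthetic motif-driven interactome
#'
#' @param spec An [interactome_spec()].
#' @param seed Integer RNG seed.
#' @return List with `records` (named list of `id`/`sequence` records),
#'   `pairs` (data.frame `id_a`, `id_b`, `label`), and `family` (integer
#'   family assignment per protein; 0 = no family).
#' @export
gen_interactome <- function(spec = interactome_spec(), seed = 1L) {
  set.seed(seed)
  aa <- names(AA_CODES)
  n <- spec$n_proteins
  ids <- sprintf("prot%03d", seq_len(n))
  family <- if (spec$n_families > 0L) {
    rep_len(seq_len(spec$n_families), n)[sample.int(n)]
  } else {
    integer(n)
  }
  # family templates: background sequence with the family motif planted at
  # a family-fixed position
  motifs <- character(max(spec$n_families, 0L))
  templates <- vector("list", max(spec$n_families, 0L))
  motif_span <- vector("list", max(spec$n_families, 0L))
  for (f in seq_len(spec$n_families)) {
    motifs[f] <- paste0(sample(aa, spec$motif_len, replace = TRUE),
                        collapse = "")
    tmpl <- sample(aa, spec$seq_len, replace = TRUE, prob = spec$background)
    pos <- sample.int(spec$seq_len - spec$motif_len + 1L, 1L)
    span <- pos:(pos + spec$motif_len - 1L)
    tmpl[span] <- strsplit(motifs[f], "")[[1L]]
    templates[[f]] <- tmpl
    motif_span[[f]] <- span
  }
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (family[i] > 0L) {
      s <- templates[[family[i]]]
      mutable <- seq_len(spec$seq_len)
      if (runif(1) <= spec$p_motif) {
        mutable <- setdiff(mutable, motif_span[[family[i]]])
      }
      hit <- mutable[runif(length(mutable)) < spec$mut_rate]
      if (length(hit)) {
        s[hit] <- sample(aa, length(hit), replace = TRUE,
                         prob = spec$background)
      }
    } else {
      s <- sample(aa, spec$seq_len, replace = TRUE, prob = spec$background)
    }
    seqs[i] <- paste0(s, collapse = "")
  }
  # labeled pairs: within-family positives (w.p. p_interact), cross-family
  # negatives; the two lists are disjoint by construction
  idx <- combn(n, 2L)
  same <- family[idx[1L, ]] == family[idx[2L, ]] & family[idx[1L, ]] > 0L
  pos_idx <- which(same)
  if (spec$p_interact < 1) {
    pos_idx <- pos_idx[runif(length(pos_idx)) <= spec$p_interact]
  }
  neg_idx <- which(!same)
  if (!is.null(spec$n_pos_pairs) && length(pos_idx) > spec$n_pos_pairs) {
    pos_idx <- sort(sample(pos_idx, spec$n_pos_pairs))
  }
  if (!is.null(spec$n_neg_pairs) && length(neg_idx) > spec$n_neg_pairs) {
    neg_idx <- sort(sample(neg_idx, spec$n_neg_pairs))
  }
  sel <- c(pos_idx, neg_idx)
  pairs <- data.frame(id_a = ids[idx[1L, sel]], id_b = ids[idx[2L, sel]],
                      label = rep(c(1L, 0L), c(length(pos_idx), length(neg_idx))),
                      stringsAsFactors = FALSE)
  records <- Map(function(id, s) list(id = id, sequence = s), ids, seqs)
  names(records) <- ids
  list(records = records, pairs = pairs, family = family, motifs = motifs)
}
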