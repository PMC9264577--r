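#' Search configuration for Hamming-radius PPI prediction
#'
#' @param d Hamming distance threshold: a query/ontic code pair at distance
#'   at most `d` is called interacting. Default 4.
#' @param N Code width in bits. `2*d` must divide `N` so the codes split
#'   into `2d` equal fragments of `N/(2d)` bits.
#' @return List of class `"search_config"` with `d`, `N`, `n_frag = 2d`,
#'   `frag_bits = N/(2d)` and the fragment-combination matrix `combos`
#'   (`d`-subsets of the `2d` fragment positions, one column each, in
#'   lexicographic order).
#' @export
search_config <- function(d = 4L, N = 64L) {
  d <- as.integer(d); N <- as.integer(N)
  if (d < 1L) stop("d must be >= 1")
  if (N %% (2L * d) != 0L) {
    stop("2d must divide N: got N = ", N, ", d = ", d,
         " (fragment width would not be integral)")
  }
  structure(list(d = d, N = N, n_frag = 2L * d, frag_bits = N %/% (2L * d),
                 combos = combn(2L * d, d)),
            class = "search_config")
}

#' Hamming distance between binary codes
#'
#' @param a,b 0/1 integer vectors of equal length, or matrices with one code
#'   per row (in which case distances are computed row-wise between `a` and
#'   a single code `b`, or elementwise between matched rows).
#' @return Integer count of differing bit positions.
#' @export
hamming <- function(a, b) {
  if (is.matrix(a) && !is.matrix(b)) {
    if (ncol(a) != length(b)) stop("code width mismatch")
    return(as.integer(rowSums(a != rep(b, each = nrow(a)))))
  }
  if (length(a) != length(b)) stop("code width mismatch: ", length(a),
                                   " vs ", length(b))
  sum(a != b)
}

#' Split a binary code into its 2d pigeonhole fragments
#'
#' Fragments are contiguous, non-overlapping, in bit order; their
#' concatenation reconstructs the code. If two codes are within Hamming
#' distance `d`, at least `d` of their `2d` fragments agree exactly — the
#' pigeonhole guarantee behind the pre-screening index.
#'
#' @param code 0/1 vector of length `cfg$N`.
#' @param cfg A [search_config()].
#' @return List of `2d` 0/1 vectors, each `N/(2d)` bits.
#' @export
fragments <- function(code, cfg = search_config()) {
  if (length(code) != cfg$N) stop("code width ", length(code),
                                  " does not match config N = ", cfg$N)
  split(code, rep(seq_len(cfg$n_frag), each = cfg$frag_bits))
}

# Integer value of selected fragments of each code (rows of `codes`),
# concatenated most-significant-bit first in fragment-position order.
# Returned as doubles: d * frag_bits can be 32 bits, beyond R's integer
# range but exact in a double.
index_values <- function(codes, frag_sel, cfg) {
  cols <- as.vector(vapply(frag_sel, function(f) {
    (f - 1L) * cfg$frag_bits + seq_len(cfg$frag_bits)
  }, integer(cfg$frag_bits)))
  nb <- length(cols)
  weights <- 2^((nb - 1L):0)
  as.vector(codes[, cols, drop = FALSE] %*% weights)
}

#' Build the pigeonhole multi-index over a database of ontic codes
#'
#' Creates one sorted lookup table per `d`-subset of the `2d` fragment
#' positions (`choose(2d, d)` tables; 70 for `d = 4`). Each table stores,
#' for every protein, the integer formed by concatenating its selected
#' fragments, sorted for binary search.
#'
#' @param ids Character vector of `M` unique protein ids.
#' @param ontic_codes `M x N` 0/1 matrix of ontic hash codes (rows aligned
#'   with `ids`).
#' @param cfg A [search_config()].
#' @return An object of class `"code_db"`: list with `ids`, `codes`, `cfg`,
#'   and `tables` — a list of `choose(2d,d)` entries, each holding the
#'   sorted `values` (doubles) and the matching protein `ord`inals.
#' @export
build_index <- function(ids, ontic_codes, cfg = search_config()) {
  if (!is.matrix(ontic_codes)) ontic_codes <- matrix(ontic_codes, nrow = length(ids))
  if (length(ids) != nrow(ontic_codes)) stop("ids and codes disagree on M")
  dup <- anyDuplicated(ids)
  if (dup) stop("duplicate protein id: '", ids[dup], "'")
  if (ncol(ontic_codes) != cfg$N) stop("code width != config N")
  storage.mode(ontic_codes) <- "integer"
  tables <- apply(cfg$combos, 2L, function(sel) {
    v <- index_values(ontic_codes, sel, cfg)
    o <- order(v, seq_along(v))            # ties broken by ordinal
    list(values = v[o], ord = as.integer(o))
  }, simplify = FALSE)
  structure(list(ids = ids, codes = ontic_codes, cfg = cfg, tables = tables),
            class = "code_db")
}

#' @export
print.code_db <- function(x, ...) {
  cat(sprintf("code_db: %d proteins, %d bits, %d index tables (d = %d)\n",
              length(x$ids), x$cfg$N, length(x$tables), x$cfg$d))
  invisible(x)
}

# Equal range [lo, hi] of `q` in sorted vector `v` (0-length if absent).
# findInterval gives #\{v <= q\}; with q - 0.5 it gives #\{v < q\} since all
# values are integers held exactly in doubles.
equal_range <- function(q, v) {
  hi <- findInterval(q, v)
  lo <- findInterval(q - 0.5, v) + 1L
  if (lo > hi) integer() else seq.int(lo, hi)
}

#' Binary code searching algorithm (BCSA)
#'
#' Hamming-radius search of one query code against an indexed database.
#' Stage 1 (pre-screening): for each of the `choose(2d,d)` fragment
#' combinations, look up the query's index value in the corresponding
#' sorted table by binary search and accumulate every exact match into the
#' candidate set S. Stage 2 (verification): keep the candidates whose full
#' ontic code lies within Hamming distance `d` of the query. The pigeonhole
#' principle guarantees no true neighbour is missed in stage 1.
#'
#' @param q 0/1 query code of width `N`.
#' @param db A `code_db` from [build_index()].
#' @param return_candidates If `TRUE` also return the pre-screening
#'   candidate set.
#' @return Character vector of matching protein ids (Hamming distance
#'   `<= d`), or, with `return_candidates`, a list with elements `targets`
#'   and `candidates`.
#' @export
bcsa <- function(q, db, return_candidates = FALSE) {
  cfg <- db$cfg
  if (length(q) != cfg$N) stop("query width != database code width")
  qmat <- matrix(as.integer(q), nrow = 1L)
  cand <- integer()
  for (k in seq_len(ncol(cfg$combos))) {
    qi <- index_values(qmat, cfg$combos[, k], cfg)
    tab <- db$tables[[k]]
    rng <- equal_range(qi, tab$values)
    if (length(rng)) cand <- c(cand, tab$ord[rng])
  }
  cand <- sort(unique(cand))
  if (length(cand)) {
    dist <- hamming(db$codes[cand, , drop = FALSE], as.integer(q))
    targets <- db$ids[cand[dist <= cfg$d]]
  } else {
    targets <- character()
  }
  if (return_candidates) {
    list(targets = targets, candidates = db$ids[cand])
  } else {
    targets
  }
}

#' All-against-all PPI prediction by indexed Hamming search
#'
#' Runs [bcsa()] for every query code against the indexed ontic database
#' and collects the predicted (query_id, target_id) relations. Self-pairs
#' are dropped by default. Internally the `choose(2d,d)` table lookups are
#' vectorized across all queries.
#'
#' @param query_codes `K x N` 0/1 matrix of query codes with rownames as
#'   ids (or a named list of codes).
#' @param db A `code_db` from [build_index()].
#' @param include_self Keep predictions of a protein against its own ontic
#'   entry (homodimer-style self matches). Default `FALSE`.
#' @param symmetrize If `TRUE`, replace the directed relation set by its
#'   undirected union: \{a,b\} is reported (as a single a<b row) when (a,b)
#'   or (b,a) was predicted.
#' @return An object of class `"ppi_set"`: list with `relations`, a
#'   data.frame of `query_id`, `target_id`, `hamming`.
#' @export
predict_all <- function(query_codes, db, include_self = FALSE,
                        symmetrize = FALSE) {
  cfg <- db$cfg
  if (is.list(query_codes)) {
    query_codes <- do.call(rbind, query_codes)
  }
  if (!is.matrix(query_codes)) query_codes <- matrix(query_codes, nrow = 1L)
  if (ncol(query_codes) != cfg$N) stop("query width != database code width")
  qids <- rownames(query_codes)
  if (is.null(qids)) qids <- as.character(seq_len(nrow(query_codes)))
  storage.mode(query_codes) <- "integer"
  K <- nrow(query_codes)

  # stage 1, vectorized: per table, equal-range bounds for all K queries
  cand_q <- vector("list", ncol(cfg$combos))
  cand_t <- vector("list", ncol(cfg$combos))
  for (k in seq_len(ncol(cfg$combos))) {
    qv <- index_values(query_codes, cfg$combos[, k], cfg)
    tab <- db$tables[[k]]
    hi <- findInterval(qv, tab$values)
    lo <- findInterval(qv - 0.5, tab$values) + 1L
    nmatch <- pmax(hi - lo + 1L, 0L)
    has <- which(nmatch > 0L)
    if (length(has)) {
      cand_q[[k]] <- rep(has, nmatch[has])
      cand_t[[k]] <- unlist(lapply(has, function(i) tab$ord[lo[i]:hi[i]]),
                            use.names = FALSE)
    }
  }
  qi <- unlist(cand_q, use.names = FALSE)
  ti <- unlist(cand_t, use.names = FALSE)
  if (length(qi)) {
    # dedup candidate pairs; double arithmetic, exact far beyond any M here
    keep <- !duplicated(as.numeric(qi) * (length(db$ids) + 1) + ti)
    qi <- qi[keep]; ti <- ti[keep]
    dist <- as.integer(rowSums(query_codes[qi, , drop = FALSE] !=
                                 db$codes[ti, , drop = FALSE]))
    ok <- dist <= cfg$d
    qi <- qi[ok]; ti <- ti[ok]; dist <- dist[ok]
  } else {
    dist <- integer()
  }
  rel <- data.frame(query_id = qids[qi], target_id = db$ids[ti],
                    hamming = dist, stringsAsFactors = FALSE)
  if (!include_self) rel <- rel[rel$query_id != rel$target_id, , drop = FALSE]
  if (symmetrize && nrow(rel)) {
    a <- pmin(rel$query_id, rel$target_id)
    b <- pmax(rel$query_id, rel$target_id)
    keep <- !duplicated(paste0(a, "\r", b))
    rel <- data.frame(query_id = a[keep], target_id = b[keep],
                      hamming = rel$hamming[keep], stringsAsFactors = FALSE)
  }
  rel <- rel[order(rel$query_id, rel$target_id), , drop = FALSE]
  rownames(rel) <- NULL
  structure(list(relations = rel, symmetrized = symmetrize), class = "ppi_set")
}

#' @export
print.ppi_set <- function(x, ...) {
  cat("ppi_set:", nrow(x$relations),
      if (isTRUE(x$symmetrized)) "undirected" else "directed", "relations\n")
  if (nrow(x$relations)) print(head(x$relations, 10L))
  invisible(x)
}

#' Pre-screening candidate-set sizes across a query set
#'
#' Returns, for each query code, the size of the deduplicated candidate set
#' S gathered by the pigeonhole pre-screening stage (before Hamming
#' verification). Used to check that pre-screening keeps the candidate load
#' near the `choose(2d,d) * M / 2^(N/2)` expectation on balanced codes.
#'
#' @inheritParams predict_all
#' @return Integer vector of candidate counts, one per query.
#' @export
candidate_set_sizes <- function(query_codes, db) {
  cfg <- db$cfg
  if (!is.matrix(query_codes)) query_codes <- matrix(query_codes, nrow = 1L)
  storage.mode(query_codes) <- "integer"
  K <- nrow(query_codes)
  counts <- integer(K)
  seen <- vector("list", K)
  for (k in seq_len(ncol(cfg$combos))) {
    qv <- index_values(query_codes, cfg$combos[, k], cfg)
    tab <- db$tables[[k]]
    hi <- findInterval(qv, tab$values)
    lo <- findInterval(qv - 0.5, tab$values) + 1L
    has <- which(hi >= lo)
    for (i in has) seen[[i]] <- c(seen[[i]], tab$ord[lo[i]:hi[i]])
  }
  for (i in seq_len(K)) counts[i] <- length(unique(seen[[i]]))
  counts
}

#' Pack a 0/1 code into a hexadecimal string
#'
#' Big-endian over bit positions: bit 1 of the vector is the most
#' significant bit of the first hex digit group.
#'
#' @param code 0/1 vector whose length is a multiple of 4.
#' @return Character scalar of `length(code)/4` hex digits.
#' @export
code_to_hex <- function(code) {
  stopifnot(length(code) %% 4L == 0L)
  nib <- matrix(as.integer(code), nrow = 4L)
  vals <- as.integer(8L * nib[1L, ] + 4L * nib[2L, ] + 2L * nib[3L, ] + nib[4L, ])
  paste0(c("0","1","2","3","4","5","6","7","8","9",
           "a","b","c","d","e","f")[vals + 1L], collapse = "")
}

#' Unpack a hexadecimal string into a 0/1 code vector
#'
#' Inverse of [code_to_hex()].
#'
#' @param hex Character scalar of hex digits.
#' @return 0/1 integer vector of length `4 * nchar(hex)`.
#' @export
hex_to_code <- function(hex) {
  digits <- strtoi(strsplit(tolower(hex), "")[[1L]], base = 16L)
  if (anyNA(digits)) stop("invalid hex string: ", hex)
  as.integer(as.vector(vapply(digits, function(v) {
    c(v %/% 8L, (v %/% 4L) %% 2L, (v %/% 2L) %% 2L, v %% 2L)
  }, integer(4L))))
}
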