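test_that("search_config enforces the fragment divisibility invariant", {
  cfg <- search_config(d = 4L, N = 64L)
  expect_equal(cfg$n_frag, 8L)
  expect_equal(cfg$frag_bits, 8L)
  expect_equal(ncol(cfg$combos), choose(8L, 4L))   # 70 tables
  expect_error(search_config(d = 5L, N = 64L), "divide")
  small <- search_config(d = 2L, N = 8L)
  expect_equal(small$frag_bits, 2L)
  expect_equal(ncol(small$combos), 6L)
})

test_that("hamming counts differing bits and is symmetric", {
  a <- c(1L, 0L, 1L, 0L); b <- c(0L, 0L, 1L, 1L)
  expect_equal(hamming(a, a), 0L)
  expect_equal(hamming(a, b), 2L)
  expect_equal(hamming(a, b), hamming(b, a))
  expect_equal(hamming(rep(1L, 64), rep(0L, 64)), 64L)
  expect_error(hamming(a, c(1L, 0L)), "mismatch")
  # triangle inequality over random triples
  set.seed(3)
  for (i in 1:25) {
    x <- sample(0:1, 16, TRUE); y <- sample(0:1, 16, TRUE)
    z <- sample(0:1, 16, TRUE)
    expect_lte(hamming(x, z), hamming(x, y) + hamming(y, z))
  }
})

test_that("fragments partition the code and concatenate back", {
  cfg <- search_config(d = 4L, N = 64L)
  set.seed(5)
  code <- sample(0:1, 64, TRUE)
  fr <- fragments(code, cfg)
  expect_length(fr, 8L)
  expect_true(all(lengths(fr) == 8L))
  expect_equal(unname(unlist(fr)), code)
  fr2 <- fragments(sample(0:1, 8, TRUE), search_config(d = 2L, N = 8L))
  expect_length(fr2, 4L)
  expect_true(all(lengths(fr2) == 2L))
  expect_error(fragments(code[1:10], cfg), "does not match")
})

test_that("build_index creates choose(2d,d) sorted tables of fragment values", {
  cfg <- search_config(d = 4L, N = 64L)
  sim <- gen_codes(50L, 64L, seed = 2L)
  db <- build_index(rownames(sim$codes), sim$codes, cfg)
  expect_length(db$tables, 70L)
  for (tab in db$tables[c(1L, 35L, 70L)]) {
    expect_equal(length(tab$values), 50L)
    expect_false(is.unsorted(tab$values))
    expect_true(all(tab$values >= 0 & tab$values < 2^32))
  }
  # index soundness: every entry recomputes from its code's fragments
  for (k in c(1L, 17L, 70L)) {
    sel <- cfg$combos[, k]
    recomputed <- vapply(seq_len(50L), function(i) {
      fr <- fragments(db$codes[i, ], cfg)
      bits <- unlist(fr[sel])
      sum(bits * 2^((length(bits) - 1L):0))
    }, numeric(1))
    tab <- db$tables[[k]]
    expect_equal(tab$values, recomputed[tab$ord])
  }
  expect_error(build_index(c("a", "a"), sim$codes[1:2, ], cfg), "duplicate")
  # empty database still yields the full table set
  db0 <- build_index(character(), matrix(integer(), 0L, 64L), cfg)
  expect_length(db0$tables, 70L)
  expect_true(all(vapply(db0$tables, function(t) length(t$values), numeric(1)) == 0))
})

test_that("bcsa finds exact and radius-d matches and rejects far codes", {
  cfg <- search_config(d = 4L, N = 64L)
  sim <- gen_codes(200L, 64L, seed = 9L)
  db <- build_index(rownames(sim$codes), sim$codes, cfg)
  # a database code queried against itself is always found (distance 0)
  expect_true("c7" %in% bcsa(sim$codes[7L, ], db))
  # flipping d bits keeps the match; d+1 may drop it in verification
  q <- sim$codes[7L, ]
  flip <- c(1L, 9L, 17L, 25L)
  q[flip] <- 1L - q[flip]
  expect_true("c7" %in% bcsa(q, db))
  # a query at distance >= d+1 from everything returns nothing
  far <- gen_codes(1L, 64L, seed = 1000L)$codes[1L, ]
  dists <- hamming(sim$codes, far)
  if (min(dists) > 4L) expect_length(bcsa(far, db), 0L)
})

test_that("bcsa equals the brute-force linear scan (pigeonhole exhaustive at N=8)", {
  cfg <- search_config(d = 2L, N = 8L)
  all_codes <- as.matrix(expand.grid(rep(list(0:1), 8L)))[, 8:1]
  colnames(all_codes) <- NULL
  storage.mode(all_codes) <- "integer"
  ids <- paste0("b", seq_len(256L))
  db <- build_index(ids, all_codes, cfg)
  for (qi in seq(1L, 256L, by = 5L)) {
    q <- all_codes[qi, ]
    got <- sort(bcsa(q, db, return_candidates = TRUE)$targets)
    want <- sort(ids[brute_force_search(q, all_codes, 2L)])
    expect_identical(got, want)
  }
})

test_that("bcsa equals the brute-force linear scan on random 64-bit databases", {
  for (seed in 1:3) {
    sim <- gen_codes(400L, 64L,
                     planted = data.frame(distance = c(2L, 4L, 5L),
                                          count = c(3L, 3L, 3L)),
                     seed = seed)
    cfg <- search_config(d = 4L, N = 64L)
    db <- build_index(rownames(sim$codes), sim$codes, cfg)
    set.seed(seed + 100L)
    for (qi in sample(nrow(sim$codes), 10L)) {
      q <- sim$codes[qi, ]
      expect_identical(sort(bcsa(q, db)),
                       sort(rownames(sim$codes)[
                         brute_force_search(q, sim$codes, 4L)]))
    }
  }
})

test_that("pre-screening candidates never miss a within-distance code", {
  # exhaustive pigeonhole check at N=8, d=2: every code within distance 2
  # of the query must already be in the stage-1 candidate set
  cfg <- search_config(d = 2L, N = 8L)
  all_codes <- as.matrix(expand.grid(rep(list(0:1), 8L)))
  colnames(all_codes) <- NULL
  storage.mode(all_codes) <- "integer"
  ids <- paste0("b", seq_len(256L))
  db <- build_index(ids, all_codes, cfg)
  set.seed(11)
  for (qi in sample(256L, 40L)) {
    q <- all_codes[qi, ]
    res <- bcsa(q, db, return_candidates = TRUE)
    within <- ids[hamming(all_codes, q) <= 2L]
    expect_true(all(within %in% res$candidates))
    expect_setequal(res$targets, within)
  }
})

test_that("predict_all unions per-query searches, drops self, symmetrizes", {
  sim <- gen_codes(100L, 64L, seed = 21L)
  cfg <- search_config(d = 4L, N = 64L)
  db <- build_index(rownames(sim$codes), sim$codes, cfg)
  # use the ontic codes as queries: each query matches itself at distance 0
  ppi_self <- predict_all(sim$codes, db, include_self = TRUE)
  expect_true(all(paste0("c", 1:100) %in%
                    ppi_self$relations$query_id[
                      ppi_self$relations$hamming == 0L]))
  ppi <- predict_all(sim$codes, db)
  expect_false(any(ppi$relations$query_id == ppi$relations$target_id))
  # equals the union of independent bcsa calls
  manual <- do.call(rbind, lapply(seq_len(100L), function(i) {
    t <- bcsa(sim$codes[i, ], db)
    t <- setdiff(t, rownames(sim$codes)[i])
    if (length(t)) data.frame(query_id = rownames(sim$codes)[i],
                              target_id = t, stringsAsFactors = FALSE)
  }))
  got <- ppi$relations[, c("query_id", "target_id")]
  if (is.null(manual)) {
    expect_equal(nrow(got), 0L)
  } else {
    manual <- manual[order(manual$query_id, manual$target_id), ]
    rownames(manual) <- NULL
    expect_equal(got, manual)
  }
  # symmetrized view keeps one row per unordered pair
  sym <- predict_all(sim$codes, db, symmetrize = TRUE)
  if (nrow(sym$relations)) {
    expect_true(all(sym$relations$query_id <= sym$relations$target_id))
    expect_false(any(duplicated(
      paste(sym$relations$query_id, sym$relations$target_id))))
  }
  # empty query set
  empty <- predict_all(matrix(integer(), 0L, 64L), db)
  expect_equal(nrow(empty$relations), 0L)
})

test_that("predict_all is invariant to database row order", {
  sim <- gen_codes(80L, 64L, planted = data.frame(distance = 3L, count = 5L),
                   seed = 33L)
  cfg <- search_config(d = 4L, N = 64L)
  db1 <- build_index(rownames(sim$codes), sim$codes, cfg)
  perm <- sample(nrow(sim$codes))
  db2 <- build_index(rownames(sim$codes)[perm], sim$codes[perm, ], cfg)
  q <- sim$codes[1:20, ]
  r1 <- predict_all(q, db1)$relations
  r2 <- predict_all(q, db2)$relations
  expect_equal(r1, r2)
})

test_that("hex packing round-trips codes", {
  set.seed(12)
  code <- sample(0:1, 64, TRUE)
  expect_equal(hex_to_code(code_to_hex(code)), code)
  expect_equal(code_to_hex(c(1, 0, 1, 0, 0, 0, 1, 1)), "a3")
  expect_error(hex_to_code("zz"), "invalid hex")
})
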