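test_that("double_pairs emits both role orientations of every pair", {
  pairs <- data.frame(id_a = "A", id_b = "B", label = 1L,
                      stringsAsFactors = FALSE)
  s <- double_pairs(pairs)
  expect_equal(s$query_id, c("B", "A"))
  expect_equal(s$ontic_id, c("A", "B"))
  expect_equal(s$label, c(1L, 1L))

  expect_equal(nrow(double_pairs(pairs[0, ])), 0L)

  many <- data.frame(id_a = paste0("a", 1:100), id_b = paste0("b", 1:100),
                     label = rep_len(c(1L, 0L), 100L),
                     stringsAsFactors = FALSE)
  doubled <- double_pairs(many)
  expect_equal(nrow(doubled), 200L)
  expect_equal(sum(doubled$label), 2L * sum(many$label))
})

test_that("cv_split partitions pairs into disjoint covering folds at 9:1", {
  pairs <- data.frame(id_a = paste0("a", 1:100), id_b = paste0("b", 1:100),
                      label = rep_len(c(1L, 0L), 100L),
                      stringsAsFactors = FALSE)
  cfg <- train_config(rng_seed = 5L)
  sp <- cv_split(pairs, 1L, cfg)
  expect_equal(nrow(sp$train), 90L)
  expect_equal(nrow(sp$test), 10L)
  expect_equal(nrow(double_pairs(sp$train)), 180L)

  test_union <- do.call(rbind, lapply(1:10, function(f) cv_split(pairs, f, cfg)$test))
  expect_equal(sort(rownames(test_union)), sort(rownames(pairs)))
  expect_false(any(duplicated(rownames(test_union))))

  expect_identical(cv_split(pairs, 3L, cfg), cv_split(pairs, 3L, cfg))
  expect_false(identical(cv_split(pairs, 3L, cfg),
                         cv_split(pairs, 3L, train_config(rng_seed = 6L))))
  expect_error(cv_split(pairs, 0L, cfg), "fold")
  expect_error(cv_split(pairs, 11L, cfg), "fold")
})

test_that("cv_split partitions for arbitrary seeds and sizes", {
  for (seed in c(2L, 17L, 91L)) {
    n <- sample(20:60, 1L)
    pairs <- data.frame(id_a = paste0("x", 1:n), id_b = paste0("y", 1:n),
                        label = 1L, stringsAsFactors = FALSE)
    cfg <- train_config(cv_folds = 5L, rng_seed = seed)
    folds <- lapply(1:5, function(f) cv_split(pairs, f, cfg)$test)
    all_rows <- unlist(lapply(folds, rownames))
    expect_equal(sort(all_rows), sort(rownames(pairs)))
    sizes <- lengths(lapply(folds, rownames))
    expect_lte(max(sizes) - min(sizes), 1L)
  }
})

make_tiny_training_problem <- function(seed = 19L) {
  spec <- interactome_spec(n_proteins = 24L, seq_len = 30L, motif_len = 6L,
                           n_families = 2L, n_pos_pairs = 30L,
                           n_neg_pairs = 30L)
  sim <- gen_interactome(spec, seed = seed)
  toks <- tokenize_all(sim$records, L = 32L)
  cfg <- tiny_encoder_config(rng_seed = seed)
  list(sim = sim, toks = toks, state = build_encoder(cfg))
}

test_that("training reduces the loss and leaves frozen projections untouched", {
  prob <- make_tiny_training_problem()
  samples <- double_pairs(prob$sim$pairs)
  tcfg <- train_config(epochs = 5L, batch_size = 16L, rng_seed = 19L)
  fit <- train(prob$state, samples, prob$toks, loss_config(N = 16L), tcfg)
  expect_equal(nrow(fit$trace), 5L)
  expect_true(all(is.finite(fit$trace$total)))
  expect_lt(tail(fit$trace$total, 1L), fit$trace$total[1L])
  # frozen projections bitwise unchanged; trunk updated
  expect_identical(fit$state$params$P_ont, prob$state$params$P_ont)
  expect_identical(fit$state$params$P_que, prob$state$params$P_que)
  expect_false(identical(fit$state$params$W1, prob$state$params$W1))
})

test_that("zero epochs return the parameters unchanged", {
  prob <- make_tiny_training_problem()
  samples <- double_pairs(prob$sim$pairs)
  fit <- train(prob$state, samples, prob$toks, loss_config(N = 16L),
               train_config(epochs = 0L))
  expect_identical(fit$state$params, prob$state$params)
  expect_equal(nrow(fit$trace), 0L)
})

test_that("training is reproducible from the seed and rejects unknown ids", {
  prob <- make_tiny_training_problem()
  samples <- double_pairs(prob$sim$pairs)
  tcfg <- train_config(epochs = 2L, batch_size = 16L, rng_seed = 7L)
  f1 <- train(prob$state, samples, prob$toks, loss_config(N = 16L), tcfg)
  f2 <- train(prob$state, samples, prob$toks, loss_config(N = 16L), tcfg)
  expect_identical(f1$state$params, f2$state$params)
  expect_equal(f1$trace, f2$trace)

  bad <- samples
  bad$query_id[1L] <- "missing_protein"
  expect_error(train(prob$state, bad, prob$toks, loss_config(N = 16L), tcfg),
               "missing_protein")
})

test_that("evaluate_samples applies the Hamming decision rule", {
  prob <- make_tiny_training_problem()
  samples <- double_pairs(prob$sim$pairs)
  ev <- evaluate_samples(prob$state, samples, prob$toks, d = 4L)
  expect_equal(sum(ev$counts), nrow(samples))
  expect_equal(ev$counts[["TP"]] + ev$counts[["FN"]], sum(samples$label))
  # d = N accepts everything; d = -1 rejects everything
  ev_all <- evaluate_samples(prob$state, samples, prob$toks, d = 16L)
  expect_equal(ev_all$counts[["FN"]], 0L)
  expect_equal(ev_all$counts[["TN"]], 0L)
})
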