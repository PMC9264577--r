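#' Training configuration
#'
#' @param epochs Number of passes over the training samples.
#' @param batch_size Pairs per gradient step.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param split_ratio Training fraction of each split (default 0.9).
#' @param rng_seed Seed controlling splits and batch shuffling.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(epochs = 50L, batch_size = 64L,
                         learning_rate = 1e-3, optimizer = "adam",
                         cv_folds = 10L, split_ratio = 0.9,
                         rng_seed = 1L) {
  stopifnot(split_ratio > 0, split_ratio < 1, cv_folds >= 2L, epochs >= 0L,
            batch_size >= 1L, learning_rate > 0)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 cv_folds = as.integer(cv_folds), split_ratio = split_ratio,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Role-reversal sample doubling
#'
#' Every labeled pair (A, B) produces two directed training samples: one
#' with B as query and A as ontic, and one with the roles reversed. The
#' sample count is exactly twice the pair count.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `label`.
#' @return data.frame with columns `query_id`, `ontic_id`, `label`,
#'   `2 * nrow(pairs)` rows.
#' @export
double_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(data.frame(query_id = character(), ontic_id = character(),
                      label = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    query_id = c(pairs$id_b, pairs$id_a),
    ontic_id = c(pairs$id_a, pairs$id_b),
    label = c(pairs$label, pairs$label),
    stringsAsFactors = FALSE)[order(rep(seq_len(nrow(pairs)), 2L)), ] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Cross-validation split of labeled pairs
#'
#' Pairs are shuffled deterministically by `rng_seed` and partitioned into
#' `cv_folds` disjoint test folds covering all pairs; fold `fold` is the
#' test set and the rest is the training set (a 9:1 split with the default
#' 10 folds). Splitting happens at the level of undirected pairs, before
#' role-reversal doubling, so a pair and its reversal never straddle the
#' train/test boundary.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `label`.
#' @param fold Fold index in `1..cv_folds`.
#' @param cfg A [train_config()].
#' @return List with data.frames `train` and `test` (both still undirected
#'   pairs; apply [double_pairs()] to obtain directed samples).
#' @export
cv_split <- function(pairs, fold, cfg = train_config()) {
  fold <- as.integer(fold)
  if (fold < 1L || fold > cfg$cv_folds) {
    stop("fold must be in 1..", cfg$cv_folds)
  }
  n <- nrow(pairs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$rng_seed)
  perm <- sample.int(n)
  assignment <- integer(n)
  assignment[perm] <- rep_len(seq_len(cfg$cv_folds), n)
  list(train = pairs[assignment != fold, , drop = FALSE],
       test = pairs[assignment == fold, , drop = FALSE])
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the Siamese deep-hash encoder
#'
#' Minimizes the weighted total of the discrimination, hash-constraint and
#' bit-balance losses over directed (query, ontic, label) samples with
#' Adam. The trunk (embedding, convolutions, batch norm) is updated; the
#' two frozen random projections are never touched. Fully reproducible
#' given `train_cfg$rng_seed`.
#'
#' @param state An `encoder_state` from [build_encoder()].
#' @param samples data.frame of directed samples (`query_id`, `ontic_id`,
#'   `label`), e.g. from [double_pairs()].
#' @param tokens Token matrix (rownames = protein ids) covering every id in
#'   `samples`.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with the trained `state` and `trace`, a data.frame of
#'   per-epoch mean `ld`, `lh`, `lb`, `total`.
#' @export
train <- function(state, samples, tokens, loss_cfg = loss_config(),
                  train_cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(state, "encoder_state"))
  missing_ids <- setdiff(unique(c(samples$query_id, samples$ontic_id)),
                         rownames(tokens))
  if (length(missing_ids)) {
    stop("no sequence for id(s): ", paste(head(missing_ids, 5L), collapse = ", "))
  }
  storage.mode(tokens) <- "integer"
  params <- state$params
  cfgc <- cpp_cfg(state$config)
  lcfg <- unclass(loss_cfg)
  opt <- list(t = 0L, m = list(), v = list())
  n <- nrow(samples)
  trace <- data.frame(epoch = integer(), ld = numeric(), lh = numeric(),
                      lb = numeric(), total = numeric())
  qi <- match(samples$query_id, rownames(tokens))
  oi <- match(samples$ontic_id, rownames(tokens))
  labels <- as.numeric(samples$label)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(train_cfg$rng_seed)

  for (epoch in seq_len(train_cfg$epochs)) {
    perm <- sample.int(n)
    sums <- c(ld = 0, lh = 0, lb = 0, total = 0)
    nb <- 0L
    for (start in seq(1L, n, by = train_cfg$batch_size)) {
      idx <- perm[start:min(start + train_cfg$batch_size - 1L, n)]
      res <- cpp_pair_batch(tokens[oi[idx], , drop = FALSE],
                            tokens[qi[idx], , drop = FALSE],
                            labels[idx], params, cfgc, lcfg,
                            compute_grads = TRUE)
      if (!is.finite(res$total)) {
        stop("non-finite loss at epoch ", epoch, " (ld=", res$ld,
             ", lh=", res$lh, ", lb=", res$lb, "); aborting")
      }
      upd <- adam_update(params, res$grads, opt, train_cfg$learning_rate)
      params <- upd$params
      opt <- upd$state
      for (nm in names(res$running)) params[[nm]] <- res$running[[nm]]
      sums <- sums + c(res$ld, res$lh, res$lb, res$total)
      nb <- nb + 1L
    }
    trace <- rbind(trace, data.frame(epoch = epoch, ld = sums[["ld"]] / nb,
                                     lh = sums[["lh"]] / nb,
                                     lb = sums[["lb"]] / nb,
                                     total = sums[["total"]] / nb))
    if (verbose) {
      message(sprintf("epoch %3d  L=%.4f  (Ld=%.4f Lh=%.4f Lb=%.5f)",
                      epoch, sums[["total"]] / nb, sums[["ld"]] / nb,
                      sums[["lh"]] / nb, sums[["lb"]] / nb))
    }
  }
  state$params <- params
  rownames(trace) <- NULL
  list(state = state, trace = trace)
}

#' Evaluate directed samples under the Hamming decision rule
#'
#' Encodes every referenced protein once (query and ontic codes), then
#' calls a directed sample interacting when
#' `hamming(query_code, ontic_code) <= d`, and summarizes the result as
#' confusion counts and the six evaluation metrics.
#'
#' @param state A trained `encoder_state`.
#' @param samples Directed samples (`query_id`, `ontic_id`, `label`).
#' @param tokens Token matrix covering the referenced ids.
#' @param d Hamming decision threshold (default 4).
#' @return List with `counts` (TP/FP/FN/TN) and `metrics` (named vector).
#' @export
evaluate_samples <- function(state, samples, tokens, d = 4L) {
  eval_ids_dist(state, samples$query_id, samples$ontic_id, samples$label,
                tokens, d)
}

eval_ids_dist <- function(state, query_id, ontic_id, label, tokens, d) {
  samples <- data.frame(query_id = query_id, ontic_id = ontic_id,
                        label = label, stringsAsFactors = FALSE)
  ids <- unique(c(samples$query_id, samples$ontic_id))
  tok <- tokens[ids, , drop = FALSE]
  qcodes <- encode_database(state, tok, "query")
  ocodes <- encode_database(state, tok, "ontic")
  qi <- match(samples$query_id, ids)
  oi <- match(samples$ontic_id, ids)
  dist <- rowSums(qcodes[qi, , drop = FALSE] != ocodes[oi, , drop = FALSE])
  pred <- dist <= d
  pos <- samples$label == 1L
  counts <- c(TP = sum(pos & pred), FP = sum(!pos & pred),
              FN = sum(pos & !pred), TN = sum(!pos & !pred))
  list(counts = counts, metrics = ppi_metrics(counts), dist = dist)
}

#' Evaluate undirected pairs under the Hamming decision rule
#'
#' Pair-level analogue of [evaluate_samples()], matching the all-against-all
#' prediction pipeline with symmetrization: a pair (A, B) is called
#' interacting when either direction hits, i.e. when
#' `min(hamming(que_A, ont_B), hamming(que_B, ont_A)) <= d`.
#'
#' @param state A trained `encoder_state`.
#' @param pairs data.frame of undirected labeled pairs (`id_a`, `id_b`,
#'   `label`).
#' @param tokens Token matrix covering the referenced ids.
#' @param d Hamming decision threshold (default 4).
#' @return List with `counts` (TP/FP/FN/TN), `metrics` (named vector) and
#'   `dist` (the per-pair minimum over the two directions).
#' @export
evaluate_pairs <- function(state, pairs, tokens, d = 4L) {
  fwd <- eval_ids_dist(state, pairs$id_b, pairs$id_a, pairs$label, tokens, d)
  rev <- eval_ids_dist(state, pairs$id_a, pairs$id_b, pairs$label, tokens, d)
  dist <- pmin(fwd$dist, rev$dist)
  pred <- dist <= d
  pos <- pairs$label == 1L
  counts <- c(TP = sum(pos & pred), FP = sum(!pos & pred),
              FN = sum(pos & !pred), TN = sum(!pos & !pred))
  list(counts = counts, metrics = ppi_metrics(counts), dist = dist)
}
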