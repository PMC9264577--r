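#' Loss configuration for the deep-hash encoder
#'
#' Bundles the margins and weights of the three training losses: the
#' contrastive discrimination loss (margins `in_dist` for interacting and
#' `unin_dist` for non-interacting pairs), the hash-constraint
#' (quantization) loss with threshold `quan_thresh`, and the bit-balance
#' loss. The default weights are `lambda_d = lambda_h = 1` and
#' `lambda_b = 2/N`.
#'
#' @param N Code width in bits.
#' @param in_dist Distance margin for interacting pairs (loss-free at or
#'   below it).
#' @param unin_dist Distance margin for non-interacting pairs (loss-free at
#'   or above it).
#' @param quan_thresh Quantization threshold in (0,1).
#' @param lambda_d,lambda_h,lambda_b Non-negative loss weights;
#'   `lambda_b` defaults to `2/N`.
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(N = 64L, in_dist = 2, unin_dist = 12,
                        quan_thresh = 0.5, lambda_d = 1, lambda_h = 1,
                        lambda_b = 2 / N) {
  N <- as.integer(N)
  stopifnot(N > 0L, in_dist >= 0, in_dist < unin_dist, unin_dist <= N,
            quan_thresh > 0, quan_thresh < 1,
            lambda_d >= 0, lambda_h >= 0, lambda_b >= 0)
  structure(list(N = N, in_dist = in_dist, unin_dist = unin_dist,
                 quan_thresh = quan_thresh, lambda_d = lambda_d,
                 lambda_h = lambda_h, lambda_b = lambda_b),
            class = "loss_config")
}

#' Manhattan distance between two relaxed codes
#'
#' Sum of absolute component differences. On binary codes this equals the
#' Hamming distance; on pre-binarization (relaxed) codes it approaches the
#' Hamming distance as components saturate towards 0/1.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
manhattan_dist <- function(a, b) {
  if (length(a) != length(b)) stop("code length mismatch: ", length(a),
                                   " vs ", length(b))
  sum(abs(a - b))
}

#' Discrimination (contrastive margin) loss
#'
#' Interacting pairs (`label = 1`) are penalized for exceeding the inner
#' margin; non-interacting pairs (`label = 0`) for falling inside the outer
#' margin:
#' `label * max(dist - in_dist, 0) + (1 - label) * max(unin_dist - dist, 0)`.
#'
#' @param dist Non-negative Manhattan distance between the two codes of a
#'   pair (vectorized).
#' @param label 0/1 interaction label (vectorized, recycled against `dist`).
#' @param cfg A [loss_config()].
#' @return Loss value(s), non-negative.
#' @export
discrimination_loss <- function(dist, label, cfg = loss_config()) {
  stopifnot(all(dist >= 0), all(label %in% c(0, 1)))
  label * pmax(dist - cfg$in_dist, 0) +
    (1 - label) * pmax(cfg$unin_dist - dist, 0)
}

# per-code quantization term: max(t^2 * N - sum((x - t)^2), 0)
hash_constraint_term <- function(x, quan_thresh = 0.5) {
  max(quan_thresh^2 * length(x) - sum((x - quan_thresh)^2), 0)
}

#' Hash-constraint (quantization) loss
#'
#' Pushes every relaxed-code component towards 0 or 1. Each code contributes
#' `max(quan_thresh^2 * N - sum_i (x_i - quan_thresh)^2, 0)`; the total is
#' the sum of the ontic and query terms. Zero exactly when every component
#' is binary; maximal (`2 * quan_thresh^2 * N`) when every component sits at
#' the threshold.
#'
#' @param ont,que Relaxed codes (numeric vectors of length `cfg$N`).
#' @param cfg A [loss_config()].
#' @return Non-negative scalar.
#' @export
hash_constraint_loss <- function(ont, que, cfg = loss_config(N = length(ont))) {
  stopifnot(length(ont) == cfg$N, length(que) == cfg$N)
  hash_constraint_term(ont, cfg$quan_thresh) +
    hash_constraint_term(que, cfg$quan_thresh)
}

#' Bit-balance loss
#'
#' Penalizes codes whose mean component drifts from 0.5, encouraging each
#' bit to be 0 or 1 with equal probability:
#' `(mean(ont) - 0.5)^2 + (mean(que) - 0.5)^2`.
#'
#' @param ont,que Relaxed codes (numeric vectors of equal length).
#' @return Non-negative scalar in \[0, 0.5\].
#' @export
bit_balance_loss <- function(ont, que) {
  stopifnot(length(ont) == length(que))
  (mean(ont) - 0.5)^2 + (mean(que) - 0.5)^2
}

#' Weighted total training loss
#'
#' `lambda_d * ld + lambda_h * lh + lambda_b * lb` with the weights taken
#' from `cfg` (defaults 1, 1, 2/N).
#'
#' @param ld,lh,lb Discrimination, hash-constraint and bit-balance loss
#'   values.
#' @param cfg A [loss_config()].
#' @return Scalar total loss.
#' @export
total_loss <- function(ld, lh, lb, cfg = loss_config()) {
  stopifnot(ld >= 0, lh >= 0, lb >= 0)
  cfg$lambda_d * ld + cfg$lambda_h * lh + cfg$lambda_b * lb
}

#' All loss components for one pair of relaxed codes
#'
#' Convenience wrapper computing the Manhattan distance and the three loss
#' components plus their weighted total for a single (ontic, query, label)
#' triple.
#'
#' @param ont,que Relaxed codes.
#' @param label 0/1 interaction label.
#' @param cfg A [loss_config()].
#' @return Named list: `dist`, `ld`, `lh`, `lb`, `total`.
#' @export
pair_loss <- function(ont, que, label, cfg = loss_config(N = length(ont))) {
  d <- manhattan_dist(ont, que)
  ld <- discrimination_loss(d, label, cfg)
  lh <- hash_constraint_loss(ont, que, cfg)
  lb <- bit_balance_loss(ont, que)
  list(dist = d, ld = ld, lh = lh, lb = lb,
       total = total_loss(ld, lh, lb, cfg))
}
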