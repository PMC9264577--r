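#' Encoder architecture configuration
#'
#' Describes the deep-hash encoder: an embedding layer over the 21-token
#' alphabet (20 residues + padding), four convolution blocks
#' (convolution -> ReLU -> batch normalization -> pooling), two frozen
#' random projection heads (ontic and query) and a sigmoid range-control
#' output. The default block layout is 64/128/256/512 kernels of sizes
#' 5/7/9/15, stride 1, average pooling (global in the last block), with
#' 64-bit codes and input length 5000.
#'
#' @param L Input (padded) sequence length.
#' @param embed_dim Embedding dimensions per residue.
#' @param conv_blocks List of 4 block specs, each a list/vector with
#'   `n_kernels`, `kernel_size`, `pooling` (`"avg"` or `"global_avg"`),
#'   `stride` (must be 1). Kernel sizes must be odd (same-padding).
#' @param N Code width in bits.
#' @param d Hamming search threshold the codes are destined for; `2*d`
#'   must divide `N`. Set `NULL` to skip the check.
#' @param pool_window Average-pooling window (= stride) for the non-global
#'   blocks.
#' @param projection_seed_ontic,projection_seed_query Seeds for the two
#'   frozen projections; must differ.
#' @param rng_seed Seed for the trainable-parameter initialization.
#' @param mask_zero If `TRUE` the padding token embeds to the zero vector
#'   and receives no gradient; default keeps an ordinary learned row.
#' @param profile `"paper"` for the full-scale defaults above, or `"desk"`
#'   for a scaled-down profile (L = 512, embed_dim = 32, block widths
#'   16/32/32/192) suitable for CPU-only experimentation.
#' @return List of class `"encoder_config"`.
#' @export
encoder_config <- function(L = 5000L, embed_dim = 128L, conv_blocks = NULL,
                           N = 64L, d = 4L, pool_window = 2L,
                           projection_seed_ontic = 101L,
                           projection_seed_query = 202L,
                           rng_seed = 1L, mask_zero = FALSE,
                           profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    if (missing(L)) L <- 512L
    if (missing(embed_dim)) embed_dim <- 32L
    if (is.null(conv_blocks)) {
      # lean early blocks, wide final block: the final width is the input
      # dimension of the frozen projections, and aligning the two frozen
      # random heads needs head-space capacity more than trunk depth
      conv_blocks <- list(list(16L, 5L, "avg", 1L), list(32L, 7L, "avg", 1L),
                          list(32L, 9L, "avg", 1L),
                          list(192L, 15L, "global_avg", 1L))
    }
  }
  if (is.null(conv_blocks)) {
    conv_blocks <- list(list(64L, 5L, "avg", 1L), list(128L, 7L, "avg", 1L),
                        list(256L, 9L, "avg", 1L),
                        list(512L, 15L, "global_avg", 1L))
  }
  stopifnot(length(conv_blocks) >= 1L)
  channels <- vapply(conv_blocks, function(b) as.integer(b[[1L]]), integer(1))
  ksizes <- vapply(conv_blocks, function(b) as.integer(b[[2L]]), integer(1))
  pooling <- vapply(conv_blocks, function(b) as.character(b[[3L]]), character(1))
  strides <- vapply(conv_blocks, function(b) as.integer(b[[4L]]), integer(1))
  if (any(ksizes %% 2L == 0L)) stop("kernel sizes must be odd (same padding)")
  if (any(strides != 1L)) stop("convolution stride must be 1")
  if (any(!pooling %in% c("avg", "global_avg"))) {
    stop("pooling must be 'avg' or 'global_avg'")
  }
  if (pooling[length(pooling)] != "global_avg") {
    stop("the final block must use global average pooling")
  }
  if (any(pooling[-length(pooling)] == "global_avg")) {
    stop("only the final block may use global average pooling")
  }
  N <- as.integer(N)
  if (N < 1L) stop("N must be positive")
  if (!is.null(d)) {
    d <- as.integer(d)
    if (N %% (2L * d) != 0L) {
      stop("2d must divide N for downstream search: N = ", N, ", d = ", d)
    }
  }
  if (projection_seed_ontic == projection_seed_query) {
    stop("the two projection seeds must differ ",
         "(the ontic and query projections share no parameters)")
  }
  pool <- ifelse(pooling == "global_avg", 0L, as.integer(pool_window))
  structure(list(L = as.integer(L), embed_dim = as.integer(embed_dim),
                 channels = channels, ksizes = ksizes, pool = pool,
                 N = N, d = d,
                 projection_seed_ontic = as.integer(projection_seed_ontic),
                 projection_seed_query = as.integer(projection_seed_query),
                 rng_seed = as.integer(rng_seed),
                 mask_zero = isTRUE(mask_zero), profile = profile),
            class = "encoder_config")
}

#' @export
print.encoder_config <- function(x, ...) {
  cat("encoder_config (", x$profile, " profile): L=", x$L, ", embed_dim=",
      x$embed_dim, ", blocks=", paste(x$channels, collapse = "/"),
      " (k=", paste(x$ksizes, collapse = "/"), "), N=", x$N, " bits\n",
      sep = "")
  invisible(x)
}

glorot_limit <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

#' Build (initialize) an encoder
#'
#' Initializes all trainable parameters (embedding, convolutions,
#' batch-norm scales/offsets) from `rng_seed`, and the two frozen random
#' projections from their own seeds with a symmetric uniform distribution.
#' The trunk is shared between the ontic and query branches (Siamese); the
#' projections are never updated by training.
#'
#' @param config An [encoder_config()].
#' @return List of class `"encoder_state"` with elements `config` and
#'   `params` (named list of weight matrices/vectors, including the
#'   batch-norm running statistics `rm*`/`rv*`).
#' @export
build_encoder <- function(config = encoder_config()) {
  stopifnot(inherits(config, "encoder_config"))
  params <- list()
  with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  params <- with_seed(config$rng_seed, {
    p <- list(emb = matrix(runif(21L * config$embed_dim, -0.05, 0.05),
                           nrow = 21L))
    if (config$mask_zero) p$emb[1L, ] <- 0
    c_in <- config$embed_dim
    for (b in seq_along(config$channels)) {
      c_out <- config$channels[b]
      k <- config$ksizes[b]
      lim <- glorot_limit(k * c_in, c_out)
      p[[paste0("W", b)]] <- matrix(runif(k * c_in * c_out, -lim, lim),
                                    nrow = k * c_in, ncol = c_out)
      p[[paste0("b", b)]] <- numeric(c_out)
      p[[paste0("gamma", b)]] <- rep(1, c_out)
      p[[paste0("beta", b)]] <- numeric(c_out)
      p[[paste0("rm", b)]] <- numeric(c_out)
      p[[paste0("rv", b)]] <- rep(1, c_out)
      c_in <- c_out
    }
    p
  })
  c_last <- config$channels[length(config$channels)]
  lim <- glorot_limit(c_last, config$N)
  params$P_ont <- with_seed(config$projection_seed_ontic,
                            matrix(runif(c_last * config$N, -lim, lim),
                                   nrow = c_last, ncol = config$N))
  params$P_que <- with_seed(config$projection_seed_query,
                            matrix(runif(c_last * config$N, -lim, lim),
                                   nrow = c_last, ncol = config$N))
  structure(list(config = config, params = params), class = "encoder_state")
}

cpp_cfg <- function(config) {
  list(channels = config$channels, ksizes = config$ksizes,
       pool = config$pool, mask_zero = config$mask_zero)
}

#' Encode token sequences into relaxed (pre-binarization) codes
#'
#' Runs the trunk in inference mode (running batch-norm statistics) and the
#' requested frozen projection followed by the sigmoid range control. Every
#' output component lies strictly inside (0, 1); [binarize()] thresholds it
#' into the final hash code.
#'
#' @param state An `encoder_state` from [build_encoder()] or [train()].
#' @param tokens Integer token vector of length `L`, or a matrix with one
#'   sequence per row (rownames become code rownames).
#' @param role `"ontic"` (database side) or `"query"` (probe side).
#' @return Numeric matrix of relaxed codes (`n x N`), values in (0, 1).
#' @export
encode <- function(state, tokens, role = c("ontic", "query")) {
  role <- match.arg(role)
  if (!is.matrix(tokens)) tokens <- matrix(as.integer(tokens), nrow = 1L)
  if (ncol(tokens) != state$config$L) {
    stop("input length ", ncol(tokens), " != configured L = ", state$config$L)
  }
  storage.mode(tokens) <- "integer"
  out <- cpp_encode(tokens, state$params, cpp_cfg(state$config), role)
  rownames(out) <- rownames(tokens)
  out
}

#' Binarize a relaxed code into a hash code
#'
#' Component-wise threshold at 0.5 (inclusive: a component equal to 0.5
#' maps to 1).
#'
#' @param code Numeric vector or matrix of relaxed code(s).
#' @return 0/1 integer object of the same shape.
#' @export
binarize <- function(code) {
  out <- ifelse(code >= 0.5, 1L, 0L)
  if (is.matrix(code)) {
    out <- matrix(as.integer(out), nrow = nrow(code),
                  dimnames = dimnames(code))
  } else {
    out <- as.integer(out)
  }
  out
}

#' Encode and binarize a whole protein set
#'
#' @param state An `encoder_state`.
#' @param tokens Token matrix (one protein per row, rownames = ids).
#' @param role `"ontic"` or `"query"`.
#' @param batch_size Sequences per forward pass.
#' @return 0/1 integer matrix of hash codes with the input rownames.
#' @export
encode_database <- function(state, tokens, role = c("ontic", "query"),
                            batch_size = 256L) {
  role <- match.arg(role)
  n <- nrow(tokens)
  out <- matrix(0L, nrow = n, ncol = state$config$N,
                dimnames = list(rownames(tokens), NULL))
  for (start in seq(1L, max(n, 1L), by = batch_size)) {
    if (start > n) break
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- binarize(encode(state, tokens[idx, , drop = FALSE], role))
  }
  out
}

#' Save / load an encoder checkpoint
#'
#' Checkpoints are versioned JSON text files holding the full configuration
#' (including both projection seeds) and every parameter, so codes are
#' reproducible across sessions.
#'
#' @param state An `encoder_state`.
#' @param path Output path.
#' @return `save_encoder` returns `path` invisibly; `load_encoder` returns
#'   the restored `encoder_state`.
#' @export
save_encoder <- function(state, path) {
  payload <- list(
    format = "dhlppi-encoder", version = 1L,
    config = unclass(state$config),
    params = lapply(state$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = NULL, data = as.vector(p))
    })
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyVector = TRUE)
  if (!identical(payload$format, "dhlppi-encoder")) {
    stop("not a dhlppi encoder checkpoint: ", path)
  }
  cfg <- payload$config
  config <- structure(list(
    L = as.integer(cfg$L), embed_dim = as.integer(cfg$embed_dim),
    channels = as.integer(cfg$channels), ksizes = as.integer(cfg$ksizes),
    pool = as.integer(cfg$pool), N = as.integer(cfg$N),
    d = if (is.null(cfg$d)) NULL else as.integer(cfg$d),
    projection_seed_ontic = as.integer(cfg$projection_seed_ontic),
    projection_seed_query = as.integer(cfg$projection_seed_query),
    rng_seed = as.integer(cfg$rng_seed),
    mask_zero = isTRUE(cfg$mask_zero),
    profile = as.character(cfg$profile)), class = "encoder_config")
  params <- lapply(payload$params, function(p) {
    if (is.null(p$dim)) as.numeric(p$data)
    else matrix(as.numeric(p$data), nrow = p$dim[1L], ncol = p$dim[2L])
  })
  structure(list(config = config, params = params), class = "encoder_state")
}
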