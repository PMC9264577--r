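# Shared fixtures: a tiny encoder configuration that exercises all four
# blocks in well under a second, and small text-file helpers.

tiny_encoder_config <- function(rng_seed = 7L, N = 16L, d = 2L, L = 32L,
                                mask_zero = FALSE) {
  encoder_config(
    L = L, embed_dim = 6L,
    conv_blocks = list(list(4L, 3L, "avg", 1L), list(5L, 3L, "avg", 1L),
                       list(6L, 3L, "avg", 1L),
                       list(8L, 3L, "global_avg", 1L)),
    N = N, d = d, rng_seed = rng_seed, mask_zero = mask_zero)
}

random_tokens <- function(n, L, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:20, n * L, replace = TRUE), nrow = n,
         dimnames = list(sprintf("s%02d", seq_len(n)), NULL))
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
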