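#' Transformer encoder specification
#'
#' The shared encoder that feeds every predictor head: learned token and
#' position embeddings followed by `n_layers` post-norm transformer blocks
#' (multi-head self-attention, residual + layer norm, position-wise
#' feed-forward, residual + layer norm). The desk-scale default is a small
#' encoder trained from scratch (2 layers, width 128, 4 heads); at full
#' scale the same architecture contract is filled by a pretrained biomedical
#' encoder that is fine-tuned (see [full_scale_config()]).
#'
#' @param vocab_size sub-word vocabulary size.
#' @param max_len maximum tokens per window (default 512).
#' @param d_model embedding width.
#' @param n_layers number of transformer blocks.
#' @param n_heads attention heads (must divide `d_model`).
#' @param d_ff feed-forward width (default `2 * d_model`).
#' @return a list understood by the compiled encoder kernels.
#' @export
fg_encoder_spec <- function(vocab_size, max_len = 512L, d_model = 128L,
                            n_layers = 2L, n_heads = 4L,
                            d_ff = 2L * d_model) {
  stopifnot(d_model %% n_heads == 0, vocab_size >= 1)
  list(vocab_size = as.integer(vocab_size), max_len = as.integer(max_len),
       d_model = as.integer(d_model), n_layers = as.integer(n_layers),
       n_heads = as.integer(n_heads), d_ff = as.integer(d_ff))
}

# flat-parameter layout, mirrored by the compiled code (checked in tests
# against cpp_encoder_param_count)
encoder_layout <- function(spec) {
  d <- spec$d_model; f <- spec$d_ff
  pieces <- list(E = c(spec$vocab_size, d), P = c(spec$max_len, d))
  for (l in seq_len(spec$n_layers)) {
    lay <- list(Wq = c(d, d), bq = c(1, d), Wk = c(d, d), bk = c(1, d),
                Wv = c(d, d), bv = c(1, d), Wo = c(d, d), bo = c(1, d),
                g1 = c(1, d), be1 = c(1, d),
                W1 = c(d, f), b1 = c(1, f), W2 = c(f, d), b2 = c(1, d),
                g2 = c(1, d), be2 = c(1, d))
    names(lay) <- paste0("L", l, ".", names(lay))
    pieces <- c(pieces, lay)
  }
  pieces
}

# N(0, 0.02) weights, zero biases, unit layer-norm gains; uses the current
# RNG state (caller seeds)
init_encoder_params <- function(spec) {
  pieces <- encoder_layout(spec)
  unlist(lapply(names(pieces), function(nm) {
    dim <- pieces[[nm]]
    n <- prod(dim)
    base <- sub("^L[0-9]+\\.", "", nm)
    if (base %in% c("g1", "g2")) rep(1, n)
    else if (startsWith(base, "b")) rep(0, n)   # biases and layer-norm shifts
    else stats::rnorm(n, sd = 0.02)             # embeddings and weight matrices
  }), use.names = FALSE)
}

#' Token embeddings from a parameter vector
#'
#' Runs the encoder forward pass only, returning one `d_model`-dimensional
#' embedding per token. Deterministic given weights and input; output length
#' equals input length.
#'
#' @param theta flat parameter vector (encoder parameters first).
#' @param spec an [fg_encoder_spec()].
#' @param token_ids integer vector of 1-based token ids.
#' @return numeric matrix, one row per token.
#' @export
fg_encode_tokens <- function(theta, spec, token_ids) {
  cpp_encode(theta, spec, as.integer(token_ids))
}

# label-space sizes of the five tagging heads, in the fg_label_spaces order
tagging_head_sizes <- function(schema = fg_schema()) {
  vapply(fg_label_spaces(schema), length, integer(1))
}
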