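# Joint event embedding: the sum of (1) a linear embedding of [time, value
# features], (2) a variable-id lookup embedding, and (3) a parameter-free
# sinusoidal encoding of the dense-rank position. Special tokens (static slot,
# task tokens) receive a zero positional component; the static slot's
# embedding is produced by a small fully-connected network over the static
# vector instead of the token embedder.

#' Sinusoidal positional encoding
#'
#' Standard interleaved sin/cos table: for dimension pair `i`
#' (0-based), `PE[pos, 2i+1] = sin(pos / 10000^(2i/d))` and
#' `PE[pos, 2i+2] = cos(pos / 10000^(2i/d))`. Deterministic and
#' parameter-free; equal positions map to identical vectors.
#'
#' @param positions non-negative integer vector.
#' @param d embedding width (even).
#' @return `length(positions) x d` matrix.
#' @export
sinusoidal_encoding <- function(positions, d) {
  if (any(positions < 0)) {
    stop("sinusoidal_encoding: positions must be non-negative", call. = FALSE)
  }
  if (d %% 2L != 0L) {
    stop("sinusoidal_encoding: d must be even", call. = FALSE)
  }
  i <- seq_len(d %/% 2L) - 1L
  freq <- 1 / 10000^(2 * i / d)
  ang <- outer(positions, freq)
  out <- matrix(0, length(positions), d)
  out[, seq(1L, d, by = 2L)] <- sin(ang)
  out[, seq(2L, d, by = 2L)] <- cos(ang)
  out
}

# parameter initialization -----------------------------------------------

.init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize embedding parameters
#'
#' @param d hidden size (even).
#' @param vocab_size total id count (reserved + variables).
#' @param static_dim width of the processed static vector.
#' @param static_hidden hidden width of the 2-layer static encoder.
#' @param discrete_only if `TRUE`, the value-feature block is omitted from the
#'   fully-connected embedding input (time is retained).
#' @param seed RNG seed for initialization.
#' @return named list of numeric parameter matrices.
#' @export
init_embedding_params <- function(d, vocab_size, static_dim,
                                  static_hidden = 2L * d,
                                  discrete_only = FALSE, seed = 1L) {
  set.seed(seed)
  in_dim <- if (discrete_only) 1L else 10L
  list(
    emb.W_fc = .init_mat(in_dim, d), emb.b_fc = matrix(0, 1L, d),
    emb.E_id = .init_mat(vocab_size, d),
    emb.Ws1 = .init_mat(static_dim, static_hidden),
    emb.bs1 = matrix(0, 1L, static_hidden),
    emb.Ws2 = .init_mat(static_hidden, d),
    emb.bs2 = matrix(0, 1L, d)
  )
}

# static encoder: 2-layer MLP with GELU nonlinearity
.embed_static_node <- function(pn, static_vec) {
  x <- ag_const(matrix(static_vec, 1L))
  h <- ag_gelu(ag_linear(x, pn$emb.Ws1, pn$emb.bs1))
  ag_linear(h, pn$emb.Ws2, pn$emb.bs2)
}

# full joint embedding of an assembled sequence -> n x d autodiff node.
# Special and padding rows get zero positional encoding; the static slot row
# is replaced by the static encoder's output.
.embed_sequence_node <- function(pn, seq, d, discrete_only, training = FALSE,
                                 dropout = 0) {
  n <- length(seq$f)
  X_in <- if (discrete_only) {
    matrix(seq$t, ncol = 1L)
  } else {
    cbind(seq$t, seq$V)
  }
  pe <- sinusoidal_encoding(seq$p, d)
  pe[seq$special | seq$pad, ] <- 0
  emb <- ag_add(ag_linear(ag_const(X_in), pn$emb.W_fc, pn$emb.b_fc),
                ag_lookup(pn$emb.E_id, seq$f + 1L))
  emb <- ag_addc(emb, pe)
  s_emb <- .embed_static_node(pn, seq$static)
  out <- ag_rbind(list(s_emb, ag_rows(emb, 2:n)))
  ag_dropout(out, dropout, training)
}

#' Embed an assembled sequence (numeric interface)
#'
#' Convenience wrapper evaluating the joint embedding without gradients:
#' per token, `FC([t, v1..v9]) + lookup[f] + sinusoid[p]`, with the static
#' slot replaced by the static-network output.
#'
#' @param params named list of embedding parameters
#'   (from [init_embedding_params()] or a fitted model).
#' @param seq an `assembled_seq`.
#' @param d hidden size.
#' @param discrete_only drop the value-feature block from the FC input.
#' @return `n x d` numeric matrix.
#' @export
embed_tokens <- function(params, seq, d, discrete_only = FALSE) {
  if (max(seq$f) + 1L > nrow(params$emb.E_id)) {
    stop("embed_tokens: variable id outside the embedding table",
         call. = FALSE)
  }
  pn <- lapply(params, ag_param)
  ag_val(.embed_sequence_node(pn, seq, d, discrete_only))
}

#' Embed a static vector (numeric interface)
#'
#' @param params embedding parameter list.
#' @param static_vec processed static vector.
#' @return `1 x d` numeric matrix.
#' @export
embed_static <- function(params, static_vec) {
  if (length(static_vec) != nrow(params$emb.Ws1)) {
    stop("embed_static: static vector width mismatch", call. = FALSE)
  }
  pn <- lapply(params, ag_param)
  ag_val(.embed_static_node(pn, static_vec))
}
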