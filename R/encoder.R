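# Sliding-window / global-attention transformer encoder with per-task linear
# heads reading the concatenation of each layer's task-token representation.
#
# Layers use a pre-norm residual layout with a GELU feedforward. The sliding
# window is interpreted as a total width (floor(window/2) positions on each
# side). At the scales this package targets, attention is computed densely
# under the equivalent boolean mask; banded computation is an optimization,
# not a semantic.

#' Transformer encoder configuration
#'
#' The reference configuration mirrors a small Longformer-style encoder:
#' 8 layers, hidden 128, feedforward 512, 8 heads, sliding window 128,
#' dropout 0.1. Reduced configurations (e.g. hidden 32, 2 layers) are used
#' for desk-scale experiments.
#'
#' @param layers encoder depth.
#' @param hidden hidden size (divisible by `heads`, even).
#' @param feedforward feedforward width.
#' @param heads attention heads.
#' @param window total sliding-window width (`floor(window/2)` each side).
#' @param dropout dropout rate applied after the embedding sum, attention
#'   output and feedforward output.
#' @param n_tasks number of prediction heads (7).
#' @param ln_eps layer-norm epsilon.
#' @return a `model_config` list.
#' @export
model_config <- function(layers = 8L, hidden = 128L, feedforward = 512L,
                         heads = 8L, window = 128L, dropout = 0.1,
                         n_tasks = N_TASK_TOKENS, ln_eps = 1e-5) {
  stopifnot(hidden %% heads == 0L, hidden %% 2L == 0L, window >= 1L,
            layers >= 1L)
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 feedforward = as.integer(feedforward),
                 heads = as.integer(heads), window = as.integer(window),
                 dropout = dropout, n_tasks = as.integer(n_tasks),
                 ln_eps = ln_eps),
            class = "model_config")
}

#' Initialize transformer parameters (embedding + encoder + heads)
#'
#' @param cfg a [model_config()].
#' @param vocab_size embedding-table size.
#' @param static_dim processed static vector width.
#' @param discrete_only omit value features from the embedding FC input.
#' @param seed RNG seed.
#' @return named list of numeric matrices.
#' @export
init_transformer_params <- function(cfg, vocab_size, static_dim,
                                    discrete_only = FALSE, seed = 1L) {
  p <- init_embedding_params(cfg$hidden, vocab_size, static_dim,
                             static_hidden = 2L * cfg$hidden,
                             discrete_only = discrete_only, seed = seed)
  d <- cfg$hidden
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("L%d.", l)
    p[[paste0(pre, "Wq")]] <- .init_mat(d, d)
    p[[paste0(pre, "Wk")]] <- .init_mat(d, d)
    p[[paste0(pre, "Wv")]] <- .init_mat(d, d)
    p[[paste0(pre, "Wo")]] <- .init_mat(d, d)
    p[[paste0(pre, "bq")]] <- matrix(0, 1L, d)
    p[[paste0(pre, "bk")]] <- matrix(0, 1L, d)
    p[[paste0(pre, "bv")]] <- matrix(0, 1L, d)
    p[[paste0(pre, "bo")]] <- matrix(0, 1L, d)
    p[[paste0(pre, "ln1_g")]] <- matrix(1, 1L, d)
    p[[paste0(pre, "ln1_b")]] <- matrix(0, 1L, d)
    p[[paste0(pre, "ln2_g")]] <- matrix(1, 1L, d)
    p[[paste0(pre, "ln2_b")]] <- matrix(0, 1L, d)
    p[[paste0(pre, "W1")]] <- .init_mat(d, cfg$feedforward)
    p[[paste0(pre, "b1")]] <- matrix(0, 1L, cfg$feedforward)
    p[[paste0(pre, "W2")]] <- .init_mat(cfg$feedforward, d)
    p[[paste0(pre, "b2")]] <- matrix(0, 1L, d)
  }
  for (j in seq_len(cfg$n_tasks)) {
    p[[sprintf("head%d.W", j)]] <- .init_mat(cfg$layers * d, 1L)
    p[[sprintf("head%d.b", j)]] <- matrix(0, 1L, 1L)
  }
  p
}

#' Additive attention mask for sliding-window + global attention
#'
#' Entry `[i, j]` is 0 where query `i` may attend key `j` and `-Inf`
#' otherwise. A non-global query attends keys within `floor(window/2)`
#' positions on either side plus all global tokens; global queries attend
#' every non-padding position. Padding keys are excluded everywhere and
#' padding queries attend nothing.
#'
#' @param n sequence length.
#' @param window total window width.
#' @param global_idx indices of global-attention tokens.
#' @param pad_idx indices of padding positions.
#' @return `n x n` numeric matrix of 0 / `-Inf`.
#' @export
build_attention_mask <- function(n, window, global_idx = integer(),
                                 pad_idx = integer()) {
  half <- window %/% 2L
  idx <- seq_len(n)
  allowed <- abs(outer(idx, idx, "-")) <= half
  if (length(global_idx)) {
    allowed[global_idx, ] <- TRUE
    allowed[, global_idx] <- TRUE
  }
  if (length(pad_idx)) {
    allowed[pad_idx, ] <- FALSE
    allowed[, pad_idx] <- FALSE
  }
  ifelse(allowed, 0, -Inf)
}

# one multi-head attention block on an autodiff node (n x d)
.attention_node <- function(pn, x, prefix, mask, cfg, training) {
  d <- cfg$hidden
  dh <- d %/% cfg$heads
  Q <- ag_linear(x, pn[[paste0(prefix, "Wq")]], pn[[paste0(prefix, "bq")]])
  K <- ag_linear(x, pn[[paste0(prefix, "Wk")]], pn[[paste0(prefix, "bk")]])
  V <- ag_linear(x, pn[[paste0(prefix, "Wv")]], pn[[paste0(prefix, "bv")]])
  outs <- vector("list", cfg$heads)
  for (h in seq_len(cfg$heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ag_cols(Q, cols); Kh <- ag_cols(K, cols); Vh <- ag_cols(V, cols)
    scores <- ag_mulc(ag_matmul(Qh, ag_transpose(Kh)), 1 / sqrt(dh))
    A <- ag_softmax_rows(scores, mask)
    outs[[h]] <- ag_matmul(A, Vh)
  }
  H <- ag_cbind(outs)
  out <- ag_linear(H, pn[[paste0(prefix, "Wo")]], pn[[paste0(prefix, "bo")]])
  ag_dropout(out, cfg$dropout, training)
}

#' Sliding-window + global multi-head attention (numeric interface)
#'
#' Applies one attention block (no residual/normalization) to a state matrix
#' under the sliding-window/global/padding mask. Used directly in tests
#' against a dense masked-attention oracle.
#'
#' @param states `n x hidden` numeric matrix.
#' @param params parameter list containing `L<layer>.Wq` etc.
#' @param cfg a [model_config()].
#' @param layer which layer's projection weights to use.
#' @param global_idx,pad_idx mask inputs, see [build_attention_mask()].
#' @return `n x hidden` numeric matrix.
#' @export
sliding_global_attention <- function(states, params, cfg, layer = 1L,
                                     global_idx = integer(),
                                     pad_idx = integer()) {
  mask <- build_attention_mask(nrow(states), cfg$window, global_idx, pad_idx)
  pn <- lapply(params, ag_param)
  ag_val(.attention_node(pn, ag_const(states), sprintf("L%d.", layer), mask,
                         cfg, training = FALSE))
}

# full encoder pass for one assembled sequence.
# Returns the per-task logits node (1 x n_tasks).
.transformer_logits_node <- function(pn, seq, cfg, discrete_only, training) {
  n <- length(seq$f)
  x <- .embed_sequence_node(pn, seq, cfg$hidden, discrete_only,
                            training, cfg$dropout)
  mask <- build_attention_mask(n, cfg$window, which(seq$global),
                               which(seq$pad))
  layer_outs <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("L%d.", l)
    a_in <- ag_layernorm(x, pn[[paste0(pre, "ln1_g")]],
                         pn[[paste0(pre, "ln1_b")]], cfg$ln_eps)
    x <- ag_add(x, .attention_node(pn, a_in, pre, mask, cfg, training))
    f_in <- ag_layernorm(x, pn[[paste0(pre, "ln2_g")]],
                         pn[[paste0(pre, "ln2_b")]], cfg$ln_eps)
    ff <- ag_linear(ag_gelu(ag_linear(f_in, pn[[paste0(pre, "W1")]],
                                      pn[[paste0(pre, "b1")]])),
                    pn[[paste0(pre, "W2")]], pn[[paste0(pre, "b2")]])
    x <- ag_add(x, ag_dropout(ff, cfg$dropout, training))
    layer_outs[[l]] <- x
  }
  logits <- vector("list", cfg$n_tasks)
  for (j in seq_len(cfg$n_tasks)) {
    rep_j <- ag_cbind(lapply(layer_outs, function(h) ag_rows(h, 1L + j)))
    logits[[j]] <- ag_linear(rep_j, pn[[sprintf("head%d.W", j)]],
                             pn[[sprintf("head%d.b", j)]])
  }
  ag_cbind(logits)
}

#' Transformer forward pass over assembled sequences (numeric interface)
#'
#' Evaluation-mode forward (no dropout): embedding, encoder layers, and one
#' logit per task from each task token's per-layer concatenation.
#'
#' @param params parameter list from [init_transformer_params()] or a fitted
#'   model.
#' @param sequences list of `assembled_seq` (may be padded).
#' @param cfg a [model_config()].
#' @param discrete_only use the discrete-only embedding variant.
#' @return `length(sequences) x n_tasks` matrix of logits.
#' @export
transformer_forward <- function(params, sequences, cfg,
                                discrete_only = FALSE) {
  pn <- lapply(params, ag_param)
  out <- matrix(NA_real_, length(sequences), cfg$n_tasks,
                dimnames = list(NULL, all_tasks()[seq_len(cfg$n_tasks)]))
  for (i in seq_along(sequences)) {
    out[i, ] <- ag_val(.transformer_logits_node(pn, sequences[[i]], cfg,
                                                discrete_only,
                                                training = FALSE))
  }
  out
}
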