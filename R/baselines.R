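# Comparison models: hourly-resampled GRU (with and without an additive
# attention readout), a tokenized GRU+attention reusing the joint embedding,
# and gradient-boosted-tree adapters on flattened per-stay features.

#' Resample one stay's events to an hourly multivariate series
#'
#' Half-open bins `[k, k+1)` hours; within-bin mean; empty bins are
#' forward-filled from the last observed bin; bins before the first
#' observation (and variables never observed in the stay) are imputed with
#' the training-cohort median. Values are standardized per variable with the
#' training mean/scale of the current-value feature.
#'
#' @param events one stay's event table.
#' @param variables character vector fixing the column order across the
#'   cohort (typically `vocab$variables$variable`).
#' @param artifacts a `fit_artifacts`.
#' @param los_hours stay length; the series has `max(1, ceiling(los))` rows.
#' @return `hours x variables` numeric matrix with no missing cells.
#' @export
resample_hourly <- function(events, variables, artifacts, los_hours) {
  n_bins <- max(1L, ceiling(los_hours))
  out <- matrix(NA_real_, n_bins, length(variables),
                dimnames = list(NULL, variables))
  for (v in variables) {
    sel <- events$variable == v
    if (any(sel)) {
      bins <- pmin(floor(events$time_hours[sel]), n_bins - 1L) + 1L
      means <- tapply(events$value[sel], bins, mean)
      out[as.integer(names(means)), v] <- means
    }
    col <- out[, v]
    # forward fill, then training-median backfill for leading gaps
    last_obs <- cumsum(!is.na(col))
    col <- c(NA_real_, col[!is.na(col)])[last_obs + 1L]
    st <- artifacts$var_stats[[v]]
    med <- if (is.null(st)) 0 else st$raw_median
    col[is.na(col)] <- med
    if (!is.null(st)) {
      col <- (col - st$mean[["value"]]) / st$scale[["value"]]
      if (st$degenerate[[1L]]) col[] <- 0
    }
    out[, v] <- col
  }
  out
}

#' Initialize GRU baseline parameters
#'
#' @param input_dim per-step input width (number of variables, or the
#'   embedding width for the tokenized variant).
#' @param hidden GRU hidden size.
#' @param static_dim processed static vector width.
#' @param n_tasks number of output logits.
#' @param attention include additive-attention readout parameters.
#' @param mlp_hidden width of the post-concatenation fully-connected layer.
#' @param seed RNG seed.
#' @return named list of numeric matrices.
#' @export
init_gru_params <- function(input_dim, hidden, static_dim,
                            n_tasks = N_TASK_TOKENS, attention = FALSE,
                            mlp_hidden = 2L * hidden, seed = 1L) {
  set.seed(seed)
  sc <- 1 / sqrt(hidden)
  p <- list(
    gru.Wx = .init_mat(input_dim, 3L * hidden, sc),
    gru.bx = matrix(0, 1L, 3L * hidden),
    gru.Uz = .init_mat(hidden, hidden, sc),
    gru.Ur = .init_mat(hidden, hidden, sc),
    gru.Un = .init_mat(hidden, hidden, sc),
    out.W1 = .init_mat(hidden + static_dim, mlp_hidden, 0.05),
    out.b1 = matrix(0, 1L, mlp_hidden),
    out.W2 = .init_mat(mlp_hidden, n_tasks, 0.05),
    out.b2 = matrix(0, 1L, n_tasks)
  )
  if (attention) {
    p$att.Wa <- .init_mat(hidden, hidden, sc)
    p$att.ba <- matrix(0, 1L, hidden)
    p$att.v <- .init_mat(hidden, 1L, sc)
  }
  p
}

# GRU recurrence over the rows of an autodiff node X (T x k).
# Returns list(final = 1 x h node, states = T x h node).
.gru_scan_node <- function(pn, x_node, hidden) {
  XW <- ag_linear(x_node, pn$gru.Wx, pn$gru.bx)
  n_steps <- nrow(ag_val(x_node))
  h <- ag_const(matrix(0, 1L, hidden))
  states <- vector("list", n_steps)
  iz <- seq_len(hidden)
  ir <- hidden + iz
  inn <- 2L * hidden + iz
  for (s in seq_len(n_steps)) {
    row <- ag_rows(XW, s)
    z <- ag_sigmoid(ag_add(ag_cols(row, iz), ag_matmul(h, pn$gru.Uz)))
    r <- ag_sigmoid(ag_add(ag_cols(row, ir), ag_matmul(h, pn$gru.Ur)))
    nn <- ag_tanh(ag_add(ag_cols(row, inn),
                         ag_emul(r, ag_matmul(h, pn$gru.Un))))
    one_minus_z <- ag_addc(ag_mulc(z, -1), 1)
    h <- ag_add(ag_emul(one_minus_z, nn), ag_emul(z, h))
    states[[s]] <- h
  }
  list(final = h, states = ag_rbind(states))
}

# additive attention readout: softmax(v' tanh(Wa H + ba)) weighted state sum
.gru_attention_node <- function(pn, states_node) {
  e <- ag_matmul(ag_tanh(ag_linear(states_node, pn$att.Wa, pn$att.ba)),
                 pn$att.v)
  alpha <- ag_softmax_rows(ag_transpose(e))
  list(context = ag_matmul(alpha, states_node), weights = alpha)
}

# sequence representation -> logits: concat static, 2-layer MLP
.gru_readout_node <- function(pn, rep_node, static_vec) {
  x <- ag_cbind(list(rep_node, ag_const(matrix(static_vec, 1L))))
  h <- ag_gelu(ag_linear(x, pn$out.W1, pn$out.b1))
  ag_linear(h, pn$out.W2, pn$out.b2)
}

.gru_logits_node <- function(pn, series, static_vec, hidden, attention) {
  scan <- .gru_scan_node(pn, ag_const(series), hidden)
  rep_node <- if (attention) {
    .gru_attention_node(pn, scan$states)$context
  } else {
    scan$final
  }
  .gru_readout_node(pn, rep_node, static_vec)
}

#' GRU forward pass (numeric interface)
#'
#' Final-hidden-state readout concatenated with the static vector and passed
#' through fully-connected layers to one logit per task.
#'
#' @param params from [init_gru_params()].
#' @param series `T x k` input matrix (e.g. from [resample_hourly()]).
#' @param static_vec processed static vector.
#' @param hidden GRU hidden size.
#' @return `1 x n_tasks` logit matrix.
#' @export
gru_forward <- function(params, series, static_vec, hidden) {
  pn <- lapply(params, ag_param)
  ag_val(.gru_logits_node(pn, series, static_vec, hidden, attention = FALSE))
}

#' GRU-with-attention forward pass (numeric interface)
#'
#' Hidden states are weighted by softmax-normalized additive alignment
#' scores and summed into the sequence representation.
#'
#' @inheritParams gru_forward
#' @param return_weights also return the attention weights.
#' @return `1 x n_tasks` logit matrix, or a list with `logits` and `weights`.
#' @export
gru_attention_forward <- function(params, series, static_vec, hidden,
                                  return_weights = FALSE) {
  pn <- lapply(params, ag_param)
  scan <- .gru_scan_node(pn, ag_const(series), hidden)
  att <- .gru_attention_node(pn, scan$states)
  logits <- ag_val(.gru_readout_node(pn, att$context, static_vec))
  if (return_weights) {
    list(logits = logits, weights = as.numeric(ag_val(att$weights)))
  } else {
    logits
  }
}

#' Flatten a tokenized stay into a fixed-width tree-model feature vector
#'
#' Layout: processed static vector, then one 10-wide block per vocabulary
#' variable: the variable's final cumulative 8-vector, its last standardized
#' value, and a presence flag. Variables absent from the stay contribute a
#' zero block with presence 0.
#'
#' @param tok_stay a tokenized stay (fields `static`, `tokens`).
#' @param vocab a `vocab_map`.
#' @return named numeric vector of width `static + 10 * n_variables`.
#' @export
flatten_for_trees <- function(tok_stay, vocab) {
  toks <- tok_stay$tokens
  blocks <- lapply(seq_len(nrow(vocab$variables)), function(i) {
    vid <- vocab$variables$id[i]
    vname <- vocab$variables$variable[i]
    rows <- which(toks[, "f"] == vid)
    block <- if (length(rows)) {
      last <- toks[rows[length(rows)], , drop = TRUE]
      c(last[5:12], last[["value"]], 1)
    } else {
      c(rep(0, 9L), 0)
    }
    names(block) <- paste0(vname, ".", c(.value_feature_names[2:9],
                                         "last_value", "present"))
    block
  })
  c(tok_stay$static, unlist(blocks))
}
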