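# Shared fixtures: small cohorts and an independent dense-attention oracle.

icuseq_ns <- asNamespace("icuseq")

# internal accessors used by white-box tests
.transformer_logits_node <- get(".transformer_logits_node", icuseq_ns)
.sample_labels <- get(".sample_labels", icuseq_ns)
ag_param <- get("ag_param", icuseq_ns)
ag_const <- get("ag_const", icuseq_ns)
ag_val <- get("ag_val", icuseq_ns)
ag_backward <- get("ag_backward", icuseq_ns)
ag_bce_logits <- get("ag_bce_logits", icuseq_ns)

small_cohort <- function(n_patients = 30L, seed = 1L, ...) {
  generate_cohort(sim_config(n_patients = n_patients, seed = seed, ...))
}

# vocabulary, artifacts, tokenized stays and assembled sequences in one go
small_pipeline <- function(cohort) {
  ev <- cohort_events(cohort)
  vocab <- build_vocab(ev, n_stays = length(cohort$stays))
  artifacts <- fit_transforms(cohort$stays, vocab)
  tok <- tokenize_cohort(cohort$stays, vocab, artifacts)
  seqs <- suppressWarnings(lapply(tok, assemble_sequence,
                                  artifacts = artifacts))
  list(vocab = vocab, artifacts = artifacts, tok = tok, seqs = seqs)
}

# independently coded dense masked multi-head attention:
# re-derives the attention pattern from its definition (window neighborhood,
# global tokens, padding) with explicit loops, then computes
# softmax(QK'/sqrt(dh) + mask) V per head and the output projection.
dense_attention_oracle <- function(states, params, cfg, layer = 1L,
                                   global_idx = integer(),
                                   pad_idx = integer()) {
  n <- nrow(states)
  d <- cfg$hidden
  dh <- d / cfg$heads
  half <- floor(cfg$window / 2)
  allowed <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      near <- abs(i - j) <= half
      glob <- (i %in% global_idx) || (j %in% global_idx)
      pad <- (i %in% pad_idx) || (j %in% pad_idx)
      allowed[i, j] <- (near || glob) && !pad
    }
  }
  pre <- sprintf("L%d.", layer)
  lin <- function(W, b) sweep(states %*% params[[paste0(pre, W)]], 2,
                              params[[paste0(pre, b)]][1, ], "+")
  Q <- lin("Wq", "bq"); K <- lin("Wk", "bk"); V <- lin("Wv", "bv")
  H <- matrix(0, n, d)
  for (h in seq_len(cfg$heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(n)) {
      js <- which(allowed[i, ])
      if (!length(js)) next
      sc <- (K[js, cols, drop = FALSE] %*% Q[i, cols]) / sqrt(dh)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      H[i, cols] <- t(V[js, cols, drop = FALSE]) %*% w
    }
  }
  sweep(H %*% params[[paste0(pre, "Wo")]], 2,
        params[[paste0(pre, "bo")]][1, ], "+")
}

# central-difference numeric gradient of f (scalar) wrt matrix x
numeric_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
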