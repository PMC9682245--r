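# Encoder: attention-mask semantics, dense-oracle equivalence, padding
# invariance, head wiring and gradient flow.

test_that("attention mask encodes window, global and padding semantics", {
  m <- build_attention_mask(6L, window = 1L, global_idx = 2L)
  # window 1: self only, except the global token's row/column
  expect_true(all(m[2, ] == 0))   # global attends everything
  expect_true(all(m[, 2] == 0))   # everything attends the global token
  expect_equal(m[5, 3], -Inf)     # distant non-global pair is masked
  expect_equal(m[3, 5], -Inf)
  expect_equal(m[4, 4], 0)
  # padding excluded everywhere
  mp <- build_attention_mask(5L, window = 10L, global_idx = 1L,
                             pad_idx = 5L)
  expect_true(all(mp[5, ] == -Inf))
  expect_true(all(mp[, 5] == -Inf))
})

test_that("sliding+global attention equals the dense masked oracle on random inputs", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:24, 1)
    heads <- sample(c(1L, 2L, 4L), 1)
    d <- heads * sample(c(2L, 4L), 1)
    window <- sample(1:8, 1)
    n_glob <- sample(0:3, 1)
    glob <- if (n_glob) sort(sample(n, n_glob)) else integer()
    cfg <- model_config(layers = 1L, hidden = d, feedforward = 2L * d,
                        heads = heads, window = window, dropout = 0)
    params <- init_transformer_params(cfg, vocab_size = 10L,
                                      static_dim = 3L, seed = rep)
    X <- matrix(rnorm(n * d), n, d)
    got <- sliding_global_attention(X, params, cfg, global_idx = glob)
    want <- dense_attention_oracle(X, params, cfg, global_idx = glob)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("length-one sequences reduce attention to the value path", {
  cfg <- model_config(layers = 1L, hidden = 8L, feedforward = 16L,
                      heads = 2L, window = 4L, dropout = 0)
  params <- init_transformer_params(cfg, 10L, 3L, seed = 1L)
  X <- matrix(rnorm(8), 1, 8)
  got <- sliding_global_attention(X, params, cfg)
  v <- sweep(X %*% params$L1.Wv, 2, params$L1.bv[1, ], "+")
  want <- sweep(v %*% params$L1.Wo, 2, params$L1.bo[1, ], "+")
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("forward emits 7 logits per stay from 1024-wide head inputs under the reference config", {
  cfg <- model_config()  # 8 layers x hidden 128
  expect_equal(cfg$layers * cfg$hidden, 1024L)
  co <- small_cohort(10L, seed = 10L)
  pipe <- small_pipeline(co)
  small_cfg <- model_config(layers = 2L, hidden = 16L, feedforward = 32L,
                            heads = 2L, window = 8L, dropout = 0)
  params <- init_transformer_params(small_cfg, vocab_size(pipe$vocab),
                                    length(pipe$tok[[1]]$static), seed = 4L)
  expect_equal(dim(params$head1.W),
               c(small_cfg$layers * small_cfg$hidden, 1L))
  logits <- transformer_forward(params, pipe$seqs[1:3], small_cfg)
  expect_equal(dim(logits), c(3L, 7L))
  expect_true(all(is.finite(logits)))
  expect_equal(colnames(logits), all_tasks())
})

test_that("logits are invariant to the amount of right padding", {
  co <- small_cohort(12L, seed = 11L)
  pipe <- small_pipeline(co)
  cfg <- model_config(layers = 2L, hidden = 16L, feedforward = 32L,
                      heads = 2L, window = 8L, dropout = 0)
  params <- init_transformer_params(cfg, vocab_size(pipe$vocab),
                                    length(pipe$tok[[1]]$static), seed = 6L)
  lens <- vapply(pipe$seqs, seq_length, 1L)
  i_short <- which.min(lens)
  alone <- transformer_forward(params, pipe$seqs[i_short], cfg)
  batched <- transformer_forward(params,
                                 pad_and_batch(pipe$seqs)[i_short], cfg)
  expect_lt(max(abs(alone - batched)), 1e-5)
})

test_that("with a full window, permuting same-timestamp events leaves logits unchanged", {
  co <- small_cohort(12L, seed = 13L, panel_prob = 0.8)
  pipe <- small_pipeline(co)
  cfg <- model_config(layers = 2L, hidden = 16L, feedforward = 32L,
                      heads = 2L, window = 2048L, dropout = 0)
  params <- init_transformer_params(cfg, vocab_size(pipe$vocab),
                                    length(pipe$tok[[1]]$static), seed = 8L)
  set.seed(99)
  tested <- 0L
  for (s in pipe$seqs) {
    grp <- split(which(!s$special), s$p[!s$special])
    grp <- Filter(function(g) length(g) > 1, grp)
    if (!length(grp)) next
    s2 <- s
    for (g in grp) {
      perm <- sample(g)
      s2$f[g] <- s2$f[perm]
      s2$t[g] <- s2$t[perm]
      s2$V[g, ] <- s2$V[perm, ]
    }
    l1 <- transformer_forward(params, list(s), cfg)
    l2 <- transformer_forward(params, list(s2), cfg)
    expect_lt(max(abs(l1 - l2)), 1e-5)
    tested <- tested + 1L
    if (tested >= 5L) break
  }
  expect_gt(tested, 0L)
})

test_that("discrete-only variant ignores values and has fewer embedding parameters", {
  co <- small_cohort(10L, seed = 14L)
  pipe <- small_pipeline(co)
  cfg <- model_config(layers = 1L, hidden = 8L, feedforward = 16L,
                      heads = 2L, window = 8L, dropout = 0)
  pd <- init_transformer_params(cfg, vocab_size(pipe$vocab),
                                length(pipe$tok[[1]]$static),
                                discrete_only = TRUE, seed = 2L)
  pf <- init_transformer_params(cfg, vocab_size(pipe$vocab),
                                length(pipe$tok[[1]]$static), seed = 2L)
  expect_lt(length(pd$emb.W_fc), length(pf$emb.W_fc))
  s <- pipe$seqs[[1]]
  s2 <- s
  s2$V[!s2$special, ] <- s2$V[!s2$special, ] + 3
  expect_equal(transformer_forward(pd, list(s), cfg, discrete_only = TRUE),
               transformer_forward(pd, list(s2), cfg, discrete_only = TRUE))
})

test_that("every task head receives gradient from its own loss term", {
  co <- small_cohort(10L, seed = 15L)
  pipe <- small_pipeline(co)
  cfg <- model_config(layers = 2L, hidden = 8L, feedforward = 16L,
                      heads = 2L, window = 8L, dropout = 0)
  params <- init_transformer_params(cfg, vocab_size(pipe$vocab),
                                    length(pipe$tok[[1]]$static), seed = 3L)
  s <- pipe$seqs[[1]]
  pn <- lapply(params, ag_param)
  loss <- ag_bce_logits(.transformer_logits_node(pn, s, cfg, FALSE, FALSE),
                        .sample_labels(s))
  ag_backward(loss)
  for (j in 1:7) {
    g <- pn[[sprintf("head%d.W", j)]]$grad
    expect_false(is.null(g))
    expect_gt(max(abs(g)), 0)
  }
  # encoder and embedding receive gradient too
  expect_gt(max(abs(pn$L1.Wq$grad)), 0)
  expect_gt(max(abs(pn$emb.W_fc$grad)), 0)
})
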