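# Model families behind a single split/train/evaluate path.
#
# Seven families reproduce the comparison grid: the full tokenized
# transformer, its discrete-only variant, a GRU and GRU+attention on hourly
# resampled series, a tokenized GRU+attention reusing the joint embedding,
# and two gradient-boosted-tree adapters on flattened features (plain
# gradient boosting and a DART-booster variant standing in for a second
# boosting library).

#' Supported model family names
#'
#' The full tokenized transformer, its discrete-only variant, resampled GRU
#' with and without attention, tokenized GRU+attention, and two boosted-tree
#' adapters.
#' @export
ACUITY_FAMILIES <- c("longformer", "longformer_discrete", "gru",
                     "gru_attention", "gru_attention_tokenized",
                     "xgb", "xgb_dart")

.family_data_label <- c(
  longformer = "Tokenized events + continuous measurement values",
  longformer_discrete = "Tokenized events (discrete only)",
  gru = "Resampled multivariate time series",
  gru_attention = "Resampled multivariate time series",
  gru_attention_tokenized = "Tokenized events + continuous measurement values",
  xgb = "Tokenized events + continuous measurement values",
  xgb_dart = "Tokenized events + continuous measurement values")

#' Construct an (unfitted) acuity model
#'
#' @param family one of `"longformer"`, `"longformer_discrete"`, `"gru"`,
#'   `"gru_attention"`, `"gru_attention_tokenized"`, `"xgb"`, `"xgb_dart"`.
#' @param encoder_cfg a [model_config()] (transformer families).
#' @param gru_hidden GRU hidden size (GRU families).
#' @param emb_dim embedding width for the tokenized GRU variant.
#' @param tree_params named list of xgboost parameter overrides.
#' @param nrounds boosting rounds (tree families).
#' @param seed initialization seed.
#' @return an `acuity_model` object (S3 class `c(family, "acuity_model")`).
#' @export
acuity_model <- function(family = ACUITY_FAMILIES,
                         encoder_cfg = model_config(),
                         gru_hidden = 32L, emb_dim = 32L,
                         tree_params = list(), nrounds = 150L,
                         seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, encoder_cfg = encoder_cfg,
                 gru_hidden = as.integer(gru_hidden),
                 emb_dim = as.integer(emb_dim),
                 tree_params = tree_params, nrounds = as.integer(nrounds),
                 seed = as.integer(seed),
                 params = NULL, boosters = NULL, history = NULL),
            class = c(family, "acuity_model"))
}

#' @export
print.acuity_model <- function(x, ...) {
  cat(sprintf("acuity_model <%s>%s\n", x$family,
              if (is.null(x$params) && is.null(x$boosters)) " (unfitted)"
              else " (fitted)"))
  invisible(x)
}

.is_sequence_family <- function(family) {
  family %in% c("longformer", "longformer_discrete",
                "gru_attention_tokenized")
}

#' Prepare model-ready samples for a model family
#'
#' Transformer and tokenized-GRU families receive assembled token sequences;
#' resampled-GRU families receive hourly multivariate series; tree families
#' receive flattened fixed-width feature vectors.
#'
#' @param model an [acuity_model()].
#' @param stays raw stay records (for event access).
#' @param tok matching tokenized stays from [tokenize_cohort()].
#' @param vocab a `vocab_map`.
#' @param artifacts a `fit_artifacts`.
#' @return list of per-stay samples (each carries `labels`).
#' @export
prepare_samples <- function(model, stays, tok, vocab, artifacts) {
  if (.is_sequence_family(model$family)) {
    return(lapply(tok, assemble_sequence, artifacts = artifacts))
  }
  if (model$family %in% c("gru", "gru_attention")) {
    vars <- vocab$variables$variable
    return(lapply(seq_along(stays), function(i) {
      list(series = resample_hourly(stays[[i]]$events, vars, artifacts,
                                    stays[[i]]$los_hours),
           static = tok[[i]]$static, labels = tok[[i]]$labels,
           stay_id = tok[[i]]$stay_id)
    }))
  }
  lapply(tok, function(ts) {
    list(x = flatten_for_trees(ts, vocab), labels = ts$labels,
         stay_id = ts$stay_id)
  })
}

# family-specific 1 x 7 logits-node builders ---------------------------------

.logits_fn_for <- function(model, vocab_size, static_dim) {
  switch(model$family,
    longformer = ,
    longformer_discrete = {
      cfg <- model$encoder_cfg
      disc <- model$family == "longformer_discrete"
      function(pn, s, training) {
        .transformer_logits_node(pn, s, cfg, disc, training)
      }
    },
    gru = ,
    gru_attention = {
      hidden <- model$gru_hidden
      att <- model$family == "gru_attention"
      function(pn, s, training) {
        .gru_logits_node(pn, s$series, s$static, hidden, att)
      }
    },
    gru_attention_tokenized = {
      hidden <- model$gru_hidden
      d <- model$emb_dim
      function(pn, s, training) {
        emb <- .embed_sequence_node(pn, s, d, discrete_only = FALSE,
                                    training = training, dropout = 0.1)
        rows <- which(!s$special & !s$pad)
        if (!length(rows)) rows <- which(s$special)
        scan <- .gru_scan_node(pn, ag_rows(emb, rows), hidden)
        att <- .gru_attention_node(pn, scan$states)
        .gru_readout_node(pn, att$context, s$static)
      }
    },
    stop("no logits function for family ", model$family)
  )
}

.init_params_for <- function(model, vocab_size, static_dim, input_dim) {
  switch(model$family,
    longformer = ,
    longformer_discrete =
      init_transformer_params(model$encoder_cfg, vocab_size, static_dim,
                              discrete_only =
                                model$family == "longformer_discrete",
                              seed = model$seed),
    gru = ,
    gru_attention =
      init_gru_params(input_dim, model$gru_hidden, static_dim,
                      attention = model$family == "gru_attention",
                      seed = model$seed),
    gru_attention_tokenized = {
      p <- init_embedding_params(model$emb_dim, vocab_size, static_dim,
                                 static_hidden = 2L * model$emb_dim,
                                 seed = model$seed)
      c(p, init_gru_params(model$emb_dim, model$gru_hidden, static_dim,
                           attention = TRUE, seed = model$seed + 1L))
    },
    stop("no parameter initializer for family ", model$family)
  )
}

#' Fit an acuity model on development samples with early stopping
#'
#' Neural families train with minibatch Adam on the mean multi-task binary
#' cross-entropy and stop on the validation mean acuity AUROC with the
#' configured patience, returning the best-metric checkpoint. Tree families
#' fit one booster per target with AUC-based early stopping on the same
#' validation split.
#'
#' @param model an [acuity_model()].
#' @param dev development (training) samples from [prepare_samples()].
#' @param val validation samples.
#' @param spec a [train_spec()].
#' @param vocab the `vocab_map` (needed by embedding families).
#' @return the fitted model (with `params`/`boosters` and `history`).
#' @export
fit_acuity <- function(model, dev, val, spec = train_spec(), vocab = NULL) {
  UseMethod("fit_acuity")
}

#' @export
fit_acuity.acuity_model <- function(model, dev, val, spec = train_spec(),
                                    vocab = NULL) {
  stopifnot(length(dev) > 0L, length(val) > 0L)
  static_dim <- length(dev[[1]]$static)
  input_dim <- if (model$family %in% c("gru", "gru_attention")) {
    ncol(dev[[1]]$series)
  } else {
    NA_integer_
  }
  vs <- if (!is.null(vocab)) vocab_size(vocab) else {
    if (.is_sequence_family(model$family)) {
      max(unlist(lapply(dev, `[[`, "f"))) + 1L
    } else {
      NA_integer_
    }
  }
  params <- .init_params_for(model, vs, static_dim, input_dim)
  fn <- .logits_fn_for(model, vs, static_dim)
  fit <- .train_neural(params, fn, dev, val, spec)
  model$params <- fit$params
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$best_metric <- fit$best_metric
  model$logits_fn <- fn
  model
}

#' @export
fit_acuity.xgb <- function(model, dev, val, spec = train_spec(),
                           vocab = NULL) {
  .fit_trees(model, dev, val, spec, booster = "gbtree")
}

#' @export
fit_acuity.xgb_dart <- function(model, dev, val, spec = train_spec(),
                                vocab = NULL) {
  .fit_trees(model, dev, val, spec, booster = "dart")
}

.fit_trees <- function(model, dev, val, spec, booster) {
  X <- do.call(rbind, lapply(dev, `[[`, "x"))
  Y <- do.call(rbind, lapply(dev, .sample_labels))
  Xv <- do.call(rbind, lapply(val, `[[`, "x"))
  Yv <- do.call(rbind, lapply(val, .sample_labels))
  base <- list(objective = "binary:logistic", max_depth = 4L, eta = 0.1,
               nthread = 1L, booster = booster, eval_metric = "auc",
               seed = model$seed)
  prm <- utils::modifyList(base, model$tree_params)
  model$boosters <- lapply(seq_len(N_TASK_TOKENS), function(j) {
    y <- Y[, j]
    if (length(unique(y)) < 2L) return(NULL)  # degenerate target
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    use_es <- length(unique(Yv[, j])) == 2L
    evals <- if (use_es) {
      list(val = xgboost::xgb.DMatrix(Xv, label = Yv[, j]))
    } else {
      list(train = dtrain)
    }
    xgboost::xgb.train(params = prm, data = dtrain,
                       nrounds = model$nrounds, evals = evals,
                       early_stopping_rounds = if (use_es) 20L else NULL,
                       verbose = 0)
  })
  model$history <- data.frame(epoch = 1L, train_loss = NA_real_,
                              val_mean_auroc = NA_real_, improved = TRUE,
                              lr = prm$eta)
  model
}

#' Predict per-task risk scores
#'
#' @param object a fitted `acuity_model`.
#' @param samples samples from [prepare_samples()] for the same family.
#' @param ... unused.
#' @return `length(samples) x 7` matrix of probabilities, columns named by
#'   [all_tasks()].
#' @export
predict.acuity_model <- function(object, samples, ...) {
  if (!is.null(object$boosters)) {
    X <- do.call(rbind, lapply(samples, `[[`, "x"))
    out <- vapply(seq_len(N_TASK_TOKENS), function(j) {
      b <- object$boosters[[j]]
      if (is.null(b)) rep(0.5, nrow(X)) else {
        stats::predict(b, xgboost::xgb.DMatrix(X))
      }
    }, numeric(nrow(X)))
    out <- matrix(out, nrow = nrow(X), dimnames = list(NULL, all_tasks()))
    return(out)
  }
  if (is.null(object$params)) stop("predict: model is not fitted")
  .predict_neural(object$params, object$logits_fn, samples)
}

#' Evaluate a fitted model: per-task AUROC table and acuity mean
#'
#' The mean is the arithmetic mean of the six acuity task AUROCs; the
#' auxiliary long-term readmission task is reported separately and never
#' enters the mean. Single-class tasks evaluate to `NA` (with a warning)
#' and are excluded from the mean.
#'
#' @param model a fitted `acuity_model`.
#' @param samples evaluation samples for the same family.
#' @return list with `mean`, named `per_task` (6), `aux`, and a one-row
#'   `table` in the reporting grid layout.
#' @export
evaluate_model <- function(model, samples) {
  scores <- stats::predict(model, samples)
  labels <- do.call(rbind, lapply(samples, .sample_labels))
  aucs <- vapply(seq_len(N_TASK_TOKENS), function(j) {
    auroc(scores[, j], labels[, j])
  }, 0)
  names(aucs) <- all_tasks()
  m <- mean(aucs[acuity_tasks()], na.rm = TRUE)
  row <- data.frame(model = model$family,
                    data = .family_data_label[[model$family]],
                    mean = m, t(aucs[acuity_tasks()]),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(mean = m, per_task = aucs[acuity_tasks()],
       aux = aucs[["aux_long_readmission"]], table = row)
}

#' Run the full multi-model comparison on a cohort
#'
#' One shared pipeline: length-of-stay exclusion, chronological grouped
#' split, vocabulary and standardization fit on the development cohort,
#' tokenization, sequence-length exclusion, then per family prepare / fit /
#' evaluate on the held-out cohort. Every family is scored by the same
#' AUROC code path and reported as one row of a grid
#' (mean + six task columns).
#'
#' @param cohort an `icu_cohort`.
#' @param families subset of [ACUITY_FAMILIES] to run.
#' @param encoder_cfg [model_config()] for the transformer families.
#' @param gru_hidden,emb_dim GRU/embedding sizes.
#' @param spec a [train_spec()].
#' @param max_tokens sequence-length exclusion threshold.
#' @param los_range length-of-stay inclusion window (hours).
#' @param verbose print progress.
#' @return list with `grid` (data.frame, one row per family), `results`
#'   (per-family [evaluate_model()] output), `models` (fitted models) and
#'   `split_sizes`.
#' @export
benchmark_models <- function(cohort,
                             families = ACUITY_FAMILIES,
                             encoder_cfg = model_config(layers = 2L,
                                                        hidden = 32L,
                                                        feedforward = 64L,
                                                        heads = 4L,
                                                        window = 32L),
                             gru_hidden = 32L, emb_dim = NULL,
                             spec = train_spec(),
                             max_tokens = 256L,
                             los_range = c(1, 240),
                             verbose = TRUE) {
  families <- match.arg(families, ACUITY_FAMILIES, several.ok = TRUE)
  if (is.null(emb_dim)) emb_dim <- encoder_cfg$hidden
  los <- vapply(cohort$stays, `[[`, 0, "los_hours")
  keep <- los >= los_range[1] & los <= los_range[2]
  stays <- cohort$stays[keep]
  split <- chronological_split(stays, seed = spec$seed)
  dev_all <- c(split$dev, split$val)
  dev_events <- do.call(rbind, lapply(dev_all, `[[`, "events"))
  vocab <- build_vocab(dev_events, n_stays = length(dev_all))
  artifacts <- fit_transforms(dev_all, vocab)
  tok <- lapply(split, tokenize_cohort, vocab = vocab,
                artifacts = artifacts)
  for (part in names(tok)) {
    counts <- vapply(tok[[part]], function(t) nrow(t$tokens), 1L)
    keep_tok <- counts <= max_tokens  # LOS exclusion already applied
    split[[part]] <- split[[part]][keep_tok]
    tok[[part]] <- tok[[part]][keep_tok]
  }
  results <- list()
  models <- list()
  for (fam in families) {
    if (verbose) message("== family: ", fam)
    model <- acuity_model(fam, encoder_cfg = encoder_cfg,
                          gru_hidden = gru_hidden, emb_dim = emb_dim,
                          seed = spec$seed)
    smp <- lapply(names(split), function(part) {
      prepare_samples(model, split[[part]], tok[[part]], vocab, artifacts)
    })
    names(smp) <- names(split)
    model <- fit_acuity(model, smp$dev, smp$val, spec, vocab = vocab)
    results[[fam]] <- evaluate_model(model, smp$heldout)
    models[[fam]] <- model
    if (verbose) {
      message(sprintf("   held-out mean AUROC %.3f", results[[fam]]$mean))
    }
  }
  grid <- do.call(rbind, lapply(results, `[[`, "table"))
  row.names(grid) <- NULL
  list(grid = grid, results = results, models = models,
       vocab = vocab, artifacts = artifacts,
       split_sizes = vapply(split, length, 1L))
}

#' Desk-scale benchmark study conditions
#'
#' The reference conditions for the synthetic model-ordering experiment:
#' a cohort of roughly 2,000 stays (1,790 patients plus repeat admissions)
#' with the default planted-signal strengths and a 72-hour maximum length of
#' stay so that tokenized sequences stay within a 256-token cap, paired with
#' a reduced encoder (2 layers, hidden 32, 4 heads, window 32).
#'
#' @param n_patients number of patients.
#' @param seed cohort seed.
#' @return list with `sim` (a [sim_config()]), `encoder`
#'   (a [model_config()]) and `max_tokens`.
#' @export
benchmark_conditions <- function(n_patients = 1790L, seed = 1L) {
  list(
    sim = sim_config(n_patients = n_patients, los_range_hours = c(1, 72),
                     seed = seed),
    encoder = model_config(layers = 2L, hidden = 32L, feedforward = 64L,
                           heads = 4L, window = 32L),
    max_tokens = 256L
  )
}

# ---- checkpointing ---------------------------------------------------------

#' Save a fitted model as a JSON checkpoint
#'
#' Flat named-parameter archive plus configuration; exact floats.
#'
#' @param model a fitted `acuity_model` (neural families).
#' @param path output file.
#' @export
save_model <- function(model, path) {
  if (is.null(model$params)) {
    stop("save_model: only neural models have a parameter archive",
         call. = FALSE)
  }
  payload <- list(
    family = model$family,
    encoder_cfg = unclass(model$encoder_cfg),
    gru_hidden = model$gru_hidden, emb_dim = model$emb_dim,
    seed = model$seed, best_epoch = model$best_epoch,
    params = lapply(model$params, function(m) {
      list(dim = dim(m), data = as.numeric(m))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path JSON checkpoint.
#' @return a fitted `acuity_model`.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, x$encoder_cfg[
    c("layers", "hidden", "feedforward", "heads", "window", "dropout",
      "n_tasks", "ln_eps")])
  model <- acuity_model(x$family, encoder_cfg = cfg,
                        gru_hidden = x$gru_hidden, emb_dim = x$emb_dim,
                        seed = x$seed)
  model$params <- lapply(x$params, function(p) {
    matrix(p$data, p$dim[1], p$dim[2])
  })
  model$best_epoch <- x$best_epoch
  model$logits_fn <- .logits_fn_for(model, NA, NA)
  model
}
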