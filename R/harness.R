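# Cohort splitting, multi-task training with early stopping, and AUROC
# evaluation shared by every model family.

#' Chronological grouped cohort split
#'
#' Stays are sorted by admission time; the earliest `dev_frac` form the
#' development cohort and the remainder the held-out evaluation cohort. Any
#' held-out stay whose patient also appears in the development cohort is
#' moved into development, so no patient spans the threshold. A seeded,
#' patient-grouped `val_frac` of development stays is carved out for
#' within-training validation and early stopping.
#'
#' @param stays list of stay records with `admit_time` and `patient_id`.
#' @param dev_frac development fraction (default 0.8).
#' @param val_frac within-development validation fraction (default 0.1).
#' @param seed seed for the validation sample.
#' @return list with `dev` (training stays), `val`, `heldout`; each a list of
#'   stay records. Disjointness and grouping are asserted.
#' @export
chronological_split <- function(stays, dev_frac = 0.8, val_frac = 0.1,
                                seed = 1L) {
  if (length(stays) < 10L) {
    stop("chronological_split: need at least 10 stays", call. = FALSE)
  }
  admit <- vapply(stays, `[[`, 0, "admit_time")
  pid <- vapply(stays, `[[`, "", "patient_id")
  ord <- order(admit)
  k <- floor(dev_frac * length(stays))
  dev_idx <- ord[seq_len(k)]
  held_idx <- ord[setdiff(seq_along(ord), seq_len(k))]
  spill <- held_idx[pid[held_idx] %in% pid[dev_idx]]
  dev_idx <- c(dev_idx, spill)
  held_idx <- setdiff(held_idx, spill)
  # seeded patient-grouped validation sample within development
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  dev_pids <- unique(pid[dev_idx])
  target <- val_frac * length(dev_idx)
  val_idx <- integer()
  for (p in sample(dev_pids)) {
    if (length(val_idx) >= target) break
    val_idx <- c(val_idx, dev_idx[pid[dev_idx] == p])
  }
  train_idx <- setdiff(dev_idx, val_idx)
  stopifnot(
    length(intersect(c(train_idx, val_idx), held_idx)) == 0L,
    length(intersect(pid[c(train_idx, val_idx)], pid[held_idx])) == 0L,
    length(intersect(pid[train_idx], pid[val_idx])) == 0L
  )
  list(dev = stays[train_idx], val = stays[val_idx],
       heldout = stays[held_idx])
}

#' Rank-based AUROC with midrank tie handling
#'
#' Mann-Whitney statistic: the probability that a randomly chosen positive
#' scores above a randomly chosen negative, with ties counted half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`, or `NA` with a warning when only one class is
#'   present.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- as.numeric(sum(labels == 1L))
  nn <- as.numeric(sum(labels == 0L))
  if (np == 0 || nn == 0) {
    warning("auroc: undefined for single-class labels; returning NA")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Training specification for the neural model families
#'
#' Loss is the unweighted mean of per-task binary cross-entropy on logits
#' over all 7 targets (auxiliary weight 1.0). Early stopping monitors the
#' mean validation AUROC over the six acuity tasks only; the auxiliary task
#' regularizes the representation but is never part of the metric. The
#' optimizer family (Adam) and learning rate are package defaults, fixed
#' here and recorded in the training history.
#'
#' @param lr Adam learning rate.
#' @param max_epochs upper bound on epochs.
#' @param patience consecutive non-improving epochs tolerated (default 4).
#' @param batch_size minibatch size (default 21).
#' @param seed seed governing shuffling, dropout and initialization.
#' @param verbose print one line per epoch.
#' @return a `train_spec` list.
#' @export
train_spec <- function(lr = 1e-3, max_epochs = 20L, patience = 4L,
                       batch_size = 21L, seed = 1L, verbose = FALSE) {
  stopifnot(patience >= 1L, batch_size >= 1L, max_epochs >= 1L, lr > 0)
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_spec")
}

# labels of one sample in canonical task order, as a 1 x 7 matrix
.sample_labels <- function(sample) {
  matrix(as.numeric(sample$labels[all_tasks()]), 1L)
}

# mean AUROC over the six acuity tasks; single-class tasks are excluded
# from the mean (with the warning raised by auroc()).
.mean_acuity_auroc <- function(scores, labels_mat) {
  aucs <- vapply(seq_along(acuity_tasks()), function(j) {
    auroc(scores[, j], labels_mat[, j])
  }, 0)
  mean(aucs, na.rm = TRUE)
}

# generic minibatch Adam loop with patience-based early stopping.
# logits_fn(pn, sample, training) must return a 1 x 7 logits node.
.train_neural <- function(params, logits_fn, dev, val, spec) {
  set.seed(spec$seed)
  state <- adam_state(params)
  best <- list(metric = -Inf, params = params, epoch = 0L)
  stale <- 0L
  history <- list()
  for (epoch in seq_len(spec$max_epochs)) {
    idx <- sample(length(dev))
    batches <- split(idx, ceiling(seq_along(idx) / spec$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      pn <- lapply(params, ag_param)
      losses <- lapply(dev[b], function(s) {
        ag_bce_logits(logits_fn(pn, s, TRUE), .sample_labels(s))
      })
      total <- ag_mulc(Reduce(ag_add, losses), 1 / length(losses))
      lv <- ag_val(total)[1L]
      if (!is.finite(lv)) {
        stop(sprintf(paste0("training diverged: non-finite loss at epoch %d",
                            " (batch of %d, last finite epoch loss %.4f)"),
                     epoch, length(b), epoch_loss), call. = FALSE)
      }
      epoch_loss <- epoch_loss + lv * length(b)
      ag_backward(total)
      grads <- lapply(pn, function(n) n$grad)
      upd <- adam_step(params, grads, state, lr = spec$lr)
      params <- upd$params
      state <- upd$state
    }
    epoch_loss <- epoch_loss / length(dev)
    val_scores <- .predict_neural(params, logits_fn, val)
    val_labels <- do.call(rbind, lapply(val, .sample_labels))
    metric <- .mean_acuity_auroc(val_scores, val_labels)
    # a fully degenerate validation metric (all tasks single-class) never
    # counts as an improvement
    improved <- is.finite(metric) && metric > best$metric
    if (improved) {
      best <- list(metric = metric, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = epoch_loss,
                                   val_mean_auroc = metric,
                                   improved = improved, lr = spec$lr)
    if (spec$verbose) {
      message(sprintf("epoch %d  loss %.4f  val mean AUROC %.4f%s",
                      epoch, epoch_loss, metric,
                      if (improved) "  *" else ""))
    }
    if (stale >= spec$patience) break
  }
  list(params = best$params, history = do.call(rbind, history),
       best_epoch = best$epoch, best_metric = best$metric)
}

# evaluation-mode probabilities for a list of samples
.predict_neural <- function(params, logits_fn, samples) {
  pn <- lapply(params, ag_param)
  out <- matrix(NA_real_, length(samples), N_TASK_TOKENS,
                dimnames = list(NULL, all_tasks()))
  for (i in seq_along(samples)) {
    out[i, ] <- stats::plogis(ag_val(logits_fn(pn, samples[[i]], FALSE)))
  }
  out
}
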