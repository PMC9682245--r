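# Assembly of model-ready sequences.
#
# Layout per stay: [static token][7 task tokens][event tokens]. The static
# slot is flagged to bypass the token embedder (its embedding comes from the
# static encoder network); task tokens carry reserved variable ids, time equal
# to the standardized ICU length of stay and all value features zero. Global
# attention is marked on the 8 special positions.

#' Assemble one stay into a model-ready sequence
#'
#' @param tok_stay a tokenized stay from [tokenize_cohort()] (fields `tokens`,
#'   `static`, `labels`, `los_hours`).
#' @param artifacts a `fit_artifacts` (for the length-of-stay time
#'   standardization shared with event times).
#' @param n_tasks number of prediction targets; must equal the number of task
#'   tokens reserved in the vocabulary (7: six acuity outcomes plus the
#'   auxiliary regularization target).
#' @return an `assembled_seq`: list with vectors `p`, `f`, `t`, matrix `V`
#'   (n x 9), logical `special`, `global`, `pad`, plus `static`, `labels`,
#'   `los_hours`, `stay_id`.
#' @export
assemble_sequence <- function(tok_stay, artifacts, n_tasks = N_TASK_TOKENS) {
  if (n_tasks != N_TASK_TOKENS) {
    stop("assemble_sequence: n_tasks must match the configured outcome set (",
         N_TASK_TOKENS, ")", call. = FALSE)
  }
  toks <- tok_stay$tokens
  n_ev <- nrow(toks)
  if (n_ev == 0L) {
    warning("assemble_sequence: stay ", tok_stay$stay_id,
            " has no event tokens; sequence contains special tokens only")
  }
  n_special <- 1L + n_tasks
  t_los <- standardize_time(tok_stay$los_hours, artifacts)
  p <- c(rep(0L, n_special), as.integer(toks[, "p"]))
  f <- c(0L, seq_len(n_tasks), as.integer(toks[, "f"]))
  t <- c(0, rep(t_los, n_tasks), toks[, "t"])
  V <- rbind(matrix(0, n_special, 9L),
             toks[, 4:12, drop = FALSE])
  colnames(V) <- .value_feature_names
  n <- n_special + n_ev
  structure(list(
    p = p, f = f, t = t, V = V,
    special = c(rep(TRUE, n_special), rep(FALSE, n_ev)),
    global = c(rep(TRUE, n_special), rep(FALSE, n_ev)),
    pad = rep(FALSE, n),
    static = tok_stay$static,
    labels = tok_stay$labels,
    los_hours = tok_stay$los_hours,
    stay_id = tok_stay$stay_id
  ), class = "assembled_seq")
}

#' Sequence length of an assembled sequence (excluding padding)
#' @param seq an `assembled_seq`.
#' @return integer.
#' @export
seq_length <- function(seq) sum(!seq$pad)

#' Right-pad a list of sequences to a common length
#'
#' Padding positions carry zero features, are excluded from attention (via
#' the `pad` mask) and from the loss. Order is preserved.
#'
#' @param sequences list of `assembled_seq`.
#' @param max_len optional hard cap; a sequence longer than `max_len` is an
#'   error (length filtering should have removed it upstream).
#' @return list of padded `assembled_seq` (all the same length).
#' @export
pad_and_batch <- function(sequences, max_len = NULL) {
  lens <- vapply(sequences, seq_length, 1L)
  if (!is.null(max_len) && any(lens > max_len)) {
    stop("pad_and_batch: sequence longer than max_len (",
         max(lens), " > ", max_len, ")", call. = FALSE)
  }
  L <- max(lens)
  lapply(sequences, function(s) {
    n <- seq_length(s)
    extra <- L - n
    if (extra == 0L) return(s)
    s$p <- c(s$p, rep(0L, extra))
    s$f <- c(s$f, rep(0L, extra))
    s$t <- c(s$t, rep(0, extra))
    s$V <- rbind(s$V, matrix(0, extra, 9L))
    s$special <- c(s$special, rep(FALSE, extra))
    s$global <- c(s$global, rep(FALSE, extra))
    s$pad <- c(s$pad, rep(TRUE, extra))
    s
  })
}
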