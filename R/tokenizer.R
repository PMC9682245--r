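# Tokenization of irregular clinical event streams.
#
# Each retained event becomes a 12-tuple token: dense-rank position p (shared
# by simultaneous events), integer variable id f, standardized elapsed time t,
# and nine continuous features v = current value plus eight cumulative
# statistics of the same variable's history within the stay (mean, median,
# count, min, max, population SD, first value, gap since the previous
# measurement). Continuous features are standardized per (variable, feature)
# with statistics fit on the training split only.

N_TASK_TOKENS <- 7L  # six acuity outcomes + one auxiliary regularization task

.value_feature_names <- c("value", "cum_mean", "cum_median", "cum_count",
                          "cum_min", "cum_max", "cum_sd", "first_value",
                          "gap_hours")

#' Build the variable vocabulary from training events
#'
#' Laboratory tests and medications are retained only if they appear in at
#' least `min_prevalence` of the training stays (boundary inclusive); vital
#' signs and assessment components are always retained. Reserved ids 0..7 are
#' assigned to the static-information token (0) and the seven task tokens;
#' id 8 is an optional unknown-variable token. Variable ids follow, contiguous,
#' in sorted-name order for determinism.
#'
#' @param events long-format event table with columns `stay_id`, `variable`,
#'   `category` (one of vital/lab/medication/assessment).
#' @param n_stays number of training stays used as the prevalence denominator;
#'   defaults to the number of distinct `stay_id`s in `events`.
#' @param min_prevalence prevalence threshold for labs and medications.
#' @return a `vocab_map`: data.frame of variables plus reserved-token info.
#' @export
build_vocab <- function(events, n_stays = NULL, min_prevalence = 0.01) {
  if (is.null(n_stays)) n_stays <- length(unique(events$stay_id))
  if (nrow(events) == 0L || n_stays == 0L) {
    stop("build_vocab: empty training set", call. = FALSE)
  }
  stopifnot(all(c("stay_id", "variable", "category") %in% names(events)))
  uv <- unique(events[, c("variable", "category")])
  prev <- tapply(events$stay_id, events$variable,
                 function(s) length(unique(s))) / n_stays
  uv$prevalence <- as.numeric(prev[uv$variable])
  keep <- uv$category %in% c("vital", "assessment") |
    uv$prevalence >= min_prevalence
  uv <- uv[keep, , drop = FALSE]
  uv <- uv[order(uv$variable), , drop = FALSE]
  reserved <- data.frame(
    token = c("[STATIC]", paste0("[CLS_", all_tasks(), "]"), "[UNK]"),
    id = 0:8,
    stringsAsFactors = FALSE
  )
  uv$id <- seq_len(nrow(uv)) - 1L + nrow(reserved)
  row.names(uv) <- NULL
  structure(list(variables = uv, reserved = reserved,
                 n_train_stays = n_stays, min_prevalence = min_prevalence),
            class = "vocab_map")
}

#' @export
print.vocab_map <- function(x, ...) {
  cat(sprintf("vocab_map: %d variables + %d reserved ids (prevalence filter %.1f%% over %d stays)\n",
              nrow(x$variables), nrow(x$reserved), 100 * x$min_prevalence,
              x$n_train_stays))
  invisible(x)
}

#' Total embedding-table size implied by a vocabulary
#' @param vocab a `vocab_map`.
#' @return integer: reserved ids + variable ids.
#' @export
vocab_size <- function(vocab) nrow(vocab$reserved) + nrow(vocab$variables)

#' Dense-rank positional indices for sorted measurement times
#'
#' Simultaneous events (identical timestamps) share a position; each new
#' unique time increments the index by exactly 1, starting at 0. For example
#' times `[0.1, 0.2, 0.2, 0.3, 0.3]` map to `[0, 1, 1, 2, 2]`.
#'
#' @param times numeric vector, sorted non-decreasing (the tokenizer sorts
#'   events by time before calling this).
#' @return integer vector of positions, same length as `times`.
#' @export
assign_positions <- function(times) {
  if (length(times) == 0L) return(integer())
  if (is.unsorted(times)) {
    stop("assign_positions: times must be sorted non-decreasing",
         call. = FALSE)
  }
  c(0L, cumsum(diff(times) > 0))
}

#' Cumulative value-derived features for one variable's event history
#'
#' Statistics are computed over the history up to and including the current
#' event: running mean, median, count, min, max, population standard
#' deviation (0 for a single observation), first observed value, and the gap
#' in hours since the variable's previous measurement (0 for the first).
#'
#' @param values numeric measurement values of one variable, in time order.
#' @param times matching measurement times (hours), sorted non-decreasing.
#' @return matrix with one row per event and columns
#'   cum_mean, cum_median, cum_count, cum_min, cum_max, cum_sd, first_value,
#'   gap_hours.
#' @export
compute_cumulative_features <- function(values, times) {
  n <- length(values)
  stopifnot(length(times) == n, n >= 1L)
  if (is.unsorted(times)) {
    stop("compute_cumulative_features: times must be sorted", call. = FALSE)
  }
  idx <- seq_len(n)
  mu <- cumsum(values) / idx
  # Welford's running variance: numerically stable for large means
  varp <- numeric(n)
  m <- 0; M2 <- 0
  for (i in idx) {
    d <- values[i] - m
    m <- m + d / i
    M2 <- M2 + d * (values[i] - m)
    varp[i] <- M2 / i
  }
  varp <- pmax(varp, 0)
  med <- vapply(idx, function(i) stats::median(values[1:i]), 0)
  out <- cbind(
    cum_mean = mu,
    cum_median = med,
    cum_count = as.numeric(idx),
    cum_min = cummin(values),
    cum_max = cummax(values),
    cum_sd = sqrt(varp),
    first_value = rep(values[1L], n),
    gap_hours = c(0, diff(times))
  )
  out
}

# stable canonical event order: time, then variable name, then value
.order_events <- function(events) {
  events[order(events$time_hours, events$variable, events$value), ,
         drop = FALSE]
}

# raw (unstandardized) token feature table for one stay's events
.raw_token_features <- function(events) {
  ev <- .order_events(events)
  n <- nrow(ev)
  V <- matrix(NA_real_, n, 9L,
              dimnames = list(NULL, .value_feature_names))
  V[, "value"] <- ev$value
  for (v in unique(ev$variable)) {
    sel <- which(ev$variable == v)
    V[sel, 2:9] <- compute_cumulative_features(ev$value[sel],
                                               ev$time_hours[sel])
  }
  list(events = ev, V = V, positions = assign_positions(ev$time_hours))
}

#' Fit standardization artifacts on the training split
#'
#' Computes, from training stays only: per numeric static column the median
#' (for imputation), mean and scale; frozen one-hot level catalogs for
#' categorical static columns; per (variable, token-feature) means and scales
#' over all training tokens; the global time mean and scale; and per-variable
#' raw value medians (used by the hourly-resampling baseline). Zero-variance
#' columns are flagged and given scale 1 so transformed values are exactly 0.
#'
#' @param cohort_stays list of stay records (as in an `icu_cohort`), training
#'   split only.
#' @param vocab a `vocab_map`.
#' @return a `fit_artifacts` object.
#' @export
fit_transforms <- function(cohort_stays, vocab) {
  if (length(cohort_stays) == 0L) {
    stop("fit_transforms: empty training set", call. = FALSE)
  }
  static <- do.call(rbind, lapply(cohort_stays, function(s) {
    as.data.frame(lapply(s$static_record,
                         function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  is_num <- vapply(static, is.numeric, TRUE)
  num_cols <- names(static)[is_num]
  cat_cols <- names(static)[!is_num]
  num_stats <- lapply(num_cols, function(col) {
    x <- static[[col]]
    med <- stats::median(x, na.rm = TRUE)
    if (is.na(med)) med <- 0
    xo <- x[!is.na(x)]
    mu <- if (length(xo)) mean(xo) else 0
    sc <- if (length(xo) > 1L) stats::sd(xo) else 0
    degenerate <- !is.finite(sc) || sc <= 0
    list(median = med, mean = mu, scale = if (degenerate) 1 else sc,
         degenerate = degenerate)
  })
  names(num_stats) <- num_cols
  catalogs <- lapply(cat_cols, function(col) {
    sort(unique(stats::na.omit(as.character(static[[col]]))))
  })
  names(catalogs) <- cat_cols

  # per (variable, token-feature column) statistics over all training tokens
  feats <- list(); times_all <- list()
  for (i in seq_along(cohort_stays)) {
    ev <- cohort_stays[[i]]$events
    if (nrow(ev) == 0L) next
    rf <- .raw_token_features(ev)
    feats[[length(feats) + 1L]] <-
      data.frame(variable = rf$events$variable, rf$V,
                 stringsAsFactors = FALSE)
    times_all[[length(times_all) + 1L]] <- rf$events$time_hours
  }
  ft <- do.call(rbind, feats)
  in_vocab <- ft$variable %in% vocab$variables$variable
  ft <- ft[in_vocab, , drop = FALSE]
  var_stats <- lapply(split(ft[.value_feature_names], ft$variable),
                      function(block) {
    mu <- colMeans(block)
    sc <- vapply(block, function(x) {
      s <- stats::sd(x) * sqrt(max(length(x) - 1, 0) / max(length(x), 1))
      if (!is.finite(s) || s <= 0) NA_real_ else s
    }, 0)
    raw_median <- stats::median(block$value)
    list(mean = mu, scale = ifelse(is.na(sc), 1, sc),
         degenerate = is.na(sc), raw_median = raw_median)
  })
  tv <- unlist(times_all)
  t_mu <- if (length(tv)) mean(tv) else 0
  t_sc <- if (length(tv) > 1L) stats::sd(tv) else 1
  if (!is.finite(t_sc) || t_sc <= 0) t_sc <- 1
  structure(list(
    numeric_stats = num_stats, catalogs = catalogs,
    numeric_cols = num_cols, categorical_cols = cat_cols,
    var_stats = var_stats, time_mean = t_mu, time_scale = t_sc
  ), class = "fit_artifacts")
}

#' Standardize an elapsed time (hours) with fitted artifacts
#' @param t_hours numeric vector of times.
#' @param artifacts a `fit_artifacts`.
#' @return standardized times.
#' @export
standardize_time <- function(t_hours, artifacts) {
  (t_hours - artifacts$time_mean) / artifacts$time_scale
}

#' Transform one raw static record into the model's static vector
#'
#' Categorical columns become one-hot blocks over the frozen training level
#' catalogs (an unseen or missing level yields an all-zero block). Numeric
#' columns are median-imputed then standardized, with a binary missingness
#' mask bit per column. Layout: `[one-hots | standardized numerics | masks]`;
#' the width is fixed across stays.
#'
#' @param record named list (one stay's static record).
#' @param artifacts a `fit_artifacts`.
#' @return named numeric vector.
#' @export
process_static <- function(record, artifacts) {
  unknown <- setdiff(names(record),
                     c(artifacts$numeric_cols, artifacts$categorical_cols))
  if (length(unknown)) {
    stop("process_static: unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  onehots <- unlist(lapply(artifacts$categorical_cols, function(col) {
    lv <- artifacts$catalogs[[col]]
    x <- record[[col]]
    block <- if (is.null(x) || is.na(x) || !(x %in% lv)) {
      rep(0, length(lv))  # missing or unseen level: all-zero block
    } else {
      as.numeric(lv == x)
    }
    names(block) <- paste0(col, "=", lv)
    block
  }))
  nums <- numeric(0); masks <- numeric(0)
  for (col in artifacts$numeric_cols) {
    st <- artifacts$numeric_stats[[col]]
    x <- record[[col]]
    miss <- is.null(x) || is.na(x)
    if (miss) x <- st$median
    z <- if (st$degenerate) 0 else (x - st$mean) / st$scale
    nums <- c(nums, stats::setNames(z, col))
    masks <- c(masks, stats::setNames(as.numeric(miss),
                                      paste0(col, "_missing")))
  }
  c(onehots, nums, masks)
}

#' Tokenize one stay's events into the 12-column token matrix
#'
#' Events are stably sorted by (time, variable name); out-of-vocabulary
#' variables are dropped (or mapped to the `[UNK]` id when `oov = "unk"`).
#' Positions are dense ranks of the retained events' unique times; cumulative
#' features are computed on raw values per variable and then standardized per
#' (variable, feature column); the time column is standardized globally.
#'
#' @param events one stay's event table.
#' @param vocab a `vocab_map`.
#' @param artifacts a `fit_artifacts`.
#' @param oov `"drop"` (default) or `"unk"`.
#' @return numeric matrix with columns
#'   `p, f, t, value, cum_mean, ..., gap_hours` (12 columns, one row per
#'   retained event). A stay with no retained events yields a 0-row matrix
#'   with a warning.
#' @export
tokenize_stay <- function(events, vocab, artifacts, oov = c("drop", "unk")) {
  oov <- match.arg(oov)
  ids <- stats::setNames(vocab$variables$id, vocab$variables$variable)
  known <- events$variable %in% names(ids)
  if (oov == "drop") events <- events[known, , drop = FALSE]
  cols <- c("p", "f", "t", .value_feature_names)
  if (nrow(events) == 0L) {
    warning("tokenize_stay: stay has no in-vocabulary events")
    return(matrix(numeric(), 0L, 12L, dimnames = list(NULL, cols)))
  }
  rf <- .raw_token_features(events)
  ev <- rf$events
  V <- rf$V
  for (v in unique(ev$variable)) {
    st <- artifacts$var_stats[[v]]
    sel <- which(ev$variable == v)
    if (is.null(st)) next  # [UNK]-mapped variable: leave raw
    V[sel, ] <- sweep(sweep(V[sel, , drop = FALSE], 2L, st$mean, "-"),
                      2L, st$scale, "/")
    if (any(st$degenerate)) V[sel, which(st$degenerate)] <- 0
  }
  f <- ifelse(ev$variable %in% names(ids), ids[ev$variable],
              vocab$reserved$id[vocab$reserved$token == "[UNK]"])
  out <- cbind(p = rf$positions, f = as.numeric(f),
               t = standardize_time(ev$time_hours, artifacts), V)
  rownames(out) <- NULL
  out
}

#' Apply length-of-stay and sequence-length exclusion rules
#'
#' Retains stays with ICU length of stay within `los_range` (inclusive) and
#' token count at most `max_tokens`, mirroring common ICU cohort inclusion
#' windows (1 h to 10 days) and a maximum tokenized sequence length.
#'
#' @param stays list of stay records with `los_hours`.
#' @param token_counts integer vector of tokenized lengths, same order.
#' @param los_range inclusive hours window, default `c(1, 240)`.
#' @param max_tokens maximum tokens per stay, default 12000.
#' @return list with `stays` (retained) and `log` (data.frame stay_id,
#'   reason for each exclusion).
#' @export
filter_stays <- function(stays, token_counts, los_range = c(1, 240),
                         max_tokens = 12000L) {
  stopifnot(length(stays) == length(token_counts))
  los <- vapply(stays, `[[`, 0, "los_hours")
  reason <- rep(NA_character_, length(stays))
  reason[los < los_range[1]] <- "los_too_short"
  reason[los > los_range[2]] <- "los_too_long"
  reason[is.na(reason) & token_counts > max_tokens] <- "too_many_tokens"
  excl <- which(!is.na(reason))
  list(
    stays = stays[setdiff(seq_along(stays), excl)],
    log = data.frame(
      stay_id = vapply(stays[excl], `[[`, "", "stay_id"),
      reason = reason[excl], stringsAsFactors = FALSE)
  )
}

#' Tokenize a full cohort
#'
#' Convenience wrapper: tokenizes every stay, applies [process_static()], and
#' returns model-ready per-stay records.
#'
#' @param stays list of stay records.
#' @param vocab a `vocab_map`.
#' @param artifacts a `fit_artifacts`.
#' @param oov passed to [tokenize_stay()].
#' @return list of tokenized stays: each has `stay_id`, `patient_id`,
#'   `admit_time`, `tokens`, `static`, `labels`, `los_hours`.
#' @export
tokenize_cohort <- function(stays, vocab, artifacts, oov = "drop") {
  lapply(stays, function(s) {
    toks <- suppressWarnings(tokenize_stay(s$events, vocab, artifacts,
                                           oov = oov))
    list(stay_id = s$stay_id, patient_id = s$patient_id,
         admit_time = s$admit_time, tokens = toks,
         static = process_static(s$static_record, artifacts),
         labels = s$labels, los_hours = s$los_hours)
  })
}

# ---- JSON (de)serialization of vocab and artifacts -------------------------

#' Write a vocabulary to JSON
#' @param vocab a `vocab_map`.
#' @param path output file.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vocabulary written by [write_vocab()]
#' @param path JSON file.
#' @return a `vocab_map`.
#' @export
read_vocab <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$variables$id <- as.integer(x$variables$id)
  structure(x, class = "vocab_map")
}

#' Write fit artifacts to JSON (exact floats)
#' @param artifacts a `fit_artifacts`.
#' @param path output file.
#' @export
write_artifacts <- function(artifacts, path) {
  jsonlite::write_json(unclass(artifacts), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read fit artifacts written by [write_artifacts()]
#' @param path JSON file.
#' @return a `fit_artifacts`.
#' @export
read_artifacts <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$var_stats <- lapply(x$var_stats, function(st) {
    st$mean <- unlist(st$mean); st$scale <- unlist(st$scale)
    st$degenerate <- unlist(st$degenerate)
    st
  })
  structure(x, class = "fit_artifacts")
}
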