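# Tokenizer: vocabulary filter, dense-rank positions, cumulative features,
# standardization and exclusion rules.

toy_events <- function(stay, variable, category, time, value) {
  data.frame(stay_id = stay, variable = variable, category = category,
             time_hours = time, value = value, stringsAsFactors = FALSE)
}

test_that("prevalence filter keeps labs/meds at the inclusive 1% boundary and exempts vitals", {
  stays <- sprintf("s%03d", 1:100)
  ev <- rbind(
    toy_events(stays, "hr", "vital", 1, 80),          # every stay
    toy_events("s001", "lab_rare", "lab", 2, 5),      # exactly 1% of stays
    toy_events("s001", "med_rare", "medication", 2, 1),
    toy_events(stays[1:2], "lab_common", "lab", 3, 7)
  )
  vocab <- build_vocab(ev, n_stays = 100L, min_prevalence = 0.01)
  expect_true(all(c("lab_rare", "med_rare", "lab_common", "hr") %in%
                    vocab$variables$variable))
  # below the boundary: a lab in 1 of 1000 stays is dropped, a vital kept
  ev2 <- rbind(toy_events("s001", "lab_rare", "lab", 1, 5),
               toy_events("s001", "vital_rare", "vital", 1, 5),
               toy_events(stays, "hr", "vital", 1, 80))
  vocab2 <- build_vocab(ev2, n_stays = 1000L, min_prevalence = 0.01)
  expect_false("lab_rare" %in% vocab2$variables$variable)
  expect_true("vital_rare" %in% vocab2$variables$variable)
  expect_error(build_vocab(ev[0, ], n_stays = 0L), "empty")
})

test_that("vocabulary ids are contiguous, deterministic and disjoint from reserved ids", {
  co <- small_cohort(20L, seed = 3L)
  ev <- cohort_events(co)
  vocab <- build_vocab(ev, n_stays = length(co$stays))
  ids <- vocab$variables$id
  expect_equal(vocab$reserved$id, 0:8)
  expect_equal(sort(ids), seq(9L, 8L + length(ids)))
  expect_equal(vocab$variables$variable,
               sort(vocab$variables$variable))
  expect_length(intersect(ids, vocab$reserved$id), 0L)
})

test_that("positions are dense ranks of unique times", {
  expect_equal(assign_positions(c(0.1, 0.2, 0.2, 0.3, 0.3)),
               c(0L, 1L, 1L, 2L, 2L))
  expect_equal(assign_positions(numeric()), integer())
  expect_equal(assign_positions(c(5, 5, 5)), c(0L, 0L, 0L))
  expect_error(assign_positions(c(2, 1)), "sorted")
  # property: non-decreasing, increments in {0,1}, as many distinct
  # positions as unique timestamps
  set.seed(11)
  for (i in 1:50) {
    times <- sort(round(runif(40, 0, 10), 1))
    p <- assign_positions(times)
    expect_true(all(diff(p) %in% c(0L, 1L)))
    expect_equal(length(unique(p)), length(unique(times)))
    expect_equal(p[1], 0L)
  }
})

test_that("cumulative features match hand-computed and brute-force prefixes", {
  one <- compute_cumulative_features(10, 0.5)
  expect_equal(unname(one[1, ]), c(10, 10, 1, 10, 10, 0, 10, 0))
  two <- compute_cumulative_features(c(10, 20), c(1, 3))
  expect_equal(unname(two[2, ]), c(15, 15, 2, 10, 20, 5, 10, 2))
  # prefix oracle on random streams
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    vals <- rnorm(n, 50, 10)
    times <- sort(runif(n, 0, 72))
    got <- compute_cumulative_features(vals, times)
    for (i in seq_len(n)) {
      pre <- vals[1:i]
      sd_pop <- sqrt(mean((pre - mean(pre))^2))
      expect_equal(unname(got[i, ]),
                   c(mean(pre), median(pre), i, min(pre), max(pre), sd_pop,
                     vals[1], if (i == 1) 0 else times[i] - times[i - 1]),
                   tolerance = 1e-12)
    }
  }
  expect_error(compute_cumulative_features(c(1, 2), c(3, 1)), "sorted")
})

test_that("training-set standardization gives zero mean and unit variance per variable feature", {
  co <- small_cohort(40L, seed = 9L)
  pipe <- small_pipeline(co)
  toks <- do.call(rbind, lapply(pipe$tok, `[[`, "tokens"))
  for (v in sample(pipe$vocab$variables$variable, 5)) {
    vid <- pipe$vocab$variables$id[pipe$vocab$variables$variable == v]
    rows <- toks[toks[, "f"] == vid, , drop = FALSE]
    if (nrow(rows) < 2) next
    for (col in c("value", "cum_mean", "cum_count")) {
      x <- rows[, col]
      if (sd(x) == 0) next  # degenerate column guard takes over
      expect_lt(abs(mean(x)), 1e-9)
      expect_lt(abs(mean((x - mean(x))^2) - 1), 1e-6)
    }
  }
  # time column standardized globally across training tokens
  expect_lt(abs(mean(toks[, "t"])), 1e-9)
})

test_that("static processing imputes, masks, one-hot encodes and keeps a fixed width", {
  co <- small_cohort(30L, seed = 12L)
  pipe <- small_pipeline(co)
  art <- pipe$artifacts
  vecs <- lapply(co$stays, function(s) process_static(s$static_record, art))
  widths <- vapply(vecs, length, 1L)
  expect_equal(length(unique(widths)), 1L)
  # missing numeric -> median-imputed (standardized value of the median)
  rec <- co$stays[[1]]$static_record
  rec$age <- NA_real_
  v <- process_static(rec, art)
  st <- art$numeric_stats$age
  expect_equal(v[["age"]], (st$median - st$mean) / st$scale)
  expect_equal(v[["age_missing"]], 1)
  # categorical one-hot block
  rec$sex <- "F"
  v <- process_static(rec, art)
  expect_equal(unname(v[paste0("sex=", art$catalogs$sex)]),
               as.numeric(art$catalogs$sex == "F"))
  # unseen level -> all-zero block; unknown column -> error
  rec$sex <- "X"
  v <- process_static(rec, art)
  expect_equal(sum(v[paste0("sex=", art$catalogs$sex)]), 0)
  rec$bogus <- 1
  expect_error(process_static(rec, art), "unknown column")
})

test_that("constant columns are flagged and transform to exact zero", {
  stays <- lapply(1:5, function(i) {
    list(stay_id = paste0("s", i), patient_id = paste0("p", i),
         admit_time = i, los_hours = 10,
         static_record = list(flat = 3, sex = "F"),
         events = toy_events(paste0("s", i), "hr", "vital", c(1, 2),
                             c(60, 60)),
         labels = stats::setNames(rep(0L, 7), all_tasks()))
  })
  vocab <- build_vocab(do.call(rbind, lapply(stays, `[[`, "events")),
                       n_stays = 5L)
  art <- fit_transforms(stays, vocab)
  expect_true(art$numeric_stats$flat$degenerate)
  expect_equal(process_static(stays[[1]]$static_record, art)[["flat"]], 0)
  tok <- tokenize_stay(stays[[1]]$events, vocab, art)
  expect_true(all(tok[, "value"] == 0))
})

test_that("tokenization yields 12 columns, per-variable histories and row-order invariance", {
  co <- small_cohort(25L, seed = 5L)
  pipe <- small_pipeline(co)
  for (t in pipe$tok[1:10]) expect_equal(ncol(t$tokens), 12L)
  # interleaved variables: cumulative count of each token counts only its
  # own variable's prior events
  s <- co$stays[[which.max(vapply(co$stays, function(s) nrow(s$events), 1L))]]
  tok <- tokenize_stay(s$events, pipe$vocab, pipe$artifacts)
  # row-order invariance: shuffle the raw event rows and retokenize
  set.seed(1)
  shuffled <- s$events[sample(nrow(s$events)), ]
  tok2 <- tokenize_stay(shuffled, pipe$vocab, pipe$artifacts)
  expect_equal(tok, tok2)
  # out-of-vocab events are dropped; all-OOV stay gives empty matrix
  alien <- toy_events("x", "martian_lab", "lab", 1, 5)
  expect_warning(empty <- tokenize_stay(alien, pipe$vocab, pipe$artifacts),
                 "no in-vocabulary")
  expect_equal(dim(empty), c(0L, 12L))
})

test_that("per-variable cumulative features ignore other variables' events", {
  ev <- rbind(toy_events("s", "hr", "vital", c(1, 2, 4), c(60, 80, 100)),
              toy_events("s", "rr", "vital", c(1.5, 3), c(12, 20)))
  vocab <- build_vocab(ev, n_stays = 1L)
  # identity transform artifacts: fit on this single stay
  stay <- list(stay_id = "s", patient_id = "p", admit_time = 0,
               los_hours = 5, static_record = list(age = 50, sex = "F"),
               events = ev,
               labels = stats::setNames(rep(0L, 7), all_tasks()))
  art <- fit_transforms(list(stay), vocab)
  tok <- tokenize_stay(ev, vocab, art)
  hr_id <- vocab$variables$id[vocab$variables$variable == "hr"]
  hr_rows <- tok[tok[, "f"] == hr_id, ]
  # destandardize the count column for hr and compare to 1,2,3
  st <- art$var_stats[["hr"]]
  counts <- hr_rows[, "cum_count"] * st$scale[["cum_count"]] +
    st$mean[["cum_count"]]
  expect_equal(unname(counts), c(1, 2, 3), tolerance = 1e-9)
})

test_that("stay exclusion applies the LOS window and token cap with a reason log", {
  stays <- lapply(list(0.5, 48, 300), function(l) {
    list(stay_id = paste0("los", l), los_hours = l)
  })
  fl <- filter_stays(stays, token_counts = c(10L, 500L, 10L))
  expect_equal(vapply(fl$stays, `[[`, 0, "los_hours"), 48)
  expect_setequal(fl$log$reason, c("los_too_short", "los_too_long"))
  fl2 <- filter_stays(list(list(stay_id = "big", los_hours = 48),
                           list(stay_id = "ok", los_hours = 48)),
                      token_counts = c(12001L, 12000L))
  expect_equal(fl2$log$stay_id, "big")
  expect_equal(fl2$log$reason, "too_many_tokens")
})

test_that("vocab and artifacts survive JSON round trips", {
  co <- small_cohort(15L, seed = 14L)
  pipe <- small_pipeline(co)
  vp <- withr::local_tempfile(fileext = ".json")
  ap <- withr::local_tempfile(fileext = ".json")
  write_vocab(pipe$vocab, vp)
  v2 <- read_vocab(vp)
  expect_equal(pipe$vocab$variables$variable, v2$variables$variable)
  expect_equal(pipe$vocab$variables$id, v2$variables$id)
  write_artifacts(pipe$artifacts, ap)
  a2 <- read_artifacts(ap)
  expect_equal(pipe$artifacts$time_mean, a2$time_mean)
  v <- pipe$vocab$variables$variable[1]
  expect_equal(unname(pipe$artifacts$var_stats[[v]]$mean),
               unname(a2$var_stats[[v]]$mean))
  # transforms computed from reloaded artifacts agree
  s <- co$stays[[1]]
  expect_equal(tokenize_stay(s$events, v2, a2),
               tokenize_stay(s$events, pipe$vocab, pipe$artifacts))
})
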