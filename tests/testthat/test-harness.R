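# Harness: chronological grouped split, AUROC, early stopping, evaluation.

make_stays <- function(n, pids = sprintf("p%02d", seq_len(n)),
                       admit = seq_len(n)) {
  lapply(seq_len(n), function(i) {
    list(stay_id = sprintf("s%02d", i), patient_id = pids[i],
         admit_time = admit[i], los_hours = 24)
  })
}

test_that("chronological split takes the earliest 80% and groups boundary patients", {
  st <- make_stays(10L)
  sp <- chronological_split(st, seed = 1L)
  expect_equal(length(sp$dev) + length(sp$val), 8L)
  expect_equal(length(sp$heldout), 2L)
  held_admits <- vapply(sp$heldout, `[[`, 0, "admit_time")
  expect_true(all(held_admits > 8))
  # a patient straddling the 80% threshold is pulled into development
  pids <- sprintf("p%02d", 1:10)
  pids[9] <- "p08"  # stay 9 shares its patient with stay 8
  st2 <- make_stays(10L, pids = pids)
  sp2 <- chronological_split(st2, seed = 1L)
  expect_equal(length(sp2$heldout), 1L)
  dev_pids <- vapply(c(sp2$dev, sp2$val), `[[`, "", "patient_id")
  expect_true("p08" %in% dev_pids)
  expect_false("p08" %in% vapply(sp2$heldout, `[[`, "", "patient_id"))
  expect_error(chronological_split(make_stays(5L)), "at least 10")
})

test_that("no patient ever spans development and held-out cohorts", {
  for (seed in 1:5) {
    co <- generate_cohort(sim_config(n_patients = 60L,
                                     multi_stay_prob = 0.4, seed = seed))
    sp <- chronological_split(co$stays, seed = seed)
    dev_pids <- vapply(c(sp$dev, sp$val), `[[`, "", "patient_id")
    held_pids <- vapply(sp$heldout, `[[`, "", "patient_id")
    expect_length(intersect(dev_pids, held_pids), 0L)
    # stay sets partition the cohort
    ids <- c(vapply(sp$dev, `[[`, "", "stay_id"),
             vapply(sp$val, `[[`, "", "stay_id"),
             vapply(sp$heldout, `[[`, "", "stay_id"))
    expect_equal(sort(ids),
                 sort(vapply(co$stays, `[[`, "", "stay_id")))
  }
})

test_that("AUROC matches the all-pairs Mann-Whitney count with midrank ties", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_warning(one <- auroc(1:4, c(1, 1, 1, 1)), "single-class")
  expect_true(is.na(one))
  set.seed(33)
  for (rep in 1:5) {
    n <- 200
    y <- rbinom(n, 1, 0.3)
    s <- round(rnorm(n, y), 1)  # rounded -> plenty of ties
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    brute <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                         ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
    expect_equal(auroc(s, y), brute, tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(auroc(s, y), ref, tolerance = 1e-9)
    }
  }
})

test_that("training stops after patience non-improving epochs and returns the best checkpoint", {
  co <- generate_cohort(sim_config(n_patients = 40L, seed = 30L))
  pipe <- small_pipeline(co)
  sp <- chronological_split(co$stays, seed = 2L)
  model <- acuity_model("gru", gru_hidden = 4L, seed = 2L)
  prep <- function(part) prepare_samples(model, part,
                                         tokenize_cohort(part, pipe$vocab,
                                                         pipe$artifacts),
                                         pipe$vocab, pipe$artifacts)
  dev <- prep(sp$dev); val <- prep(sp$val)
  spec <- train_spec(max_epochs = 12L, patience = 2L, batch_size = 8L,
                     seed = 5L)
  fit <- suppressWarnings(fit_acuity(model, dev, val, spec))
  h <- fit$history
  expect_true(nrow(h) <= 12L)
  # the returned checkpoint's metric is the max over history
  expect_equal(fit$best_metric, max(h$val_mean_auroc))
  expect_equal(fit$best_epoch, which.max(h$val_mean_auroc))
  # if stopped early, the last patience epochs did not improve
  if (nrow(h) < 12L) {
    expect_true(all(!h$improved[(nrow(h) - 1L):nrow(h)]))
  }
  # determinism: same seed, same data -> identical history
  fit2 <- suppressWarnings(fit_acuity(acuity_model("gru", gru_hidden = 4L,
                                                   seed = 2L),
                                      dev, val, spec))
  expect_equal(fit$history, fit2$history)
  expect_equal(fit$params, fit2$params)
})

test_that("evaluation reports the arithmetic mean of the six acuity AUROCs, auxiliary apart", {
  co <- generate_cohort(sim_config(n_patients = 150L, seed = 31L))
  pipe <- small_pipeline(co)
  sp <- chronological_split(co$stays, seed = 3L)
  model <- acuity_model("xgb", nrounds = 20L, seed = 3L)
  prep <- function(part) prepare_samples(model, part,
                                         tokenize_cohort(part, pipe$vocab,
                                                         pipe$artifacts),
                                         pipe$vocab, pipe$artifacts)
  fit <- suppressWarnings(fit_acuity(model, prep(sp$dev), prep(sp$val)))
  res <- suppressWarnings(evaluate_model(fit, prep(sp$heldout)))
  expect_equal(res$mean, mean(res$per_task, na.rm = TRUE))
  expect_named(res$per_task, acuity_tasks())
  expect_false("aux_long_readmission" %in% names(res$per_task))
  expect_true(is.numeric(res$aux))
  expect_equal(names(res$table),
               c("model", "data", "mean", acuity_tasks()))
  # two evaluations of one fitted model agree exactly
  res2 <- suppressWarnings(evaluate_model(fit, prep(sp$heldout)))
  expect_identical(res$per_task, res2$per_task)
})

test_that("neural model checkpoints round-trip through JSON", {
  co <- generate_cohort(sim_config(n_patients = 30L, seed = 32L))
  pipe <- small_pipeline(co)
  cfg <- model_config(layers = 1L, hidden = 8L, feedforward = 16L,
                      heads = 2L, window = 8L)
  sp <- chronological_split(co$stays, seed = 4L)
  model <- acuity_model("longformer", encoder_cfg = cfg, seed = 6L)
  prep <- function(part) prepare_samples(model, part,
                                         tokenize_cohort(part, pipe$vocab,
                                                         pipe$artifacts),
                                         pipe$vocab, pipe$artifacts)
  dev <- prep(sp$dev); val <- prep(sp$val)
  fit <- suppressWarnings(fit_acuity(model, dev, val,
                                     train_spec(max_epochs = 1L, seed = 6L),
                                     vocab = pipe$vocab))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_equal(stats::predict(back, val), stats::predict(fit, val),
               tolerance = 1e-12)
})
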