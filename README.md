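# icuseq

Tokenized sequence models for multi-task ICU acuity estimation in R.

ICU electronic health records are irregular by nature: vitals, labs,
medications and bedside assessment scores arrive at arbitrary times, often
several at the same timestamp, and every stay observes a different subset of
variables. Most sequence models force this stream onto a regular grid with
resampling and imputation. `icuseq` instead models the raw event stream: it
is written for methods researchers who want a complete, inspectable,
pure-R implementation of flexible EHR tokenization and
sliding-window-attention sequence classification, exercised end to end on a
synthetic cohort with a planted severity signal.

## The model

Each clinical event becomes a 12-tuple token $(p, f, t, \vec v)$:

* $p$ — dense-rank position of the event's timestamp (simultaneous events
  share a position: hours $[0.1, 0.2, 0.2, 0.3, 0.3]$ →
  positions $[0, 1, 1, 2, 2]$);
* $f$ — integer variable id (labs/medications filtered at ≥ 1% training
  prevalence, vitals and assessments always kept);
* $t$ — standardized elapsed hours from ICU admission;
* $\vec v$ — current value plus eight cumulative statistics of the same
  variable's history in the stay (mean, median, count, min, max, SD, first
  value, gap since previous), standardized per (variable, feature).

Token embeddings are a sum $W[t;\vec v] + E_f + \mathrm{PE}_p$: a linear
map of time and values, an id lookup, and a sinusoidal encoding at the
(non-unique) position. The sequence
`[static token][7 task tokens][events]` passes through a pre-norm
transformer encoder with sliding-window attention plus global attention on
the 8 special tokens; a linear head per task reads the concatenation of its
task token's representation at every layer. The six scored outcomes are ICU
readmission, inpatient mortality, and 7-day/30-day/90-day/1-year mortality
(an auxiliary long-term readmission head regularizes training only). The
loss is the mean per-task binary cross-entropy; early stopping monitors the
validation mean AUROC over the six acuity tasks with patience 4.

Comparison families behind the same split/train/evaluate path: a
discrete-only transformer (values omitted from the embedding), GRU and
GRU+attention on hourly-resampled series, a tokenized GRU+attention reusing
the same embedding module, and two gradient-boosted-tree adapters on
flattened per-variable features.

Everything neural runs on a small reverse-mode autodiff engine over base R
matrices, gradient-checked against finite differences in the test suite;
the sliding+global attention is pinned to an independent dense
masked-attention oracle at 1e-5.

## Worked example

```r
library(icuseq)

# a 500-patient synthetic ICU cohort with the default planted acuity signal
cohort <- generate_cohort(sim_config(n_patients = 500,
                                     los_range_hours = c(1, 72), seed = 42))
cohort
#> icu_cohort: 551 stays, 500 patients, 65963 events

# chronological grouped split; vocabulary + standardization fit on development
split <- chronological_split(cohort$stays, seed = 42)
dev <- c(split$dev, split$val)
vocab <- build_vocab(do.call(rbind, lapply(dev, `[[`, "events")),
                     n_stays = length(dev))
vocab
#> vocab_map: 30 variables + 9 reserved ids (prevalence filter 1.0% over 440 stays)
artifacts <- fit_transforms(dev, vocab)

# one held-out stay as a 12-column token matrix (first 5 tokens, 7 of 12 cols)
tok <- tokenize_cohort(split$heldout[1], vocab, artifacts)[[1]]
round(tok$tokens[1:5, c("p", "f", "t", "value", "cum_mean", "cum_count",
                        "gap_hours")], 2)
#>      p  f     t value cum_mean cum_count gap_hours
#> [1,] 0 21 -1.41 -0.29    -0.36     -1.08     -0.84
#> [2,] 1 32 -1.40 -0.18    -0.27     -0.87     -0.72
#> [3,] 2 12 -1.37  0.14     0.18     -1.02     -0.78
#> [4,] 3 33 -1.36 -0.52    -1.00     -1.27     -0.93
#> [5,] 3 34 -1.36 -0.50    -0.90     -1.28     -0.92
```

Rows 4–5 share position 3: two simultaneous measurements of the same panel.
All continuous columns are standardized with training statistics, so a
`cum_count` of −1.08 simply means "fewer prior measurements than the
training average for this variable".

Model comparison on the desk-scale study conditions (~2,000 stays, reduced
2-layer / hidden-32 encoder — see `benchmark_conditions()`):

```r
cond <- benchmark_conditions(seed = 8)
bm <- benchmark_models(generate_cohort(cond$sim),
                       families = c("longformer", "longformer_discrete"),
                       encoder_cfg = cond$encoder,
                       spec = train_spec(max_epochs = 4, seed = 1),
                       max_tokens = cond$max_tokens)
transform(bm$grid[, c("model", "mean")], mean = round(mean, 3))
#>                 model  mean
#> 1          longformer 0.893
#> 2 longformer_discrete 0.558
```

The value-aware transformer recovers the planted acuity signal (held-out
mean AUROC 0.89 over the six tasks; readmission 0.82, 7-day mortality 0.92)
while the discrete-only variant, which sees the same token identities and
times but no measurement values, stays far behind — the model ordering the
tokenization scheme is designed to produce. Individual AUROCs vary with the
cohort seed; readmission is the hardest task by construction (its label
link tops out near AUROC 0.83).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/icuseq simulate --out cohort --patients 500 --seed 42
Rscript inst/cli/icuseq benchmark --cohort cohort --families longformer,xgb
```

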