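# Synthetic ICU cohort generator with a planted acuity signal.
#
# The generator emulates the statistical shape of an EHR-derived ICU cohort:
# irregular event times from per-variable Poisson processes, simultaneous
# vital-sign panels, per-stay variable subsets, stay lengths from ~1 hour to
# 10 days, and six correlated binary outcomes driven by a latent per-stay
# acuity. It makes no attempt at physiological realism; its purpose is to
# exercise the tokenizer, sequence models and harness end to end.

#' Configuration for the synthetic ICU cohort generator
#'
#' The defaults define the reference study conditions used throughout the
#' package: outcome prevalences and the acuity-outcome separability were
#' calibrated against published ICU cohort summary statistics (1-year
#' mortality near 20-30%, readmission near 6-8%, rank AUROC of the latent
#' acuity against mortality near 0.90) before any model was trained on them.
#'
#' @param n_patients number of patients (each contributes 1+ stays).
#' @param multi_stay_prob probability a patient contributes a second stay.
#' @param n_vitals,n_labs,n_meds,n_assess number of distinct variables per
#'   category. The first medication is a designated "rescue" medication whose
#'   administration frequency carries the discrete part of the acuity signal.
#' @param panel_prob probability mass of vital measurements arriving as
#'   simultaneous all-vital panels rather than independent readings.
#' @param base_rates named events/hour rates for categories
#'   `vital`, `lab`, `medication`, `assessment`.
#' @param acuity_effect strength of the planted signal on measurement values
#'   (an acuity-proportional time trend, in within-variable SD units).
#' @param discrete_effect log-rate coefficient of acuity on the rescue
#'   medication's administration frequency.
#' @param los_range_hours inclusive `[min, max]` ICU length-of-stay window;
#'   must lie within `[1, 240]` hours.
#' @param hazard_scale baseline exponential death hazard (events/hour).
#' @param hazard_acuity log-hazard coefficient of acuity; the death hazard is
#'   `hazard_scale * exp(hazard_acuity * acuity)`.
#' @param include_probs per-category probability that a lab / medication /
#'   assessment variable is part of a given stay's variable subset.
#' @param static_missing_prob missingness rate injected into numeric static
#'   columns.
#' @param seed integer seed; the whole cohort is a pure function of the
#'   configuration.
#' @return a `sim_config` object (validated list).
#' @export
sim_config <- function(n_patients = 500L,
                       multi_stay_prob = 0.12,
                       n_vitals = 6L, n_labs = 12L, n_meds = 8L, n_assess = 4L,
                       panel_prob = 0.3,
                       base_rates = c(vital = 0.30, lab = 0.10,
                                      medication = 0.05, assessment = 0.08),
                       acuity_effect = 1.0,
                       discrete_effect = 0.5,
                       los_range_hours = c(1, 240),
                       hazard_scale = 2e-5,
                       hazard_acuity = 2.0,
                       include_probs = c(lab = 0.5, medication = 0.4,
                                         assessment = 0.7),
                       static_missing_prob = 0.10,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), multi_stay_prob = multi_stay_prob,
    n_vitals = as.integer(n_vitals), n_labs = as.integer(n_labs),
    n_meds = as.integer(n_meds), n_assess = as.integer(n_assess),
    panel_prob = panel_prob, base_rates = base_rates,
    acuity_effect = acuity_effect, discrete_effect = discrete_effect,
    los_range_hours = as.numeric(los_range_hours),
    hazard_scale = hazard_scale, hazard_acuity = hazard_acuity,
    include_probs = include_probs,
    static_missing_prob = static_missing_prob,
    seed = as.integer(seed)
  )
  probs <- c(cfg$multi_stay_prob, cfg$panel_prob, cfg$include_probs,
             cfg$static_missing_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(cfg$n_patients, cfg$n_vitals, cfg$n_labs, cfg$n_meds,
              cfg$n_assess)
  if (any(counts < 1L)) {
    stop("sim_config: counts must be >= 1", call. = FALSE)
  }
  if (any(cfg$base_rates <= 0) || cfg$hazard_scale <= 0) {
    stop("sim_config: rates must be positive", call. = FALSE)
  }
  if (length(cfg$los_range_hours) != 2L ||
      cfg$los_range_hours[1] < 1 || cfg$los_range_hours[2] > 240 ||
      diff(cfg$los_range_hours) < 0) {
    stop("sim_config: los_range_hours must be within [1, 240] hours",
         call. = FALSE)
  }
  if (!setequal(names(cfg$base_rates),
                c("vital", "lab", "medication", "assessment"))) {
    stop("sim_config: base_rates must name all four categories",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# variable catalog: name, category, baseline mean/sd and an acuity loading
.sim_variables <- function(cfg) {
  nm <- c(sprintf("vital_%02d", seq_len(cfg$n_vitals)),
          sprintf("lab_%02d", seq_len(cfg$n_labs)),
          c("med_rescue",
            if (cfg$n_meds > 1L) sprintf("med_%02d", seq_len(cfg$n_meds)[-1])),
          sprintf("assess_%02d", seq_len(cfg$n_assess)))
  cat <- rep(c("vital", "lab", "medication", "assessment"),
             c(cfg$n_vitals, cfg$n_labs, cfg$n_meds, cfg$n_assess))
  n <- length(nm)
  data.frame(
    variable = nm, category = cat,
    base = round(stats::runif(n, 10, 150), 2),
    sd = round(stats::runif(n, 1, 15), 2),
    loading = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
}

.sim_static_record <- function(acuity, cfg) {
  rec <- list(
    age = round(stats::rnorm(1, 62 + 3 * acuity, 14)),
    sex = sample(c("F", "M"), 1L),
    bmi = round(stats::rnorm(1, 28, 6), 1),
    charlson = stats::rpois(1, 2 * exp(0.3 * acuity)),
    distance_km = round(stats::rexp(1, 1 / 40), 1),
    admission_type = sample(c("elective", "emergent", "urgent"), 1L,
                            prob = c(0.3, 0.5, 0.2)),
    insurance = sample(c("medicare", "private", "medicaid", "uninsured"), 1L,
                       prob = c(0.5, 0.22, 0.17, 0.11))
  )
  for (col in c("age", "bmi", "charlson", "distance_km")) {
    if (stats::runif(1) < cfg$static_missing_prob) rec[[col]] <- NA_real_
  }
  rec
}

.sim_stay_events <- function(stay_id, acuity, los, vars, cfg) {
  rows <- vector("list", nrow(vars) + 1L)
  k <- 0L
  # vital panels: all vitals measured at shared timestamps
  vit <- vars[vars$category == "vital", , drop = FALSE]
  n_panel <- stats::rpois(1, cfg$base_rates[["vital"]] * cfg$panel_prob * los)
  if (n_panel > 0L) {
    pt <- stats::runif(n_panel, 0, los)
    k <- k + 1L
    rows[[k]] <- data.frame(
      variable = rep(vit$variable, each = n_panel),
      category = "vital",
      time_hours = rep(pt, nrow(vit)),
      base = rep(vit$base, each = n_panel),
      sd = rep(vit$sd, each = n_panel),
      loading = rep(vit$loading, each = n_panel),
      stringsAsFactors = FALSE
    )
  }
  # independent events per included variable
  inc <- cfg$include_probs
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    rate <- cfg$base_rates[[v$category]]
    if (v$category == "vital") {
      rate <- rate * (1 - cfg$panel_prob)
    } else {
      p_inc <- if (v$variable == "med_rescue") 1.0 else inc[[v$category]]
      if (stats::runif(1) >= p_inc) next
    }
    if (v$variable == "med_rescue") {
      rate <- rate * exp(cfg$discrete_effect * acuity)
    }
    n_ev <- stats::rpois(1, rate * los)
    if (n_ev == 0L) next
    k <- k + 1L
    rows[[k]] <- data.frame(
      variable = v$variable, category = v$category,
      time_hours = stats::runif(n_ev, 0, los),
      base = v$base, sd = v$sd, loading = v$loading,
      stringsAsFactors = FALSE
    )
  }
  if (k == 0L) {
    return(data.frame(stay_id = character(), variable = character(),
                      category = character(), time_hours = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, rows[seq_len(k)])
  trend <- 0.5 + 0.5 * ev$time_hours / los
  ev$value <- round(ev$base + ev$sd *
    (cfg$acuity_effect * ev$loading * acuity * trend +
       stats::rnorm(nrow(ev))), 4)
  ev <- ev[order(ev$time_hours, ev$variable, ev$value), ]
  data.frame(stay_id = stay_id, variable = ev$variable,
             category = ev$category, time_hours = ev$time_hours,
             value = ev$value, row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive the seven outcome labels for one ICU stay
#'
#' Mortality horizons are measured in hours from ICU admission (the anchor is
#' configurable only through the horizons themselves): the horizon-k label is
#' `death_time <= k * 24`. Inpatient mortality is death on or before hospital
#' discharge. The nesting 7d => 30d => 90d => 1y holds by construction. ICU
#' readmission is forced to 0 when the patient dies during the ICU stay.
#'
#' @param death_time_hours death time from ICU admission; `Inf` for survivors.
#' @param los_hours ICU length of stay in hours.
#' @param hospital_discharge_hours hospital discharge time from ICU admission;
#'   must be `>= los_hours`.
#' @param readmit_draw 0/1 draw for ICU readmission within the encounter.
#' @param aux_draw 0/1 draw for the auxiliary long-term hospital readmission
#'   target (used for regularization only, never scored as an acuity task).
#' @param horizons_days mortality horizons in days.
#' @return named integer vector of 7 labels.
#' @export
derive_labels <- function(death_time_hours, los_hours,
                          hospital_discharge_hours,
                          readmit_draw = 0L, aux_draw = 0L,
                          horizons_days = c(7, 30, 90, 365)) {
  stopifnot(death_time_hours > 0, los_hours <= hospital_discharge_hours)
  mort <- as.integer(death_time_hours <= horizons_days * 24)
  died_in_icu <- death_time_hours <= los_hours
  out <- c(
    icu_readmission = as.integer(readmit_draw == 1L && !died_in_icu),
    mortality_inpatient =
      as.integer(death_time_hours <= hospital_discharge_hours),
    mortality_7d = mort[1], mortality_30d = mort[2],
    mortality_90d = mort[3], mortality_1y = mort[4],
    aux_long_readmission = as.integer(aux_draw == 1L)
  )
  out
}

#' Names of the six scored acuity outcomes
#' @return character vector in reporting order.
#' @export
acuity_tasks <- function() {
  c("icu_readmission", "mortality_inpatient", "mortality_7d",
    "mortality_30d", "mortality_90d", "mortality_1y")
}

#' Names of all seven prediction targets (auxiliary last)
#' @return character vector.
#' @export
all_tasks <- function() c(acuity_tasks(), "aux_long_readmission")

#' Generate a synthetic ICU cohort
#'
#' Event times are homogeneous Poisson processes per (stay, variable) at the
#' configured category rate; a `panel_prob` fraction of vital measurements is
#' emitted as simultaneous all-vital panels. Values are a variable baseline
#' plus an acuity-proportional time trend plus Gaussian noise; the rescue
#' medication's event rate is multiplied by `exp(discrete_effect * acuity)`.
#' Death times are exponential with hazard
#' `hazard_scale * exp(hazard_acuity * acuity)`; death during the ICU stay
#' truncates the event stream and the length of stay. Hospital discharge is
#' ICU discharge plus an exponential tail (mean 46 h), so inpatient mortality
#' differs from any fixed ICU horizon.
#'
#' @param config a [sim_config()].
#' @return an `icu_cohort`: list with `stays` (list of stay records) and
#'   `config`. Each stay carries its events, static record, death and
#'   discharge times, latent acuity, and the 7 derived labels.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  vars <- .sim_variables(config)
  stays <- list()
  clock <- 0
  stay_no <- 0L
  for (p in seq_len(config$n_patients)) {
    patient_id <- sprintf("pat%05d", p)
    a_pat <- stats::rnorm(1)
    n_stays <- 1L + as.integer(stats::runif(1) < config$multi_stay_prob)
    for (s in seq_len(n_stays)) {
      stay_no <- stay_no + 1L
      stay_id <- sprintf("stay%05d", stay_no)
      acuity <- sqrt(0.5) * a_pat + sqrt(0.5) * stats::rnorm(1)
      clock <- clock + stats::rexp(1, 1 / 5)
      admit_time <- clock
      lo <- config$los_range_hours[1]
      hi <- config$los_range_hours[2]
      los <- min(max(stats::rlnorm(1, log(40), 0.9), lo), hi)
      rate <- config$hazard_scale * exp(config$hazard_acuity * acuity)
      death <- stats::rexp(1, rate)
      if (death <= los) los <- death
      hosp <- if (death <= los) death else los + stats::rexp(1, 1 / 46)
      readmit <- as.integer(stats::runif(1) <
                              stats::plogis(-3.2 + 1.5 * acuity))
      aux <- as.integer(stats::runif(1) < stats::plogis(-1.4 + 0.8 * acuity))
      labels <- derive_labels(death, los, hosp, readmit, aux)
      events <- .sim_stay_events(stay_id, acuity, los, vars, config)
      stays[[stay_no]] <- list(
        stay_id = stay_id, patient_id = patient_id,
        admit_time = admit_time, los_hours = los,
        latent_acuity = acuity,
        death_time_hours = death,
        hospital_discharge_hours = hosp,
        events = events,
        static_record = .sim_static_record(acuity, config),
        labels = labels
      )
      clock <- clock + los / 24
    }
  }
  structure(list(stays = stays, config = config), class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  n_ev <- sum(vapply(x$stays, function(s) nrow(s$events), 1L))
  cat(sprintf("icu_cohort: %d stays, %d patients, %d events\n",
              length(x$stays),
              length(unique(vapply(x$stays, `[[`, "", "patient_id"))),
              n_ev))
  invisible(x)
}

# ---- cohort container helpers ---------------------------------------------

#' Long-format event table for a cohort
#' @param cohort an `icu_cohort`.
#' @return data.frame with columns stay_id, variable, category, time_hours,
#'   value (one row per clinical event).
#' @export
cohort_events <- function(cohort) {
  if (!length(cohort$stays)) {
    return(data.frame(stay_id = character(), variable = character(),
                      category = character(), time_hours = numeric(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(lapply(cohort$stays, `[[`, "events"),
                   make.row.names = FALSE))
}

#' Static-feature table for a cohort (one row per stay)
#' @param cohort an `icu_cohort`.
#' @return data.frame; NA encodes injected missingness.
#' @export
cohort_static <- function(cohort) {
  if (!length(cohort$stays)) {
    return(data.frame(stay_id = character(), age = numeric(),
                      sex = character(), bmi = numeric(),
                      charlson = numeric(), distance_km = numeric(),
                      admission_type = character(),
                      insurance = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(cohort$stays, function(s) {
    c(list(stay_id = s$stay_id),
      lapply(s$static_record, function(v) if (is.null(v)) NA else v))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Label table for a cohort (one row per stay)
#' @param cohort an `icu_cohort`.
#' @return data.frame with stay_id, the 7 labels and los_hours.
#' @export
cohort_labels <- function(cohort) {
  if (!length(cohort$stays)) {
    out <- data.frame(stay_id = character())
    for (task in all_tasks()) out[[task]] <- integer()
    out$los_hours <- numeric()
    return(out)
  }
  do.call(rbind, lapply(cohort$stays, function(s) {
    data.frame(stay_id = s$stay_id, t(s$labels), los_hours = s$los_hours,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to a directory of delimited tables
#'
#' Produces `events.csv`, `static.csv`, `labels.csv` and `stays.csv` plus the
#' generator configuration as `config.yaml`. All tables carry headers even
#' when empty.
#'
#' @param cohort an `icu_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort_events(cohort), file.path(dir, "events.csv"))
  data.table::fwrite(cohort_static(cohort), file.path(dir, "static.csv"))
  data.table::fwrite(cohort_labels(cohort), file.path(dir, "labels.csv"))
  meta <- do.call(rbind, lapply(cohort$stays, function(s) {
    data.frame(stay_id = s$stay_id, patient_id = s$patient_id,
               admit_time = s$admit_time, los_hours = s$los_hours,
               latent_acuity = s$latent_acuity,
               death_time_hours = s$death_time_hours,
               hospital_discharge_hours = s$hospital_discharge_hours,
               stringsAsFactors = FALSE)
  }))
  if (is.null(meta)) {
    meta <- data.frame(stay_id = character(), patient_id = character(),
                       admit_time = numeric(), los_hours = numeric(),
                       latent_acuity = numeric(),
                       death_time_hours = numeric(),
                       hospital_discharge_hours = numeric())
  }
  data.table::fwrite(meta, file.path(dir, "stays.csv"))
  cfg <- unclass(cohort$config)
  cfg$base_rates <- as.list(cfg$base_rates)
  cfg$include_probs <- as.list(cfg$include_probs)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

.read_numeric_col <- function(x, col, file) {
  raw <- x[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) & !(is.na(raw) | raw == "" | raw == "NA"))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                 file, col, bad[1] + 1L), call. = FALSE)
  }
  val
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing the cohort tables.
#' @return an `icu_cohort`; round-trips all stay fields.
#' @export
read_cohort <- function(dir) {
  fe <- file.path(dir, "events.csv")
  events <- data.table::fread(fe, colClasses = "character",
                              data.table = FALSE)
  if (nrow(events)) {
    events$time_hours <- .read_numeric_col(events, "time_hours", "events.csv")
    events$value <- .read_numeric_col(events, "value", "events.csv")
  } else {
    events$time_hours <- numeric()
    events$value <- numeric()
  }
  static <- data.table::fread(file.path(dir, "static.csv"),
                              data.table = FALSE, na.strings = c("NA", ""))
  labels <- data.table::fread(file.path(dir, "labels.csv"),
                              data.table = FALSE)
  meta <- data.table::fread(file.path(dir, "stays.csv"), data.table = FALSE)
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfgl$base_rates <- unlist(cfgl$base_rates)
  cfgl$include_probs <- unlist(cfgl$include_probs)
  config <- do.call(sim_config, cfgl[setdiff(names(cfgl), character())])
  ev_split <- if (nrow(events)) split(events, events$stay_id) else list()
  empty_ev <- data.frame(stay_id = character(), variable = character(),
                         category = character(), time_hours = numeric(),
                         value = numeric(), stringsAsFactors = FALSE)
  stays <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$stay_id[i]
    ev <- ev_split[[sid]]
    if (is.null(ev)) ev <- empty_ev else row.names(ev) <- NULL
    li <- labels[labels$stay_id == sid, , drop = FALSE]
    lab <- as.integer(li[1, all_tasks()])
    names(lab) <- all_tasks()
    st <- static[static$stay_id == sid, , drop = FALSE]
    rec <- as.list(st[1, setdiff(names(st), "stay_id")])
    list(stay_id = sid, patient_id = meta$patient_id[i],
         admit_time = meta$admit_time[i], los_hours = meta$los_hours[i],
         latent_acuity = meta$latent_acuity[i],
         death_time_hours = meta$death_time_hours[i],
         hospital_discharge_hours = meta$hospital_discharge_hours[i],
         events = ev, static_record = rec, labels = lab)
  })
  structure(list(stays = stays, config = config), class = "icu_cohort")
}
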