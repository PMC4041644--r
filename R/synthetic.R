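# Synthetic flow-sheet generator.
#
# Emulates the event structure a neuroscience-ICU cohort produces in airway
# charting: every patient is intubated on admission, ventilated for >= 48 h,
# extubated, and then follows one scenario. The scenario catalog covers the
# documented misclassification modes of rule-based reintubation detection:
# nasal-trumpet insertions charted after extubation (false positives for the
# initial signature), accidental extubations with prompt reintubation and
# brief procedural reintubations (gold-negative yet genuinely reintubated,
# so false positives even for the final signature), extubation status
# charted with a non-matching token (false negatives), out-of-ICU
# intubations, and tracheostomy tube types.

SCENARIOS <- c("TRUE_FAILURE", "LATE_REINTUBATION", "NO_REINTUBATION",
               "NASAL_TRUMPET", "ACCIDENTAL_EXTUBATION",
               "PROCEDURAL_REINTUBATION", "MISCODED_STATUS",
               "OR_INTUBATION_ONLY", "TRACHEOSTOMY")

# Gold labels are fixed per scenario: accidental and procedural
# reintubations are gold-NEGATIVE (manual reviewers do not count them as
# extubation failure) although they are real endotracheal reintubations
# within the window — they are false-positive generators by design.
SCENARIO_GOLD <- c(
  TRUE_FAILURE = TRUE, MISCODED_STATUS = TRUE,
  LATE_REINTUBATION = FALSE, NO_REINTUBATION = FALSE,
  NASAL_TRUMPET = FALSE, ACCIDENTAL_EXTUBATION = FALSE,
  PROCEDURAL_REINTUBATION = FALSE, OR_INTUBATION_ONLY = FALSE,
  TRACHEOSTOMY = FALSE
)

round_minute <- function(t) {
  as.POSIXct(round(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

#' Configure a synthetic cohort
#'
#' @param n_patients Number of patients to generate.
#' @param prevalence Target gold-positive proportion; must equal the total
#'   probability mass of gold-positive scenarios in `mix`.
#' @param mix Named vector of scenario proportions summing to 1. Defaults to
#'   a clean cohort: `TRUE_FAILURE = prevalence`, the remainder split 80/20
#'   between `NO_REINTUBATION` and `LATE_REINTUBATION`.
#' @param n_ineligible Number of patients planted as cohort-ineligible
#'   (under-age or ventilated < 48 h), for exercising the eligibility funnel.
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, prevalence = 0.14, mix = NULL,
                          n_ineligible = 0L, seed = 1L) {
  if (n_patients < 1) config_error("n_patients must be positive")
  if (is.null(mix)) {
    mix <- c(TRUE_FAILURE = prevalence,
             NO_REINTUBATION = 0.8 * (1 - prevalence),
             LATE_REINTUBATION = 0.2 * (1 - prevalence))
  }
  unknown <- setdiff(names(mix), SCENARIOS)
  if (length(unknown) > 0) {
    config_error(sprintf("unknown scenario(s) in mix: %s",
                         paste(unknown, collapse = ", ")))
  }
  if (abs(sum(mix) - 1) > 1e-6) {
    config_error("scenario mix proportions must sum to 1")
  }
  pos_mass <- sum(mix[names(mix) %in% names(SCENARIO_GOLD)[SCENARIO_GOLD]])
  if (abs(pos_mass - prevalence) > 1e-6) {
    config_error(sprintf(
      "prevalence %.3f inconsistent with gold-positive scenario mass %.3f",
      prevalence, pos_mass))
  }
  if (n_ineligible > n_patients) {
    config_error("n_ineligible cannot exceed n_patients")
  }
  structure(
    list(n_patients = as.integer(n_patients), prevalence = prevalence,
         mix = mix, n_ineligible = as.integer(n_ineligible),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# One patient's charting. Runs inside an already-seeded RNG context.
# Timeline: ICU admission t0, intubation t0+1h, extubation after the
# ventilation period, then scenario-specific rows. All charting is rounded
# to minute resolution.
build_patient <- function(patient_id, scenario, t0, ineligible = FALSE) {
  if (ineligible && runif(1) < 0.5) {
    age <- round(runif(1, 14, 17.5), 1)
    vent_h <- runif(1, 50, 160)
  } else if (ineligible) {
    age <- round(runif(1, 18, 90), 1)
    vent_h <- runif(1, 6, 40)
  } else {
    age <- round(runif(1, 18, 90), 1)
    vent_h <- runif(1, 50, 160)
  }
  t_intub <- round_minute(t0 + 3600)
  t_ext <- round_minute(t_intub + vent_h * 3600)

  row <- function(time, name, value, location = "ICU") {
    list(timestamp = time, row_name = name, value = value, location = location)
  }
  rows <- list(
    row(t_intub, "Airway Tube Status", "Intubated"),
    row(t_intub, "Airway Tube Type", "Endotracheal tube")
  )
  # occasional mid-stay status noise exercises the OTHER class
  if (runif(1) < 0.25) {
    rows <- c(rows, list(row(round_minute(t_intub + runif(1, 2, vent_h - 2) * 3600),
                             "Airway Tube Status", "Patent")))
  }
  ext_value <- if (scenario == "MISCODED_STATUS") "Removed" else "Extubated"
  rows <- c(rows, list(row(t_ext, "Airway Tube Status", ext_value)))

  reint <- function(delay_h, status = "Intubated", type = "Endotracheal tube",
                    location = "ICU") {
    t <- round_minute(t_ext + delay_h * 3600)
    list(t, list(row(t, "Airway Tube Status", status, location),
                 row(t, "Airway Tube Type", type, location)))
  }
  t_reint <- parse_ts(NA_character_)
  extra <- list()
  if (scenario == "TRUE_FAILURE" || scenario == "MISCODED_STATUS") {
    r <- reint(runif(1, 1, 72))
    t_reint <- r[[1]]; extra <- r[[2]]
  } else if (scenario == "LATE_REINTUBATION") {
    r <- reint(runif(1, 73, 120))
    t_reint <- r[[1]]; extra <- r[[2]]
  } else if (scenario == "NASAL_TRUMPET") {
    r <- reint(runif(1, 1, 72), status = "Inserted", type = "Nasal trumpet")
    t_reint <- r[[1]]; extra <- r[[2]]
  } else if (scenario == "ACCIDENTAL_EXTUBATION") {
    r <- reint(runif(1, 0.1, 1))
    t_reint <- r[[1]]; extra <- r[[2]]
  } else if (scenario == "PROCEDURAL_REINTUBATION") {
    r <- reint(runif(1, 1, 48))
    t_reint <- r[[1]]
    t_reext <- round_minute(t_reint + runif(1, 0.5, 2) * 3600)
    extra <- c(r[[2]], list(row(t_reext, "Airway Tube Status", "Extubated")))
  } else if (scenario == "OR_INTUBATION_ONLY") {
    r <- reint(runif(1, 1, 72), location = "OR")
    t_reint <- r[[1]]; extra <- r[[2]]
  } else if (scenario == "TRACHEOSTOMY") {
    r <- reint(runif(1, 1, 72), type = "Tracheostomy")
    t_reint <- r[[1]]; extra <- r[[2]]
  }
  rows <- c(rows, extra)

  times <- do.call(c, lapply(rows, `[[`, "timestamp"))
  ord <- order(times)
  entries <- tibble(
    row_index = seq_along(rows),
    timestamp = times[ord],
    row_name = vapply(rows, `[[`, character(1), "row_name")[ord],
    value = vapply(rows, `[[`, character(1), "value")[ord],
    location = vapply(rows, `[[`, character(1), "location")[ord]
  )
  icu_end <- round_minute(max(times) + runif(1, 4, 24) * 3600)
  rec <- patient_record(
    patient_id, "A1", entries = entries,
    age_years = age, vent_duration_h = round(vent_h, 1),
    icu_start = round_minute(t0), icu_end = icu_end,
    gold_label = unname(SCENARIO_GOLD[scenario])
  )
  list(
    record = rec,
    manifest = tibble(
      patient_id = patient_id, admission_id = "A1", scenario = scenario,
      gold_label = unname(SCENARIO_GOLD[scenario]),
      eligible = !ineligible,
      extubation_time = t_ext, reintubation_time = t_reint
    )
  )
}

build_cohort <- function(scenarios, ineligible, id_prefix) {
  t_base <- parse_ts("2010-01-04T08:00")
  built <- lapply(seq_along(scenarios), function(i) {
    build_patient(sprintf("%s%04d", id_prefix, i), scenarios[i],
                  t_base + (i - 1) * 86400, ineligible[i])
  })
  list(
    records = lapply(built, `[[`, "record"),
    manifest = dplyr::bind_rows(lapply(built, `[[`, "manifest"))
  )
}

#' Generate a synthetic labeled cohort
#'
#' Each patient's scenario is drawn from the config's mix, so the realized
#' gold-positive count is binomial around `prevalence`. Identical configs
#' (including seed) generate identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `records` (list of
#'   [patient_record()] with gold labels), `manifest` (tibble of planted
#'   scenarios and times per patient), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  out <- withr::with_seed(config$seed, {
    scen <- sample(names(config$mix), config$n_patients, replace = TRUE,
                   prob = unname(config$mix))
    inel <- rep(FALSE, config$n_patients)
    if (config$n_ineligible > 0) {
      inel[sample.int(config$n_patients, config$n_ineligible)] <- TRUE
    }
    build_cohort(scen, inel, "S")
  })
  out$config <- config
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d gold-positive\n",
              length(x$records), sum(x$manifest$gold_label)))
  print(table(x$manifest$scenario))
  invisible(x)
}

# Deterministic packaged fixture: fixed scenario counts shuffled under a
# fixed internal seed.
build_fixture <- function(counts, seed, id_prefix) {
  scen <- rep(names(counts), counts)
  out <- withr::with_seed(seed, {
    build_cohort(sample(scen), rep(FALSE, length(scen)), id_prefix)
  })
  class(out) <- "synthetic_cohort"
  out
}

#' Packaged derivation-like fixture (100 patients)
#'
#' 14 gold-positives (12 clean true failures plus 2 with the extubation
#' status miscoded so no signature can see it), 4 nasal-trumpet insertions
#' (initial-signature false positives that the final signature's
#' endotracheal requirement eliminates), and 82 clean negatives. Against its
#' gold labels the initial signature yields the 2x2 table
#' (TP=12, FP=4, FN=2, TN=82); the final signature removes all 4 false
#' positives.
#'
#' @return A `synthetic_cohort`; deterministic (fixed internal seed).
#' @export
fixture_derivation <- function() {
  build_fixture(
    c(TRUE_FAILURE = 12, MISCODED_STATUS = 2, NASAL_TRUMPET = 4,
      NO_REINTUBATION = 66, LATE_REINTUBATION = 16),
    seed = 101L, id_prefix = "D")
}

#' Packaged validation-like fixture (100 patients)
#'
#' 16 gold-positives (15 clean true failures plus 1 miscoded-status miss)
#' and 4 gold-negative patients the final signature cannot distinguish from
#' failures — 2 accidental extubations with prompt reintubation and 2 brief
#' procedural reintubations, all genuine endotracheal reintubations within
#' 72 h — so the final signature disagrees with gold for exactly 5 patients
#' (4 false positives, 1 false negative).
#'
#' @return A `synthetic_cohort`; deterministic (fixed internal seed).
#' @export
fixture_validation <- function() {
  build_fixture(
    c(TRUE_FAILURE = 15, MISCODED_STATUS = 1, ACCIDENTAL_EXTUBATION = 2,
      PROCEDURAL_REINTUBATION = 2, NO_REINTUBATION = 64,
      LATE_REINTUBATION = 16),
    seed = 202L, id_prefix = "V")
}

#' Write a synthetic cohort to disk
#'
#' Emits `flowsheet.csv` and `metadata.csv` in the package's CSV dialects
#' plus `manifest.json` listing each patient's planted scenario.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_flowsheet(cohort$records, file.path(dir, "flowsheet.csv"))
  write_metadata(cohort$records, file.path(dir, "metadata.csv"))
  man <- cohort$manifest
  man$extubation_time <- format_ts(man$extubation_time)
  man$reintubation_time <- format_ts(man$reintubation_time)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, na = "null", digits = NA)
  invisible(dir)
}

#' Read a generator config from YAML or JSON
#'
#' Recognized keys mirror [cohort_config()]: `n_patients`, `prevalence`,
#' `mix` (named map), `n_ineligible`, `seed`.
#'
#' @param path Config file path.
#' @return A [cohort_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) data_error(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  allowed <- c("n_patients", "prevalence", "mix", "n_ineligible", "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    config_error(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$mix)) raw$mix <- unlist(raw$mix)
  do.call(cohort_config, raw)
}
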