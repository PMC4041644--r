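# Flow-sheet I/O, normalization, and cohort eligibility.

flowsheet_header <- "patient_id,admission_id,timestamp,row_name,value,location"

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

test_that("flow-sheet CSV rows group into one record per admission", {
  path <- write_lines_tmp(c(
    flowsheet_header,
    "P1,A1,2010-01-01T08:00,Airway Tube Status,Intubated,ICU",
    "P1,A1,2010-01-01T08:00,Airway Tube Type,Endotracheal tube,ICU",
    "P1,A1,2010-01-03T10:00,Airway Tube Status,Extubated,ICU"))
  recs <- quietly(read_flowsheet(path))
  expect_length(recs, 1)
  expect_s3_class(recs[[1]], "patient_record")
  expect_equal(nrow(recs[[1]]$entries), 3)
  expect_equal(recs[[1]]$entries$row_index, 1:3)

  empty <- quietly(read_flowsheet(write_lines_tmp(flowsheet_header)))
  expect_identical(empty, list())
})

test_that("malformed timestamps fail with the offending file row named", {
  path <- write_lines_tmp(c(
    flowsheet_header,
    "P1,A1,2010-01-01T08:00,Airway Tube Status,Intubated,ICU",
    "P1,A1,2010-99-99T08:00,Airway Tube Status,Extubated,ICU"))
  expect_error(quietly(read_flowsheet(path)), "row 3",
               class = "extufail_data_error")
  expect_error(quietly(read_flowsheet(write_lines_tmp("patient_id,timestamp"))),
               "missing required column",
               class = "extufail_data_error")
})

test_that("unknown locations map to OTHER with a warning", {
  path <- write_lines_tmp(c(
    flowsheet_header,
    "P1,A1,2010-01-01T08:00,Airway Tube Status,Intubated,Helipad"))
  expect_warning(recs <- suppressMessages(read_flowsheet(path)), "OTHER")
  expect_equal(recs[[1]]$entries$location, "OTHER")
})

test_that("write then read round-trips a full cohort field-for-field", {
  cohort <- fixture_derivation()
  dir <- tempfile()
  write_cohort(cohort, dir)
  back <- quietly(read_cohort(file.path(dir, "flowsheet.csv"),
                              file.path(dir, "metadata.csv")))
  expect_length(back, length(cohort$records))
  ids <- vapply(back, function(r) r$patient_id, character(1))
  for (orig in cohort$records) {
    r <- back[[match(orig$patient_id, ids)]]
    expect_identical(r$entries$timestamp, orig$entries$timestamp)
    expect_identical(r$entries$row_name, orig$entries$row_name)
    expect_identical(r$entries$value, orig$entries$value)
    expect_identical(r$entries$location, orig$entries$location)
    expect_identical(r$age_years, orig$age_years)
    expect_identical(r$vent_duration_h, orig$vent_duration_h)
    expect_identical(r$icu_start, orig$icu_start)
    expect_identical(r$icu_end, orig$icu_end)
    expect_identical(r$gold_label, orig$gold_label)
  }
})

test_that("status vocabulary drives event classes by whole-token match", {
  rec <- rec_from_rows(list(
    c("2010-01-01T08:00", "Airway Tube Status", "Extubated"),
    c("2010-01-01T10:00", "Airway Tube Status", "Inserted"),
    c("2010-01-01T12:00", "Airway Tube Status", "re-intubated"),
    c("2010-01-01T14:00", "Airway Tube Status", "Patent"),
    c("2010-01-01T16:00", "Airway Tube Status", "EXTUBATION done")))
  ev <- normalize_events(rec)
  expect_equal(ev$event_class,
               c("EXTUBATION", "INTUBATION", "OTHER", "OTHER", "EXTUBATION"))
  # matched-event count equals vocabulary-matching status rows
  expect_equal(sum(ev$event_class != "OTHER"), 3)
})

test_that("tube types associate by identical timestamp, then nearest in window", {
  rec <- rec_from_rows(list(
    c("2010-01-01T10:00", "Airway Tube Status", "Inserted"),
    c("2010-01-01T10:00", "Airway Tube Type", "Nasal trumpet"),
    c("2010-01-01T09:30", "Airway Tube Type", "Endotracheal tube")))
  ev <- normalize_events(rec)
  expect_equal(ev$tube_type[ev$event_class == "INTUBATION"], "NASAL_TRUMPET")

  # nearest within +/-60 min when no exact-timestamp row
  rec2 <- rec_from_rows(list(
    c("2010-01-01T10:00", "Airway Tube Status", "Inserted"),
    c("2010-01-01T10:45", "Airway Tube Type", "Tracheostomy"),
    c("2010-01-01T09:10", "Airway Tube Type", "Endotracheal tube")))
  ev2 <- normalize_events(rec2)
  expect_equal(ev2$tube_type[1], "TRACHEOSTOMY")

  # equidistant tie resolves to the earlier-charted entry
  rec3 <- rec_from_rows(list(
    c("2010-01-01T10:00", "Airway Tube Status", "Inserted"),
    c("2010-01-01T09:30", "Airway Tube Type", "Endotracheal tube"),
    c("2010-01-01T10:30", "Airway Tube Type", "Tracheostomy")))
  ev3 <- normalize_events(rec3)
  expect_equal(ev3$tube_type[1], "ENDOTRACHEAL")

  # nothing within the window -> UNKNOWN
  rec4 <- rec_from_rows(list(
    c("2010-01-01T10:00", "Airway Tube Status", "Inserted"),
    c("2010-01-01T11:30", "Airway Tube Type", "Endotracheal tube")))
  expect_equal(normalize_events(rec4)$tube_type[1], "UNKNOWN")
  expect_equal(normalize_events(rec4, assoc_window_min = 120)$tube_type[1],
               "ENDOTRACHEAL")
})

test_that("entry order within a patient never changes the event stream", {
  cohort <- fixture_validation()
  set.seed(42)
  for (rec in cohort$records[sample.int(100, 10)]) {
    ev <- normalize_events(rec)
    shuffled <- rec
    perm <- sample.int(nrow(rec$entries))
    shuffled$entries <- rec$entries[perm, ]
    ev2 <- normalize_events(shuffled)
    expect_identical(ev2$timestamp, ev$timestamp)
    expect_identical(ev2$event_class, ev$event_class)
    expect_identical(ev2$tube_type, ev$tube_type)
    # downstream call unchanged too
    expect_identical(detect(shuffled, final_signature())$positive,
                     detect(rec, final_signature())$positive)
  }
})

test_that("eligibility thresholds are inclusive and missing metadata excludes", {
  mk <- function(id, age, vent) patient_record(id, "A1", age_years = age,
                                               vent_duration_h = vent)
  recs <- list(mk("P1", 17.9, 100), mk("P2", 18, 48), mk("P3", 45, 47.9),
               mk("P4", 30, NA))
  expect_warning(kept <- suppressMessages(filter_cohort(recs)), "missing")
  expect_equal(vapply(kept, function(r) r$patient_id, character(1)), "P2")
  funnel <- attr(kept, "funnel")
  expect_equal(unname(funnel[c("input", "excluded_missing", "excluded_age",
                               "excluded_vent", "retained")]),
               c(4, 1, 1, 1, 1))
})

test_that("planted ineligible patients are excluded by the funnel", {
  cfg <- cohort_config(50, prevalence = 0.14, n_ineligible = 10, seed = 11)
  cohort <- generate_cohort(cfg)
  kept <- quietly(filter_cohort(cohort$records))
  expect_length(kept, 40)
  expect_setequal(vapply(kept, function(r) r$patient_id, character(1)),
                  cohort$manifest$patient_id[cohort$manifest$eligible])
})

test_that("subset sampling is seeded, uniform, and bounded", {
  recs <- lapply(1:978, function(i) patient_record(paste0("P", i), "A1"))
  s1 <- sample_subset(recs, 100, seed = 7)
  s2 <- sample_subset(recs, 100, seed = 7)
  expect_identical(vapply(s1, `[[`, character(1), "patient_id"),
                   vapply(s2, `[[`, character(1), "patient_id"))
  s3 <- sample_subset(recs, 100, seed = 8)
  expect_false(identical(vapply(s1, `[[`, character(1), "patient_id"),
                         vapply(s3, `[[`, character(1), "patient_id")))
  all_of_them <- sample_subset(recs, 978, seed = 1)
  expect_setequal(vapply(all_of_them, `[[`, character(1), "patient_id"),
                  vapply(recs, `[[`, character(1), "patient_id"))
  expect_error(sample_subset(recs, 979, seed = 1),
               class = "extufail_config_error")
})
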