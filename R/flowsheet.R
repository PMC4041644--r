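# Flow-sheet domain model and CSV I/O.
#
# A flow-sheet entry is one nurse-charted row: who/when/which row/what
# value/where. Entries are grouped per (patient_id, admission_id) into
# patient records carrying admission metadata (age, hours of mechanical
# ventilation, ICU stay interval) and an optional gold-standard label from
# manual chart review.

FLOWSHEET_COLS <- c("patient_id", "admission_id", "timestamp",
                    "row_name", "value", "location")
METADATA_COLS <- c("patient_id", "admission_id", "age_years",
                   "vent_duration_h", "icu_start", "icu_end", "gold_label")
KNOWN_LOCATIONS <- c("ICU", "ED", "OR", "PACU", "WARD", "OTHER")

TS_FORMAT <- "%Y-%m-%dT%H:%M"

parse_ts <- function(x) {
  as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
}

format_ts <- function(t) {
  out <- format(t, TS_FORMAT, tz = "UTC")
  out[is.na(t)] <- NA_character_
  out
}

empty_entries <- function() {
  tibble(
    row_index = integer(),
    timestamp = parse_ts(character()),
    row_name = character(),
    value = character(),
    location = character()
  )
}

#' Construct a patient record
#'
#' Bundles one ICU admission's flow-sheet entries with its metadata. Entries
#' need not arrive time-sorted; downstream normalization sorts them. Location
#' and row-name comparisons throughout the package are case-insensitive.
#'
#' @param patient_id,admission_id Opaque identifier strings.
#' @param entries Tibble with columns `row_index`, `timestamp` (POSIXct, UTC,
#'   minute resolution), `row_name`, `value`, `location`.
#' @param age_years,vent_duration_h Admission metadata: age and hours on
#'   mechanical ventilation during the ICU admission (supplied, not inferred
#'   from ventilator rows). `NA` when unknown.
#' @param icu_start,icu_end ICU stay interval (POSIXct); start must precede
#'   end when both are present.
#' @param gold_label Optional logical: extubation failure per manual review.
#'
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, admission_id, entries = empty_entries(),
                           age_years = NA_real_, vent_duration_h = NA_real_,
                           icu_start = parse_ts(NA_character_),
                           icu_end = parse_ts(NA_character_),
                           gold_label = NA) {
  entries <- as_tibble(entries)
  rec <- structure(
    list(
      patient_id = as.character(patient_id),
      admission_id = as.character(admission_id),
      age_years = as.numeric(age_years),
      vent_duration_h = as.numeric(vent_duration_h),
      icu_start = icu_start,
      icu_end = icu_end,
      gold_label = as.logical(gold_label),
      entries = entries
    ),
    class = "patient_record"
  )
  validate_patient_record(rec)
  rec
}

validate_patient_record <- function(rec) {
  if (!is.na(rec$age_years) && rec$age_years < 0) {
    data_error("age_years must be non-negative")
  }
  if (!is.na(rec$vent_duration_h) && rec$vent_duration_h < 0) {
    data_error("vent_duration_h must be non-negative")
  }
  if (!is.na(rec$icu_start) && !is.na(rec$icu_end) &&
      rec$icu_start >= rec$icu_end) {
    data_error(sprintf("icu_start must precede icu_end (patient %s)",
                       rec$patient_id))
  }
  invisible(rec)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s / %s: %d entries, age %s, vent %s h, gold %s\n",
              x$patient_id, x$admission_id, nrow(x$entries),
              format(x$age_years), format(x$vent_duration_h),
              format(x$gold_label)))
  invisible(x)
}

#' Read a flow-sheet CSV into patient records
#'
#' Expects the header `patient_id,admission_id,timestamp,row_name,value,location`
#' with timestamps as `YYYY-MM-DDTHH:MM` (single implicit timezone, minute
#' resolution). Rows are grouped per (patient_id, admission_id) in order of
#' first appearance; within a record, entries keep their file order as
#' `row_index` (provenance for normalized events).
#'
#' @param path Path to the CSV file.
#' @return A list of [patient_record()] objects, metadata fields unset (attach
#'   them with [attach_metadata()]).
#' @seealso [write_flowsheet()], [read_metadata()]
#' @export
read_flowsheet <- function(path) {
  if (!file.exists(path)) {
    data_error(sprintf("flow-sheet file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(FLOWSHEET_COLS, names(raw))
  if (length(missing_cols) > 0) {
    data_error(sprintf("flow-sheet CSV is missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    message("Parsed 0 flow-sheet rows into 0 patient records")
    return(list())
  }
  ts <- parse_ts(raw$timestamp)
  bad <- which(is.na(ts) | is.na(raw$patient_id) | is.na(raw$admission_id))
  if (length(bad) > 0) {
    # +1 for the header line so the reported number matches the file
    data_error(sprintf(
      "malformed timestamp or missing id at file row %d (value: %s)",
      bad[1] + 1L, raw$timestamp[bad[1]]))
  }
  loc <- toupper(trimws(raw$location))
  unknown <- !(loc %in% KNOWN_LOCATIONS) | is.na(loc)
  if (any(unknown)) {
    warn(sprintf("%d row(s) with unknown location mapped to OTHER (e.g. %s)",
                 sum(unknown), raw$location[which(unknown)[1]]))
    loc[unknown] <- "OTHER"
  }
  entries <- tibble(
    patient_id = raw$patient_id,
    admission_id = raw$admission_id,
    timestamp = ts,
    row_name = raw$row_name,
    value = raw$value,
    location = loc
  )
  key <- paste(entries$patient_id, entries$admission_id, sep = "\r")
  groups <- split(seq_len(nrow(entries)), factor(key, levels = unique(key)))
  records <- lapply(groups, function(idx) {
    ent <- entries[idx, c("timestamp", "row_name", "value", "location")]
    ent <- tibble(row_index = seq_along(idx), ent)
    patient_record(entries$patient_id[idx[1]], entries$admission_id[idx[1]],
                   entries = ent)
  })
  names(records) <- NULL
  message(sprintf("Parsed %d flow-sheet rows into %d patient records",
                  nrow(raw), length(records)))
  records
}

#' Write patient records back to the flow-sheet CSV dialect
#'
#' @param records List of [patient_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flowsheet <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (nrow(r$entries) == 0) return(NULL)
    tibble(
      patient_id = r$patient_id,
      admission_id = r$admission_id,
      timestamp = format_ts(r$entries$timestamp),
      row_name = r$entries$row_name,
      value = r$entries$value,
      location = r$entries$location
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(patient_id = character(), admission_id = character(),
                  timestamp = character(), row_name = character(),
                  value = character(), location = character())
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the patient metadata CSV
#'
#' Header: `patient_id,admission_id,age_years,vent_duration_h,icu_start,icu_end,gold_label`
#' with `gold_label` in {0, 1, NA}.
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per admission, with parsed timestamps and a
#'   logical `gold_label`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    data_error(sprintf("metadata file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(METADATA_COLS, names(raw))
  if (length(missing_cols) > 0) {
    data_error(sprintf("metadata CSV is missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  tibble(
    patient_id = raw$patient_id,
    admission_id = raw$admission_id,
    age_years = as.numeric(raw$age_years),
    vent_duration_h = as.numeric(raw$vent_duration_h),
    icu_start = parse_ts(raw$icu_start),
    icu_end = parse_ts(raw$icu_end),
    gold_label = as.logical(as.integer(raw$gold_label))
  )
}

#' Write admission metadata for a list of records
#'
#' @inheritParams write_flowsheet
#' @export
write_metadata <- function(records, path) {
  out <- dplyr::bind_rows(lapply(records, function(r) {
    tibble(
      patient_id = r$patient_id,
      admission_id = r$admission_id,
      age_years = r$age_years,
      vent_duration_h = r$vent_duration_h,
      icu_start = format_ts(r$icu_start),
      icu_end = format_ts(r$icu_end),
      gold_label = as.integer(r$gold_label)
    )
  }))
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Attach admission metadata to flow-sheet records
#'
#' Joins by (patient_id, admission_id). Metadata rows without any charted
#' entries become records with empty entry tables (such patients still get a
#' detector verdict: negative). Records without a metadata row keep `NA`
#' metadata and are later excluded by [filter_cohort()] with a warning.
#'
#' @param records List of [patient_record()] objects.
#' @param meta Tibble from [read_metadata()].
#' @param add_missing Create empty records for metadata-only admissions.
#' @return A list of [patient_record()] objects.
#' @export
attach_metadata <- function(records, meta, add_missing = TRUE) {
  rec_keys <- vapply(records, function(r) paste(r$patient_id, r$admission_id, sep = "\r"),
                     character(1))
  meta_keys <- paste(meta$patient_id, meta$admission_id, sep = "\r")
  if (anyDuplicated(meta_keys)) {
    data_error("duplicate (patient_id, admission_id) rows in metadata")
  }
  out <- lapply(seq_along(records), function(i) {
    j <- match(rec_keys[i], meta_keys)
    r <- records[[i]]
    if (is.na(j)) return(r)
    patient_record(r$patient_id, r$admission_id, entries = r$entries,
                   age_years = meta$age_years[j],
                   vent_duration_h = meta$vent_duration_h[j],
                   icu_start = meta$icu_start[j], icu_end = meta$icu_end[j],
                   gold_label = meta$gold_label[j])
  })
  if (add_missing) {
    extra <- which(!(meta_keys %in% rec_keys))
    out <- c(out, lapply(extra, function(j) {
      patient_record(meta$patient_id[j], meta$admission_id[j],
                     age_years = meta$age_years[j],
                     vent_duration_h = meta$vent_duration_h[j],
                     icu_start = meta$icu_start[j], icu_end = meta$icu_end[j],
                     gold_label = meta$gold_label[j])
    }))
  }
  out
}

#' Read flow-sheet and metadata files into one cohort
#'
#' @param flowsheet_path,meta_path CSV paths in the package's dialects.
#' @return A list of [patient_record()] objects with metadata attached.
#' @export
read_cohort <- function(flowsheet_path, meta_path) {
  attach_metadata(read_flowsheet(flowsheet_path), read_metadata(meta_path))
}

#' Apply the cohort eligibility filter
#'
#' Retains adults (age >= `min_age` years) mechanically ventilated for at
#' least `min_vent_h` hours during the ICU admission; both thresholds are
#' inclusive. Records with missing eligibility metadata are excluded
#' conservatively, with a warning. The funnel counts (input, excluded by
#' missing metadata / age / ventilation duration, retained) are logged and
#' attached as the `"funnel"` attribute so a run is auditable.
#'
#' @param records List of [patient_record()] objects.
#' @param min_age Minimum age in years (default 18).
#' @param min_vent_h Minimum hours of mechanical ventilation (default 48).
#' @return The retained records, with a `funnel` attribute.
#' @export
filter_cohort <- function(records, min_age = 18, min_vent_h = 48) {
  age <- vapply(records, function(r) r$age_years, numeric(1))
  vent <- vapply(records, function(r) r$vent_duration_h, numeric(1))
  missing_meta <- is.na(age) | is.na(vent)
  if (any(missing_meta)) {
    warn(sprintf("%d record(s) excluded: missing age or ventilation metadata",
                 sum(missing_meta)))
  }
  excl_age <- !missing_meta & age < min_age
  excl_vent <- !missing_meta & !excl_age & vent < min_vent_h
  keep <- !missing_meta & !excl_age & !excl_vent
  out <- records[keep]
  funnel <- c(input = length(records), excluded_missing = sum(missing_meta),
              excluded_age = sum(excl_age), excluded_vent = sum(excl_vent),
              retained = sum(keep))
  attr(out, "funnel") <- funnel
  message(sprintf(
    "Cohort funnel: %d in; %d missing metadata, %d under age %s, %d under %s vent-hours; %d retained",
    funnel[["input"]], funnel[["excluded_missing"]], funnel[["excluded_age"]],
    format(min_age), funnel[["excluded_vent"]], format(min_vent_h),
    funnel[["retained"]]))
  out
}

#' Draw a random patient subset
#'
#' Uniform sampling without replacement, reproducible under `seed`. Two draws
#' with different seeds are not guaranteed disjoint; remove the first subset
#' before drawing a second if disjointness is needed (as when splitting
#' derivation and validation subsets).
#'
#' @param records List of [patient_record()] objects.
#' @param n Subset size; must not exceed the population.
#' @param seed Integer seed.
#' @return A list of `n` records.
#' @export
sample_subset <- function(records, n = 100, seed) {
  if (n > length(records)) {
    config_error(sprintf("cannot sample %d from a population of %d",
                         n, length(records)))
  }
  idx <- withr::with_seed(seed, sample.int(length(records), n))
  records[idx]
}
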