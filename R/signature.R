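# The detection algorithm: temporal search signatures over airway events.
#
# A signature is a declarative rule: an extubation followed within window_h
# hours by a reintubation, both charted in the ICU during the same admission.
# The initial signature accepts any intubation-class charting; the final
# signature additionally requires the associated airway tube type to be an
# endotracheal tube, which eliminates nasal-trumpet insertions and
# tracheostomy/nasotracheal chartings.

#' Build a search signature
#'
#' @param name `"initial"` or `"final"`. The final signature differs from the
#'   initial one only by requiring an endotracheal tube type on the
#'   reintubation event.
#' @param window_h Detection window in hours (default 72); an event pair
#'   qualifies when `0 < delta <= window_h`.
#' @param icu_only Restrict both events to ICU-charted locations, excluding
#'   intubations performed in the emergency department or operating room
#'   (default `TRUE`).
#' @param require_endotracheal Override the tube-type requirement; defaults
#'   to `FALSE` for the initial signature and `TRUE` for the final one.
#' @return An object of class `airway_signature`.
#' @export
signature <- function(name = c("final", "initial"), window_h = 72,
                      icu_only = TRUE, require_endotracheal = NULL) {
  name <- toupper(match.arg(name))
  if (!is.numeric(window_h) || window_h <= 0) {
    config_error("window_h must be a positive number of hours")
  }
  if (is.null(require_endotracheal)) {
    require_endotracheal <- name == "FINAL"
  }
  structure(
    list(name = name, window_h = window_h,
         require_endotracheal = isTRUE(require_endotracheal),
         icu_only = isTRUE(icu_only)),
    class = "airway_signature"
  )
}

#' @rdname signature
#' @export
initial_signature <- function(window_h = 72, icu_only = TRUE) {
  signature("initial", window_h = window_h, icu_only = icu_only)
}

#' @rdname signature
#' @export
final_signature <- function(window_h = 72, icu_only = TRUE) {
  signature("final", window_h = window_h, icu_only = icu_only)
}

#' @export
print.airway_signature <- function(x, ...) {
  cat(sprintf("<airway_signature> %s: reintubation within %g h%s%s\n",
              x$name, x$window_h,
              if (x$require_endotracheal) ", endotracheal tube required" else "",
              if (x$icu_only) ", ICU locations only" else ""))
  invisible(x)
}

#' Enumerate qualifying extubation-reintubation pairs
#'
#' Returns every (extubation e, intubation i) pair with `i` strictly after
#' `e`, at most `window_h` hours apart, with no other extubation strictly
#' between them (each reintubation is paired with its most recent prior
#' extubation). With `icu_only`, only ICU-located events are considered;
#' with `require_endotracheal`, only intubations whose associated tube type
#' is `ENDOTRACHEAL` can complete a pair.
#'
#' @param events A tibble from [normalize_events()], sorted by timestamp,
#'   all from one patient-admission. Unsorted input is a contract violation.
#' @param sig An [signature()] object.
#' @return A tibble of evidence pairs ordered by extubation time:
#'   `extubation_time`, `reintubation_time`, `delta_h`, `tube_type`,
#'   `extubation_row`, `reintubation_row`.
#' @export
qualifying_pairs <- function(events, sig) {
  stopifnot(inherits(sig, "airway_signature"))
  if (is.unsorted(as.numeric(events$timestamp))) {
    abort("events must be sorted by timestamp (see normalize_events)")
  }
  ev <- events
  if (sig$icu_only) {
    ev <- ev[toupper(ev$location) == "ICU", ]
  }
  ext <- ev[ev$event_class == "EXTUBATION", ]
  int <- ev[ev$event_class == "INTUBATION", ]
  if (sig$require_endotracheal) {
    int <- int[!is.na(int$tube_type) & int$tube_type == "ENDOTRACHEAL", ]
  }
  out <- list()
  if (nrow(ext) > 0 && nrow(int) > 0) {
    ext_t <- as.numeric(ext$timestamp)
    for (k in seq_len(nrow(int))) {
      it <- as.numeric(int$timestamp[k])
      prior <- which(ext_t < it)
      if (length(prior) == 0) next
      # most recent prior extubation(s); ties at the same minute all pair
      latest <- prior[ext_t[prior] == max(ext_t[prior])]
      delta_h <- (it - ext_t[latest]) / 3600
      ok <- latest[delta_h <= sig$window_h]
      for (e in ok) {
        out[[length(out) + 1L]] <- tibble(
          extubation_time = ext$timestamp[e],
          reintubation_time = int$timestamp[k],
          delta_h = (it - ext_t[e]) / 3600,
          tube_type = int$tube_type[k],
          extubation_row = ext$source_row_index[e],
          reintubation_row = int$source_row_index[k]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(
      extubation_time = parse_ts(character()),
      reintubation_time = parse_ts(character()),
      delta_h = numeric(), tube_type = character(),
      extubation_row = integer(), reintubation_row = integer()))
  }
  pairs <- dplyr::bind_rows(out)
  pairs[order(pairs$extubation_time, pairs$reintubation_time), ]
}

#' Classify one patient record
#'
#' Normalizes the record's entries and applies the signature. The verdict is
#' patient-level: any qualifying pair makes the patient positive, with the
#' first qualifying pair kept as evidence.
#'
#' @param record A [patient_record()].
#' @param sig An [signature()] object.
#' @param assoc_window_min Passed to [normalize_events()].
#' @return A one-row tibble (a failure call): `patient_id`, `admission_id`,
#'   `signature`, `positive`, and evidence columns `extubation_time`,
#'   `reintubation_time`, `delta_h`, `tube_type` (`NA` when negative).
#' @export
detect <- function(record, sig = final_signature(), assoc_window_min = 60) {
  events <- normalize_events(record, assoc_window_min = assoc_window_min)
  pairs <- qualifying_pairs(events, sig)
  if (nrow(pairs) > 0) {
    ev <- pairs[1, ]
    tibble(
      patient_id = record$patient_id, admission_id = record$admission_id,
      signature = sig$name, positive = TRUE,
      extubation_time = ev$extubation_time,
      reintubation_time = ev$reintubation_time,
      delta_h = ev$delta_h, tube_type = ev$tube_type
    )
  } else {
    tibble(
      patient_id = record$patient_id, admission_id = record$admission_id,
      signature = sig$name, positive = FALSE,
      extubation_time = parse_ts(NA_character_),
      reintubation_time = parse_ts(NA_character_),
      delta_h = NA_real_, tube_type = NA_character_
    )
  }
}

#' Classify a cohort
#'
#' @param records List of [patient_record()] objects.
#' @inheritParams detect
#' @return A tibble of failure calls, one row per record, order-preserving.
#' @export
classify_cohort <- function(records, sig = final_signature(),
                            assoc_window_min = 60) {
  calls <- dplyr::bind_rows(lapply(records, detect, sig = sig,
                                   assoc_window_min = assoc_window_min))
  if (nrow(calls) == 0) {
    calls <- detect(patient_record("__none__", "__none__"), sig)[0, ]
  }
  message(sprintf("%s signature: %d of %d patients positive",
                  sig$name, sum(calls$positive), nrow(calls)))
  calls
}

#' Write / read failure calls as CSV
#'
#' Columns: `patient_id,admission_id,signature,positive,extubation_time,reintubation_time,delta_h,tube_type`.
#'
#' @param calls Tibble from [classify_cohort()].
#' @param path CSV path.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  out$extubation_time <- format_ts(out$extubation_time)
  out$reintubation_time <- format_ts(out$reintubation_time)
  readr::write_csv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) data_error(sprintf("calls file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    admission_id = readr::col_character(),
    signature = readr::col_character(),
    positive = readr::col_logical(),
    extubation_time = readr::col_character(),
    reintubation_time = readr::col_character(),
    delta_h = readr::col_double(),
    tube_type = readr::col_character()
  ), progress = FALSE)
  raw$extubation_time <- parse_ts(raw$extubation_time)
  raw$reintubation_time <- parse_ts(raw$reintubation_time)
  raw
}
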