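# Term normalization: raw charted values -> airway events.
#
# Flow-sheet values are picklist-like tokens, so matching is whole-token and
# case-insensitive against closed vocabularies, never substring: "re-intubated"
# does not match "intubated". Tube types are carried on separate "Airway Tube
# Type" rows and joined to intubation events by charting time.

STATUS_EXTUBATION_TERMS <- c("extubation", "extubated")
STATUS_INTUBATION_TERMS <- c("intubation", "intubated", "inserted")

EVENT_CLASSES <- c("EXTUBATION", "INTUBATION", "OTHER")
TUBE_TYPES <- c("ENDOTRACHEAL", "TRACHEOSTOMY", "NASOTRACHEAL",
                "NASAL_TRUMPET", "UNKNOWN")

# Whitespace-delimited tokens with edge punctuation stripped; internal
# hyphens are kept so hyphenated compounds stay single tokens.
status_tokens <- function(value) {
  toks <- strsplit(tolower(value), "\\s+")[[1]]
  toks <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", toks)
  toks[nzchar(toks)]
}

classify_status_value <- function(value) {
  if (is.na(value)) return("OTHER")
  toks <- status_tokens(value)
  if (any(toks %in% STATUS_EXTUBATION_TERMS)) return("EXTUBATION")
  if (any(toks %in% STATUS_INTUBATION_TERMS)) return("INTUBATION")
  "OTHER"
}

classify_tube_value <- function(value) {
  if (is.na(value)) return("UNKNOWN")
  v <- tolower(value)
  if (grepl("endotracheal", v)) return("ENDOTRACHEAL")
  if (grepl("tracheostomy|tracheotomy", v)) return("TRACHEOSTOMY")
  if (grepl("nasotracheal", v)) return("NASOTRACHEAL")
  if (grepl("trumpet", v)) return("NASAL_TRUMPET")
  "UNKNOWN"
}

#' Normalize charted rows into airway events
#'
#' Every "Airway Tube Status" entry becomes one event: values token-matching
#' {extubation, extubated} yield `EXTUBATION`, {intubation, intubated,
#' inserted} yield `INTUBATION`, anything else yields `OTHER` (never an
#' error). Each intubation event is assigned the tube type of the "Airway
#' Tube Type" entry charted at the identical timestamp; failing that, the
#' nearest such entry within `assoc_window_min` minutes either side (a
#' distance tie resolves to the earlier entry); failing that, `UNKNOWN`.
#'
#' @param record A [patient_record()].
#' @param assoc_window_min Half-width, in minutes, of the window used to
#'   associate a tube-type row with an intubation charting (default 60).
#' @return A tibble of events (`timestamp`, `event_class`, `tube_type`,
#'   `location`, `source_row_index`), sorted by timestamp with file order
#'   breaking ties. `tube_type` is `NA` for non-intubation events.
#' @export
normalize_events <- function(record, assoc_window_min = 60) {
  ent <- record$entries
  row_lower <- tolower(ent$row_name)
  is_status <- row_lower == "airway tube status"
  is_type <- row_lower == "airway tube type"

  status <- ent[is_status, ]
  if (nrow(status) == 0) {
    return(tibble(
      patient_id = character(), admission_id = character(),
      timestamp = parse_ts(character()), event_class = character(),
      tube_type = character(), location = character(),
      source_row_index = integer()))
  }
  cls <- vapply(status$value, classify_status_value, character(1),
                USE.NAMES = FALSE)

  types <- ent[is_type, ]
  type_enum <- vapply(types$value, classify_tube_value, character(1),
                      USE.NAMES = FALSE)
  type_min <- as.numeric(types$timestamp) / 60

  tube <- rep(NA_character_, nrow(status))
  for (k in which(cls == "INTUBATION")) {
    tube[k] <- "UNKNOWN"
    if (nrow(types) == 0) next
    t_min <- as.numeric(status$timestamp[k]) / 60
    d <- type_min - t_min
    exact <- which(d == 0)
    if (length(exact) > 0) {
      tube[k] <- type_enum[exact[1]]
      next
    }
    inwin <- which(abs(d) <= assoc_window_min)
    if (length(inwin) > 0) {
      best <- inwin[abs(d[inwin]) == min(abs(d[inwin]))]
      # distance tie: the earlier-charted entry wins
      best <- best[order(type_min[best], types$row_index[best])][1]
      tube[k] <- type_enum[best]
    }
  }

  ord <- order(status$timestamp, status$row_index)
  tibble(
    patient_id = record$patient_id,
    admission_id = record$admission_id,
    timestamp = status$timestamp[ord],
    event_class = cls[ord],
    tube_type = tube[ord],
    location = toupper(status$location[ord]),
    source_row_index = status$row_index[ord]
  )
}
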