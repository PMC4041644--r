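# Independent oracles and small builders shared across the suite.

quietly <- function(expr) suppressWarnings(suppressMessages(expr))

ts_utc <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")

# Build a patient record from rows given as c(timestamp, row_name, value[, location]).
rec_from_rows <- function(rows, patient_id = "P1", ...) {
  ent <- tibble::tibble(
    row_index = seq_along(rows),
    timestamp = ts_utc(vapply(rows, `[[`, character(1), 1)),
    row_name = vapply(rows, `[[`, character(1), 2),
    value = vapply(rows, `[[`, character(1), 3),
    location = vapply(rows, function(r) if (length(r) >= 4) r[[4]] else "ICU",
                      character(1))
  )
  patient_record(patient_id, "A1", entries = ent, ...)
}

# Exhaustive pair enumeration: checks every (extubation, intubation) ordered
# pair against the signature's conditions directly, independent of the
# most-recent-prior-extubation shortcut used by qualifying_pairs().
brute_force_pairs <- function(events, sig) {
  ev <- events
  if (sig$icu_only) ev <- ev[toupper(ev$location) == "ICU", , drop = FALSE]
  found <- list()
  n <- nrow(ev)
  for (a in seq_len(n)) {
    if (n == 0 || ev$event_class[a] != "EXTUBATION") next
    for (b in seq_len(n)) {
      if (ev$event_class[b] != "INTUBATION") next
      if (!(ev$timestamp[b] > ev$timestamp[a])) next
      delta <- as.numeric(difftime(ev$timestamp[b], ev$timestamp[a],
                                   units = "hours"))
      if (delta > sig$window_h) next
      if (sig$require_endotracheal &&
          (is.na(ev$tube_type[b]) || ev$tube_type[b] != "ENDOTRACHEAL")) next
      intervening <- any(ev$event_class == "EXTUBATION" &
                           ev$timestamp > ev$timestamp[a] &
                           ev$timestamp < ev$timestamp[b])
      if (intervening) next
      found[[length(found) + 1L]] <- c(ext = ev$source_row_index[a],
                                       int = ev$source_row_index[b])
    }
  }
  if (length(found) == 0) {
    return(data.frame(ext = integer(), int = integer()))
  }
  out <- as.data.frame(do.call(rbind, found))
  out[order(out$ext, out$int), , drop = FALSE]
}

# Random normalized event stream of at most max_events events; caller seeds
# the RNG. Duplicate timestamps are possible on purpose.
random_event_stream <- function(max_events = 10) {
  n <- sample.int(max_events, 1)
  mins <- sort(sample(200 * 60, n, replace = TRUE))
  cls <- sample(c("EXTUBATION", "INTUBATION", "OTHER"), n, replace = TRUE,
                prob = c(0.35, 0.35, 0.3))
  tube <- ifelse(
    cls == "INTUBATION",
    sample(c("ENDOTRACHEAL", "TRACHEOSTOMY", "NASAL_TRUMPET", "UNKNOWN"),
           n, replace = TRUE),
    NA_character_)
  tibble::tibble(
    patient_id = "X", admission_id = "A1",
    timestamp = ts_utc("2010-01-01T00:00") + mins * 60,
    event_class = cls, tube_type = tube,
    location = sample(c("ICU", "OR", "ED"), n, replace = TRUE,
                      prob = c(0.7, 0.15, 0.15)),
    source_row_index = seq_len(n)
  )
}

# Clopper-Pearson by direct binomial tail-sum inversion (uniroot), kept
# independent of the qbeta closed form used by the package.
cp_tail_inversion <- function(successes, trials, conf_level = 0.95) {
  alpha <- (1 - conf_level) / 2
  lower <- if (successes == 0) 0 else {
    stats::uniroot(function(p) sum(stats::dbinom(successes:trials, trials, p)) - alpha,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  upper <- if (successes == trials) 1 else {
    stats::uniroot(function(p) sum(stats::dbinom(0:successes, trials, p)) - alpha,
                   c(1e-12, 1 - 1e-12), tol = 1e-10)$root
  }
  c(lower = lower, upper = upper)
}

pair_keys <- function(pairs) {
  # canonical representation for set comparison
  df <- data.frame(ext = pairs$extubation_row, int = pairs$reintubation_row)
  df[order(df$ext, df$int), , drop = FALSE]
}
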