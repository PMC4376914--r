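#' Risk domains used throughout the three study designs
#'
#' The five real-life risk domains (financial, health/safety, recreational,
#' ethical, social) that scenarios are drawn from.
#'
#' @return Character vector of the five canonical domain labels.
#' @export
risk_domains <- function() {
  c("financial", "health/safety", "recreational", "ethical", "social")
}

#' Declare rating-scale bounds for a trial table
#'
#' Builds the scale declaration that [read_trial_table()] and
#' [validate_trial_table()] use to check rating columns. Each argument is a
#' length-2 numeric `c(lower, upper)`; use `NULL` to skip checking a column.
#'
#' @param x Bounds for the predictor score (recoded thought valence on
#'   -2..2, imagery vividness on 1..10, or a mean IAI, depending on design).
#' @param stress Bounds for the stress rating.
#' @param risk_perception Bounds for the risk-perception rating.
#' @param risk_taking Bounds for the risk-taking rating (1..5 or 1..10
#'   depending on study).
#' @return A named list of bounds with class `"trial_scales"`.
#' @examples
#' trial_scales(x = c(-2, 2), risk_taking = c(1, 5))
#' @export
trial_scales <- function(x = c(-2, 2),
                         stress = c(1, 10),
                         risk_perception = c(1, 10),
                         risk_taking = c(1, 5)) {
  sc <- list(x = x, stress = stress,
             risk_perception = risk_perception, risk_taking = risk_taking)
  for (nm in names(sc)) {
    b <- sc[[nm]]
    if (!is.null(b) && (length(b) != 2 || !is.numeric(b) || b[1] >= b[2])) {
      stop("scale bounds for '", nm, "' must be numeric c(lower, upper)",
           call. = FALSE)
    }
  }
  structure(sc, class = "trial_scales")
}

# Sniff the field delimiter and decimal mark of a delimited text file.
# Supplementary tables in this literature come as TXT with locale-dependent
# separators (tab/comma/semicolon, decimal comma or point).
sniff_delim <- function(path) {
  lines <- readLines(path, n = 5L, warn = FALSE)
  if (length(lines) == 0) stop("file is empty: ", path, call. = FALSE)
  counts <- vapply(c("\t", ";", ","), function(d) {
    stats::median(vapply(lines, function(l) lengths(regmatches(l, gregexpr(d, l, fixed = TRUE))), 1L))
  }, 1.0)
  delim <- names(counts)[which.max(counts)]
  if (max(counts) == 0) delim <- "\t"
  # decimal comma only possible when the field separator is not a comma
  decimal <- "."
  if (delim != "," &&
      any(grepl("[0-9],[0-9]", lines[-1])) &&
      !any(grepl("[0-9]\\.[0-9]", lines[-1]))) {
    decimal <- ","
  }
  list(delim = delim, decimal = decimal)
}

read_delim_auto <- function(path) {
  fmt <- sniff_delim(path)
  readr::read_delim(
    path, delim = fmt$delim,
    locale = readr::locale(decimal_mark = fmt$decimal),
    show_col_types = FALSE, progress = FALSE,
    na = c("", "NA", "na", "n/a")
  )
}

#' Read a long-format trial table
#'
#' Reads one row per subject-by-scenario observation from delimited text
#' (tab, comma or semicolon separated; decimal comma tolerated) and validates
#' it against the declared rating scales. Mandatory columns are `subject_id`,
#' `item_id`, and at least one of the rating columns (`x`, `stress`,
#' `risk_perception`, `risk_taking`); `domain`, `stai` and `siri` are optional.
#'
#' @param path Path to a delimited text file with a header row.
#' @param scales A [trial_scales()] declaration.
#' @return A validated tibble (the trial table).
#' @seealso [validate_trial_table()]
#' @export
read_trial_table <- function(path, scales = trial_scales()) {
  tab <- read_delim_auto(path)
  if (!all(c("subject_id", "item_id") %in% names(tab))) {
    stop("schema error: trial table must have columns 'subject_id' and 'item_id'",
         call. = FALSE)
  }
  tab$subject_id <- as.character(tab$subject_id)
  tab$item_id <- as.character(tab$item_id)
  if (nrow(tab) == 0) {
    warning("trial table at '", path, "' has a header but no rows", call. = FALSE)
    return(tibble::as_tibble(tab))
  }
  validate_trial_table(tibble::as_tibble(tab), scales)
}

#' Validate a trial table
#'
#' Checks the structural invariants of a long-format trial table: rating
#' columns within their declared bounds, unique `(subject_id, item_id)` pairs,
#' subject-level covariates (`stai`, `siri`) constant within subject, and no
#' row with every outcome column missing.
#'
#' @param table A data frame of trial-level observations.
#' @param scales A [trial_scales()] declaration.
#' @return The table, invisibly as a tibble, if valid; otherwise an error
#'   naming the offending rows.
#' @export
validate_trial_table <- function(table, scales = trial_scales()) {
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0) return(invisible(table))
  key <- paste(table$subject_id, table$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("integrity error: duplicate (subject_id, item_id) pairs at rows ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  for (nm in intersect(names(scales), names(table))) {
    b <- scales[[nm]]
    if (is.null(b)) next
    v <- table[[nm]]
    bad <- which(!is.na(v) & (v < b[1] | v > b[2]))
    if (length(bad)) {
      stop("integrity error: column '", nm, "' outside declared scale [",
           b[1], ", ", b[2], "] at rows ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  for (cov in intersect(c("stai", "siri"), names(table))) {
    n_per <- tapply(table[[cov]], table$subject_id,
                    function(v) length(unique(v[!is.na(v)])))
    if (any(n_per > 1, na.rm = TRUE)) {
      stop("integrity error: covariate '", cov,
           "' varies within subject(s) ",
           paste(utils::head(names(n_per)[which(n_per > 1)], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  out_cols <- intersect(c("x", "stress", "risk_perception", "risk_taking"),
                        names(table))
  if (length(out_cols) == 0) {
    stop("schema error: no rating columns found (expected at least one of ",
         "x, stress, risk_perception, risk_taking)", call. = FALSE)
  }
  all_na <- rowSums(!is.na(table[out_cols])) == 0
  if (any(all_na)) {
    stop("integrity error: rows with all rating fields missing: ",
         paste(utils::head(which(all_na), 5), collapse = ", "), call. = FALSE)
  }
  invisible(table)
}

#' Read a cuff blood-pressure series
#'
#' Reads ordered systolic/diastolic readings with phase labels from delimited
#' text. Expected columns: `subject_id`, `phase` (one of `pre_baseline`,
#' `training`, `scenario`, `post_baseline`), `systolic`, `diastolic`, and
#' optionally `scenario_domain` for scenario readings. Acquisition order is
#' the file order within subject.
#'
#' @param path Path to a delimited text file with a header row.
#' @return A validated tibble of readings.
#' @export
read_bp_series <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("subject_id", "phase", "systolic", "diastolic")
  if (!all(need %in% names(tab))) {
    stop("schema error: blood-pressure series needs columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab$subject_id <- as.character(tab$subject_id)
  validate_bp_series(tibble::as_tibble(tab))
}

#' Validate a blood-pressure series
#'
#' Checks phase labels and that `systolic > diastolic > 0` for every reading.
#'
#' @param series A data frame of cuff readings.
#' @return The series, invisibly as a tibble, if valid.
#' @export
validate_bp_series <- function(series) {
  series <- tibble::as_tibble(series)
  ok_phase <- c("pre_baseline", "training", "scenario", "post_baseline")
  bad <- which(!series$phase %in% ok_phase)
  if (length(bad)) {
    stop("integrity error: unknown phase label at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(series$systolic > series$diastolic & series$diastolic > 0))
  if (length(bad)) {
    stop("domain error: need systolic > diastolic > 0; violated at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(series)
}

#' Validate PANAS pre/post records
#'
#' One row per subject with `pa_pre`, `pa_post`, `na_pre`, `na_post` scale
#' sums, each within the 10-item PANAS range of 10 to 50.
#'
#' @param records A data frame of PANAS records.
#' @return The records, invisibly as a tibble, if valid.
#' @export
validate_panas <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("subject_id", "pa_pre", "pa_post", "na_pre", "na_post")
  if (!all(need %in% names(records))) {
    stop("schema error: PANAS records need columns ",
         paste(setdiff(need, names(records)), collapse = ", "), call. = FALSE)
  }
  for (nm in need[-1]) {
    v <- records[[nm]]
    bad <- which(!is.na(v) & (v < 10 | v > 50))
    if (length(bad)) {
      stop("integrity error: '", nm, "' outside [10, 50] at rows ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(records)
}

#' Construct an EEG recording object
#'
#' Bundles a multichannel amplitude matrix with its event segments. Channels
#' are any ordered subset of the six montage sites Fp1, Fp2, P3, P4, O1, O2;
#' events use 0-based half-open sample intervals `[start_sample, end_sample)`.
#'
#' @param subject_id Subject label.
#' @param signal Numeric matrix, one column per channel, amplitudes in
#'   microvolts.
#' @param channels Character vector of channel names, one per signal column.
#' @param events Data frame with columns `segment_kind` (`baseline`,
#'   `listening` or `visualization`), `scenario_id`, `domain` (NA for
#'   baseline), `start_sample`, `end_sample`.
#' @param sampling_rate Sampling rate in Hz (canonical 200).
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(subject_id, signal, channels, events,
                          sampling_rate = 200) {
  signal <- as.matrix(signal)
  known <- c("Fp1", "Fp2", "P3", "P4", "O1", "O2")
  if (!all(channels %in% known)) {
    stop("schema error: unknown channel name(s): ",
         paste(setdiff(channels, known), collapse = ", "), call. = FALSE)
  }
  if (ncol(signal) != length(channels)) {
    stop("schema error: signal has ", ncol(signal), " columns but ",
         length(channels), " channel names", call. = FALSE)
  }
  colnames(signal) <- channels
  events <- tibble::as_tibble(events)
  kinds <- c("baseline", "listening", "visualization")
  if (!all(events$segment_kind %in% kinds)) {
    stop("schema error: unknown segment_kind", call. = FALSE)
  }
  if (any(events$start_sample < 0) || any(events$end_sample > nrow(signal))) {
    stop("integrity error: event segment lies outside the signal", call. = FALSE)
  }
  if (any(events$end_sample <= events$start_sample)) {
    stop("integrity error: empty or inverted event segment", call. = FALSE)
  }
  ev <- events[order(events$start_sample), ]
  if (nrow(ev) > 1 && any(ev$start_sample[-1] < ev$end_sample[-nrow(ev)])) {
    stop("integrity error: overlapping event segments", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id),
         sampling_rate = sampling_rate,
         channels = channels, signal = signal, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject", x$subject_id, "-",
      nrow(x$signal), "samples @", x$sampling_rate, "Hz,",
      length(x$channels), "channels (", paste(x$channels, collapse = ", "),
      "),", nrow(x$events), "events\n")
  invisible(x)
}

#' Read an EEG recording from a signal matrix and a JSON event sidecar
#'
#' The signal file is a delimited numeric matrix with a header row of channel
#' names (one column per channel, amplitudes in microvolts); the events file
#' is a JSON array of segment records with 0-based half-open sample indices.
#'
#' @param path_signal Path to the delimited signal matrix.
#' @param path_events Path to the JSON events sidecar.
#' @param subject_id Subject label (defaults to the signal file stem).
#' @param sampling_rate Sampling rate in Hz.
#' @return An [eeg_recording()] object with all invariants checked.
#' @export
read_eeg <- function(path_signal, path_events,
                     subject_id = sub("\\.[^.]*$", "", basename(path_signal)),
                     sampling_rate = 200) {
  sig <- read_delim_auto(path_signal)
  events <- jsonlite::fromJSON(path_events)
  events <- tibble::as_tibble(events)
  if (!"domain" %in% names(events)) events$domain <- NA_character_
  eeg_recording(subject_id, as.matrix(sig), names(sig), events, sampling_rate)
}

#' Write an EEG recording to disk
#'
#' Inverse of [read_eeg()]: a TSV signal matrix plus a JSON event sidecar.
#'
#' @param recording An [eeg_recording()] object.
#' @param path_signal,path_events Output paths.
#' @return The recording, invisibly.
#' @export
write_eeg <- function(recording, path_signal, path_events) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(recording$signal)),
                   path_signal, progress = FALSE)
  jsonlite::write_json(recording$events, path_events,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(recording)
}

#' Write an analysis result to structured JSON
#'
#' Serializes any result object (mediation, moderation, ANOVA tables, study
#' bundles) to JSON, attaching a reproducibility fingerprint (package version,
#' R version, timestamp). Numbers are written at full precision so a read-back
#' reproduces the written values exactly.
#'
#' @param result A result object or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(result, path) {
  payload <- list(
    result = strip_for_json(result),
    fingerprint = list(
      package = "riskimagery",
      version = as.character(utils::packageVersion("riskimagery")),
      r_version = as.character(getRversion())
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", force = TRUE)
  invisible(path)
}

# drop heavy model objects / functions before serialization
strip_for_json <- function(x) {
  if (inherits(x, "merMod")) return(NULL)
  if (is.function(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    out <- lapply(x, strip_for_json)
    out[!vapply(out, is.null, TRUE)]
  } else x
}

#' Read back a result JSON written by [write_results()]
#'
#' @param path Path to the JSON file.
#' @return A list with elements `result` and `fingerprint`.
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
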