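#' HFO event subtypes and patient outcome labels
#'
#' The closed vocabulary of high-frequency-oscillation event subtypes:
#' ripples on oscillations (`RonO`), ripples on spikes (`RonS`), fast
#' ripples on oscillations (`fRonO`), fast ripples on spikes (`fRonS`), and
#' epileptiform sharp spikes without true oscillatory content
#' (`sharp_spike`). Catalog rows with any other subtype string are rejected
#' at load time.
#'
#' @return Character vector of valid subtype (or outcome) labels.
#' @export
hfo_subtypes <- function() c("RonO", "RonS", "fRonO", "fRonS", "sharp_spike")

#' @rdname hfo_subtypes
#' @export
outcome_levels <- function() c("responder", "non_responder", "no_resection_rns", "unknown")

#' Fixed anatomical region coding table
#'
#' Regions are entered into mixed-effects models as a numeric location code.
#' The coding is an ordered lookup table so it can be replaced wholesale;
#' the mapping itself carries no anatomical meaning beyond identity.
#'
#' @return Data frame with columns `region` and `code`.
#' @export
region_codes <- function() {
  regions <- c("mesial_temporal", "lateral_temporal", "frontal", "parietal",
               "occipital", "insula", "cingulate", "limbic")
  data.frame(region = regions, code = seq_along(regions))
}

#' Construct a validated patient record
#'
#' A patient record bundles the contact table (MNI coordinates, anatomical
#' region, SOZ flag), the HFO event catalog, the analyzed recording
#' duration, and the surgical outcome label. All invariants are enforced at
#' construction: unique contact ids, finite coordinates, event onsets within
#' the recording, positive peak frequencies, and subtype/outcome labels
#' drawn from the closed vocabularies.
#'
#' @param patient_id Character scalar.
#' @param contacts Data frame with columns `contact_id`, `x`, `y`, `z`
#'   (MNI mm), `region`, `is_soz` (logical).
#' @param events Data frame with columns `contact_id`, `onset_s`, `subtype`,
#'   `peak_freq_hz`, `peak_power`, `duration_ms`. May have zero rows.
#' @param duration_min Analyzed recording duration in minutes (> 0).
#' @param outcome One of [outcome_levels()].
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, contacts, events, duration_min,
                           outcome = "unknown") {
  if (!is.character(patient_id) || length(patient_id) != 1L)
    stop_schema("patient_id must be a single string")
  need_c <- c("contact_id", "x", "y", "z", "region", "is_soz")
  miss <- setdiff(need_c, names(contacts))
  if (length(miss)) stop_schema("contacts missing column(s): ",
                                paste(miss, collapse = ", "))
  need_e <- c("contact_id", "onset_s", "subtype", "peak_freq_hz",
              "peak_power", "duration_ms")
  miss <- setdiff(need_e, names(events))
  if (length(miss)) stop_schema("events missing column(s): ",
                                paste(miss, collapse = ", "))
  contacts <- as.data.frame(contacts)[, need_c]
  events <- as.data.frame(events)[, need_e]
  contacts$contact_id <- as.character(contacts$contact_id)
  contacts$is_soz <- as.logical(contacts$is_soz)
  events$contact_id <- as.character(events$contact_id)
  events$subtype <- as.character(events$subtype)

  if (anyDuplicated(contacts$contact_id))
    stop_integrity("duplicate contact_id in contacts table")
  if (!all(is.finite(as.matrix(contacts[, c("x", "y", "z")]))))
    stop_integrity("non-finite MNI coordinates")
  if (any(is.na(contacts$is_soz)))
    stop_integrity("is_soz must be TRUE/FALSE")
  if (!is.numeric(duration_min) || length(duration_min) != 1L ||
      !is.finite(duration_min) || duration_min <= 0)
    stop("duration_min must be a positive number")
  if (!outcome %in% outcome_levels())
    stop_schema("unknown outcome label: ", outcome)

  if (nrow(events)) {
    bad <- setdiff(events$contact_id, contacts$contact_id)
    if (length(bad))
      stop_integrity("events reference unknown contact(s): ",
                     paste(unique(bad), collapse = ", "))
    bad_sub <- setdiff(events$subtype, hfo_subtypes())
    if (length(bad_sub))
      stop_integrity("unknown event subtype(s): ",
                     paste(unique(bad_sub), collapse = ", "))
    if (any(!is.finite(events$onset_s)) || any(events$onset_s < 0) ||
        any(events$onset_s > duration_min * 60))
      stop_integrity("event onset_s outside [0, recording duration]")
    if (any(!is.finite(events$peak_freq_hz)) || any(events$peak_freq_hz <= 0))
      stop_integrity("peak_freq_hz must be positive")
  }
  rownames(contacts) <- NULL
  rownames(events) <- NULL
  structure(list(patient_id = patient_id, contacts = contacts,
                 events = events, duration_min = duration_min,
                 outcome = outcome),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %d contacts (%d SOZ), %d events, %.1f min, %s>\n",
              x$patient_id, nrow(x$contacts), sum(x$contacts$is_soz),
              nrow(x$events), x$duration_min, x$outcome))
  invisible(x)
}

#' Read and write patient records as CSV + JSON
#'
#' The on-disk form is an event-catalog CSV
#' (`contact_id,onset_s,subtype,peak_freq_hz,peak_power,duration_ms`), a
#' contact-table CSV (`contact_id,x_mni,y_mni,z_mni,region,is_soz` with
#' `is_soz` coded 0/1), and a metadata JSON with keys `patient_id`,
#' `duration_min`, `outcome`. `write_patient()` emits the three files into
#' `dir` named `<patient_id>_events.csv`, `<patient_id>_contacts.csv`,
#' `<patient_id>_meta.json`; `read_patient()` validates on load, so a write
#' followed by a read reproduces the record exactly.
#'
#' @param catalog_path,contacts_path,meta_path Paths to the three files.
#' @param record A [patient_record()].
#' @param dir Output directory (created if needed).
#' @return `read_patient()` returns a `patient_record`; `write_patient()`
#'   invisibly returns the three paths written.
#' @export
read_patient <- function(catalog_path, contacts_path, meta_path) {
  events <- read.csv(catalog_path, stringsAsFactors = FALSE)
  contacts <- read.csv(contacts_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (k in c("patient_id", "duration_min", "outcome"))
    if (is.null(meta[[k]])) stop_schema("metadata missing key: ", k)
  need <- c("contact_id", "x_mni", "y_mni", "z_mni", "region", "is_soz")
  miss <- setdiff(need, names(contacts))
  if (length(miss)) stop_schema("contacts missing column(s): ",
                                paste(miss, collapse = ", "))
  names(contacts)[match(c("x_mni", "y_mni", "z_mni"), names(contacts))] <-
    c("x", "y", "z")
  contacts$is_soz <- contacts$is_soz == 1
  patient_record(as.character(meta$patient_id), contacts, events,
                 as.numeric(meta$duration_min), as.character(meta$outcome))
}

#' @rdname read_patient
#' @export
write_patient <- function(record, dir) {
  stopifnot(inherits(record, "patient_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pid <- record$patient_id
  paths <- file.path(dir, paste0(pid, c("_events.csv", "_contacts.csv", "_meta.json")))
  write.csv(record$events, paths[1], row.names = FALSE, quote = FALSE)
  ct <- record$contacts
  out <- data.frame(contact_id = ct$contact_id, x_mni = ct$x, y_mni = ct$y,
                    z_mni = ct$z, region = ct$region,
                    is_soz = as.integer(ct$is_soz))
  write.csv(out, paths[2], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(patient_id = pid,
                            duration_min = record$duration_min,
                            outcome = record$outcome),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Event filter specification
#'
#' An event filter selects catalog events by subtype and, optionally, by a
#' strict peak-spectral-frequency threshold. The default selects fast-ripple
#' events (`fRonO` and `fRonS` combined) with peak frequency strictly above
#' 350 Hz, the filter used throughout the network analyses: a 350.0 Hz
#' event is excluded.
#'
#' @param subtypes Non-empty subset of [hfo_subtypes()].
#' @param min_freq_hz Strict lower frequency bound in Hz, or `NULL` for no
#'   frequency restriction.
#' @return A list of class `fr_filter`.
#' @export
fr_filter <- function(subtypes = c("fRonO", "fRonS"), min_freq_hz = 350) {
  if (!length(subtypes)) stop("subtypes must be non-empty")
  bad <- setdiff(subtypes, hfo_subtypes())
  if (length(bad)) stop_schema("unknown subtype(s): ", paste(bad, collapse = ", "))
  structure(list(subtypes = subtypes, min_freq_hz = min_freq_hz),
            class = "fr_filter")
}

#' Filter catalog events by subtype and peak frequency
#'
#' @param record A [patient_record()].
#' @param subtypes Subtypes to keep, or an [fr_filter()] object (in which
#'   case `min_freq_hz` is taken from it).
#' @param min_freq_hz Strict threshold: events are kept when
#'   `peak_freq_hz > min_freq_hz`. `NULL` keeps all frequencies.
#' @return The event data frame restricted to matching rows, original order
#'   preserved.
#' @export
filter_events <- function(record, subtypes = fr_filter(), min_freq_hz = NULL) {
  if (inherits(subtypes, "fr_filter")) {
    min_freq_hz <- subtypes$min_freq_hz
    subtypes <- subtypes$subtypes
  }
  if (!length(subtypes)) stop("subtypes must be non-empty")
  ev <- record$events
  keep <- ev$subtype %in% subtypes
  if (!is.null(min_freq_hz)) keep <- keep & ev$peak_freq_hz > min_freq_hz
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-contact event rates
#'
#' Computes, for every contact in the record, the rate of filtered events in
#' events per minute: filtered event count divided by the analyzed recording
#' duration. Contacts with no matching events appear with rate 0.
#'
#' @param record A [patient_record()].
#' @param event_filter An [fr_filter()].
#' @return Data frame with columns `contact_id`, `n_events`, `rate`
#'   (events/min), one row per contact in contact-table order.
#' @export
compute_rates <- function(record, event_filter = fr_filter()) {
  if (record$duration_min <= 0) stop("duration_min must be positive")
  ev <- filter_events(record, event_filter)
  counts <- table(factor(ev$contact_id, levels = record$contacts$contact_id))
  data.frame(contact_id = record$contacts$contact_id,
             n_events = as.integer(counts),
             rate = as.numeric(counts) / record$duration_min)
}
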