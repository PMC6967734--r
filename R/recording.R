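#' Canonical analysis montage
#'
#' The eight 10-20 channels analysed by the pipeline, in the fixed canonical
#' order all downstream indexing relies on: prefrontal (Fp1, Fp2), frontal
#' (F5, F6, Fz), parietal (P5, P6, Pz).
#'
#' @return character vector of length 8.
#' @export
analysis_montage <- function() {
  c("Fp1", "Fp2", "F5", "F6", "Fz", "P5", "P6", "Pz")
}

#' Region channel groups
#'
#' @return named list with `prefrontal`, `frontal`, `parietal` label sets.
#' @export
region_channels <- function() {
  list(prefrontal = c("Fp1", "Fp2"),
       frontal    = c("F5", "F6", "Fz"),
       parietal   = c("P5", "P6", "Pz"))
}

#' Construct an EEG recording
#'
#' @param subject_id subject identifier.
#' @param fs sampling rate, Hz.
#' @param channels ordered channel labels (10-20 names).
#' @param samples channels x time numeric matrix, microvolts.
#' @param events data frame with columns `label` (character) and `time`
#'   (seconds from record start), non-decreasing.
#' @return object of class `recording`.
#' @export
recording <- function(subject_id, fs, channels, samples,
                      events = data.frame(label = character(),
                                          time = numeric())) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("metadata error: sampling rate must be a single positive number")
  if (anyDuplicated(channels))
    stopf("metadata error: duplicate channel label(s): %s",
          paste(unique(channels[duplicated(channels)]), collapse = ", "))
  if (nrow(samples) != length(channels))
    stopf("shape error: %d sample rows for %d channels",
          nrow(samples), length(channels))
  dur <- ncol(samples) / fs
  ev <- as.data.frame(events)
  if (nrow(ev)) {
    if (is.unsorted(ev$time))
      stopf("event error: event times must be non-decreasing")
    if (any(ev$time < 0 | ev$time > dur))
      stopf("event error: event time outside [0, %.3f]", dur)
  }
  structure(list(subject_id = as.character(subject_id), fs = fs,
                 channels = as.character(channels), samples = samples,
                 events = ev),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d ch x %d samples @ %g Hz (%.1f s), %d event(s)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, nrow(x$events)))
  invisible(x)
}

duration <- function(rec) ncol(rec$samples) / rec$fs

#' Read an EEG recording
#'
#' Reads either the plain tabular dialect (one column per channel; a one-line
#' header carrying the sampling rate and the channel labels) or an EDF /
#' EDF+ file. Events come from EDF+ annotations when present, or from a
#' sibling two-column events file (label, seconds).
#'
#' @param path file path.
#' @param format `"tabular"` or `"edf"`.
#' @param events_path optional path to a delimited events file.
#' @param subject_id subject identifier; defaults to the file stem.
#' @return a [recording].
#' @export
read_recording <- function(path, format = c("tabular", "edf"),
                           events_path = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("format error: file not found: %s", path)
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  rec <- switch(format,
                tabular = read_tabular(path, subject_id),
                edf = read_edf(path, subject_id))
  if (!is.null(events_path)) {
    ev <- read_events(events_path)
    rec <- recording(rec$subject_id, rec$fs, rec$channels, rec$samples,
                     rbind(rec$events, ev))
  }
  rec
}

# Tabular dialect: tab-separated; line 1 is "fs=<Hz>\t<ch1>\t<ch2>..."; data
# rows are one sample per line, one column per channel.
read_tabular <- function(path, subject_id) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2L || !grepl("^fs=", hdr[1]))
    stopf("metadata error: tabular header must be 'fs=<Hz>' followed by channel labels")
  fs <- suppressWarnings(as.numeric(sub("^fs=", "", hdr[1])))
  if (is.na(fs)) stopf("metadata error: unparseable sampling rate in %s", path)
  channels <- hdr[-1]
  dat <- utils::read.table(path, sep = "\t", skip = 1L,
                           colClasses = "numeric")
  if (ncol(dat) != length(channels))
    stopf("format error: %d data columns for %d header channels",
          ncol(dat), length(channels))
  recording(subject_id, fs, channels, t(as.matrix(dat)))
}

#' Write a recording in the tabular dialect
#'
#' @param rec a [recording].
#' @param path output path.
#' @param events_path optional path for a sibling events file.
#' @export
write_tabular <- function(rec, path, events_path = NULL) {
  hdr <- paste(c(sprintf("fs=%.10g", rec$fs), rec$channels), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(t(rec$samples), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(events_path))
    utils::write.table(rec$events, events_path, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column events file (label, seconds)
#' @param path file path.
#' @return data frame with `label`, `time`.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", col.names = c("label", "time"),
                          colClasses = c("character", "numeric"))
  ev[order(ev$time), , drop = FALSE]
}

#' Extract the anesthetic-maintenance epoch
#'
#' Crops a recording to the interval from `start_offset` seconds after the
#' start event to the end event, and reduces the montage to the eight
#' canonical analysis channels.
#'
#' @param rec a [recording].
#' @param start_label event label marking epoch start (e.g. skin incision).
#' @param end_label event label marking end of maintenance.
#' @param start_offset seconds added to the start event time; default 30.
#' @return object of class `maintenance_epoch` with fields `subject_id`,
#'   `fs`, `channels`, `samples`, `t0`, `t1`.
#' @export
extract_maintenance <- function(rec, start_label, end_label,
                                start_offset = 30) {
  tfor <- function(lab) {
    hit <- rec$events$time[rec$events$label == lab]
    if (!length(hit)) stopf("event error: no event labelled '%s'", lab)
    hit[1]
  }
  t0 <- tfor(start_label) + start_offset
  t1 <- tfor(end_label)
  if (t1 - t0 < 30)
    stopf("epoch-too-short error: maintenance epoch is %.1f s (< 30 s)", t1 - t0)
  want <- analysis_montage()
  missing <- setdiff(want, rec$channels)
  if (length(missing))
    stopf("montage error: recording lacks channel(s): %s",
          paste(missing, collapse = ", "))
  i0 <- floor(t0 * rec$fs) + 1L
  i1 <- min(floor(t1 * rec$fs), ncol(rec$samples))
  sel <- match(want, rec$channels)
  structure(list(subject_id = rec$subject_id, fs = rec$fs, channels = want,
                 samples = rec$samples[sel, i0:i1, drop = FALSE],
                 t0 = t0, t1 = t1),
            class = "maintenance_epoch")
}

#' @export
print.maintenance_epoch <- function(x, ...) {
  cat(sprintf("<maintenance_epoch> %s: [%.1f, %.1f] s, %.1f s @ %g Hz\n",
              x$subject_id, x$t0, x$t1, ncol(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Resample a recording
#'
#' Anti-aliased zero-phase resampling to a lower rate. The rate ratio must be
#' rational with small terms (e.g. 500 -> 250 Hz). The signal is zero-stuffed
#' by the upsampling factor where needed, low-pass filtered with a linear-phase
#' FIR applied forward-backward (no group delay), and decimated.
#'
#' @param rec a [recording] (or `maintenance_epoch`).
#' @param target_fs target sampling rate, Hz; must not exceed `rec$fs`.
#' @return resampled object of the same class.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs)
    stopf("unsupported-rate error: upsampling %g -> %g Hz not supported",
          rec$fs, target_fs)
  if (isTRUE(all.equal(target_fs, rec$fs))) return(rec)
  rat <- ratio_terms(target_fs, rec$fs)
  L <- rat[1]; M <- rat[2]
  out <- t(apply(rec$samples, 1L, function(v) resample_1d(v, L, M)))
  rec$fs <- target_fs
  rec$samples <- out
  rec
}

# smallest L/M with target/source == L/M (terms <= 1000)
ratio_terms <- function(target, source) {
  for (L in 1:1000) {
    M <- L * source / target
    if (abs(M - round(M)) < 1e-9) return(c(L, as.integer(round(M))))
  }
  stopf("unsupported-rate error: %g/%g is not a small rational ratio",
        target, source)
}

resample_1d <- function(x, L, M) {
  n <- length(x)
  if (L > 1L) {
    up <- numeric(n * L)
    up[seq(1L, length(up), by = L)] <- x
  } else up <- x
  ord <- max(64L, 16L * max(L, M))
  h <- as.numeric(signal::fir1(ord, 1 / max(L, M)))
  flt <- signal::filtfilt(h, 1, up) * L
  flt[seq(1L, length(flt), by = M)]
}

#' Construct per-subject metadata
#'
#' @param subject_id subject identifier.
#' @param age age in years (study inclusion requires >= 18).
#' @param nitrous logical, nitrous oxide used.
#' @param agent_fractions named numeric vector of end-tidal fractions (vol%).
#' @param mac_age_adjusted optional precomputed age-adjusted MAC multiple.
#' @return object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, age, nitrous = FALSE,
                         agent_fractions = numeric(), mac_age_adjusted = NULL) {
  if (age < 18) warning("subject age below the study inclusion bound (18 y)")
  if (any(agent_fractions < 0))
    stopf("metadata error: negative agent fraction")
  structure(list(subject_id = as.character(subject_id), age = age,
                 nitrous = isTRUE(nitrous), agent_fractions = agent_fractions,
                 mac_age_adjusted = mac_age_adjusted),
            class = "subject_meta")
}

#' Collect subject metadata into a cohort table
#' @param metas list of [subject_meta] objects.
#' @return data frame with subject_id, age, nitrous, mac.
#' @export
meta_table <- function(metas) {
  do.call(rbind, lapply(metas, function(m)
    data.frame(subject_id = m$subject_id, age = m$age, nitrous = m$nitrous,
               mac = m$mac_age_adjusted %||% NA_real_)))
}
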